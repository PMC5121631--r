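## Bipartite orchid-fungus network: construction, the modularity index
##   M = sum_s [ l_s / L - (d_s / 2L)^2 ],
## simulated-annealing module detection over joint partitions of species
## and OTU nodes, and degree-preserving null-model significance.

#' Build a bipartite species-by-OTU network
#'
#' @param x either a named list mapping species to character vectors of OTU
#'   ids (the output of [prevalence_by_group]) or a binary species-by-OTU
#'   matrix. Isolated nodes (species without OTUs, OTUs without species) are
#'   pruned with a warning. Species and OTU identifiers must not collide.
#' @return object of class `bipartite_network`: list with `incidence`
#'   (binary matrix species x OTUs), `L` (number of links) and `degrees`
#'   (named vector over all nodes).
#' @export
build_network <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    if (length(x) == 0) stop("empty prevalence mapping")
    otus <- sort(unique(unlist(x, use.names = FALSE)))
    if (length(otus) == 0) stop("no OTUs in prevalence mapping")
    inc <- matrix(0L, length(x), length(otus),
                  dimnames = list(names(x), otus))
    for (sp in names(x)) inc[sp, x[[sp]]] <- 1L
  } else {
    inc <- (unclass(x) > 0) + 0L
    if (is.null(rownames(inc)) || is.null(colnames(inc)))
      stop("incidence matrix must have row and column names")
  }
  iso_sp <- rownames(inc)[rowSums(inc) == 0]
  iso_otu <- colnames(inc)[colSums(inc) == 0]
  if (length(iso_sp) + length(iso_otu) > 0) {
    warning("pruning isolated node(s): ",
            paste(c(iso_sp, iso_otu), collapse = ", "))
    inc <- inc[rowSums(inc) > 0, colSums(inc) > 0, drop = FALSE]
  }
  if (nrow(inc) < 2 || ncol(inc) < 2)
    stop("network needs at least 2 species and 2 OTUs after pruning")
  if (length(intersect(rownames(inc), colnames(inc))) > 0)
    stop("species and OTU identifiers collide: ",
         paste(intersect(rownames(inc), colnames(inc)), collapse = ", "))
  structure(list(
    incidence = inc,
    L = sum(inc),
    degrees = c(setNames(rowSums(inc), rownames(inc)),
                setNames(colSums(inc), colnames(inc)))
  ), class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("Bipartite network: %d species x %d OTUs, L = %d links (connectance %.3f)\n",
              nrow(x$incidence), ncol(x$incidence), x$L,
              x$L / length(x$incidence)))
  invisible(x)
}

## Internal edge list (0-based) over joint node indexing: species first.
network_edges <- function(net) {
  idx <- which(net$incidence == 1L, arr.ind = TRUE)
  list(i = idx[, 1] - 1L,
       j = nrow(net$incidence) + idx[, 2] - 1L,
       nodes = c(rownames(net$incidence), colnames(net$incidence)))
}

#' Modularity of a partition of a bipartite network
#'
#' Evaluates `M = sum_s [ l_s / L - (d_s / 2L)^2 ]` where `L` is the number
#' of links, `l_s` the number of links with both endpoints in module `s` and
#' `d_s` the summed degrees of the nodes of module `s`. Links spanning two
#' modules contribute to no `l_s`. `M = 0` exactly for the single-module
#' partition, and `M <= 1 - 1/N_M` for any partition into `N_M` modules.
#'
#' @param net a [build_network] object.
#' @param assignment named integer/character vector mapping every node
#'   (species and OTU ids) to a module label.
#' @return numeric modularity value.
#' @export
modularity_index <- function(net, assignment) {
  e <- network_edges(net)
  missing <- setdiff(e$nodes, names(assignment))
  if (length(missing) > 0)
    stop("node(s) missing from assignment: ", paste(missing, collapse = ", "))
  mem <- as.integer(factor(assignment[e$nodes]))
  L <- net$L
  same <- mem[e$i + 1L] == mem[e$j + 1L]
  l_s <- tapply(same, mem[e$i + 1L], sum)  # internal links keyed by module
  d_s <- tapply(net$degrees[e$nodes], mem, sum)
  l_full <- setNames(numeric(length(d_s)), names(d_s))
  l_full[names(l_s)] <- l_s
  sum(l_full / L - (d_s / (2 * L))^2)
}

#' Module partition of a bipartite network
#'
#' Bundles a node-to-module assignment with its bookkeeping (`l_s`, `d_s`,
#' `L`) and modularity `M`. Module labels are canonical: modules are
#' numbered by decreasing size, ties broken by their lexicographically
#' smallest member, so equal partitions compare equal.
#'
#' @param net a [build_network] object.
#' @param assignment named vector mapping every node to a module.
#' @return object of class `module_partition` with elements `assignment`
#'   (named integer vector), `n_modules`, `l_s`, `d_s`, `L`, `M`.
#' @export
module_partition <- function(net, assignment) {
  e <- network_edges(net)
  nodes <- e$nodes
  missing <- setdiff(nodes, names(assignment))
  if (length(missing) > 0)
    stop("node(s) missing from assignment: ", paste(missing, collapse = ", "))
  raw <- as.integer(factor(assignment[nodes]))
  ## canonical labels: by decreasing size, then smallest member name
  sizes <- table(raw)
  first <- vapply(split(nodes, raw), function(v) min(v), character(1))
  ord <- order(-as.integer(sizes), first[names(sizes)])
  relab <- integer(length(sizes))
  relab[as.integer(names(sizes))[ord]] <- seq_along(ord)
  mem <- setNames(relab[raw], nodes)

  L <- net$L
  same <- mem[e$i + 1L] == mem[e$j + 1L]
  n_mod <- max(mem)
  l_s <- vapply(seq_len(n_mod), function(s)
    sum(same & mem[e$i + 1L] == s), numeric(1))
  d_s <- vapply(seq_len(n_mod), function(s)
    sum(net$degrees[nodes][mem == s]), numeric(1))
  stopifnot(sum(d_s) == 2 * L)
  M <- sum(l_s / L - (d_s / (2 * L))^2)
  structure(list(assignment = mem, n_modules = n_mod,
                 l_s = l_s, d_s = d_s, L = L, M = M),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("Module partition: %d modules, M = %.4f (L = %d links)\n",
              x$n_modules, x$M, x$L))
  sizes <- table(x$assignment)
  cat("  module sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Simulated-annealing schedule parameters
#'
#' Defaults follow the usual design of annealing-based module detection:
#' the initial temperature is auto-scaled so that roughly 97% of worsening
#' single-node moves are accepted at the start, geometric cooling by factor
#' `cooling`, `move_factor * n^2` single-node moves and `move_factor * n`
#' collective (merge / random split) moves per temperature, and a stop after
#' `patience` consecutive temperatures without improvement of the best
#' partition. A final greedy polish (best single-node moves and merges to a
#' local optimum) is always applied.
#'
#' @param t0 initial temperature, or `NULL` to auto-scale.
#' @param cooling geometric cooling factor in (0, 1).
#' @param move_factor effort multiplier `f`.
#' @param patience temperatures without improvement before stopping.
#' @param t_min hard floor for the temperature.
#' @param max_temps hard cap on the number of temperature steps.
#' @return list of class `sa_schedule`.
#' @export
sa_schedule <- function(t0 = NULL, cooling = 0.995, move_factor = 1,
                        patience = 3, t_min = 1e-7, max_temps = 10000) {
  if (cooling <= 0 || cooling >= 1)
    stop("cooling factor must lie in (0, 1)")
  if (move_factor <= 0) stop("move_factor must be positive")
  structure(list(t0 = t0, cooling = cooling, move_factor = move_factor,
                 patience = patience, t_min = t_min, max_temps = max_temps),
            class = "sa_schedule")
}

#' Detect modules by simulated annealing
#'
#' Maximises the modularity index over joint partitions of species and OTU
#' nodes (modules may and usually do contain both) by simulated annealing:
#' single-node reassignments plus module merges and random splits, accepting
#' worsening moves with probability `exp(dM / T)`; the best partition seen
#' is greedily polished to a local optimum. The whole procedure is run
#' `n_restarts` times from independent sub-seeds and the highest-M partition
#' is returned. Deterministic given `seed`.
#'
#' @param net a [build_network] object.
#' @param seed integer seed or `NULL` (a seed is then drawn from the
#'   session RNG).
#' @param schedule an [sa_schedule].
#' @param n_restarts independent annealing runs; the best is kept.
#' @return a [module_partition].
#' @export
detect_modules <- function(net, seed = NULL, schedule = sa_schedule(),
                           n_restarts = 5) {
  if (!inherits(net, "bipartite_network")) stop("not a bipartite_network")
  if (!inherits(schedule, "sa_schedule")) schedule <- do.call(sa_schedule, schedule)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  e <- network_edges(net)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    res <- sa_detect_cpp(e$i, e$j, length(e$nodes),
                         as.integer(net$degrees[e$nodes]),
                         schedule$t0 %||% -1, schedule$cooling,
                         schedule$move_factor, schedule$patience,
                         schedule$t_min, schedule$max_temps,
                         as.integer(derive_seed(seed, r) %% .Machine$integer.max))
    if (is.null(best) || res$M > best$M) best <- res
  }
  module_partition(net, setNames(best$membership, e$nodes))
}

#' Degree-preserving randomisation of a bipartite network
#'
#' Produces a random network with exactly the same species and OTU degree
#' sequences via checkerboard trial swaps: a uniformly chosen 2x2 submatrix
#' is swapped whenever it is a checkerboard (`[[1,0],[0,1]]` or its mirror).
#' Because the proposal is symmetric, the chain's stationary distribution is
#' uniform over all fillings with the observed margins. Deterministic given
#' `seed`.
#'
#' @param net a [build_network] object.
#' @param n_swaps number of trial swaps; defaults to `10 * L`.
#' @param seed integer seed or `NULL`.
#' @return a new `bipartite_network` with identical margins.
#' @export
randomize_network <- function(net, n_swaps = NULL, seed = NULL) {
  if (!inherits(net, "bipartite_network")) stop("not a bipartite_network")
  n_swaps <- n_swaps %||% (10 * net$L)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  res <- checkerboard_swap_cpp(net$incidence, as.integer(n_swaps),
                               as.integer(seed %% .Machine$integer.max))
  if (res$n_successful == 0 && !has_checkerboard(net$incidence))
    warning("no swappable checkerboard; returning an identical copy")
  m <- res$matrix
  dimnames(m) <- dimnames(net$incidence)
  build_network(m)
}

## Exhaustive scan for any swappable 2x2 checkerboard (small matrices only).
has_checkerboard <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  for (r1 in seq_len(nr - 1)) for (r2 in (r1 + 1):nr)
    for (c1 in seq_len(nc - 1)) for (c2 in (c1 + 1):nc) {
      a <- m[r1, c1]; b <- m[r1, c2]; cc <- m[r2, c1]; d <- m[r2, c2]
      if (a == d && b == cc && a != b) return(TRUE)
    }
  FALSE
}

#' Significance of network modularity against a degree-preserving null
#'
#' Detects modules on the observed network and on `n_null` independent
#' degree-preserving randomisations (identical annealing schedule for
#' observed and null networks) and reports
#' `p = (1 + #\{null M >= M_obs\}) / (1 + n_null)`.
#'
#' @param net a [build_network] object.
#' @param n_null number of null networks (999 for a p floor of 0.001).
#' @param seed integer seed or `NULL`; null draws and their annealing runs
#'   derive their own sub-seeds from it.
#' @param schedule an [sa_schedule] used for observed and null networks.
#' @param n_swaps trial swaps per null draw; defaults to `10 * L`.
#' @param n_restarts annealing restarts, identical for observed and nulls.
#' @return object of class `modularity_significance`: list with `M_obs`,
#'   `partition` (observed [module_partition]), `null_Ms`, `null_mean`,
#'   `null_sd`, `p_value`, `n_null`.
#' @export
modularity_significance <- function(net, n_null = 999, seed = NULL,
                                    schedule = sa_schedule(),
                                    n_swaps = NULL, n_restarts = 5) {
  if (n_null < 1) stop("n_null must be >= 1")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  obs <- detect_modules(net, seed = derive_seed(seed, 0), schedule = schedule,
                        n_restarts = n_restarts)
  null_Ms <- vapply(seq_len(n_null), function(b) {
    rnet <- randomize_network(net, n_swaps = n_swaps,
                              seed = derive_seed(seed, 2 * b))
    detect_modules(rnet, seed = derive_seed(seed, 2 * b + 1),
                   schedule = schedule, n_restarts = n_restarts)$M
  }, numeric(1))
  structure(list(M_obs = obs$M, partition = obs, null_Ms = null_Ms,
                 null_mean = mean(null_Ms), null_sd = sd(null_Ms),
                 p_value = (1 + sum(null_Ms >= obs$M)) / (1 + n_null),
                 n_null = n_null),
            class = "modularity_significance")
}

#' @export
print.modularity_significance <- function(x, ...) {
  cat("Bipartite network modularity vs degree-preserving null model\n")
  cat(sprintf("  M_obs = %.4f, M_random = %.4f +/- %.4f, P = %.4g (%d nulls)\n",
              x$M_obs, x$null_mean, x$null_sd, x$p_value, x$n_null))
  cat(sprintf("  %d modules detected\n", x$partition$n_modules))
  invisible(x)
}

#' @export
plot.modularity_significance <- function(x, ...) {
  graphics::hist(x$null_Ms, breaks = 30, col = "grey80", border = "white",
                 xlim = range(c(x$null_Ms, x$M_obs)),
                 main = "Null distribution of modularity",
                 xlab = "M (degree-preserving null)")
  graphics::abline(v = x$M_obs, col = "red", lwd = 2)
  invisible(x)
}

#' Module-sorted incidence matrix (matrix-figure layout)
#'
#' Orders species rows and OTU columns by module so that within-module links
#' form diagonal blocks; between-module links fall outside the blocks.
#'
#' @param net a [build_network] object.
#' @param partition a [module_partition] of `net`.
#' @return the incidence matrix re-ordered, with attributes `row_module`
#'   and `col_module`.
#' @export
module_matrix <- function(net, partition) {
  sp <- rownames(net$incidence)
  ot <- colnames(net$incidence)
  rs <- partition$assignment[sp]
  cs <- partition$assignment[ot]
  m <- net$incidence[order(rs, sp), order(cs, ot), drop = FALSE]
  attr(m, "row_module") <- sort(rs)
  attr(m, "col_module") <- sort(cs)
  m
}

#' @export
plot.module_partition <- function(x, net, ...) {
  m <- module_matrix(net, x)
  rm_ <- attr(m, "row_module"); cm_ <- attr(m, "col_module")
  same <- outer(rm_, cm_, "==")
  img <- unclass(m) * (1 + same)  # 0 none, 1 between-module, 2 within
  grDevices::palette(c("white", "red", "grey20"))
  graphics::image(t(img[rev(seq_len(nrow(img))), , drop = FALSE]),
                  col = c("white", "red", "grey20"), axes = FALSE,
                  main = sprintf("Module matrix (M = %.3f, %d modules)",
                                 x$M, x$n_modules), ...)
  invisible(x)
}
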