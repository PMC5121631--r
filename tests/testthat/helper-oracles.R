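# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately brute-force and avoids the code paths it
# is used to check.

# random OTU count table
random_table <- function(seed, n_samples = 6, n_otus = 10, lambda = 3) {
  set.seed(seed)
  m <- matrix(rpois(n_samples * n_otus, lambda), n_samples, n_otus,
              dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                              sprintf("OTU%02d", seq_len(n_otus))))
  otu_table(m)
}

# metadata covering the samples of a table; species assigned round-robin,
# habitat and ploidy determined by the species index
random_meta <- function(x, n_species = 3, n_habitats = 2) {
  ids <- rownames(x)
  sp_idx <- rep(seq_len(n_species), length.out = length(ids))
  data.frame(sample_id = ids,
             species = sprintf("species_%02d", sp_idx),
             population_id = sprintf("species_%02d_p1", sp_idx),
             habitat = habitat_levels()[(sp_idx - 1) %% n_habitats + 1],
             ploidy = ploidy_levels()[(sp_idx - 1) %% 3 + 1],
             genome = "AA", stringsAsFactors = FALSE)
}

# random connected-enough bipartite network with no isolated nodes
random_network <- function(seed, nr = NULL, nc = NULL, p = 0.5) {
  set.seed(seed)
  repeat {
    nr2 <- nr %||% sample(2:4, 1)
    nc2 <- nc %||% sample(2:4, 1)
    m <- matrix(rbinom(nr2 * nc2, 1, p), nr2, nc2,
                dimnames = list(paste0("sp", seq_len(nr2)),
                                paste0("o", seq_len(nc2))))
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(build_network(m))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive maximum of the modularity index over all set partitions of the
# nodes (restricted-growth-string enumeration); feasible up to ~9 nodes
oracle_max_M <- function(net) {
  e <- dactynet:::network_edges(net)
  deg <- as.numeric(net$degrees[e$nodes])
  L <- net$L
  n <- length(e$nodes)
  ei <- e$i + 1L
  ej <- e$j + 1L
  best <- -Inf
  rec <- function(a, maxv, i) {
    if (i > n) {
      same <- a[ei] == a[ej]
      ls <- tabulate(a[ei][same], maxv)
      ds <- vapply(seq_len(maxv), function(s) sum(deg[a == s]), 0)
      M <- sum(ls / L - (ds / (2 * L))^2)
      if (M > best) best <<- M
      return(invisible(NULL))
    }
    for (v in seq_len(maxv + 1L)) {
      a[i] <- v
      rec(a, max(maxv, v), i + 1L)
    }
  }
  rec(integer(n), 0L, 1L)
  best
}

# all 4x4 binary matrices with every row and column margin equal to 2
enumerate_2222_fillings <- function() {
  combs <- combn(4, 2)
  rows <- lapply(seq_len(ncol(combs)), function(i) {
    v <- integer(4); v[combs[, i]] <- 1L; v
  })
  out <- list()
  for (r1 in 1:6) for (r2 in 1:6) for (r3 in 1:6) for (r4 in 1:6) {
    m <- rbind(rows[[r1]], rows[[r2]], rows[[r3]], rows[[r4]])
    if (all(colSums(m) == 2)) out[[length(out) + 1]] <- m
  }
  out
}

# brute-force IndVal for a single union, straight from the definition
oracle_indval <- function(x, groups, target) {
  x <- unclass(x)
  g <- as.character(groups)
  habs <- sort(unique(g))
  in_g <- g %in% target
  vapply(seq_len(ncol(x)), function(j) {
    mu_g <- mean(x[in_g, j])
    denom <- mu_g + sum(vapply(setdiff(habs, target), function(h)
      mean(x[g == h, j]), numeric(1)))
    if (denom == 0) return(NA_real_)
    A <- mu_g / denom
    B <- mean(x[in_g, j] > 0)
    sqrt(A * B)
  }, numeric(1))
}

# fast small-schedule for annealing in tests
test_schedule <- function() sa_schedule(cooling = 0.95, move_factor = 0.5)
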