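## Community-composition stage: aggregation, dissimilarity, NMDS
## ordination and permutational multivariate ANOVA on distance matrices.

#' Aggregate an OTU table to one row per orchid species
#'
#' `"presence"` gives a binary species-by-OTU occurrence matrix (an OTU is
#' scored 1 for a species if any of its samples carries at least one read);
#' `"summed_counts"` sums reads over the samples of each species.
#'
#' @param x an [otu_table].
#' @param meta metadata covering the samples of `x`.
#' @param mode `"presence"` or `"summed_counts"`.
#' @return an [otu_table] with one row per species (metadata species order).
#' @export
aggregate_by_species <- function(x, meta, mode = c("presence", "summed_counts")) {
  mode <- match.arg(mode)
  agg <- aggregate_rows(x, meta, "species")
  if (mode == "presence") agg <- (agg > 0) + 0L
  otu_table(agg)
}

#' Aggregate an OTU table to one row per population (site)
#'
#' Sites for indicator analysis: reads are summed over the samples of each
#' population and optionally converted to within-site relative abundances,
#' which guards against sequencing-depth artefacts.
#'
#' @param x an [otu_table].
#' @param meta metadata covering the samples of `x`.
#' @param relative divide each site row by its total read count?
#' @return numeric matrix, rows = populations; with
#'   `attr(, "habitat")` the named habitat vector of the sites.
#' @export
aggregate_by_population <- function(x, meta, relative = TRUE) {
  agg <- aggregate_rows(x, meta, "population_id")
  hab <- setNames(meta$habitat[match(rownames(agg), meta$population_id)],
                  rownames(agg))
  out <- agg
  if (relative) {
    tot <- rowSums(agg)
    if (any(tot == 0)) stop("population with zero reads: ",
                            paste(rownames(agg)[tot == 0], collapse = ", "))
    out <- agg / tot
  }
  attr(out, "habitat") <- hab
  out
}

aggregate_rows <- function(x, meta, col) {
  validate_otu_table(x)
  validate_metadata(meta)
  idx <- match(rownames(x), meta$sample_id)
  if (anyNA(idx))
    stop("samples missing from metadata: ",
         paste(rownames(x)[is.na(idx)], collapse = ", "))
  groups <- meta[[col]][idx]
  agg <- rowsum(unclass(x), group = groups, reorder = FALSE)
  agg[unique(meta[[col]][meta[[col]] %in% groups]), , drop = FALSE]
}

#' Pairwise community dissimilarity
#'
#' Bray-Curtis on counts, `d = 1 - 2 * sum_j min(x_j, y_j) / (sum x + sum y)`,
#' or Jaccard on presence/absence, `d = 1 - |A intersect B| / |A union B|`.
#' Computed with [vegan::vegdist]; rows with no reads are rejected because
#' their dissimilarity to anything is undefined.
#'
#' @param x an [otu_table] (or plain non-negative matrix).
#' @param metric `"jaccard"` (presence-based, the default analysis unit) or
#'   `"bray_curtis"`.
#' @return a [stats::dist] with `Size` = number of rows of `x`.
#' @export
dissimilarity <- function(x, metric = c("jaccard", "bray_curtis")) {
  metric <- match.arg(metric)
  m <- unclass(x)
  if (nrow(m) < 2) stop("need at least two rows")
  zero <- rowSums(m) == 0
  if (any(zero))
    stop("all-zero row(s): ", paste(rownames(m)[zero], collapse = ", "))
  if (metric == "bray_curtis")
    vegan::vegdist(m, method = "bray")
  else
    vegan::vegdist(m, method = "jaccard", binary = TRUE)
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Minimises Kruskal stress-1 (monotone regression of configuration
#' distances on dissimilarity ranks, weak tie treatment) with
#' [vegan::monoMDS], taking the best of `n_restarts` starts: the first start
#' is the classical (metric) MDS configuration, the rest are random.
#' Deterministic for a given `seed`.
#'
#' @param d a [stats::dist] or symmetric matrix of dissimilarities.
#' @param k embedding dimension; must satisfy `k <= n - 1`.
#' @param n_restarts number of starts.
#' @param seed integer seed or `NULL`.
#' @return object of class `myco_nmds`: list with `points` (n x k matrix,
#'   centred), `stress`, `converged`, `n_restarts`, `k`.
#' @export
nmds <- function(d, k = 2, n_restarts = 20, seed = NULL) {
  if (!inherits(d, "dist")) d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (k < 1) stop("k must be >= 1")
  if (k > n - 1) stop("k must be <= n - 1 (", n - 1, " for this matrix)")
  labs <- attr(d, "Labels") %||% as.character(seq_len(n))

  if (n == 2) {
    pts <- matrix(c(-1, 1) * as.vector(d)[1] / 2, ncol = 1,
                  dimnames = list(labs, NULL))
    pts <- cbind(pts, matrix(0, 2, k - 1))
    return(structure(list(points = pts, stress = 0, converged = TRUE,
                          n_restarts = n_restarts, k = k),
                     class = "myco_nmds"))
  }

  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      init <- if (r == 1) {
        y <- suppressWarnings(cmdscale(d, k = k))
        if (ncol(y) < k) y <- cbind(y, matrix(rnorm(n * (k - ncol(y)), sd = 1e-4),
                                              n, k - ncol(y)))
        y
      } else {
        matrix(runif(n * k, -1, 1), n, k)
      }
      fit <- vegan::monoMDS(d, y = init, k = k, model = "global")
      if (is.null(best) || fit$stress < best$stress) best <- fit
    }
    pts <- scale(best$points, center = TRUE, scale = FALSE)
    attr(pts, "scaled:center") <- NULL
    dimnames(pts) <- list(labs, paste0("NMDS", seq_len(k)))
    structure(list(points = pts, stress = best$stress,
                   converged = best$icause != 1L,
                   n_restarts = n_restarts, k = k),
              class = "myco_nmds")
  })
}

#' @export
print.myco_nmds <- function(x, ...) {
  cat(sprintf("NMDS ordination: %d points in %d dimensions\n",
              nrow(x$points), x$k))
  cat(sprintf("  Kruskal stress-1 = %.4f (best of %d starts, %s)\n",
              x$stress, x$n_restarts,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' @export
plot.myco_nmds <- function(x, groups = NULL, ...) {
  pts <- x$points
  col <- if (is.null(groups)) 1 else as.integer(factor(groups[rownames(pts)]))
  graphics::plot(pts[, 1], pts[, 2], col = col, pch = 19,
                 xlab = "NMDS1", ylab = "NMDS2",
                 main = sprintf("NMDS (stress = %.3f)", x$stress), ...)
  graphics::text(pts[, 1], pts[, 2], rownames(pts), pos = 3, cex = 0.7,
                 col = col)
  invisible(x)
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Partitions the total sum of squared dissimilarities into between- and
#' within-group components directly from the distance matrix:
#' `SS_total = sum_{i<j} d_ij^2 / n`, `SS_within = sum_g sum_{i<j in g}
#' d_ij^2 / n_g`, `SS_between = SS_total - SS_within`, and forms
#' `pseudo-F = (SS_between / (a - 1)) / (SS_within / (n - a))` for `a`
#' groups. Significance comes from uniform random permutations of the group
#' labels; the observed statistic is included in numerator and denominator,
#' so `p >= 1 / (n_permutations + 1)`.
#'
#' @param d a [stats::dist] or symmetric dissimilarity matrix.
#' @param groups group label per object: named vector (matched to the
#'   distance labels) or unnamed vector in distance order.
#' @param n_permutations number of label permutations.
#' @param seed integer seed or `NULL`.
#' @return object of class `permanova`: list with `pseudo_F`, `df_between`,
#'   `df_within`, `ss_between`, `ss_within`, `ss_total`, `p_value`,
#'   `n_permutations`.
#' @export
permanova <- function(d, groups, n_permutations = 999, seed = NULL) {
  if (!inherits(d, "dist")) d <- stats::as.dist(d)
  n <- attr(d, "Size")
  labs <- attr(d, "Labels")
  if (!is.null(names(groups)) && !is.null(labs)) {
    missing <- setdiff(labs, names(groups))
    if (length(missing) > 0)
      stop("no group label for: ", paste(missing, collapse = ", "))
    groups <- groups[labs]
  }
  if (length(groups) != n) stop("groups must have one label per object")
  g <- as.integer(factor(groups))
  a <- length(unique(g))
  if (a < 2) stop("need at least two groups")
  if (n <= a) stop("need more objects than groups")
  counts <- tabulate(g, a)

  D2 <- as.matrix(d)^2
  ss_total <- sum(D2) / (2 * n)
  ss_within_of <- function(g) {
    s <- 0
    for (lev in seq_len(a)) {
      idx <- which(g == lev)
      s <- s + sum(D2[idx, idx]) / (2 * length(idx))
    }
    s
  }
  ss_within <- ss_within_of(g)
  if (ss_within <= .Machine$double.eps * ss_total)
    stop("within-group sum of squares is zero; pseudo-F undefined")
  ss_between <- ss_total - ss_within
  df_between <- as.integer(a - 1)
  df_within <- as.integer(n - a)
  f_obs <- (ss_between / df_between) / (ss_within / df_within)

  p <- with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_permutations)) {
      gp <- g[sample.int(n)]
      sw <- ss_within_of(gp)
      fp <- ((ss_total - sw) / df_between) / (sw / df_within)
      if (fp >= f_obs - 1e-12) hits <- hits + 1L
    }
    (1 + hits) / (1 + n_permutations)
  })

  structure(list(pseudo_F = f_obs, df_between = df_between,
                 df_within = df_within, ss_between = ss_between,
                 ss_within = ss_within, ss_total = ss_total,
                 p_value = p, n_permutations = n_permutations),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat("Permutational multivariate analysis of variance\n")
  cat(sprintf("  pseudo-F = %.4g on (%d, %d) df; P = %.4g (%d permutations)\n",
              x$pseudo_F, x$df_between, x$df_within, x$p_value,
              x$n_permutations))
  invisible(x)
}
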