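## Indicator-species analysis: IndVal = sqrt(A * B) where A (specificity)
## concentrates an OTU's mean abundance in the target site group and B
## (fidelity) is its occurrence frequency within the group, extended to
## unions of habitats; significance by site-label permutation.

## Per-habitat summaries used by all IndVal computations.
habitat_stats <- function(x, groups) {
  x <- unclass(x)
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
  if (!is.null(names(groups))) {
    missing <- setdiff(rownames(x), names(groups))
    if (length(missing) > 0)
      stop("no habitat label for site(s): ", paste(missing, collapse = ", "))
    groups <- groups[rownames(x)]
  }
  if (length(groups) != nrow(x)) stop("one habitat label per site required")
  g <- factor(groups)
  list(x = x, g = g,
       n = as.vector(table(g)),
       sums = rowsum(x, g, reorder = TRUE),
       pres = rowsum((x > 0) + 0, g, reorder = TRUE),
       levels = levels(g))
}

## Binary union-by-habitat matrix for all unions of size 1..max_order,
## ordered by (size, label) so ties resolve to the smallest union first.
union_matrix <- function(levels, max_order) {
  H <- length(levels)
  if (max_order >= H)
    stop("max_order must be smaller than the number of habitats (", H, ")")
  rows <- list()
  for (k in seq_len(max_order)) {
    cmb <- combn(H, k)
    for (c in seq_len(ncol(cmb))) {
      u <- integer(H)
      u[cmb[, c]] <- 1L
      rows[[length(rows) + 1]] <- u
    }
  }
  U <- do.call(rbind, rows)
  colnames(U) <- levels
  rownames(U) <- apply(U, 1, function(u) paste(levels[u == 1], collapse = "+"))
  U
}

## A, B and IndVal for every union (rows) x OTU (columns).
indval_matrix <- function(st, U) {
  mu_h <- st$sums / st$n                      # habitat means
  N1 <- as.vector(U %*% st$n)                 # sites per union
  S1 <- U %*% st$sums
  mu_g <- S1 / N1                             # pooled mean in the union
  denom <- mu_g + rep(colSums(mu_h), each = nrow(U)) - U %*% mu_h
  A <- ifelse(denom > 0, mu_g / denom, NA_real_)
  B <- (U %*% st$pres) / N1
  list(A = A, B = B, indval = sqrt(A * B))
}

#' IndVal components for one target habitat union
#'
#' For a target group `g` (one habitat or a union), specificity
#' `A = mean abundance over the sites of g / (that mean + the per-habitat
#' means of the habitats outside g)` and fidelity `B = fraction of sites of
#' g where the OTU occurs`; `IndVal = sqrt(A * B)`. An OTU absent from every
#' site has undefined `A` and is reported as `NA`.
#'
#' @param x sites-by-OTU abundance matrix (counts or relative abundances;
#'   `A` is scale-free per OTU, `B` presence-based).
#' @param groups habitat label per site (named or in row order).
#' @param target character vector of habitat labels forming the union; must
#'   be a non-empty proper subset of the habitats.
#' @return data frame with columns `otu_id`, `A`, `B`, `ind_val`.
#' @export
indval_components <- function(x, groups, target) {
  st <- habitat_stats(x, groups)
  if (length(target) == 0 || !all(target %in% st$levels))
    stop("target must be a non-empty subset of the observed habitats")
  if (length(unique(target)) >= length(st$levels))
    stop("target must be a proper subset of the habitats")
  U <- matrix(as.integer(st$levels %in% target), nrow = 1,
              dimnames = list(paste(sort(unique(target)), collapse = "+"),
                              st$levels))
  iv <- indval_matrix(st, U)
  data.frame(otu_id = colnames(st$x), A = as.vector(iv$A),
             B = as.vector(iv$B), ind_val = as.vector(iv$indval),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Best habitat combination per OTU
#'
#' Evaluates IndVal for every habitat union of size 1 to `max_order` and
#' keeps, per OTU, the union maximising it; ties go to the smallest union,
#' then lexicographically.
#'
#' @inheritParams indval_components
#' @param max_order largest union size considered; must be smaller than the
#'   number of habitats.
#' @return object of class `indicator_result`: data frame with columns
#'   `otu_id`, `best_group`, `A`, `B`, `ind_val`, `p_value` (NA here; filled
#'   by [indicator_test]).
#' @export
best_combination <- function(x, groups, max_order = NULL) {
  st <- habitat_stats(x, groups)
  max_order <- max_order %||% (length(st$levels) - 1L)
  U <- union_matrix(st$levels, max_order)
  iv <- indval_matrix(st, U)
  pick <- apply(iv$indval, 2, function(col) {
    if (all(is.na(col))) return(NA_integer_)
    m <- max(col, na.rm = TRUE)
    which(!is.na(col) & col >= m - 1e-12)[1]  # rows pre-ordered by size, label
  })
  res <- data.frame(
    otu_id = colnames(st$x),
    best_group = ifelse(is.na(pick), NA_character_, rownames(U)[pick]),
    A = iv$A[cbind(pick, seq_along(pick))],
    B = iv$B[cbind(pick, seq_along(pick))],
    ind_val = iv$indval[cbind(pick, seq_along(pick))],
    p_value = NA_real_,
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(res) <- c("indicator_result", "data.frame")
  res
}

#' Permutation test for habitat indicator OTUs
#'
#' Computes each OTU's best-combination IndVal, then permutes the site
#' habitat labels `n_perm` times, recomputing the best-combination IndVal
#' under each permutation; `p = (1 + #\{perm >= observed\}) / (1 + n_perm)`.
#' OTUs with `p <= alpha` are flagged significant. No multiple-testing
#' correction is applied by default; pass `adjust = "BH"` for
#' Benjamini-Hochberg adjusted p-values in an extra column.
#'
#' @inheritParams best_combination
#' @param n_perm number of label permutations.
#' @param seed integer seed or `NULL`.
#' @param alpha significance level for the `significant` flag.
#' @param adjust `"none"` or `"BH"`.
#' @return an `indicator_result` data frame with `p_value`, `significant`
#'   and optionally `p_adjusted` columns.
#' @export
indicator_test <- function(x, groups, max_order = NULL, n_perm = 999,
                           seed = NULL, alpha = 0.05,
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (n_perm < 1) stop("n_perm must be >= 1")
  st <- habitat_stats(x, groups)
  max_order <- max_order %||% (length(st$levels) - 1L)
  U <- union_matrix(st$levels, max_order)
  res <- best_combination(x, groups, max_order)
  obs <- res$ind_val

  hits <- with_seed(seed, {
    h <- integer(length(obs))
    glab <- as.character(st$g)
    for (b in seq_len(n_perm)) {
      stp <- habitat_stats(st$x, glab[sample.int(length(glab))])
      iv <- indval_matrix(stp, U)
      mx <- suppressWarnings(apply(iv$indval, 2, max, na.rm = TRUE))
      h <- h + as.integer(!is.na(obs) & mx >= obs - 1e-12)
    }
    h
  })
  res$p_value <- ifelse(is.na(obs), NA_real_, (1 + hits) / (1 + n_perm))
  res$significant <- !is.na(res$p_value) & res$p_value <= alpha
  if (adjust == "BH") {
    res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
    res$significant <- !is.na(res$p_adjusted) & res$p_adjusted <= alpha
  }
  attr(res, "n_perm") <- n_perm
  attr(res, "alpha") <- alpha
  res
}

#' @export
print.indicator_result <- function(x, ...) {
  cat(sprintf("Indicator-species analysis: %d OTUs\n", nrow(x)))
  if (!is.null(x$p_value) && !all(is.na(x$p_value))) {
    flag <- x$significant %||%
      (x$p_value <= (attr(x, "alpha") %||% 0.05))
    sig <- x[!is.na(x$p_value) & flag, , drop = FALSE]
    cat(sprintf("  %d significant at alpha = %g (%d permutations)\n",
                nrow(sig), attr(x, "alpha") %||% 0.05,
                attr(x, "n_perm") %||% NA))
    if (nrow(sig) > 0) print.data.frame(utils::head(
      sig[order(sig$p_value, -sig$ind_val), ], 15), digits = 3)
  } else {
    print.data.frame(utils::head(as.data.frame(x), 10), digits = 3)
  }
  invisible(x)
}
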