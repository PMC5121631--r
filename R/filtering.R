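## OTU retention rules and descriptive prevalence / ploidy-partition
## summaries. Both filters are pure column deletions: counts of retained
## OTUs are never modified.

filter_report <- function(n_input, removed_rare = character(),
                          removed_nonmyc = character()) {
  structure(list(
    n_input_otus = n_input,
    n_removed_rare = length(removed_rare),
    n_removed_nonmycorrhizal = length(removed_nonmyc),
    n_retained = n_input - length(removed_rare) - length(removed_nonmyc),
    removed_ids = c(removed_rare, removed_nonmyc)
  ), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0("OTU filter report: %d input, %d rare removed, ",
                     "%d non-mycorrhizal removed, %d retained\n"),
              x$n_input_otus, x$n_removed_rare,
              x$n_removed_nonmycorrhizal, x$n_retained))
  invisible(x)
}

#' Remove globally rare OTUs
#'
#' Drops OTUs whose total read count over the whole dataset falls below
#' `min_total_count`. The default of 3 removes global singletons and
#' doubletons (OTUs represented by only one or two sequences), which are
#' likely sequencing artefacts and are known to bias diversity estimates.
#'
#' @param x an [otu_table].
#' @param min_total_count minimum whole-dataset read count to retain an OTU.
#' @return list with elements `table` (filtered [otu_table]) and `report`
#'   (a `filter_report`).
#' @export
remove_rare_otus <- function(x, min_total_count = 3) {
  validate_otu_table(x)
  if (min_total_count < 1) stop("min_total_count must be >= 1")
  totals <- colSums(x)
  drop <- colnames(x)[totals < min_total_count]
  keep <- setdiff(colnames(x), drop)
  if (length(keep) == 0) stop("all OTUs removed by rarity filter")
  list(table = otu_table(unclass(x)[, keep, drop = FALSE]),
       report = filter_report(ncol(x), removed_rare = drop))
}

#' Restrict an OTU table to putatively mycorrhizal OTUs
#'
#' Keeps exactly the OTUs flagged `putative_mycorrhizal` in the taxonomy
#' (see [flag_mycorrhizal]); every OTU in the table must have a taxonomy
#' record.
#'
#' @param x an [otu_table].
#' @param taxonomy taxonomy data frame with a `putative_mycorrhizal` column;
#'   if the column is absent it is computed with [flag_mycorrhizal] defaults.
#' @return list with elements `table` and `report` as in [remove_rare_otus].
#' @export
subset_mycorrhizal <- function(x, taxonomy) {
  validate_otu_table(x)
  if (!("putative_mycorrhizal" %in% names(taxonomy)))
    taxonomy <- flag_mycorrhizal(taxonomy)
  validate_taxonomy(taxonomy)
  missing <- setdiff(colnames(x), taxonomy$otu_id)
  if (length(missing) > 0)
    stop("no taxonomy record for OTU(s): ", paste(missing, collapse = ", "))
  flag <- taxonomy$putative_mycorrhizal[match(colnames(x), taxonomy$otu_id)]
  drop <- colnames(x)[!flag]
  keep <- colnames(x)[flag]
  if (length(keep) == 0) stop("no putatively mycorrhizal OTUs retained")
  list(table = otu_table(unclass(x)[, keep, drop = FALSE]),
       report = filter_report(ncol(x), removed_nonmyc = drop))
}

#' Per-group OTU presence sets
#'
#' For each level of the grouping variable (orchid species or population),
#' returns the set of OTUs observed (count >= 1) in at least one sample of
#' the group. Groups with zero samples in the table are excluded with a
#' warning.
#'
#' @param x an [otu_table].
#' @param meta metadata data frame covering the samples of `x`.
#' @param group_by `"species"` or `"population"`.
#' @return named list of character vectors (OTU ids per group).
#' @export
prevalence_by_group <- function(x, meta, group_by = c("species", "population")) {
  group_by <- match.arg(group_by)
  validate_otu_table(x)
  validate_metadata(meta)
  col <- if (group_by == "species") "species" else "population_id"
  idx <- match(rownames(x), meta$sample_id)
  if (anyNA(idx))
    stop("samples missing from metadata: ",
         paste(rownames(x)[is.na(idx)], collapse = ", "))
  groups <- meta[[col]][idx]
  all_groups <- unique(meta[[col]])
  empty <- setdiff(all_groups, groups)
  if (length(empty) > 0)
    warning("group(s) with no samples in table excluded: ",
            paste(empty, collapse = ", "))
  out <- lapply(split(seq_len(nrow(x)), groups), function(rows) {
    colnames(x)[colSums(unclass(x)[rows, , drop = FALSE]) > 0]
  })
  out[unique(groups)]
}

#' Summarise per-group OTU richness
#'
#' @param prevalence named list from [prevalence_by_group].
#' @return list with `n_groups`, `min`, `max`, `mean` of set sizes and the
#'   per-group sizes themselves.
#' @export
prevalence_summary <- function(prevalence) {
  sizes <- vapply(prevalence, length, integer(1))
  list(n_groups = length(sizes), min = min(sizes), max = max(sizes),
       mean = mean(sizes), sizes = sizes)
}

#' Partition OTUs by the ploidy classes they occur in
#'
#' Assigns every OTU to the exact subset of ploidy levels (2x, 3x, 4x) of
#' the species it was observed in, yielding the counts behind a
#' three-set Venn diagram, plus per-ploidy totals (an OTU found in both a
#' diploid and a tetraploid species counts towards both totals).
#'
#' @param prevalence named list species -> OTU ids ([prevalence_by_group]
#'   with `group_by = "species"`).
#' @param meta metadata data frame mapping each species to one ploidy.
#' @return object of class `venn_partition`: list with `subsets` (named
#'   integer vector keyed e.g. `"2x"`, `"2x:4x"`, `"2x:3x:4x"`) and `totals`
#'   (per-ploidy integer vector).
#' @export
venn_by_ploidy <- function(prevalence, meta) {
  validate_metadata(meta)
  map <- unique(meta[, c("species", "ploidy")])
  if (anyDuplicated(map$species))
    stop("species mapped to more than one ploidy: ",
         paste(map$species[duplicated(map$species)], collapse = ", "))
  missing <- setdiff(names(prevalence), map$species)
  if (length(missing) > 0)
    stop("species missing from metadata: ", paste(missing, collapse = ", "))
  ploidy_of <- setNames(map$ploidy, map$species)

  otus <- unique(unlist(prevalence, use.names = FALSE))
  lv <- ploidy_levels()
  keys <- unlist(lapply(seq_along(lv), function(k)
    apply(combn(lv, k), 2, paste, collapse = ":")))
  subsets <- setNames(integer(length(keys)), keys)
  totals <- setNames(integer(length(lv)), lv)
  for (otu in otus) {
    in_species <- names(prevalence)[vapply(prevalence, function(s)
      otu %in% s, logical(1))]
    pl <- sort(unique(ploidy_of[in_species]))
    key <- paste(pl, collapse = ":")
    subsets[key] <- subsets[key] + 1L
    totals[pl] <- totals[pl] + 1L
  }
  structure(list(subsets = subsets, totals = totals),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("OTU sharing across ploidy classes\n")
  cat("  totals:",
      paste(sprintf("%s=%d", names(x$totals), x$totals), collapse = ", "),
      "\n")
  nz <- x$subsets[x$subsets > 0]
  for (k in names(nz)) cat(sprintf("  {%s}: %d\n", k, nz[k]))
  invisible(x)
}
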