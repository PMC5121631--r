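#' Default whitelist of orchid-associating mycorrhizal families
#'
#' Families and clades routinely recovered as orchid mycorrhizal symbionts
#' in European terrestrial orchids: the rhizoctonia families Tulasnellaceae,
#' Ceratobasidiaceae and Sebacinales (clades A and B treated as separate
#' labels), plus ectomycorrhizal Thelephoraceae.
#'
#' @return character vector of family / clade labels.
#' @export
mycorrhizal_whitelist <- function() {
  c("Tulasnellaceae", "Ceratobasidiaceae",
    "Sebacinales_A", "Sebacinales_B", "Thelephoraceae")
}

#' Validate an OTU taxonomy table
#'
#' Requires columns `otu_id`, `family_or_clade`, `percent_identity`;
#' identities must lie in [0, 100] and OTU identifiers must be unique.
#'
#' @param taxonomy data frame to validate.
#' @return `taxonomy`, invisibly, if valid.
#' @export
validate_taxonomy <- function(taxonomy) {
  required <- c("otu_id", "family_or_clade", "percent_identity")
  missing <- setdiff(required, names(taxonomy))
  if (length(missing) > 0)
    stop("taxonomy is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(taxonomy$otu_id))
    stop("duplicate otu_id in taxonomy: ",
         paste(unique(taxonomy$otu_id[duplicated(taxonomy$otu_id)]),
               collapse = ", "))
  pid <- taxonomy$percent_identity
  if (anyNA(pid) || any(pid < 0) || any(pid > 100))
    stop("percent_identity must lie within [0, 100]")
  invisible(taxonomy)
}

#' Read an OTU taxonomy table from a tab-separated file
#'
#' @param path TSV with columns `otu_id`, `family_or_clade`,
#'   `percent_identity` (and optionally `putative_mycorrhizal`).
#' @return validated data frame; `percent_identity` numeric.
#' @export
read_taxonomy <- function(path) {
  tax <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    fill = FALSE)
  tax$percent_identity <- as.numeric(tax$percent_identity)
  if ("putative_mycorrhizal" %in% names(tax))
    tax$putative_mycorrhizal <- as.logical(tax$putative_mycorrhizal)
  validate_taxonomy(tax)
  tax
}

#' Write an OTU taxonomy table to a tab-separated file
#'
#' @param taxonomy validated taxonomy data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  validate_taxonomy(taxonomy)
  write_tsv(taxonomy, path)
}

#' Flag putatively mycorrhizal OTUs
#'
#' An OTU is considered a putative orchid mycorrhizal fungus when its best
#' BLAST hit falls in a whitelisted orchid-associating family or clade
#' *and* the percent identity of that hit strictly exceeds `min_identity`.
#' The 90% default is deliberately strict: an identity of exactly 90 fails.
#'
#' @param taxonomy taxonomy data frame (see [read_taxonomy]).
#' @param whitelist character vector of accepted family / clade labels.
#' @param min_identity identity threshold in percent; strict inequality.
#' @return `taxonomy` with a logical `putative_mycorrhizal` column (re)set.
#' @examples
#' tax <- data.frame(otu_id = c("a", "b", "c"),
#'                   family_or_clade = c("Tulasnellaceae", "Tulasnellaceae",
#'                                       "Mycena"),
#'                   percent_identity = c(95, 90, 99))
#' flag_mycorrhizal(tax)$putative_mycorrhizal  # TRUE FALSE FALSE
#' @export
flag_mycorrhizal <- function(taxonomy, whitelist = mycorrhizal_whitelist(),
                             min_identity = 90) {
  validate_taxonomy(taxonomy)
  if (length(whitelist) == 0) stop("whitelist must be non-empty")
  taxonomy$putative_mycorrhizal <-
    taxonomy$family_or_clade %in% whitelist &
    taxonomy$percent_identity > min_identity
  taxonomy
}
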