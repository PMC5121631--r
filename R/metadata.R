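#' Closed vocabularies for sample metadata
#'
#' The five habitat classes and three ploidy levels used throughout the
#' package. Metadata validation rejects any value outside these sets.
#'
#' @return character vector of allowed tokens.
#' @export
habitat_levels <- function() {
  c("mediterranean", "peat_bog", "wetland", "coastal", "alpine_boreal")
}

#' @rdname habitat_levels
#' @export
ploidy_levels <- function() c("2x", "3x", "4x")

#' The fourteen Dactylorhiza study species
#'
#' Species of the orchid genus *Dactylorhiza* with the habitat each was
#' sampled from, its ploidy level and a genome-composition label (F and I
#' denote the *D. fuchsii* and *D. incarnata* parental genomes, FM the
#' *D. maculata*-like genome, S the *D. sambucina* group genome and V the
#' *D. viridis* genome). Used by the paper-scale synthetic preset.
#'
#' @return data frame with columns `species`, `habitat`, `ploidy`, `genome`.
#' @export
dactylorhiza_species <- function() {
  data.frame(
    species = c("D_sambucina", "D_romana", "D_insularis", "D_markusii",
                "D_sphagnicola", "D_maculata",
                "D_fuchsii", "D_majalis", "D_viridis", "D_elata",
                "D_praetermissa", "D_incarnata",
                "D_alpestris", "D_lapponica"),
    habitat = c(rep("mediterranean", 4), rep("peat_bog", 2),
                rep("wetland", 4), rep("coastal", 2),
                rep("alpine_boreal", 2)),
    ploidy  = c("2x", "2x", "3x", "2x",
                "4x", "4x",
                "2x", "4x", "2x", "4x",
                "4x", "2x",
                "4x", "4x"),
    genome  = c("SS", "SS", "SSS", "SS",
                "FmFmII", "FmFm",
                "FF", "FFII", "VV", "FmFmII",
                "FFII", "II",
                "FFII", "FFII"),
    stringsAsFactors = FALSE
  )
}

#' Validate a sample metadata table
#'
#' Requires columns `sample_id`, `species`, `population_id`, `habitat`,
#' `ploidy`, `genome`; `habitat` and `ploidy` must come from the closed
#' vocabularies ([habitat_levels], [ploidy_levels]) and sample identifiers
#' must be unique.
#'
#' @param meta data frame to validate.
#' @return `meta`, invisibly, if valid.
#' @export
validate_metadata <- function(meta) {
  required <- c("sample_id", "species", "population_id", "habitat",
                "ploidy", "genome")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0)
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
               collapse = ", "))
  bad_hab <- !(meta$habitat %in% habitat_levels())
  if (any(bad_hab))
    stop("unknown habitat '", meta$habitat[bad_hab][1], "' in metadata row ",
         which(bad_hab)[1], " (sample ", meta$sample_id[bad_hab][1], ")")
  bad_plo <- !(meta$ploidy %in% ploidy_levels())
  if (any(bad_plo))
    stop("unknown ploidy '", meta$ploidy[bad_plo][1], "' in metadata row ",
         which(bad_plo)[1], " (sample ", meta$sample_id[bad_plo][1], ")")
  invisible(meta)
}

#' Read a sample metadata table from a tab-separated file
#'
#' @param path file path to a TSV with columns `sample_id`, `species`,
#'   `population_id`, `habitat`, `ploidy`, `genome`.
#' @return validated data frame, one row per sample.
#' @export
read_metadata <- function(path) {
  meta <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                     check.names = FALSE, colClasses = "character",
                     fill = FALSE, stringsAsFactors = FALSE)
  validate_metadata(meta)
  meta
}

#' Write a sample metadata table to a tab-separated file
#'
#' @param meta validated metadata data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  validate_metadata(meta)
  write_tsv(meta, path)
}

## Byte-stable TSV writer shared by the tabular writers.
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0) {
    cols <- lapply(df, function(col) {
      if (is.double(col)) format(col, trim = TRUE, digits = 15, scientific = FALSE)
      else as.character(col)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}
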