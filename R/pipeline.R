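## End-to-end orchestration: filter -> community (NMDS + permutational
## MANOVA) -> network modularity -> indicator analysis, with every stage
## artifact written to disk and a consolidated machine-readable summary.

#' Pipeline configuration
#'
#' Either the three input paths (`otu_table`, `metadata`, `taxonomy`) or a
#' simulation preset must be given. A single master `seed` is expanded into
#' independent per-stage seeds by a fixed splitting rule, so each stage is
#' reproducible in isolation.
#'
#' @param otu_table,metadata,taxonomy input TSV paths (see [read_otu_table],
#'   [read_metadata], [read_taxonomy]).
#' @param simulate a [sim_config] to generate inputs instead of reading them.
#' @param out_dir output directory.
#' @param metric dissimilarity metric for the community stage.
#' @param aggregate community analysis unit: `"presence"` (species-level
#'   presence/absence) or `"summed_counts"`.
#' @param min_total_count rarity threshold (see [remove_rare_otus]).
#' @param min_identity,whitelist mycorrhizal retention rule
#'   (see [flag_mycorrhizal]).
#' @param n_permutations label permutations for the permutational MANOVA.
#' @param n_null null networks for modularity significance.
#' @param schedule [sa_schedule] for module detection.
#' @param n_perm_indicators permutations for the indicator test.
#' @param alpha significance level for indicators.
#' @param ploidy_binary test ploidy as diploid vs polyploid (default) rather
#'   than as three levels.
#' @param seed master seed (mandatory).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(otu_table = NULL, metadata = NULL, taxonomy = NULL,
                            simulate = NULL, out_dir = tempfile("dactynet_"),
                            metric = c("jaccard", "bray_curtis"),
                            aggregate = c("presence", "summed_counts"),
                            min_total_count = 3, min_identity = 90,
                            whitelist = mycorrhizal_whitelist(),
                            n_permutations = 999, n_null = 999,
                            schedule = sa_schedule(),
                            n_perm_indicators = 999, alpha = 0.05,
                            ploidy_binary = TRUE, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  metric <- match.arg(metric)
  aggregate <- match.arg(aggregate)
  if (is.null(simulate)) {
    paths <- c(otu_table, metadata, taxonomy)
    if (length(paths) != 3)
      stop("either all three input paths or a simulation config is required")
    missing_paths <- paths[!file.exists(paths)]
    if (length(missing_paths) > 0)
      stop("input file(s) not found: ", paste(missing_paths, collapse = ", "))
  }
  structure(list(otu_table = otu_table, metadata = metadata,
                 taxonomy = taxonomy, simulate = simulate, out_dir = out_dir,
                 metric = metric, aggregate = aggregate,
                 min_total_count = min_total_count,
                 min_identity = min_identity, whitelist = whitelist,
                 n_permutations = n_permutations, n_null = n_null,
                 schedule = schedule,
                 n_perm_indicators = n_perm_indicators, alpha = alpha,
                 ploidy_binary = ploidy_binary, seed = seed),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes filtering, community ordination and permutational MANOVA,
#' network modularity with null-model significance, and indicator-species
#' analysis on the filtered mycorrhizal table; writes every stage artifact
#' (TSV/JSON) plus `summary.json` and a human-readable `report.txt` to
#' `cfg$out_dir`. Fully deterministic given the config's seed.
#'
#' @param cfg a [pipeline_config].
#' @return object of class `dactynet_pipeline`: list with elements `tables`,
#'   `filter`, `community`, `network`, `indicators`, `summary`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## ---- inputs ---------------------------------------------------------
  inputs <- stage("input", {
    if (!is.null(cfg$simulate)) {
      sim <- simulate_dataset(cfg$simulate)
      write_simulation(sim, file.path(cfg$out_dir, "inputs"))
      list(table = sim$table, meta = sim$metadata, tax = sim$taxonomy,
           truth = sim$truth)
    } else {
      list(table = read_otu_table(cfg$otu_table),
           meta = read_metadata(cfg$metadata),
           tax = read_taxonomy(cfg$taxonomy), truth = NULL)
    }
  })
  table <- stage("align", align_samples(inputs$table, inputs$meta))
  meta <- inputs$meta

  ## ---- filtering ------------------------------------------------------
  filt <- stage("filter", {
    rare <- remove_rare_otus(table, cfg$min_total_count)
    tax <- flag_mycorrhizal(inputs$tax, cfg$whitelist, cfg$min_identity)
    myco <- subset_mycorrhizal(rare$table, tax)
    report <- filter_report(
      ncol(table),
      removed_rare = rare$report$removed_ids,
      removed_nonmyc = myco$report$removed_ids)
    prev_sp <- prevalence_by_group(myco$table, meta, "species")
    prev_pop <- prevalence_by_group(myco$table, meta, "population")
    venn <- venn_by_ploidy(prev_sp, meta)
    write_otu_table(myco$table, file.path(cfg$out_dir, "filtered_table.tsv"))
    write_json_file(unclass(report), file.path(cfg$out_dir, "filter_report.json"))
    write_json_file(list(subsets = as.list(venn$subsets),
                         totals = as.list(venn$totals)),
                    file.path(cfg$out_dir, "venn.json"))
    list(table = myco$table, taxonomy = tax, report = report,
         prevalence_species = prev_sp, prevalence_population = prev_pop,
         venn = venn)
  })

  ## ---- community ------------------------------------------------------
  community <- stage("community", {
    agg <- aggregate_by_species(filt$table, meta, cfg$aggregate)
    d <- dissimilarity(agg, cfg$metric)
    ord <- nmds(d, k = 2, seed = derive_seed(cfg$seed, 1))
    sp_hab <- setNames(meta$habitat[match(rownames(agg), meta$species)],
                       rownames(agg))
    sp_plo <- setNames(meta$ploidy[match(rownames(agg), meta$species)],
                       rownames(agg))
    if (cfg$ploidy_binary)
      sp_plo <- ifelse(sp_plo == "2x", "diploid", "polyploid")
    perm_hab <- permanova(d, sp_hab, cfg$n_permutations,
                          seed = derive_seed(cfg$seed, 2))
    perm_plo <- permanova(d, sp_plo, cfg$n_permutations,
                          seed = derive_seed(cfg$seed, 3))
    coords <- data.frame(species = rownames(ord$points), ord$points,
                         stringsAsFactors = FALSE)
    write_tsv(coords, file.path(cfg$out_dir, "nmds_coordinates.tsv"))
    write_json_file(list(habitat = unclass(perm_hab),
                         ploidy = unclass(perm_plo)),
                    file.path(cfg$out_dir, "permanova.json"))
    list(aggregated = agg, distance = d, nmds = ord,
         permanova_habitat = perm_hab, permanova_ploidy = perm_plo)
  })

  ## ---- network --------------------------------------------------------
  network <- stage("network", {
    net <- build_network(filt$prevalence_species)
    sig <- modularity_significance(net, n_null = cfg$n_null,
                                   seed = derive_seed(cfg$seed, 4),
                                   schedule = cfg$schedule)
    write_otu_table(otu_table(net$incidence),
                    file.path(cfg$out_dir, "incidence.tsv"))
    write_json_file(list(assignment = as.list(sig$partition$assignment),
                         n_modules = sig$partition$n_modules,
                         M = sig$partition$M),
                    file.path(cfg$out_dir, "partition.json"))
    write_json_file(list(M_obs = sig$M_obs, null_mean = sig$null_mean,
                         null_sd = sig$null_sd, p_value = sig$p_value,
                         n_null = sig$n_null),
                    file.path(cfg$out_dir, "modularity.json"))
    mm <- module_matrix(net, sig$partition)
    write_otu_table(otu_table(unclass(mm)),
                    file.path(cfg$out_dir, "module_matrix.tsv"))
    list(net = net, significance = sig)
  })

  ## ---- indicators -----------------------------------------------------
  indicators <- stage("indicators", {
    sites <- aggregate_by_population(filt$table, meta, relative = TRUE)
    res <- indicator_test(sites, attr(sites, "habitat"),
                          n_perm = cfg$n_perm_indicators,
                          seed = derive_seed(cfg$seed, 5),
                          alpha = cfg$alpha)
    write_tsv(as.data.frame(res), file.path(cfg$out_dir, "indicators.tsv"))
    res
  })

  ## ---- summary --------------------------------------------------------
  prev_sum <- prevalence_summary(filt$prevalence_species)
  summary <- list(
    settings = list(metric = cfg$metric, aggregate = cfg$aggregate,
                    site_unit = "population",
                    min_total_count = cfg$min_total_count,
                    min_identity = cfg$min_identity,
                    ploidy_binary = cfg$ploidy_binary,
                    n_permutations = cfg$n_permutations,
                    n_null = cfg$n_null,
                    n_perm_indicators = cfg$n_perm_indicators,
                    schedule = unclass(cfg$schedule), seed = cfg$seed),
    filtering = list(n_input_otus = filt$report$n_input_otus,
                     n_removed_rare = filt$report$n_removed_rare,
                     n_removed_nonmycorrhizal =
                       filt$report$n_removed_nonmycorrhizal,
                     n_retained = filt$report$n_retained),
    richness = list(per_species_min = prev_sum$min,
                    per_species_max = prev_sum$max,
                    per_species_mean = prev_sum$mean),
    venn_totals = as.list(filt$venn$totals),
    nmds = list(stress = community$nmds$stress,
                converged = community$nmds$converged),
    permanova = list(
      habitat = list(pseudo_F = community$permanova_habitat$pseudo_F,
                     p_value = community$permanova_habitat$p_value),
      ploidy = list(pseudo_F = community$permanova_ploidy$pseudo_F,
                    p_value = community$permanova_ploidy$p_value)),
    modularity = list(M_obs = network$significance$M_obs,
                      null_mean = network$significance$null_mean,
                      null_sd = network$significance$null_sd,
                      p_value = network$significance$p_value,
                      n_modules = network$significance$partition$n_modules),
    indicators = list(n_significant = sum(indicators$significant,
                                          na.rm = TRUE))
  )
  write_json_file(summary, file.path(cfg$out_dir, "summary.json"))

  report_lines <- c(
    "dactynet pipeline report",
    "========================",
    sprintf("OTUs: %d input, %d rare removed, %d non-mycorrhizal removed, %d retained",
            summary$filtering$n_input_otus, summary$filtering$n_removed_rare,
            summary$filtering$n_removed_nonmycorrhizal,
            summary$filtering$n_retained),
    sprintf("Per-species OTU richness: %d-%d (mean %.1f)",
            prev_sum$min, prev_sum$max, prev_sum$mean),
    sprintf("NMDS stress = %.4f", summary$nmds$stress),
    sprintf("Permutational MANOVA habitat: pseudo-F = %.3f, P = %.4g",
            summary$permanova$habitat$pseudo_F,
            summary$permanova$habitat$p_value),
    sprintf("Permutational MANOVA ploidy: pseudo-F = %.3f, P = %.4g",
            summary$permanova$ploidy$pseudo_F,
            summary$permanova$ploidy$p_value),
    sprintf("Modularity: M_obs = %.4f, M_random = %.4f +/- %.4f, P = %.4g, %d modules",
            summary$modularity$M_obs, summary$modularity$null_mean,
            summary$modularity$null_sd, summary$modularity$p_value,
            summary$modularity$n_modules),
    sprintf("Indicator OTUs significant at alpha = %g: %d",
            cfg$alpha, summary$indicators$n_significant))
  writeLines(report_lines, file.path(cfg$out_dir, "report.txt"))

  structure(list(tables = inputs, filter = filt, community = community,
                 network = network, indicators = indicators,
                 summary = summary, out_dir = cfg$out_dir),
            class = "dactynet_pipeline")
}

#' @export
print.dactynet_pipeline <- function(x, ...) {
  writeLines(readLines(file.path(x$out_dir, "report.txt")))
  invisible(x)
}
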