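## Synthetic community generator: orchid species in habitat classes,
## fungal OTUs organised in planted habitat blocks plus generalists,
## negative-binomial read counts with log-normal OTU size effects, and
## deterministic spike-ins (rare OTUs, non-mycorrhizal taxa, low-identity
## hits) that exercise every filtering rule. Ground truth for every
## planted feature is returned alongside the tables.

JUNK_GENERA <- c("Mycena", "Armillaria", "Atractiella", "Clavulina",
                 "Coprinus", "Cortinarius", "Inocybe", "Marasmius",
                 "Psathyrella")

#' Configuration for the synthetic community generator
#'
#' @param n_species number of orchid species.
#' @param habitat_allocation named integer vector: species per habitat;
#'   must sum to `n_species` and use only [habitat_levels] names.
#' @param species_table optional data frame (`species`, `habitat`, `ploidy`,
#'   `genome`) overriding the generated species list; the paper-scale preset
#'   uses [dactylorhiza_species].
#' @param populations_per_species integer (recycled) or per-species vector
#'   of population counts (1-3).
#' @param samples_per_population root samples collected per population.
#' @param n_otus_mycorrhizal mycorrhizal OTUs before spike-ins.
#' @param n_otus_junk OTUs from genera of doubtful mycorrhizal status.
#' @param n_otus_low_identity whitelisted-family OTUs with BLAST identity
#'   below the retention threshold.
#' @param n_otus_rare injected OTUs with whole-dataset totals of 1 or 2.
#' @param p_within probability that a habitat-block OTU associates with a
#'   species of its habitat.
#' @param p_between probability it associates with a species of another
#'   habitat.
#' @param generalist_fraction fraction of mycorrhizal OTUs that are habitat
#'   generalists.
#' @param p_generalist association probability of a generalist OTU with any
#'   species.
#' @param n_indicators_per_habitat planted indicator OTUs per habitat:
#'   linked to every species of their habitat, to no other species, with an
#'   elevated abundance effect.
#' @param read_depth mean mycorrhizal reads per sample.
#' @param depth_sdlog log-normal spread of per-sample depth.
#' @param dispersion negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param effect_sdlog log-normal spread of per-OTU abundance effects.
#' @param seed integer seed making the whole dataset reproducible.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_species = 14,
                       habitat_allocation = c(mediterranean = 4, peat_bog = 2,
                                              wetland = 4, coastal = 2,
                                              alpine_boreal = 2),
                       species_table = NULL,
                       populations_per_species = 2,
                       samples_per_population = 3,
                       n_otus_mycorrhizal = 115,
                       n_otus_junk = 25,
                       n_otus_low_identity = 2,
                       n_otus_rare = 20,
                       p_within = 0.5,
                       p_between = 0.02,
                       generalist_fraction = 0.05,
                       p_generalist = 0.5,
                       n_indicators_per_habitat = 1,
                       read_depth = 830,
                       depth_sdlog = 0.3,
                       dispersion = 0.5,
                       effect_sdlog = 1.0,
                       seed = 1) {
  if (!is.null(species_table)) {
    n_species <- nrow(species_table)
    habitat_allocation <- table(factor(species_table$habitat,
                                       levels = habitat_levels()))
    habitat_allocation <- setNames(as.integer(habitat_allocation),
                                   names(habitat_allocation))
  }
  if (sum(habitat_allocation) != n_species)
    stop("habitat_allocation must sum to n_species")
  if (!all(names(habitat_allocation) %in% habitat_levels()))
    stop("unknown habitat in allocation")
  if (!(p_between >= 0 && p_between < p_within && p_within <= 1))
    stop("need 0 <= p_between < p_within <= 1")
  cfg <- list(n_species = n_species, habitat_allocation = habitat_allocation,
              species_table = species_table,
              populations_per_species = populations_per_species,
              samples_per_population = samples_per_population,
              n_otus_mycorrhizal = n_otus_mycorrhizal,
              n_otus_junk = n_otus_junk,
              n_otus_low_identity = n_otus_low_identity,
              n_otus_rare = n_otus_rare,
              p_within = p_within, p_between = p_between,
              generalist_fraction = generalist_fraction,
              p_generalist = p_generalist,
              n_indicators_per_habitat = n_indicators_per_habitat,
              read_depth = read_depth, depth_sdlog = depth_sdlog,
              dispersion = dispersion, effect_sdlog = effect_sdlog,
              seed = seed)
  class(cfg) <- "sim_config"
  cfg
}

#' Paper-scale synthetic preset
#'
#' The study design emulated throughout: 14 *Dactylorhiza* species in five
#' habitat classes (4 Mediterranean / 2 peat bog / 4 wetland / 2 coastal /
#' 2 alpine-boreal), 38 populations of one to three per species, three root
#' samples per population (114 samples), 115 mycorrhizal OTUs dominated by
#' Tulasnellaceae / Ceratobasidiaceae / Sebacinales, a mean mycorrhizal read
#' depth of ~830 reads per sample, plus rare and non-mycorrhizal spike-ins.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [sim_config].
#' @return a `sim_config`.
#' @export
paperlike_preset <- function(seed = 1, ...) {
  ## population counts per species, summing to 38 sites
  pops <- c(3, 3, 3, 3, 2, 3, 3, 2, 3, 3, 2, 2, 3, 3)
  args <- list(species_table = dactylorhiza_species(),
               populations_per_species = pops,
               samples_per_population = 3,
               n_otus_mycorrhizal = 115,
               seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

#' Generate a synthetic orchid-mycorrhiza dataset
#'
#' Draws a species-by-OTU association structure with planted habitat blocks
#' (block OTU linked to a same-habitat species with probability `p_within`,
#' otherwise `p_between`; generalists link uniformly), then per-sample read
#' counts for linked OTUs from a negative binomial whose means follow
#' log-normal OTU effects scaled to the sample's expected depth. Spike-ins
#' are added last: junk-genus OTUs, whitelisted-family OTUs with sub-threshold
#' identity, and rare OTUs with whole-dataset totals of 1-2. Byte-identical
#' output for a given config (the seed is part of the config).
#'
#' @param cfg a [sim_config].
#' @return object of class `myco_sim`: list with `table` ([otu_table]),
#'   `metadata`, `taxonomy` (data frames) and `truth` (list with
#'   `otu_block` (habitat / "generalist" per mycorrhizal OTU),
#'   `planted_partition` (node -> habitat module over species and block
#'   OTUs), `indicator_otus` (named by habitat), `spikes` (ids of rare /
#'   junk / low-identity OTUs), `expected_depth` per sample).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    ## --- species and sampling design -----------------------------------
    sp <- cfg$species_table
    if (is.null(sp)) {
      hab <- rep(names(cfg$habitat_allocation), cfg$habitat_allocation)
      ploidy <- rep(c("2x", "4x"), length.out = cfg$n_species)
      ploidy[min(3, cfg$n_species)] <- "3x"
      sp <- data.frame(species = sprintf("species_%02d", seq_len(cfg$n_species)),
                       habitat = hab, ploidy = ploidy,
                       genome = ifelse(ploidy == "2x", "AA",
                                       ifelse(ploidy == "3x", "AAA", "AABB")),
                       stringsAsFactors = FALSE)
    }
    n_sp <- nrow(sp)
    pops <- rep(cfg$populations_per_species, length.out = n_sp)
    meta <- do.call(rbind, lapply(seq_len(n_sp), function(i) {
      do.call(rbind, lapply(seq_len(pops[i]), function(p) {
        data.frame(sample_id = sprintf("%s_p%d_s%d", sp$species[i], p,
                                       seq_len(cfg$samples_per_population)),
                   species = sp$species[i],
                   population_id = sprintf("%s_p%d", sp$species[i], p),
                   habitat = sp$habitat[i], ploidy = sp$ploidy[i],
                   genome = sp$genome[i], stringsAsFactors = FALSE)
      }))
    }))
    rownames(meta) <- NULL
    validate_metadata(meta)

    ## --- mycorrhizal OTU layout ----------------------------------------
    n_myco <- cfg$n_otus_mycorrhizal
    habs <- names(cfg$habitat_allocation)[cfg$habitat_allocation > 0]
    n_gen <- round(cfg$generalist_fraction * n_myco)
    n_block_total <- n_myco - n_gen
    ## block sizes proportional to species allocation (largest remainder)
    w <- cfg$habitat_allocation[habs] / sum(cfg$habitat_allocation[habs])
    raw <- w * n_block_total
    sizes <- floor(raw)
    rem <- n_block_total - sum(sizes)
    if (rem > 0) {
      extra <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
      sizes[extra] <- sizes[extra] + 1
    }
    otu_block <- c(rep(habs, sizes), rep("generalist", n_gen))
    otu_ids <- sprintf("OTU%03d", seq_len(n_myco))
    names(otu_block) <- otu_ids

    ## planted indicators: first k OTUs of each block
    ind_ids <- character(0)
    for (h in habs) {
      blk <- otu_ids[otu_block == h]
      k <- min(cfg$n_indicators_per_habitat, length(blk))
      ind_ids <- c(ind_ids, setNames(blk[seq_len(k)],
                                     rep(h, k)))
    }

    ## species x OTU association
    inc <- matrix(0L, n_sp, n_myco, dimnames = list(sp$species, otu_ids))
    for (j in seq_len(n_myco)) {
      blk <- otu_block[j]
      if (otu_ids[j] %in% ind_ids) {
        inc[sp$habitat == blk, j] <- 1L
      } else if (blk == "generalist") {
        inc[, j] <- as.integer(runif(n_sp) < cfg$p_generalist)
      } else {
        pr <- ifelse(sp$habitat == blk, cfg$p_within, cfg$p_between)
        inc[, j] <- as.integer(runif(n_sp) < pr)
      }
      if (sum(inc[, j]) == 0) {  # keep every OTU attached somewhere
        host <- if (blk == "generalist") sample.int(n_sp, 1)
                else sample(which(sp$habitat == blk), 1)
        inc[host, j] <- 1L
      }
    }

    ## --- read counts ----------------------------------------------------
    effect <- rlnorm(n_myco, meanlog = 0, sdlog = cfg$effect_sdlog)
    names(effect) <- otu_ids
    effect[ind_ids] <- effect[ind_ids] * 3  # planted indicators stand out
    depth <- cfg$read_depth * rlnorm(nrow(meta), 0, cfg$depth_sdlog)
    counts <- matrix(0L, nrow(meta), n_myco,
                     dimnames = list(meta$sample_id, otu_ids))
    for (s in seq_len(nrow(meta))) {
      linked <- which(inc[meta$species[s], ] == 1L)
      if (length(linked) == 0) next
      mu <- depth[s] * effect[linked] / sum(effect[linked])
      counts[s, linked] <- rnbinom(length(linked), mu = mu,
                                   size = cfg$dispersion)
    }

    tax <- data.frame(
      otu_id = otu_ids,
      family_or_clade = myco_families(n_myco),
      percent_identity = round(runif(n_myco, 92, 100), 1),
      stringsAsFactors = FALSE)

    ## --- spike-ins ------------------------------------------------------
    add_col <- function(counts, id, col) {
      counts <- cbind(counts, col)
      colnames(counts)[ncol(counts)] <- id
      counts
    }
    next_id <- n_myco
    junk_ids <- character(0)
    for (k in seq_len(cfg$n_otus_junk)) {
      next_id <- next_id + 1
      id <- sprintf("OTU%03d", next_id)
      junk_ids <- c(junk_ids, id)
      hosts <- sample.int(n_sp, sample(1:3, 1))
      col <- integer(nrow(meta))
      rows <- which(meta$species %in% sp$species[hosts])
      hit <- rows[runif(length(rows)) < 0.3]
      col[hit] <- rnbinom(length(hit), mu = 8, size = 0.5) + 1L
      counts <- add_col(counts, id, col)
      tax <- rbind(tax, data.frame(
        otu_id = id,
        family_or_clade = sample(JUNK_GENERA, 1),
        percent_identity = round(runif(1, 85, 100), 1),
        stringsAsFactors = FALSE))
    }
    lowid_ids <- character(0)
    for (k in seq_len(cfg$n_otus_low_identity)) {
      next_id <- next_id + 1
      id <- sprintf("OTU%03d", next_id)
      lowid_ids <- c(lowid_ids, id)
      col <- integer(nrow(meta))
      hit <- sample.int(nrow(meta), 5)
      col[hit] <- rpois(5, 20) + 1L
      counts <- add_col(counts, id, col)
      tax <- rbind(tax, data.frame(
        otu_id = id,
        family_or_clade = sample(mycorrhizal_whitelist(), 1),
        percent_identity = round(runif(1, 80, 90), 1),
        stringsAsFactors = FALSE))
    }
    rare_ids <- character(0)
    if (cfg$n_otus_rare > 0) {
      for (k in seq_len(cfg$n_otus_rare)) {
        next_id <- next_id + 1
        id <- sprintf("OTU%03d", next_id)
        rare_ids <- c(rare_ids, id)
        total <- 1L + (k %% 2L)  # alternate singletons and doubletons
        col <- integer(nrow(meta))
        where <- sample.int(nrow(meta), total)
        col[where] <- 1L
        counts <- add_col(counts, id, col)
        tax <- rbind(tax, data.frame(
          otu_id = id,
          family_or_clade = sample(mycorrhizal_whitelist(), 1),
          percent_identity = round(runif(1, 92, 100), 1),
          stringsAsFactors = FALSE))
      }
    }
    tax <- flag_mycorrhizal(tax)

    ## planted module partition: species + block OTUs, by habitat
    block_otus <- otu_ids[otu_block %in% habs]
    planted <- c(setNames(match(sp$habitat, habs), sp$species),
                 setNames(match(otu_block[block_otus], habs), block_otus))

    structure(list(
      table = otu_table(counts),
      metadata = meta,
      taxonomy = tax,
      truth = list(otu_block = otu_block,
                   planted_partition = planted,
                   indicator_otus = ind_ids,
                   spikes = list(rare = rare_ids, junk = junk_ids,
                                 low_identity = lowid_ids),
                   expected_depth = setNames(depth, meta$sample_id))
    ), class = "myco_sim")
  })
}

## Family labels in roughly the empirical proportions of orchid mycorrhizal
## surveys: Tulasnellaceae and Ceratobasidiaceae dominant, Sebacinales
## split into clades A and B, some Thelephoraceae.
myco_families <- function(n) {
  base <- c(Tulasnellaceae = 31, Ceratobasidiaceae = 33,
            Sebacinales_A = 9, Sebacinales_B = 23, Thelephoraceae = 19)
  fams <- rep(names(base), base)
  rep(fams, length.out = n)
}

#' @export
print.myco_sim <- function(x, ...) {
  cat("Synthetic orchid-mycorrhiza dataset\n")
  cat(sprintf("  %d samples, %d species, %d populations, %d OTUs\n",
              nrow(x$table), length(unique(x$metadata$species)),
              length(unique(x$metadata$population_id)), ncol(x$table)))
  cat(sprintf("  spike-ins: %d rare, %d junk, %d low-identity\n",
              length(x$truth$spikes$rare), length(x$truth$spikes$junk),
              length(x$truth$spikes$low_identity)))
  invisible(x)
}

#' Write the three synthetic tables plus ground truth to a directory
#'
#' @param sim a `myco_sim`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_otu_table(sim$table, file.path(dir, "otu_table.tsv"))
  write_metadata(sim$metadata, file.path(dir, "metadata.tsv"))
  write_taxonomy(sim$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_json_file(list(
    otu_block = as.list(sim$truth$otu_block),
    planted_partition = as.list(sim$truth$planted_partition),
    indicator_otus = as.list(sim$truth$indicator_otus),
    spikes = sim$truth$spikes
  ), file.path(dir, "ground_truth.json"))
  invisible(dir)
}
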