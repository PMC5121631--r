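test_that("global singletons and doubletons are removed at the boundary", {
  m <- matrix(c(1L, 1L,   # total 2 -> removed
                2L, 1L,   # total 3 -> retained
                0L, 1L,   # total 1 -> removed
                5L, 0L),  # retained
              nrow = 2,
              dimnames = list(c("s1", "s2"), paste0("OTU", 1:4)))
  res <- remove_rare_otus(otu_table(m))
  expect_identical(colnames(res$table), c("OTU2", "OTU4"))
  expect_identical(res$report$removed_ids, c("OTU1", "OTU3"))
  expect_identical(res$report$n_removed_rare, 2L)
  expect_error(remove_rare_otus(otu_table(m), min_total_count = 0), ">= 1")
})

test_that("rarity filter equals the column-sum oracle and only deletes columns", {
  for (seed in 1:10) {
    x <- random_table(seed, n_samples = 5, n_otus = 50, lambda = 0.4)
    keep_oracle <- colnames(x)[colSums(unclass(x)) >= 3]
    if (length(keep_oracle) == 0) next
    res <- remove_rare_otus(x)
    expect_identical(colnames(res$table), keep_oracle)
    expect_identical(unclass(res$table), unclass(x)[, keep_oracle])
    expect_identical(sum(x) - sum(res$table),
                     sum(unclass(x)[, res$report$removed_ids]))
    expect_identical(res$report$n_input_otus,
                     res$report$n_removed_rare + res$report$n_retained)
  }
})

test_that("mycorrhizal flag applies the whitelist with a strict identity cut", {
  tax <- data.frame(
    otu_id = c("a", "b", "c", "d"),
    family_or_clade = c("Tulasnellaceae", "Tulasnellaceae", "Mycena",
                        "Sebacinales_B"),
    percent_identity = c(95, 90, 99, 90.1),
    stringsAsFactors = FALSE)
  out <- flag_mycorrhizal(tax)
  expect_identical(out$putative_mycorrhizal, c(TRUE, FALSE, FALSE, TRUE))
  expect_error(flag_mycorrhizal(tax, whitelist = character(0)), "non-empty")
})

test_that("subset_mycorrhizal keeps exactly the flagged OTUs", {
  x <- random_table(2, n_samples = 3, n_otus = 3)
  tax <- data.frame(otu_id = colnames(x),
                    family_or_clade = c("Tulasnellaceae", "Mycena",
                                        "Ceratobasidiaceae"),
                    percent_identity = c(99, 99, 99),
                    stringsAsFactors = FALSE)
  res <- subset_mycorrhizal(x, tax)
  expect_identical(colnames(res$table), colnames(x)[c(1, 3)])

  tax_all <- tax; tax_all$family_or_clade <- "Tulasnellaceae"
  expect_identical(unclass(subset_mycorrhizal(x, tax_all)$table), unclass(x))

  expect_error(subset_mycorrhizal(x, tax[1:2, ]), "no taxonomy record")
})

test_that("the two column filters commute", {
  sim <- simulate_dataset(paperlike_preset(seed = 4))
  a <- subset_mycorrhizal(remove_rare_otus(sim$table)$table, sim$taxonomy)$table
  b <- remove_rare_otus(subset_mycorrhizal(sim$table, sim$taxonomy)$table)$table
  expect_identical(unclass(a), unclass(b))
})

test_that("prevalence sets follow union semantics and match the set oracle", {
  m <- matrix(c(3L, 0L, 0L, 0L, 1L, 2L), nrow = 3,
              dimnames = list(c("s1", "s2", "s3"), c("a", "b")))
  meta <- data.frame(sample_id = c("s1", "s2", "s3"),
                     species = c("sp1", "sp1", "sp2"),
                     population_id = c("p1", "p2", "p3"),
                     habitat = "wetland", ploidy = "2x", genome = "AA",
                     stringsAsFactors = FALSE)
  prev <- prevalence_by_group(otu_table(m), meta, "species")
  expect_identical(prev$sp1, c("a", "b"))  # union over s1 (a) and s2 (b)
  expect_identical(prev$sp2, "b")

  sim <- simulate_dataset(paperlike_preset(seed = 2))
  prev <- prevalence_by_group(sim$table, sim$metadata, "species")
  for (sp in names(prev)) {
    rows <- sim$metadata$sample_id[sim$metadata$species == sp]
    oracle <- colnames(sim$table)[colSums(unclass(sim$table)[rows, , drop = FALSE] > 0) > 0]
    expect_identical(sort(prev[[sp]]), sort(oracle))
  }
  s <- prevalence_summary(prev)
  expect_identical(s$n_groups, 14L)
  expect_true(s$min >= 1 && s$max <= ncol(sim$table))
})

test_that("empty groups are dropped from prevalence with a warning", {
  x <- random_table(3, n_samples = 2)
  meta <- random_meta(x, n_species = 2)
  meta <- rbind(meta, data.frame(sample_id = "extra", species = "species_99",
                                 population_id = "p", habitat = "coastal",
                                 ploidy = "3x", genome = "AA",
                                 stringsAsFactors = FALSE))
  expect_warning(prev <- prevalence_by_group(x, meta, "species"), "species_99")
  expect_false("species_99" %in% names(prev))
})

test_that("ploidy Venn partition assigns OTUs to exact subsets", {
  prev <- list(dip = c("a", "b"), tet = c("a", "c"), tri = "d")
  meta <- data.frame(sample_id = c("s1", "s2", "s3"),
                     species = c("dip", "tet", "tri"),
                     population_id = c("p1", "p2", "p3"),
                     habitat = "wetland",
                     ploidy = c("2x", "4x", "3x"), genome = "AA",
                     stringsAsFactors = FALSE)
  v <- venn_by_ploidy(prev, meta)
  expect_identical(v$subsets[["2x:4x"]], 1L)  # OTU a
  expect_identical(v$subsets[["2x"]], 1L)     # OTU b
  expect_identical(v$subsets[["4x"]], 1L)     # OTU c
  expect_identical(v$subsets[["3x"]], 1L)     # OTU d
  expect_identical(unname(v$totals), c(2L, 1L, 2L))

  # single diploid species: everything in {2x}
  v2 <- venn_by_ploidy(list(dip = c("a", "b")), meta[1, ])
  expect_identical(unname(v2$totals), c(2L, 0L, 0L))

  # per-ploidy total equals the sum of subset counts containing that ploidy
  sim <- simulate_dataset(paperlike_preset(seed = 6))
  f <- subset_mycorrhizal(remove_rare_otus(sim$table)$table, sim$taxonomy)
  prev3 <- prevalence_by_group(f$table, sim$metadata, "species")
  v3 <- venn_by_ploidy(prev3, sim$metadata)
  for (pl in ploidy_levels()) {
    contains <- grepl(pl, names(v3$subsets), fixed = TRUE)
    expect_identical(sum(v3$subsets[contains]), v3$totals[[pl]])
  }
  expect_identical(sum(v3$subsets), length(unique(unlist(prev3))))
})
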