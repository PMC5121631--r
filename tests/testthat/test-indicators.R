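make_sites <- function() {
  # 6 sites in 2 equal habitat groups
  x <- matrix(0, 6, 4, dimnames = list(paste0("s", 1:6),
                                       c("perfect", "ubiq", "absent", "g2only")))
  x[1:3, "perfect"] <- 5
  x[, "ubiq"] <- 3
  x[4:6, "g2only"] <- c(2, 4, 6)
  g <- setNames(rep(c("g1", "g2"), each = 3), rownames(x))
  list(x = x, g = g)
}

test_that("IndVal components reproduce the closed-form cases", {
  s <- make_sites()
  res <- indval_components(s$x, s$g, "g1")
  expect_equal(res$A[res$otu_id == "perfect"], 1)
  expect_equal(res$B[res$otu_id == "perfect"], 1)
  expect_equal(res$ind_val[res$otu_id == "perfect"], 1)

  expect_equal(res$A[res$otu_id == "ubiq"], 0.5)
  expect_equal(res$B[res$otu_id == "ubiq"], 1)
  expect_equal(res$ind_val[res$otu_id == "ubiq"], sqrt(0.5), tolerance = 1e-12)

  # absent from the target group entirely
  expect_equal(res$B[res$otu_id == "g2only"], 0)
  expect_equal(res$ind_val[res$otu_id == "g2only"], 0)

  # absent everywhere: undefined, not zero
  expect_true(is.na(res$ind_val[res$otu_id == "absent"]))

  expect_error(indval_components(s$x, s$g, "nope"), "subset")
  expect_error(indval_components(s$x, s$g, c("g1", "g2")), "proper subset")
})

test_that("IndVal is invariant to positive rescaling of an OTU", {
  set.seed(8)
  x <- matrix(rpois(60, 2), 10, 6,
              dimnames = list(paste0("s", 1:10), paste0("o", 1:6)))
  g <- setNames(rep(c("a", "b"), each = 5), rownames(x))
  base <- indval_components(x, g, "a")
  x2 <- x
  x2[, 3] <- x[, 3] * 17
  scaled <- indval_components(x2, g, "a")
  expect_equal(scaled$ind_val, base$ind_val, tolerance = 1e-12)
})

test_that("IndVal components match the brute-force definition on random data", {
  set.seed(21)
  x <- matrix(rpois(120, 1.5), 12, 10,
              dimnames = list(paste0("s", 1:12), paste0("o", 1:10)))
  g <- setNames(sample(c("a", "b", "c"), 12, replace = TRUE), rownames(x))
  while (length(unique(g)) < 3) g <- setNames(sample(c("a", "b", "c"), 12, TRUE),
                                              rownames(x))
  for (target in list("a", "b", c("a", "c"))) {
    mine <- indval_components(x, g, target)$ind_val
    expect_equal(mine, oracle_indval(x, g, target), tolerance = 1e-12)
  }
})

test_that("best_combination equals enumeration over all unions", {
  set.seed(31)
  hab <- c("mediterranean", "peat_bog", "wetland", "coastal")
  x <- matrix(rpois(16 * 8, 1), 16, 8,
              dimnames = list(paste0("s", 1:16), paste0("o", 1:8)))
  g <- setNames(rep(hab, each = 4), rownames(x))
  res <- best_combination(x, g, max_order = 3)
  unions <- unlist(lapply(1:3, function(k)
    combn(sort(unique(g)), k, paste, collapse = "+", simplify = FALSE)),
    recursive = FALSE)
  for (j in seq_len(ncol(x))) {
    vals <- vapply(unions, function(u)
      oracle_indval(x, g, strsplit(u, "+", fixed = TRUE)[[1]])[j], numeric(1))
    if (all(is.na(vals))) {
      expect_true(is.na(res$ind_val[j]))
    } else {
      expect_equal(res$ind_val[j], max(vals, na.rm = TRUE), tolerance = 1e-12)
    }
  }

  # OTU spread evenly over exactly two habitats picks their union
  x2 <- matrix(0, 16, 1, dimnames = list(rownames(x), "pair"))
  x2[g %in% c("wetland", "mediterranean"), 1] <- 4
  r2 <- best_combination(x2, g, max_order = 3)
  expect_identical(r2$best_group, "mediterranean+wetland")
  expect_equal(r2$ind_val, 1)

  # single-habitat OTU picks its singleton
  x3 <- matrix(0, 16, 1, dimnames = list(rownames(x), "solo"))
  x3[g == "coastal", 1] <- 2
  expect_identical(best_combination(x3, g, max_order = 3)$best_group, "coastal")

  # constant OTU: best IndVal < 1, maximal allowed union wins
  x4 <- matrix(3, 16, 1, dimnames = list(rownames(x), "const"))
  r4 <- best_combination(x4, g, max_order = 3)
  expect_lt(r4$ind_val, 1)
  expect_identical(length(strsplit(r4$best_group, "+", fixed = TRUE)[[1]]), 3L)
})

test_that("union fidelity is the site-weighted mean of member fidelities", {
  set.seed(41)
  x <- matrix(rpois(36, 1), 12, 3,
              dimnames = list(paste0("s", 1:12), paste0("o", 1:3)))
  g <- setNames(rep(c("a", "b", "c"), c(3, 4, 5)), rownames(x))
  Ba <- indval_components(x, g, "a")$B
  Bb <- indval_components(x, g, "b")$B
  Bab <- indval_components(x, g, c("a", "b"))$B
  expect_equal(Bab, (3 * Ba + 4 * Bb) / 7, tolerance = 1e-12)
})

test_that("permutation p matches exhaustive relabeling on six sites", {
  s <- make_sites()
  x <- s$x[, c("perfect", "ubiq", "g2only")]
  x["s2", "perfect"] <- 0  # imperfect indicator: non-degenerate p
  # exact permutation distribution: all 20 assignments of 3 sites to g1
  combos <- combn(6, 3)
  exact_p <- function(j) {
    obs <- max(oracle_indval(x, s$g, "g1")[j], oracle_indval(x, s$g, "g2")[j])
    stats_perm <- apply(combos, 2, function(idx) {
      gg <- setNames(rep("g2", 6), rownames(x))
      gg[idx] <- "g1"
      max(oracle_indval(x, gg, "g1")[j], oracle_indval(x, gg, "g2")[j])
    })
    mean(stats_perm >= obs - 1e-12)
  }
  res <- indicator_test(x, s$g, n_perm = 9999, seed = 2)
  for (j in seq_len(ncol(x))) {
    expect_lt(abs(res$p_value[j] - exact_p(j)), 0.02)
  }
  expect_error(indicator_test(x, s$g, n_perm = 0), "n_perm")
})

test_that("planted indicators are significant; exchangeable OTUs are not", {
  # background = ubiquitous generalists: present in every species, so only
  # sequencing noise distinguishes sites and habitat labels are exchangeable
  # for them; the planted indicators are the only habitat-linked OTUs
  cfg <- sim_config(n_species = 8,
                    habitat_allocation = c(mediterranean = 2, peat_bog = 2,
                                           wetland = 2, coastal = 2,
                                           alpine_boreal = 0),
                    n_otus_mycorrhizal = 40, n_otus_junk = 0,
                    n_otus_low_identity = 0, n_otus_rare = 0,
                    generalist_fraction = 0.8, p_generalist = 1,
                    n_indicators_per_habitat = 2,
                    populations_per_species = 3, seed = 77)
  sim <- simulate_dataset(cfg)
  sites <- aggregate_by_population(sim$table, sim$metadata)
  res <- indicator_test(sites, attr(sites, "habitat"), n_perm = 499,
                        seed = 1, alpha = 0.05, adjust = "BH")
  planted <- sim$truth$indicator_otus
  hit <- res$significant[match(planted, res$otu_id)]
  expect_gte(mean(hit), 0.9)  # sensitivity
  false_pos <- sum(res$significant) - sum(hit)
  fdr <- false_pos / max(1, sum(res$significant))
  expect_lte(fdr, 0.1)
})
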