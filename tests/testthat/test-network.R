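test_that("network construction counts links and prunes isolated nodes", {
  net <- build_network(list(A = "o1", B = "o2"))
  expect_identical(net$L, 2L)
  expect_identical(unname(unclass(net$incidence)),
                   matrix(c(1L, 0L, 0L, 1L), 2, 2))

  shared <- build_network(list(A = c("o1", "o2", "o3"),
                               B = c("o1", "o2", "o3"),
                               C = c("o1", "o2", "o3")))
  expect_identical(shared$L, 9L)
  expect_true(all(shared$incidence == 1L))

  sim <- simulate_dataset(paperlike_preset(seed = 8))
  f <- subset_mycorrhizal(remove_rare_otus(sim$table)$table, sim$taxonomy)
  prev <- prevalence_by_group(f$table, sim$metadata, "species")
  net <- build_network(prev)
  pres <- aggregate_by_species(f$table, sim$metadata, "presence")
  expect_identical(net$L, sum(unclass(pres)))  # counting oracle
  expect_identical(unname(net$degrees[rownames(net$incidence)]),
                   unname(rowSums(net$incidence)))

  m <- matrix(c(1L, 0L, 1L, 0L, 0L, 0L), 2, 3,
              dimnames = list(c("A", "B"), c("o1", "o2", "o3")))
  expect_warning(expect_error(build_network(m), "at least 2 species"),
                 "pruning isolated")
  expect_error(build_network(list()), "empty")
})

test_that("the modularity index satisfies its closed-form values", {
  net <- build_network(list(A = "o1", B = "o2"))
  one <- setNames(rep(1, 4), c("A", "B", "o1", "o2"))
  expect_identical(modularity_index(net, one), 0)  # l=L, d=2L exactly

  good <- setNames(c(1, 2, 1, 2), c("A", "B", "o1", "o2"))
  expect_equal(modularity_index(net, good), 0.5, tolerance = 1e-12)

  bad <- setNames(c(1, 2, 2, 1), c("A", "B", "o1", "o2"))
  expect_equal(modularity_index(net, bad), -0.5, tolerance = 1e-12)

  expect_error(modularity_index(net, good[1:3]), "missing from assignment")
})

test_that("modularity matches igraph on random networks and partitions", {
  skip_if_not_installed("igraph")
  for (seed in 1:10) {
    net <- random_network(seed)
    e <- dactynet:::network_edges(net)
    g <- igraph::graph_from_edgelist(cbind(e$i + 1, e$j + 1), directed = FALSE)
    set.seed(seed)
    mem <- sample(1:3, length(e$nodes), replace = TRUE)
    expect_equal(modularity_index(net, setNames(mem, e$nodes)),
                 igraph::modularity(g, membership = mem),
                 tolerance = 1e-12)
  }
})

test_that("module partitions keep consistent bookkeeping and canonical labels", {
  for (seed in 1:20) {
    net <- random_network(seed)
    p <- detect_modules(net, seed = seed, schedule = test_schedule())
    # internal consistency: stored M reproduces modularity_index
    expect_equal(p$M, modularity_index(net, p$assignment), tolerance = 1e-12)
    expect_equal(p$M, sum(p$l_s / p$L - (p$d_s / (2 * p$L))^2),
                 tolerance = 1e-12)
    expect_identical(sum(p$d_s), 2 * p$L)
    expect_lte(sum(p$l_s), p$L)
    expect_lte(p$M, 1 - 1 / p$n_modules + 1e-12)

    # canonicalization: arbitrary relabeling maps to the same partition
    shuffled <- setNames(match(p$assignment, sample(max(p$assignment))) * 10,
                         names(p$assignment))
    p2 <- module_partition(net, shuffled)
    expect_identical(p2$assignment, p$assignment)
  }
})

test_that("annealing recovers planted structure on easy networks", {
  # two disconnected stars -> the two components, M = 0.5
  m <- matrix(0L, 2, 4, dimnames = list(c("A", "B"), paste0("o", 1:4)))
  m["A", c("o1", "o2")] <- 1L
  m["B", c("o3", "o4")] <- 1L
  p <- detect_modules(build_network(m), seed = 1)
  expect_equal(p$M, 0.5, tolerance = 1e-12)
  expect_identical(p$n_modules, 2L)
  expect_identical(p$assignment[["A"]], p$assignment[["o1"]])
  expect_identical(p$assignment[["B"]], p$assignment[["o4"]])

  # complete bipartite graphs: M = 0, single module after tie-breaking
  for (k in 2:3) {
    mk <- matrix(1L, k, k, dimnames = list(paste0("sp", 1:k), paste0("o", 1:k)))
    pk <- detect_modules(build_network(mk), seed = 2)
    expect_equal(pk$M, 0, tolerance = 1e-12)
    expect_identical(pk$n_modules, 1L)
  }
})

test_that("annealing attains the exhaustive maximum on small networks", {
  for (seed in 1:12) {
    net <- random_network(seed)
    p <- detect_modules(net, seed = seed + 100, schedule = test_schedule())
    expect_equal(p$M, oracle_max_M(net), tolerance = 1e-10)
  }
})

test_that("detect_modules is deterministic given a seed", {
  net <- random_network(31, nr = 4, nc = 4)
  p1 <- detect_modules(net, seed = 5, schedule = test_schedule())
  p2 <- detect_modules(net, seed = 5, schedule = test_schedule())
  expect_identical(p1$assignment, p2$assignment)
  expect_error(detect_modules(net, seed = 1,
                              schedule = sa_schedule(cooling = 1.2)),
               "cooling")
})

test_that("checkerboard randomisation preserves both margins on every draw", {
  # unique swap on the 2x2 checkerboard
  m <- matrix(c(1L, 0L, 0L, 1L), 2, 2,
              dimnames = list(c("A", "B"), c("o1", "o2")))
  net <- build_network(m)
  r <- randomize_network(net, n_swaps = 51, seed = 3)
  expect_identical(unname(rowSums(r$incidence)), c(1, 1))
  expect_identical(unname(colSums(r$incidence)), c(1, 1))

  # all-ones: nothing to swap, identical copy with a warning
  ones <- build_network(matrix(1L, 2, 2, dimnames = dimnames(m)))
  expect_warning(r1 <- randomize_network(ones, seed = 1), "no swappable")
  expect_identical(unclass(r1$incidence), unclass(ones$incidence))

  # margins preserved exactly on every draw of a larger random fixture
  net <- random_network(17, nr = 6, nc = 8, p = 0.4)
  for (s in 1:50) {
    r <- randomize_network(net, seed = s)
    expect_identical(rowSums(r$incidence)[rownames(net$incidence)],
                     rowSums(net$incidence))
    expect_identical(colSums(r$incidence)[colnames(net$incidence)],
                     colSums(net$incidence))
  }
  expect_identical(randomize_network(net, seed = 9)$incidence,
                   randomize_network(net, seed = 9)$incidence)
})

test_that("modularity significance separates planted from random structure", {
  # strongly modular: two near-disconnected blocks
  set.seed(5)
  m <- matrix(0L, 6, 12, dimnames = list(paste0("sp", 1:6), paste0("o", 1:12)))
  m[1:3, 1:6] <- rbinom(18, 1, 0.8)
  m[4:6, 7:12] <- rbinom(18, 1, 0.8)
  m[1, 7] <- 1L; m[4, 1] <- 1L  # keep it connected
  m[rowSums(m) == 0, 1] <- 1L
  net <- build_network(m[, colSums(m) > 0])
  sig <- modularity_significance(net, n_null = 19, seed = 2,
                                 schedule = test_schedule())
  expect_equal(sig$p_value, 1 / 20, tolerance = 1e-12)
  expect_equal(sig$p_value,
               (1 + sum(sig$null_Ms >= sig$M_obs)) / (1 + sig$n_null),
               tolerance = 1e-12)
  expect_equal(sig$null_mean, mean(sig$null_Ms), tolerance = 1e-12)
  expect_equal(sig$null_sd, sd(sig$null_Ms), tolerance = 1e-12)
  expect_identical(length(sig$null_Ms), 19L)
  expect_error(modularity_significance(net, n_null = 0), "n_null")
})

test_that("module-sorted incidence matrix blocks within-module links", {
  net <- build_network(list(A = c("o1", "o2"), B = c("o3", "o4")))
  p <- detect_modules(net, seed = 1)
  mm <- module_matrix(net, p)
  rm_ <- attr(mm, "row_module"); cm_ <- attr(mm, "col_module")
  expect_true(!is.unsorted(rm_))
  expect_true(!is.unsorted(cm_))
  expect_identical(sum(mm), net$L)
})
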