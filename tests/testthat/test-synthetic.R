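test_that("two tips give a single node at the requested root age", {
  set.seed(71)
  tt <- simulate_bd_tree(2, birth = 0.002, death = 0, root_age = 1234)
  expect_equal(length(tt$phy$tip.label), 2L)
  expect_equal(tt$ages[3], 1234)
})

test_that("simulated chronograms are ultrametric", {
  set.seed(72)
  for (rep in 1:5) {
    tt <- simulate_bd_tree(sample(5:30, 1), birth = 0.002, death = 5e-4,
                           root_age = 2000)
    depth <- ape::node.depth.edgelength(tt$phy)
    tipd <- depth[seq_along(tt$phy$tip.label)]
    expect_lt(max(abs(tipd - 2000)), 1e-6)
    expect_equal(tt$ages[length(tt$phy$tip.label) + 1L], 2000,
                 tolerance = 1e-9)
  }
  expect_error(simulate_bd_tree(1, 1, 0, 1), "two tips")
  expect_error(simulate_bd_tree(5, 0.1, 0.2, 1), "birth > death")
})

test_that("pure-birth node depths follow the conditioned Yule distribution", {
  lambda <- 0.003; T0 <- 1000; n <- 8
  # analytic CDF of a non-root node depth for a Yule tree conditioned on
  # its crown age (coalescent-point-process form)
  F <- function(t) (1 - exp(-lambda * t)) / (1 - exp(-lambda * T0))
  set.seed(73)
  depths <- unlist(lapply(1:300, function(i) {
    tt <- simulate_bd_tree(n, birth = lambda, death = 0, root_age = T0)
    ages <- tt$ages[(n + 2):(2 * n - 1)] # internal nodes minus the root
  }))
  ks <- suppressWarnings(ks.test(depths, F)$statistic)
  expect_lt(ks, 0.035)
})

test_that("generated calibrations always bracket the true node ages", {
  for (seed in 1:5) {
    ds <- simulate_dataset(scenario_spec(placement = "mito_like"),
                           seed = seed)
    nodes <- vapply(ds$calibrations, function(cal)
      resolve_clade(ds$tree, cal$clade), integer(1))
    for (i in seq_along(nodes)) {
      age <- ds$tree$ages[nodes[i]]
      expect_gte(age, ds$calibrations[[i]]$t_min)
      expect_lte(age, ds$calibrations[[i]]$t_max)
    }
  }
})

test_that("vanishing noise returns the true branch lengths", {
  ds <- simulate_dataset(scenario_spec(cv = 1e-9), seed = 3)
  b_true <- expected_branch_lengths(ds$tree, ds$rates$branch_rates)
  expect_lt(max(abs(ds$partitions[[1]]$b_hat - b_true) /
                  pmax(b_true, 1e-8)), 1e-3)
})

test_that("matched placements share tree, rates and noise", {
  ds <- simulate_dataset(scenario_spec(placement = "both"), seed = 4)
  expect_s3_class(ds$calibrations_mito, "calibration_set")
  expect_s3_class(ds$calibrations_cyano, "calibration_set")
  # identical nodes and identical minimum bounds; maxima differ
  tm <- vapply(ds$calibrations_mito, `[[`, 1, "t_min")
  tc <- vapply(ds$calibrations_cyano, `[[`, 1, "t_min")
  expect_equal(tm, tc)
  n_int <- length(tm) - 1L
  expect_true(all(is.infinite(vapply(ds$calibrations_cyano, `[[`, 1,
                                     "t_max")[seq_len(n_int)])))
  expect_true(all(is.finite(vapply(ds$calibrations_mito, `[[`, 1, "t_max"))))
})

test_that("every generated dataset passes the pipeline's own validators", {
  for (seed in 6:8) {
    ds <- simulate_dataset(scenario_spec(), seed = seed)
    expect_identical(nrow(suppressWarnings(
      check_consistency(ds$calibrations, ds$tree))), 0L)
    expect_s3_class(timetree(ds$tree$phy, ds$tree$ages), "timetree")
    ages <- prior_sample(ds$tree, ds$calibrations, 2)
    expect_true(all(ages[, ds$tree$phy$edge[, 1]] -
                      ages[, ds$tree$phy$edge[, 2]] > 0))
    nb <- nrow(ds$tree$phy$edge)
    for (p in ds$partitions) expect_length(p$b_hat, nb)
  }
})

test_that("host-state simulation respects frozen and ergodic limits", {
  set.seed(74)
  tt <- random_chronogram(10, root_age = 1)
  frozen <- simulate_host_states(tt, 0, 0)
  expect_length(unique(as.character(frozen)), 1L)
  # high rates: tip frequencies approach the stationary distribution
  freq <- mean(replicate(300, {
    st <- simulate_host_states(tt, 30, 10)
    mean(st == "P")
  }))
  expect_equal(freq, 0.75, tolerance = 0.03)
  set.seed(5); a <- simulate_host_states(tt, 1, 2)
  set.seed(5); b <- simulate_host_states(tt, 1, 2)
  expect_identical(a, b)
})

test_that("datasets round-trip through their plain-text files", {
  ds <- simulate_dataset(scenario_spec(), seed = 9)
  d <- tempfile(); write_dataset(ds, d)
  expect_true(all(c("tree.nwk", "calibrations.tsv", "truth.json") %in%
                    list.files(d)))
  tt <- parse_newick(paste(readLines(file.path(d, "tree.nwk")),
                           collapse = ""))
  expect_equal(sort(tt$phy$tip.label), sort(ds$tree$phy$tip.label))
  truth <- jsonlite::read_json(file.path(d, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$mu, ds$mu, tolerance = 1e-12)
  p1 <- read_partition_data(d, "part1")
  expect_equal(p1$b_hat, ds$partitions[[1]]$b_hat)
})

test_that("the packaged benchmark loads and is internally consistent", {
  b <- benchmark_dataset()
  expect_equal(length(b$tree$phy$tip.label), 20L)
  expect_length(b$calibrations, 3L)
  expect_length(b$partitions, 2L)
  expect_identical(nrow(suppressWarnings(
    check_consistency(b$calibrations, b$tree))), 0L)
  b_true <- expected_branch_lengths(b$tree, b$truth$branch_rates)
  expect_equal(length(b_true), nrow(b$tree$phy$edge))
})
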