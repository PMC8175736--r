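# helper: a minimal posterior_trace-like object from an age matrix
fake_trace <- function(ages, nodes) {
  colnames(ages) <- paste0("t_", nodes)
  structure(list(ages = ages, internal_nodes = nodes,
                 hyper = data.frame(mu = rep(1e-4, nrow(ages)),
                                    sigma2 = rep(1e-4, nrow(ages)))),
            class = "posterior_trace")
}

test_that("infinite-sites regression recovers exact lines and the OLS oracle", {
  d <- data.frame(mean = seq(100, 2000, length.out = 20))
  d$width <- 0.3 * d$mean
  fit <- suppressWarnings(infinite_sites_regression(d))
  expect_equal(fit$slope, 0.3)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)

  flat <- data.frame(mean = seq(100, 500, length.out = 10), width = 50)
  expect_equal(suppressWarnings(infinite_sites_regression(flat))$slope, 0)

  set.seed(51)
  r <- data.frame(mean = runif(50, 100, 3000), width = runif(50, 10, 500))
  fit2 <- infinite_sites_regression(r)
  X <- cbind(1, r$mean)
  beta <- solve(t(X) %*% X, t(X) %*% r$width) # normal equations oracle
  expect_equal(fit2$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fit2$slope, beta[2], tolerance = 1e-10)

  expect_error(infinite_sites_regression(d[1:2, ]), "three")
  expect_error(infinite_sites_regression(
    data.frame(mean = rep(5, 5), width = 1:5)), "degenerate")
})

test_that("prior/posterior comparison flags uninformative nodes", {
  set.seed(52)
  n <- 4000
  prior <- fake_trace(cbind(rnorm(n, 1000, 100), rnorm(n, 500, 50)), c(9, 10))
  same <- prior_posterior_compare(prior, prior)
  expect_true(all(!same$informative))
  expect_true(all(same$ks < 1e-12))
  post <- fake_trace(cbind(rnorm(n, 1000, 100), rnorm(n, 525, 50)), c(9, 10))
  cmp <- prior_posterior_compare(prior, post, ks_threshold = 0.1)
  # node 10 shifted by half a prior SD: KS ~ 0.2, flagged informative
  expect_true(cmp$informative[cmp$node == 10])
  expect_equal(cmp$mean_shift[cmp$node == 10], 25, tolerance = 0.2)
  empty <- fake_trace(matrix(numeric(0), 0, 2), c(9, 10))
  expect_error(prior_posterior_compare(empty, empty), "empty")
  other <- fake_trace(cbind(rnorm(n), rnorm(n)), c(9, 11))
  expect_error(prior_posterior_compare(prior, other), "different")
})

test_that("composite posterior pools analyses with equal weight", {
  n <- 2000
  set.seed(53)
  a <- fake_trace(cbind(rnorm(n, 1500, 100)), 9)
  same <- composite_posterior(list(a, a))
  expect_equal(same$mean, node_summary(a)$mean)
  expect_equal(same$lower, node_summary(a)$lower)
  expect_identical(attr(same, "pooled_n"), as.integer(2 * n))

  p1 <- fake_trace(matrix(1000, n, 1), 9)
  p2 <- fake_trace(matrix(2000, n, 1), 9)
  mix <- composite_posterior(list(p1, p2))
  expect_equal(mix$mean, 1500)

  b <- fake_trace(cbind(rnorm(n, 1800, 120)), 9)
  got <- composite_posterior(list(a, b))
  pooled <- c(a$ages[, 1], b$ages[, 1]) # equal sizes: pooling = concatenation
  expect_equal(unname(c(got$lower, got$upper)), hpd(pooled, 0.95))
})

test_that("scheme presets transform calibrations, clock and partitions", {
  cals <- calibration_set(
    calibration("A", t_min = 125, t_max = 250, name = "phan",
                tags = "phanerozoic"),
    calibration("B", t_min = 1033, t_max = 1891, name = "prot",
                tags = c("proterozoic", "max_1891")),
    calibration("C", t_min = 1000, t_max = 3000, name = "root",
                tags = "root"))
  clock <- clock_config("AR")
  p1 <- partition_data(c(0.1, 0.2), -diag(c(4, 4)))
  p2 <- partition_data(c(0.2, 0.3), -diag(c(4, 4)))

  phan <- apply_scheme("Phan", cals, clock, list(p1, p2))
  expect_equal(vapply(phan$calibrations, `[[`, "", "name"),
               c("phan", "root"))
  m2 <- apply_scheme("Max-2", cals, clock, list(p1, p2))
  expect_true(is.infinite(m2$calibrations[[2]]$t_max))
  expect_false(is.infinite(m2$calibrations[[1]]$t_max))
  ir <- apply_scheme("IR", cals, clock, list(p1, p2))
  expect_identical(ir$clock$model, "IR")
  sig <- apply_scheme("Sigma", cals, clock, list(p1, p2))
  expect_equal(sig$clock$sigma2_mean, 10 * clock$sigma2_mean)
  sp <- apply_scheme("SinglePartition", cals, clock, list(p1, p2))
  expect_length(sp$partitions, 1L)
  # equal precisions: pooled estimate is the plain average
  expect_equal(sp$partitions[[1]]$b_hat, c(0.15, 0.25))
  expect_equal(sp$partitions[[1]]$hessian, -diag(c(8, 8)))
})

test_that("root sweep demands a usable grid", {
  d <- toy_dataset(seed = 54)
  st <- mcmc_settings(burn_in = 200, sample_every = 1, n_samples = 50,
                      seed = 1)
  expect_error(root_sweep(d$tree, d$calibrations, 3000, d$clock,
                          d$partitions, st, list(11L)), "two grid points")
  expect_error(root_sweep(d$tree, d$calibrations, c(3000, 2500), d$clock,
                          d$partitions, st, list(11L)), "increasing")
})

test_that("root sweep produces per-clade slopes and is seed-reproducible", {
  d <- toy_dataset(seed = 55)
  st <- mcmc_settings(burn_in = 2000, sample_every = 2, n_samples = 400,
                      seed = 5)
  clades <- list(10L, 11L)
  sw1 <- root_sweep(d$tree, d$calibrations, c(2500, 3000, 3500), d$clock,
                    d$partitions, st, clades)
  sw2 <- root_sweep(d$tree, d$calibrations, c(2500, 3000, 3500), d$clock,
                    d$partitions, st, clades)
  expect_identical(sw1$means, sw2$means)
  expect_length(sw1$slopes, 2L)
  expect_true(all(is.finite(sw1$slopes)))
})
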