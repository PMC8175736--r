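test_that("hpd matches an exhaustive window scan and basic contracts", {
  expect_equal(hpd(c(5, 5, 5, 5)), c(5, 5))
  expect_error(hpd(1), "two samples")
  expect_error(hpd(1:10, mass = 1.2), "mass")
  set.seed(31)
  x <- rnorm(1000)
  got <- hpd(x, 0.95)
  xs <- sort(x)
  m <- ceiling(0.95 * 1000)
  widths <- xs[m:1000] - xs[1:(1000 - m + 1)]
  i <- which.min(widths)
  expect_equal(got, c(xs[i], xs[i + m - 1]))
  expect_gte(mean(x >= got[1] & x <= got[2]), 0.95)
})

test_that("ess recovers iid and AR(1) effective sizes", {
  set.seed(32)
  x <- rnorm(1e4)
  expect_lt(abs(ess(x) - 1e4) / 1e4, 0.15)
  # AR(1) with rho = 0.5: 1 + 2 * sum(rho^k) = 3, so ESS ~ N/3
  n <- 5e4
  e <- rnorm(n)
  y <- as.numeric(stats::filter(e, 0.5, method = "recursive"))
  expect_equal(ess(y), n / 3, tolerance = 0.2)
  expect_warning(ez <- ess(rep(1, 100)), "constant")
  expect_identical(ez, 0)
  expect_error(ess(1:5), "short")
})

test_that("two-chain comparison flags shifted parameters", {
  m <- matrix(rnorm(2000), 500, 4,
              dimnames = list(NULL, c("t_5", "t_6", "mu", "sigma2")))
  same <- two_chain_check(m, m)
  expect_true(same$pass)
  expect_equal(max(same$table$rel_diff), 0)
  shifted <- m
  shifted[, "t_5"] <- m[, "t_5"] + 0.1 * abs(mean(m[, "t_5"])) + 2
  chk <- two_chain_check(m, shifted, tol = 0.05)
  expect_false(chk$pass)
  expect_true(chk$table$flagged[chk$table$parameter == "t_5"])
  expect_error(two_chain_check(m, m[, 1:2]), "different parameter")
})

test_that("identical seeds give identical traces", {
  d <- toy_dataset(seed = 41)
  st <- mcmc_settings(burn_in = 500, sample_every = 2, n_samples = 200,
                      seed = 99)
  a <- run_mcmc(d$tree, d$calibrations, d$clock, d$partitions, st)
  b <- run_mcmc(d$tree, d$calibrations, d$clock, d$partitions, st)
  expect_identical(a$ages, b$ages)
  expect_identical(a$rates, b$rates)
  expect_identical(a$hyper, b$hyper)
})

test_that("every stored sample respects the node-age ordering", {
  d <- toy_dataset(seed = 42)
  st <- mcmc_settings(burn_in = 1000, sample_every = 5, n_samples = 500,
                      seed = 7)
  tr <- run_mcmc(d$tree, d$calibrations, d$clock, d$partitions, st)
  phy <- tr$tree$phy
  ages <- cbind(matrix(0, nrow(tr$ages), length(phy$tip.label)), tr$ages)
  dur <- ages[, phy$edge[, 1]] - ages[, phy$edge[, 2]]
  expect_true(all(dur > 0))
})

test_that("prior-only sampling matches the independent prior constructor", {
  set.seed(43)
  tt <- random_chronogram(8, root_age = 1800)
  phy <- tt$phy
  labs <- phy$tip.label
  kids <- phy$edge[phy$edge[, 1] == 9, 2]
  sub <- kids[kids > 8][1] # an internal child of the root
  subtips <- ape::extract.clade(phy, sub)$tip.label
  cals <- calibration_set(
    calibration(labs, t_min = 900, t_max = 2400, name = "root"),
    calibration(subtips, t_min = 50, t_max = 1200, name = "c1"))
  ps <- prior_sample(tt, cals, 15000)
  tr <- run_mcmc(tt, cals, clock_config("AR"), settings = mcmc_settings(
    burn_in = 10000, sample_every = 60, n_samples = 15000, prior_only = TRUE,
    seed = 11))
  for (nd in tr$internal_nodes) {
    ks <- suppressWarnings(
      ks.test(ps[, nd], tr$ages[, paste0("t_", nd)])$statistic)
    expect_lt(ks, 0.025)
  }
})

test_that("posterior marginal matches quadrature on a two-leaf problem", {
  # IR clock with near-fixed hyperparameters: the root-age marginal is a
  # one-dimensional integral the sampler must reproduce.
  tt <- timetree(parse_newick("(A:1,B:1);")$phy, ages = c(0, 0, 1500))
  cal <- calibration(c("A", "B"), t_min = 800, t_max = 2200, name = "root")
  cals <- calibration_set(cal)
  mu0 <- 2e-4; s20 <- 0.3
  clock <- clock_config("IR", mu_shape = 1e6, mu_mean = mu0,
                        sigma2_shape = 1e6, sigma2_mean = s20)
  set.seed(44)
  r_true <- exp(rnorm(2, log(mu0) - s20 / 2, sqrt(s20)))
  b_true <- 1500 * r_true
  s <- 0.15 * b_true
  b_hat <- b_true + rnorm(2, 0, s)
  pd <- partition_data(b_hat, -diag(1 / s^2))
  tr <- run_mcmc(tt, cals, clock, pd, mcmc_settings(
    burn_in = 20000, sample_every = 30, n_samples = 8000, seed = 3))
  # quadrature oracle for p(t | data)
  branch_lik <- function(t, bh, sd1) {
    vapply(t, function(ti) integrate(function(r)
      dnorm(bh, r * ti, sd1) * dlnorm(r, log(mu0) - s20 / 2, sqrt(s20)),
      0, qlnorm(1 - 1e-10, log(mu0), sqrt(s20)), rel.tol = 1e-9)$value,
      numeric(1))
  }
  post_un <- function(t) soft_uniform_logpdf(t, cal, log = FALSE) *
    branch_lik(t, b_hat[1], s[1]) * branch_lik(t, b_hat[2], s[2])
  Z <- integrate(post_un, 200, 6000, rel.tol = 1e-8)$value
  want_mean <- integrate(function(t) t * post_un(t), 200, 6000,
                         rel.tol = 1e-8)$value / Z
  got <- tr$ages[, 1]
  se <- sd(got) / sqrt(ess(got))
  expect_lt(abs(mean(got) - want_mean), 4 * se + 0.005 * want_mean)
  # full-distribution check against the quadrature CDF
  grid <- seq(200, 6000, length.out = 2000)
  dens <- post_un(grid) / Z
  cdf <- cumsum(dens) * diff(grid)[1]
  ks <- max(abs(stats::ecdf(got)(grid) - pmin(cdf, 1)))
  expect_lt(ks, 0.03)
})

test_that("mcmc settings validate and expose the chain presets", {
  p <- mcmc_settings(preset = "paper")
  expect_identical(p$burn_in, 200000L)
  expect_identical(p$sample_every, 100L)
  expect_identical(p$n_samples, 20000L)
  d <- mcmc_settings(preset = "desk")
  expect_identical(d$burn_in, 20000L)
  expect_error(mcmc_settings(n_samples = 0), "positive")
})
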