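test_that("transition matrix has the closed-form limits and matches expm", {
  expect_equal(transition_matrix(0.3, 0.6, 0), diag(2), ignore_attr = TRUE)
  P_inf <- transition_matrix(0.3, 0.6, 1e9)
  statn <- c(0.6, 0.3) / 0.9
  expect_equal(unname(P_inf[1, ]), statn, tolerance = 1e-12)
  expect_equal(unname(P_inf[2, ]), statn, tolerance = 1e-12)
  Q <- matrix(c(-0.3, 0.3, 0.6, -0.6), 2, 2, byrow = TRUE)
  want <- as.matrix(Matrix::expm(Q * 0.7))
  expect_lt(max(abs(transition_matrix(0.3, 0.6, 0.7) - want)), 1e-10)
  expect_equal(rowSums(transition_matrix(0.2, 0.9, 1.3)), c(A = 1, P = 1))
  expect_error(transition_matrix(0.3, 0.6, -1), "non-negative")
})

test_that("pruning likelihood matches exhaustive enumeration", {
  set.seed(61)
  # forced case: two tips on zero-length branches, uniform root
  t0 <- parse_newick("(A:0,B:0);", dating = FALSE)
  st0 <- host_states(c(A = "A", B = "A"))
  expect_warning(
    ll0 <- pruning_loglik(t0, st0, 0.4, 0.8, root = "uniform"),
    "identifiable")
  expect_equal(ll0, log(0.5))
  # random small trees, states including '?'
  for (rep in 1:6) {
    n <- sample(3:4, 1)
    tt <- random_chronogram(n, root_age = 1)
    states <- host_states(setNames(sample(c("A", "P", "?"), n, replace = TRUE,
                                          prob = c(0.4, 0.4, 0.2)),
                                   tt$phy$tip.label))
    q1 <- runif(1, 0.1, 2); q2 <- runif(1, 0.1, 2)
    for (root in c("stationary", "uniform")) {
      got <- pruning_loglik(tt, states, q1, q2, root = root)
      want <- mk2_enum_loglik(tt$phy, states, q1, q2, root = root)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("frozen chains behave as point processes", {
  tt <- parse_newick("((A:1,B:1):1,C:2);")
  mono <- host_states(c(A = "A", B = "A", C = "A"))
  poly <- host_states(c(A = "A", B = "P", C = "A"))
  expect_equal(suppressWarnings(
    pruning_loglik(tt, mono, 0, 0, root = "uniform")), log(0.5))
  expect_identical(pruning_loglik(tt, poly, 0, 0, root = "uniform"), -Inf)
})

test_that("likelihood is invariant to relabeling tips with identical data", {
  set.seed(62)
  tt <- random_chronogram(6, root_age = 1)
  states <- host_states(setNames(c("A", "A", "P", "A", "P", "A"),
                                 tt$phy$tip.label))
  base <- pruning_loglik(tt, states, 0.7, 0.4)
  perm <- tt
  perm$phy$tip.label <- paste0("x_", perm$phy$tip.label)
  states2 <- host_states(setNames(as.character(states),
                                  paste0("x_", names(states))))
  expect_equal(pruning_loglik(perm, states2, 0.7, 0.4), base)
})

test_that("marginal ancestral states normalise and match enumeration", {
  set.seed(63)
  tt <- random_chronogram(4, root_age = 1)
  phy <- tt$phy
  states <- host_states(setNames(c("A", "P", "A", "?"), phy$tip.label))
  q1 <- 0.8; q2 <- 0.3
  m <- marginal_anc_states(tt, states, q1, q2)
  expect_equal(rowSums(m), rep(1, 7), tolerance = 1e-12)
  # enumeration oracle: P(node i in state s | data)
  for (node in 5:7) {
    withA <- states
    # clamp the focal node by brute force: likelihood of data AND node = A
    num <- 0; den <- 0
    for (s in 1:2) {
      ll <- mk2_enum_clamped(phy, states, q1, q2, node, s)
      if (s == 1) num <- ll
      den <- den + ll
    }
    expect_equal(unname(m[node, "A"]), num / den, tolerance = 1e-10)
  }
  # monomorphic data pull the root toward the observed state
  allA <- host_states(setNames(rep("A", 4), phy$tip.label))
  mA <- suppressWarnings(marginal_anc_states(tt, allA, 0.5, 0.5))
  expect_gt(mA[5, "A"], 0.5)
})

test_that("rate MCMC samples its exponential prior when data are disabled", {
  set.seed(64)
  tt <- random_chronogram(12, root_age = 1)
  states <- simulate_host_states(tt, 1, 2)
  fit <- run_asr_mcmc(tt, states, n_iter = 3.2e5, burn_in = 2e4, thin = 150,
                      prior_mean = c(0.5, 1.5), prior_only = TRUE, seed = 9,
                      n_marginal = 0)
  ks1 <- suppressWarnings(ks.test(fit$trace$q_ap, pexp, 1 / 0.5)$statistic)
  ks2 <- suppressWarnings(ks.test(fit$trace$q_pa, pexp, 1 / 1.5)$statistic)
  expect_lt(ks1, 0.025)
  expect_lt(ks2, 0.025)
})

test_that("rate asymmetry is recovered from simulated data", {
  set.seed(65)
  wins <- 0
  for (rep in 1:5) {
    tt <- random_chronogram(120, root_age = 1)
    TL <- sum(tt$phy$edge.length)
    qap <- 3 / TL; qpa <- 10 * qap
    states <- simulate_host_states(tt, qap, qpa)
    fit <- run_asr_mcmc(tt, states, n_iter = 6000, burn_in = 1500, thin = 5,
                        prior_mean = 30 / TL, n_marginal = 0)
    wins <- wins + (mean(fit$trace$q_pa) > mean(fit$trace$q_ap))
  }
  expect_gte(wins, 4)
})

test_that("asr runs are seed-reproducible", {
  set.seed(66)
  tt <- random_chronogram(10, root_age = 1)
  states <- simulate_host_states(tt, 0.5, 1)
  a <- run_asr_mcmc(tt, states, n_iter = 2000, burn_in = 500, thin = 5,
                    seed = 4, n_marginal = 10)
  b <- run_asr_mcmc(tt, states, n_iter = 2000, burn_in = 500, thin = 5,
                    seed = 4, n_marginal = 10)
  expect_identical(a$trace, b$trace)
  expect_identical(a$marginals, b$marginals)
})

test_that("stepping stone reduces to the likelihood with no free parameters", {
  set.seed(67)
  tt <- random_chronogram(8, root_age = 1)
  states <- simulate_host_states(tt, 0.8, 1.6)
  f <- stepping_stone_logml(tt, states, model = "fixed",
                            fixed_rates = c(0.8, 1.6))
  expect_equal(f$logml, pruning_loglik(tt, states, 0.8, 1.6))
})

test_that("stepping stone matches direct quadrature of the marginal likelihood", {
  set.seed(68)
  tt <- random_chronogram(10, root_age = 1)
  states <- simulate_host_states(tt, 0.8, 2)
  pm <- 1.5
  ub <- qexp(1 - 1e-9, 1 / pm)
  # 2-D quadrature oracle (free model)
  inner <- function(qa) integrate(Vectorize(function(qp)
    exp(pruning_loglik(tt, states, qa, qp) + 10) * dexp(qp, 1 / pm)),
    0, ub, rel.tol = 1e-8)$value
  quad_free <- log(integrate(Vectorize(function(qa) inner(qa) *
    dexp(qa, 1 / pm)), 0, ub, rel.tol = 1e-7)$value) - 10
  ss_free <- stepping_stone_logml(tt, states, model = "free", prior_mean = pm,
                                  rung_sweeps = 900, rung_burn = 300,
                                  seed = 10)
  expect_lt(abs(ss_free$logml - quad_free), 0.15)
  # 1-D quadrature oracle (equal-rates model)
  quad_eq <- log(integrate(Vectorize(function(q)
    exp(pruning_loglik(tt, states, q, q) + 10) * dexp(q, 1 / pm)),
    0, ub, rel.tol = 1e-9)$value) - 10
  ss_eq <- stepping_stone_logml(tt, states, model = "equal", prior_mean = pm,
                                rung_sweeps = 900, rung_burn = 300, seed = 11)
  expect_lt(abs(ss_eq$logml - quad_eq), 0.15)
})

test_that("a model compared against itself has logBF near zero", {
  set.seed(69)
  tt <- random_chronogram(10, root_age = 1)
  states <- simulate_host_states(tt, 0.5, 1.5)
  a <- stepping_stone_logml(tt, states, model = "equal", seed = 1)
  b <- stepping_stone_logml(tt, states, model = "equal", seed = 2)
  expect_lt(abs(2 * (a$logml - b$logml)), 0.5)
})

test_that("host state tables validate and round-trip", {
  expect_error(host_states(c("A", "P")), "named")
  expect_error(host_states(c(x = "Q")), "invalid")
  st <- host_states(c(t1 = "A", t2 = "?", t3 = "P"))
  f <- tempfile(fileext = ".tsv")
  write_host_states(st, f)
  expect_identical(unclass(read_host_states(f)), unclass(st))
})
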