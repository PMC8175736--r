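# The soft-bound construction: flat interior carrying mass
# 1 - p_lower - p_upper, a power-form lower tail and exponential upper tail
# joined continuously at the bounds.

soft_pdf <- function(t, cal) soft_uniform_logpdf(t, cal, log = FALSE)

test_that("interior density equals the flat-interior mass formula", {
  cal <- calibration(c("A", "B"), t_min = 125, t_max = 250)
  expect_equal(soft_pdf(200, cal), 0.95 / 125)
  expect_equal(soft_pdf(125, cal), 0.95 / 125)
  expect_equal(soft_pdf(250, cal), 0.95 / 125)
})

test_that("density is continuous at both bounds", {
  cal <- calibration("A", t_min = 300, t_max = 900, p_lower = 0.1,
                     p_upper = 0.05)
  eps <- 1e-9
  expect_equal(soft_pdf(300 - eps, cal), soft_pdf(300 + eps, cal),
               tolerance = 1e-6)
  expect_equal(soft_pdf(900 - eps, cal), soft_pdf(900 + eps, cal),
               tolerance = 1e-6)
})

test_that("density integrates to one and tails carry their stated masses", {
  set.seed(5)
  for (rep in 1:50) {
    tmin <- runif(1, 10, 2000)
    tmax <- tmin * runif(1, 1.2, 4)
    pl <- runif(1, 0.005, 0.1); pu <- runif(1, 0.005, 0.1)
    cal <- calibration("A", t_min = tmin, t_max = tmax, p_lower = pl,
                       p_upper = pu)
    lo <- integrate(soft_pdf, 1e-12, tmin, cal = cal, rel.tol = 1e-10)$value
    mid <- integrate(soft_pdf, tmin, tmax, cal = cal, rel.tol = 1e-10)$value
    up <- integrate(soft_pdf, tmax, Inf, cal = cal, rel.tol = 1e-10)$value
    expect_equal(lo + mid + up, 1, tolerance = 1e-6)
    expect_equal(up, pu, tolerance = 1e-6)
    expect_equal(lo, pl, tolerance = 1e-6)
  }
})

test_that("non-positive ages are rejected", {
  cal <- calibration("A", t_min = 100, t_max = 200)
  expect_error(soft_uniform_logpdf(0, cal), "positive")
  expect_error(soft_uniform_logpdf(c(10, -1), cal), "positive")
})

test_that("sampler matches the density: region masses and KS distance", {
  cal <- calibration("A", t_min = 125, t_max = 250)
  set.seed(9)
  x <- soft_uniform_sample(1e5, cal)
  expect_equal(mean(x >= 125 & x <= 250), 0.95, tolerance = 0.01)
  ks <- suppressWarnings(
    ks.test(x, function(q) soft_uniform_cdf(q, cal))$statistic)
  expect_lt(ks, 0.005)
})

test_that("hard bounds confine all draws and sampling is seed-stable", {
  cal <- calibration("A", t_min = 100, t_max = 200, p_lower = 0,
                     p_upper = 0)
  set.seed(2)
  x <- soft_uniform_sample(1e4, cal)
  expect_true(all(x >= 100 & x <= 200))
  set.seed(77); a <- soft_uniform_sample(100, cal)
  set.seed(77); b <- soft_uniform_sample(100, cal)
  expect_identical(a, b)
})

test_that("calibration invariants are enforced", {
  expect_error(calibration("A", t_min = -1, t_max = 10), "positive")
  expect_error(calibration("A", t_min = 10, t_max = 5), "exceed")
  expect_error(calibration("A", t_min = 10, t_max = 20, p_lower = 0.6,
                           p_upper = 0.5), "tail")
})

test_that("consistency check flags impossible ancestor/descendant bounds", {
  tt <- parse_newick("((A:1,B:1):1,C:2);")
  ok <- calibration_set(
    calibration(c("A", "B", "C"), t_min = 1000, t_max = 3000, name = "root"),
    calibration(c("A", "B"), t_min = 450, t_max = 509, name = "plants"))
  expect_identical(nrow(check_consistency(ok, tt)), 0L)

  bad <- calibration_set(
    calibration(c("A", "B", "C"), t_min = 500, t_max = 1000, name = "root"),
    calibration(c("A", "B"), t_min = 1200, t_max = 1500, name = "child"))
  expect_warning(v <- check_consistency(bad, tt), "conflict")
  expect_identical(nrow(v), 1L)
  expect_identical(v$descendant, "child")

  expect_error(check_consistency(calibration_set(list()), tt), "root")
  noroot <- calibration_set(
    calibration(c("A", "B"), t_min = 450, t_max = 509))
  expect_error(check_consistency(noroot, tt), "root")
})

test_that("calibration TSVs round-trip and packaged schemes load", {
  mito <- read_calibrations(system.file("extdata", "calibrations",
                                        "mito_encoded.tsv",
                                        package = "endoclock"))
  expect_length(mito, 5L)
  nuc <- read_calibrations(system.file("extdata", "calibrations",
                                       "nuclear_encoded.tsv",
                                       package = "endoclock"))
  expect_length(nuc, 11L)
  roots <- Filter(function(cal) "root" %in% cal$tags, nuc)
  expect_equal(roots[[1]]$t_min, 1000)
  expect_equal(roots[[1]]$t_max, 3000)
  f <- tempfile(fileext = ".tsv")
  write_calibrations(mito, f)
  back <- read_calibrations(f)
  expect_equal(vapply(back, `[[`, 1, "t_min"),
               vapply(mito, `[[`, 1, "t_min"))
  expect_equal(vapply(back, `[[`, 1, "t_max"),
               vapply(mito, `[[`, 1, "t_max"))
})
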