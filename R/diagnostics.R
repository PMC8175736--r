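# Analysis-level diagnostics: infinite-sites regression, prior-vs-posterior
# comparison, composite posteriors across dating schemes, and the
# root-maximum sensitivity sweep.

#' Per-node posterior age summary
#'
#' @param trace a `posterior_trace` from [run_mcmc()].
#' @param mass HPD mass (default 0.95).
#' @return data frame with columns `node`, `mean`, `lower`, `upper`, `width`.
#' @export
node_summary <- function(trace, mass = 0.95) {
  stopifnot(inherits(trace, "posterior_trace"))
  nodes <- trace$internal_nodes
  out <- data.frame(node = nodes, mean = NA_real_, lower = NA_real_,
                    upper = NA_real_)
  for (k in seq_along(nodes)) {
    x <- trace$ages[, k]
    h <- hpd(x, mass)
    out$mean[k] <- mean(x); out$lower[k] <- h[1]; out$upper[k] <- h[2]
  }
  out$width <- out$upper - out$lower
  out
}

#' Infinite-sites regression
#'
#' Ordinary least squares of the 95% HPD width on the posterior mean age
#' across nodes.  In the infinite-data limit the points fall on a straight
#' line; a lower slope means the calibrations, not the sequence data, are
#' the binding source of uncertainty, i.e. higher dating precision.
#'
#' @param summaries a node summary data frame (columns `mean` and `width`),
#'   as from [node_summary()].
#' @return list with `slope`, `intercept`, `r_squared`.
#' @export
infinite_sites_regression <- function(summaries) {
  if (nrow(summaries) < 3L) stop("need at least three nodes")
  if (sd(summaries$mean) == 0) stop("degenerate: all posterior means equal")
  fit <- lm(width ~ mean, data = summaries)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = summary(fit)$r.squared)
}

#' Compare posterior age samples with the effective prior
#'
#' The `usedata = 0` style check: per node, the two-sample
#' Kolmogorov-Smirnov distance and mean shift between prior-only and
#' posterior age samples.  Nodes whose posterior is indistinguishable from
#' the prior are flagged as uninformative (the sequence data moved nothing).
#'
#' @param prior_trace,posterior_trace `posterior_trace` objects over the
#'   same nodes (the former from a `prior_only` run).
#' @param ks_threshold KS distance below which a node is flagged
#'   uninformative (default 0.1).
#' @return data frame with `node`, `ks`, `mean_shift`, `informative`.
#' @export
prior_posterior_compare <- function(prior_trace, posterior_trace,
                                    ks_threshold = 0.1) {
  stopifnot(inherits(prior_trace, "posterior_trace"),
            inherits(posterior_trace, "posterior_trace"))
  if (!identical(prior_trace$internal_nodes, posterior_trace$internal_nodes))
    stop("traces cover different node sets")
  if (nrow(prior_trace$ages) == 0L || nrow(posterior_trace$ages) == 0L)
    stop("empty trace")
  nodes <- prior_trace$internal_nodes
  out <- data.frame(node = nodes, ks = NA_real_, mean_shift = NA_real_)
  for (k in seq_along(nodes)) {
    a <- prior_trace$ages[, k]; b <- posterior_trace$ages[, k]
    out$ks[k] <- suppressWarnings(ks.test(a, b)$statistic)
    out$mean_shift[k] <- mean(b) - mean(a)
  }
  out$informative <- out$ks > ks_threshold
  out
}

#' Composite posterior across several dating analyses
#'
#' Pools age samples from several analyses with equal weight (each trace is
#' resampled to a common size), then summarises the pooled sample per node
#' with mean and HPD.
#'
#' @param traces list of `posterior_trace` objects covering the same nodes.
#' @param size per-analysis resample size; defaults to the smallest trace.
#' @param mass HPD mass.
#' @return a node summary data frame; attribute `"pooled_n"` gives the
#'   pooled sample size (`length(traces) * size`).
#' @export
composite_posterior <- function(traces, size = NULL, mass = 0.95) {
  if (!length(traces)) stop("no traces supplied")
  nodes <- traces[[1]]$internal_nodes
  for (tr in traces)
    if (!identical(tr$internal_nodes, nodes))
      stop("traces cover different node sets")
  if (is.null(size)) size <- min(vapply(traces, function(tr) nrow(tr$ages), 1L))
  pooled <- do.call(rbind, lapply(traces, function(tr) {
    if (nrow(tr$ages) == size) tr$ages
    else tr$ages[sample.int(nrow(tr$ages), size, replace = TRUE), , drop = FALSE]
  }))
  out <- data.frame(node = nodes, mean = NA_real_, lower = NA_real_,
                    upper = NA_real_)
  for (k in seq_along(nodes)) {
    h <- hpd(pooled[, k], mass)
    out$mean[k] <- mean(pooled[, k]); out$lower[k] <- h[1]; out$upper[k] <- h[2]
  }
  out$width <- out$upper - out$lower
  attr(out, "pooled_n") <- nrow(pooled)
  out
}

#' Named dating-scheme presets
#'
#' The sensitivity schemes applied on top of a best-practiced configuration:
#' `Phan` keeps only calibrations tagged `phanerozoic` (plus the root);
#' `Max-1` removes maximum bounds from calibrations tagged
#' `proterozoic_max`; `Max-2` removes maximum bounds from calibrations
#' tagged `max_1891`; `SinglePartition` collapses the partitions into one by
#' precision-weighted pooling; `IR` switches to the independent-rates clock;
#' `Sigma` enlarges the rate-variance hyperprior tenfold.
#'
#' @return character vector of scheme names.
#' @export
scheme_presets <- function() {
  c("best", "Phan", "Max-1", "Max-2", "SinglePartition", "IR", "Sigma")
}

drop_max <- function(cal) {
  calibration(cal$clade, t_min = cal$t_min, t_max = Inf,
              p_lower = cal$p_lower, name = cal$name, tags = cal$tags)
}

#' Apply a named dating scheme to a set of inputs
#'
#' @param scheme one of [scheme_presets()].
#' @param calibrations a [calibration_set()].
#' @param clock a [clock_config()].
#' @param partitions list of [partition_data()].
#' @return list with modified `calibrations`, `clock`, `partitions`.
#' @export
apply_scheme <- function(scheme, calibrations, clock, partitions) {
  scheme <- match.arg(scheme, scheme_presets())
  partitions <- as_partition_list(partitions)
  if (scheme == "Phan") {
    keep <- vapply(calibrations, function(cal)
      "phanerozoic" %in% cal$tags || "root" %in% cal$tags, logical(1))
    calibrations <- calibration_set(unclass(calibrations)[keep])
  } else if (scheme == "Max-1") {
    calibrations <- calibration_set(lapply(calibrations, function(cal)
      if ("proterozoic_max" %in% cal$tags) drop_max(cal) else cal))
  } else if (scheme == "Max-2") {
    calibrations <- calibration_set(lapply(calibrations, function(cal)
      if ("max_1891" %in% cal$tags) drop_max(cal) else cal))
  } else if (scheme == "SinglePartition") {
    partitions <- list(pool_partitions(partitions))
  } else if (scheme == "IR") {
    clock <- clock_config("IR", mu_shape = clock$mu_shape,
                          mu_mean = clock$mu_mean,
                          sigma2_shape = clock$sigma2_shape, tau0 = clock$tau0)
  } else if (scheme == "Sigma") {
    clock <- clock_config(clock$model, mu_shape = clock$mu_shape,
                          mu_mean = clock$mu_mean,
                          sigma2_shape = clock$sigma2_shape,
                          sigma2_mean = clock$sigma2_mean, tau0 = clock$tau0,
                          preset = "sigma-large")
  }
  list(calibrations = calibrations, clock = clock, partitions = partitions)
}

# precision-weighted single-partition pooling: H = sum H_p, and b_hat the
# H-weighted combination (exact when gradients vanish at each b_hat)
pool_partitions <- function(partitions) {
  partitions <- as_partition_list(partitions)
  H <- Reduce(`+`, lapply(partitions, `[[`, "hessian"))
  rhs <- Reduce(`+`, lapply(partitions, function(p)
    p$hessian %*% p$b_hat - p$gradient))
  b <- as.numeric(solve(H, rhs))
  partition_data(b_hat = b, hessian = H,
                 sites = sum(vapply(partitions, function(p)
                   ifelse(is.na(p$sites), 0L, p$sites), 0L)))
}

#' Root-maximum sensitivity sweep
#'
#' Re-runs the dating analysis over a grid of root maximum bounds (internal
#' calibrations held fixed) and fits, per focal clade, the slope of the
#' posterior mean age against the root maximum.  Calibration strategies that
#' carry internal maximum bounds should show near-zero slopes; strategies
#' whose only maximum is the root inherit its uncertainty roughly linearly.
#'
#' @param tree a [timetree].
#' @param calibrations a [calibration_set()] whose root calibration's
#'   maximum is replaced by each grid value.
#' @param root_maxima strictly increasing grid of root maximum bounds (Ma),
#'   length >= 2.
#' @param clock a [clock_config()].
#' @param partitions list of [partition_data()].
#' @param settings an [mcmc_settings()]; the same seed policy is applied to
#'   every grid point so runs differ only in the root bound.
#' @param clades node ids (or list of [clade_spec()]) whose posterior mean
#'   ages are tracked.
#' @return object of class `sweep_result`: the grid, the per-clade matrix of
#'   posterior mean ages, and the fitted slopes.
#' @export
root_sweep <- function(tree, calibrations, root_maxima, clock, partitions,
                       settings, clades) {
  if (length(root_maxima) < 2L)
    stop("need at least two grid points to fit a slope")
  if (any(diff(root_maxima) <= 0)) stop("grid must be strictly increasing")
  phy <- as_phylo(tree)
  root <- length(phy$tip.label) + 1L
  nodes <- vapply(clades, function(cl)
    if (is.numeric(cl)) as.integer(cl) else resolve_clade(phy, cl), integer(1))
  means <- matrix(NA_real_, length(root_maxima), length(nodes),
                  dimnames = list(NULL, paste0("t_", nodes)))
  iroot <- which(vapply(calibrations, function(cal)
    resolve_clade(phy, cal$clade) == root, logical(1)))
  if (length(iroot) != 1L) stop("exactly one root calibration required")
  for (g in seq_along(root_maxima)) {
    cals <- unclass(calibrations)
    rc <- cals[[iroot]]
    cals[[iroot]] <- calibration(rc$clade, t_min = rc$t_min,
                                 t_max = root_maxima[g],
                                 p_lower = rc$p_lower, p_upper = 0.025,
                                 name = rc$name, tags = rc$tags)
    tr <- run_mcmc(tree, calibration_set(cals), clock, partitions, settings)
    idx <- match(nodes, tr$internal_nodes)
    means[g, ] <- colMeans(tr$ages)[idx]
  }
  slopes <- apply(means, 2, function(y) unname(coef(lm(y ~ root_maxima))[2]))
  structure(list(root_maxima = root_maxima, means = means, slopes = slopes,
                 nodes = nodes),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("root-maximum sweep over", length(x$root_maxima), "grid points\n")
  print(data.frame(clade = colnames(x$means), slope = x$slopes,
                   row.names = NULL))
  invisible(x)
}
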