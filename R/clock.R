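# Among-branch rate models.  AR: geometric Brownian motion of the node
# rates along the tree (log-rate diffuses with variance sigma2 per Ma and
# drift -sigma2/2, so the child rate is a martingale given the parent);
# branch rate = arithmetic mean of the endpoint node rates.  IR: each
# branch's log-rate is drawn independently from
# Normal(log mu - sigma2/2, sigma2), so the branch rate has mean mu.

#' Clock model parameters
#'
#' @param model `"AR"` (autocorrelated, geometric Brownian) or `"IR"`
#'   (independent log-normal rates).
#' @param mu mean rate, substitutions/site/Ma (> 0).
#' @param sigma2 rate-variance parameter: per-Ma diffusion variance of the
#'   log-rate (AR) or the variance of the log-rate (IR); >= 0.
#' @param tau0 (AR only) time span in Ma whose worth of diffusion variance
#'   defines the log-normal prior spread of the root node rate around `mu`.
#' @return object of class `clock_params`.
#' @export
clock_params <- function(model = c("AR", "IR"), mu, sigma2, tau0 = 100) {
  model <- match.arg(model)
  if (!(mu > 0)) stop("mu must be positive")
  if (sigma2 < 0) stop("sigma2 must be non-negative")
  structure(list(model = model, mu = mu, sigma2 = sigma2, tau0 = tau0),
            class = "clock_params")
}

#' Clock configuration: model choice plus gamma hyperpriors
#'
#' Hyperpriors for `mu` and `sigma2` are gamma distributions parameterised by
#' shape and mean.  The `"sigma-large"` preset multiplies the `sigma2` prior
#' mean tenfold, the sensitivity scheme that admits much larger among-branch
#' rate variation.
#'
#' @param model `"AR"` or `"IR"`.
#' @param mu_shape,mu_mean gamma hyperprior for the mean rate
#'   (substitutions/site/Ma).
#' @param sigma2_shape,sigma2_mean gamma hyperprior for the rate-variance
#'   parameter; default mean 4e-4 per Ma (AR) or 0.2 (IR).
#' @param tau0 see [clock_params()].
#' @param preset `NULL` or `"sigma-large"`.
#' @return object of class `clock_config`.
#' @export
clock_config <- function(model = c("AR", "IR"), mu_shape = 2, mu_mean = 2e-4,
                         sigma2_shape = 2, sigma2_mean = NULL, tau0 = 100,
                         preset = NULL) {
  model <- match.arg(model)
  if (is.null(sigma2_mean)) sigma2_mean <- if (model == "AR") 4e-4 else 0.2
  if (!is.null(preset)) {
    preset <- match.arg(preset, "sigma-large")
    sigma2_mean <- sigma2_mean * 10
  }
  if (mu_shape <= 0 || mu_mean <= 0 || sigma2_shape <= 0 || sigma2_mean <= 0)
    stop("hyperprior shapes and means must be positive")
  structure(list(model = model, mu_shape = mu_shape, mu_mean = mu_mean,
                 sigma2_shape = sigma2_shape, sigma2_mean = sigma2_mean,
                 tau0 = tau0, preset = preset),
            class = "clock_config")
}

#' Draw clock hyperparameters from their gamma hyperpriors
#'
#' @param config a [clock_config()].
#' @param n number of draws.
#' @return data frame with columns `mu` and `sigma2`.
#' @export
sample_hyperpriors <- function(config, n = 1) {
  stopifnot(inherits(config, "clock_config"))
  data.frame(
    mu = rgamma(n, shape = config$mu_shape,
                scale = config$mu_mean / config$mu_shape),
    sigma2 = rgamma(n, shape = config$sigma2_shape,
                    scale = config$sigma2_mean / config$sigma2_shape))
}

#' Simulate among-branch substitution rates on a chronogram
#'
#' @param tree a [timetree] with ages.
#' @param params a [clock_params()].
#' @return a list with `branch_rates` (per edge, `phy$edge` row order) and,
#'   for the AR model, `node_rates` (per node).
#' @export
simulate_rates <- function(tree, params) {
  stopifnot(inherits(tree, "timetree"), inherits(params, "clock_params"))
  if (anyNA(tree$ages)) stop("tree must carry node ages")
  phy <- ape::reorder.phylo(tree$phy, "cladewise")
  ntot <- length(phy$tip.label) + phy$Nnode
  edge <- phy$edge
  if (params$model == "IR") {
    br <- exp(rnorm(nrow(edge), log(params$mu) - params$sigma2 / 2,
                    sqrt(params$sigma2)))
    return(list(branch_rates = br))
  }
  s2 <- params$sigma2
  lr <- numeric(ntot)
  root <- root_node(tree)
  s0 <- s2 * params$tau0
  lr[root] <- rnorm(1, log(params$mu) - s0 / 2, sqrt(s0))
  # pre-order walk: edges of a phylo in cladewise order visit parents first
  for (k in seq_len(nrow(edge))) {
    a <- edge[k, 1]; d <- edge[k, 2]
    v <- s2 * (tree$ages[a] - tree$ages[d])
    lr[d] <- rnorm(1, lr[a] - v / 2, sqrt(v))
  }
  nr <- exp(lr)
  list(node_rates = nr, branch_rates = (nr[edge[, 1]] + nr[edge[, 2]]) / 2)
}

#' Joint log prior density of rates under the clock model
#'
#' Evaluates the model's joint density of the rates on the natural (rate, not
#' log-rate) scale, Jacobian included.  For AR, `rates` must be the per-node
#' rates; for IR, the per-branch rates (edge row order).
#'
#' @param tree a [timetree].
#' @param rates numeric vector of positive rates (see above).
#' @param params a [clock_params()].
#' @return log density.  With `sigma2 = 0` the model is degenerate: `-Inf`
#'   unless every rate equals `mu`.
#' @export
log_prior_rates <- function(tree, rates, params) {
  stopifnot(inherits(tree, "timetree"), inherits(params, "clock_params"))
  if (any(rates <= 0)) stop("rates must be positive")
  phy <- tree$phy
  edge <- phy$edge
  if (params$sigma2 == 0)
    return(if (all(abs(rates - params$mu) < 1e-12)) Inf else -Inf)
  if (params$model == "IR") {
    if (length(rates) != nrow(edge)) stop("expected one rate per branch")
    return(sum(dnorm(log(rates), log(params$mu) - params$sigma2 / 2,
                     sqrt(params$sigma2), log = TRUE) - log(rates)))
  }
  ntot <- length(phy$tip.label) + phy$Nnode
  if (length(rates) != ntot) stop("AR model expects one rate per node")
  lr <- log(rates)
  root <- root_node(tree)
  s0 <- params$sigma2 * params$tau0
  lp <- dnorm(lr[root], log(params$mu) - s0 / 2, sqrt(s0), log = TRUE) - lr[root]
  v <- params$sigma2 * (tree$ages[edge[, 1]] - tree$ages[edge[, 2]])
  lp + sum(dnorm(lr[edge[, 2]], lr[edge[, 1]] - v / 2, sqrt(v), log = TRUE) -
             lr[edge[, 2]])
}
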