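# Two-state CTMC ancestral host-lifestyle reconstruction: pruning
# likelihood, marginal node probabilities, Metropolis rate estimation under
# exponential priors, and stepping-stone marginal likelihoods for Bayes
# factor model comparison (free two-rate vs equal-rates).
#
# The log Bayes factor convention used throughout is
# logBF = 2 * (logML_model1 - logML_model2); on this scale values above 10
# count as very strong evidence.  Branch lengths are taken from the input
# tree as-is (no clock assumption).

.host_levels <- c("A", "P", "?")

#' Tip host-state table
#'
#' @param states named character vector, one entry per tip, values `"A"`
#'   (animal-associated), `"P"` (protist-associated) or `"?"` (unknown).
#' @return object of class `host_states`.
#' @export
host_states <- function(states) {
  states <- unlist(states)
  if (is.null(names(states))) stop("states must be named by tip label")
  bad <- setdiff(unique(states), .host_levels)
  if (length(bad)) stop("invalid state(s): ", paste(bad, collapse = ", "))
  structure(setNames(as.character(states), names(states)), class = "host_states")
}

#' Read a tip-state TSV (columns `tip`, `state`)
#' @param file path.
#' @return a [host_states()].
#' @export
read_host_states <- function(file) {
  tab <- read.delim(file, stringsAsFactors = FALSE, comment.char = "#")
  host_states(setNames(tab$state, tab$tip))
}

#' Write a tip-state TSV
#' @param states a [host_states()].
#' @param file path.
#' @export
write_host_states <- function(states, file) {
  write.table(data.frame(tip = names(states), state = as.character(states)),
              file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Mk2 transition probability matrix
#'
#' Closed-form solution of the two-state CTMC over a branch of length `t`:
#' rows are the starting state (`A`, `P`), columns the ending state.
#'
#' @param q_ap rate A -> P per unit branch length (>= 0).
#' @param q_pa rate P -> A (>= 0).
#' @param t branch length (>= 0).
#' @return 2 x 2 stochastic matrix.
#' @export
transition_matrix <- function(q_ap, q_pa, t) {
  if (t < 0) stop("branch length must be non-negative")
  if (q_ap < 0 || q_pa < 0) stop("rates must be non-negative")
  q <- q_ap + q_pa
  if (q == 0 || t == 0) {
    P <- diag(2)
  } else {
    piA <- q_pa / q; piP <- q_ap / q
    e <- exp(-q * t)
    P <- matrix(c(piA + piP * e, piP * (1 - e),
                  piA * (1 - e), piP + piA * e),
                2, 2, byrow = TRUE)
  }
  dimnames(P) <- list(c("A", "P"), c("A", "P"))
  P
}

# integer-array view of a phylo + states for the C++ core
mk2_tree_data <- function(phy, states) {
  phy <- ape::reorder.phylo(as_phylo(phy), "cladewise")
  if (is.null(phy$edge.length)) stop("tree must have branch lengths")
  ntip <- length(phy$tip.label)
  ntot <- ntip + phy$Nnode
  miss <- setdiff(phy$tip.label, names(states))
  if (length(miss)) stop("missing tip state(s): ", paste(miss, collapse = ", "))
  ts <- match(as.character(states)[match(phy$tip.label, names(states))],
              .host_levels) - 1L
  obs <- ts[ts != 2L]
  if (length(unique(obs)) < 2L)
    warning("fewer than two observed states: transition rates are not identifiable")
  blen <- numeric(ntot)
  blen[phy$edge[, 2]] <- phy$edge.length
  depth <- integer(ntot)
  for (k in seq_len(nrow(phy$edge)))
    depth[phy$edge[k, 2]] <- depth[phy$edge[k, 1]] + 1L
  ints <- internal_nodes(phy)
  postorder <- ints[order(depth[ints], decreasing = TRUE)]
  list(phy = phy,
       cpp = list(ntip = ntip, ntot = ntot,
                  children = lapply(children_list(phy),
                                    function(k) as.integer(k - 1L)),
                  blen = blen, postorder = as.integer(postorder - 1L),
                  tipstate = as.integer(ts)))
}

#' Mk2 pruning log-likelihood
#'
#' Felsenstein post-order pruning over the two-state model; `"?"` tips are
#' uninformative partials.  The root is combined with the stationary
#' distribution of the rate matrix (default) or a uniform distribution.
#'
#' @param tree a `phylo` (or [timetree]) with branch lengths.
#' @param states a [host_states()] covering every tip.
#' @param q_ap,q_pa transition rates.
#' @param root `"stationary"` or `"uniform"` root state distribution.
#' @return log-likelihood.
#' @export
pruning_loglik <- function(tree, states, q_ap, q_pa,
                           root = c("stationary", "uniform")) {
  root <- match.arg(root)
  td <- mk2_tree_data(tree, states)
  mk2_loglik_cpp(td$cpp, q_ap, q_pa, root == "uniform")
}

#' Marginal ancestral state probabilities
#'
#' Up-down (post-order then pre-order) marginal probabilities of each state
#' at every node, conditioning on all tip states.
#'
#' @inheritParams pruning_loglik
#' @return matrix (nodes x 2, columns `A`, `P`); every row sums to 1.  Tip
#'   rows reproduce the observed states (or the posterior for `"?"` tips).
#' @export
marginal_anc_states <- function(tree, states, q_ap, q_pa,
                                root = c("stationary", "uniform")) {
  root <- match.arg(root)
  td <- mk2_tree_data(tree, states)
  phy <- td$phy
  ntip <- length(phy$tip.label)
  ntot <- ntip + phy$Nnode
  kids <- children_list(phy)
  blen <- td$cpp$blen
  # up pass (conditional likelihoods, scaled)
  f <- matrix(0, ntot, 2)
  for (i in seq_len(ntip)) {
    s <- td$cpp$tipstate[i]
    f[i, ] <- if (s == 2L) c(1, 1) else if (s == 0L) c(1, 0) else c(0, 1)
  }
  post <- td$cpp$postorder + 1L
  edgeP <- vector("list", ntot) # transition matrix on the branch above node
  for (i in seq_len(ntot))
    if (blen[i] > 0 || i != ntip + 1L)
      edgeP[[i]] <- transition_matrix(q_ap, q_pa, blen[i])
  for (i in post) {
    part <- c(1, 1)
    for (ch in kids[[i]]) part <- part * as.numeric(edgeP[[ch]] %*% f[ch, ])
    f[i, ] <- part / max(part)
  }
  q <- q_ap + q_pa
  pi0 <- if (root == "uniform" || q == 0) c(0.5, 0.5) else c(q_pa, q_ap) / q
  # down pass: 'above' partials
  a <- matrix(0, ntot, 2)
  rootn <- ntip + 1L
  a[rootn, ] <- pi0
  for (i in rev(post)) { # pre-order over internal nodes
    for (ch in kids[[i]]) {
      sibs <- setdiff(kids[[i]], ch)
      above <- a[i, ]
      for (s in sibs) above <- above * as.numeric(edgeP[[s]] %*% f[s, ])
      a[ch, ] <- as.numeric(t(edgeP[[ch]]) %*% above)
      a[ch, ] <- a[ch, ] / max(a[ch, ])
    }
  }
  m <- a * f
  m <- m / rowSums(m)
  colnames(m) <- c("A", "P")
  m
}

default_rate_prior_mean <- function(phy) {
  # prior mean chosen so the expected number of transitions per rate over
  # the whole tree is ~2
  2 / sum(as_phylo(phy)$edge.length)
}

#' MCMC estimation of Mk2 transition rates
#'
#' Metropolis sampling of `(q_AP, q_PA)` under independent exponential
#' priors, optionally with both rates constrained equal.  Node marginal
#' probabilities are averaged over the rate posterior.
#'
#' @inheritParams pruning_loglik
#' @param n_iter total sweeps.
#' @param burn_in discarded sweeps (adaptation happens here).
#' @param thin keep every `thin`-th sweep.
#' @param prior_mean exponential prior mean for each rate; default makes the
#'   expected number of transitions per rate over the tree about 2.
#' @param equal_rates constrain `q_AP = q_PA`.
#' @param prior_only sample the prior (likelihood tempered to zero).
#' @param seed optional seed.
#' @param n_marginal number of posterior draws over which node marginals are
#'   averaged (0 to skip).
#' @return list with `trace` (data frame `q_ap`, `q_pa`, `loglik`),
#'   `marginals` (averaged node probabilities or `NULL`), `accept`,
#'   `prior_mean`.
#' @export
run_asr_mcmc <- function(tree, states, n_iter = 20000, burn_in = 4000,
                         thin = 10, prior_mean = NULL, equal_rates = FALSE,
                         root = c("stationary", "uniform"), prior_only = FALSE,
                         seed = NULL, n_marginal = 100) {
  root <- match.arg(root)
  if (!is.null(seed)) set.seed(seed)
  td <- mk2_tree_data(tree, states)
  if (is.null(prior_mean)) prior_mean <- default_rate_prior_mean(td$phy)
  prior_mean <- rep_len(prior_mean, 2)
  if (any(prior_mean <= 0)) stop("prior mean must be positive")
  res <- mk2_mcmc_cpp(td$cpp, beta = if (prior_only) 0 else 1,
                      equal_rates = equal_rates,
                      root_uniform = root == "uniform",
                      n_sweeps = n_iter, burn = burn_in, thin = thin,
                      prior_rate_ap = 1 / prior_mean[1],
                      prior_rate_pa = 1 / prior_mean[2],
                      init_ap = prior_mean[1], init_pa = prior_mean[2])
  trace <- data.frame(q_ap = res$trace[, 1], q_pa = res$trace[, 2],
                      loglik = res$trace[, 3])
  marg <- NULL
  if (n_marginal > 0 && nrow(trace) > 0) {
    idx <- unique(round(seq(1, nrow(trace), length.out = min(n_marginal, nrow(trace)))))
    acc <- 0
    for (i in idx)
      acc <- acc + marginal_anc_states(td$phy, states, trace$q_ap[i],
                                       trace$q_pa[i], root = root)
    marg <- acc / length(idx)
  }
  list(trace = trace, marginals = marg, accept = res$accept,
       prior_mean = prior_mean, equal_rates = equal_rates, root = root)
}

#' Stepping-stone estimate of the Mk2 log marginal likelihood
#'
#' Runs a ladder of power posteriors `prior * likelihood^beta` with the beta
#' rungs placed at quantiles of a Beta(`alpha`, 1) distribution (dense near
#' zero) and accumulates the stepping-stone estimator.  Chains are
#' warm-started rung to rung.
#'
#' @inheritParams run_asr_mcmc
#' @param model `"free"` (two rates), `"equal"` (one shared rate) or
#'   `"fixed"` (no free parameters: the log marginal likelihood is the
#'   log-likelihood at `fixed_rates`).
#' @param K number of stepping-stone rungs (>= 8).
#' @param alpha Beta quantile parameter for rung spacing.
#' @param rung_sweeps,rung_burn,rung_thin per-rung chain settings.
#' @param fixed_rates length-2 rate vector, only for `model = "fixed"`.
#' @return list with `logml`, the `betas` ladder and per-rung contributions.
#' @export
stepping_stone_logml <- function(tree, states, model = c("free", "equal", "fixed"),
                                 K = 32, alpha = 0.3, rung_sweeps = 600,
                                 rung_burn = 200, rung_thin = 2,
                                 prior_mean = NULL,
                                 root = c("stationary", "uniform"),
                                 fixed_rates = NULL, seed = NULL) {
  model <- match.arg(model)
  root <- match.arg(root)
  if (!is.null(seed)) set.seed(seed)
  td <- mk2_tree_data(tree, states)
  if (model == "fixed") {
    if (is.null(fixed_rates)) stop("fixed model needs fixed_rates")
    ll <- mk2_loglik_cpp(td$cpp, fixed_rates[1], fixed_rates[2],
                         root == "uniform")
    return(list(logml = ll, betas = c(0, 1), contributions = ll))
  }
  if (K < 8) stop("need at least 8 stepping-stone rungs")
  if (is.null(prior_mean)) prior_mean <- default_rate_prior_mean(td$phy)
  prior_mean <- rep_len(prior_mean, 2)
  betas <- ((0:K) / K)^(1 / alpha)
  if (any(diff(betas) <= 0)) stop("beta ladder must be strictly increasing")
  init <- prior_mean
  contrib <- numeric(K)
  for (k in seq_len(K)) {
    res <- mk2_mcmc_cpp(td$cpp, beta = betas[k],
                        equal_rates = model == "equal",
                        root_uniform = root == "uniform",
                        n_sweeps = rung_sweeps, burn = rung_burn,
                        thin = rung_thin,
                        prior_rate_ap = 1 / prior_mean[1],
                        prior_rate_pa = 1 / prior_mean[2],
                        init_ap = init[1], init_pa = init[2])
    ll <- res$trace[, 3]
    d <- betas[k + 1] - betas[k]
    mx <- max(d * ll)
    contrib[k] <- mx + log(mean(exp(d * ll - mx)))
    init <- res$last
  }
  list(logml = sum(contrib), betas = betas, contributions = contrib)
}

#' Bayes-factor comparison of the free vs equal-rates Mk2 models
#'
#' `logBF = 2 * (logML_free - logML_equal)` by stepping-stone sampling;
#' values above 10 are conventionally read as very strong support for the
#' free (asymmetric) model.
#'
#' @inheritParams stepping_stone_logml
#' @return list with `logml_free`, `logml_equal` and `logBF`.
#' @export
asr_model_compare <- function(tree, states, K = 32, alpha = 0.3,
                              rung_sweeps = 600, rung_burn = 200,
                              rung_thin = 2, prior_mean = NULL,
                              root = c("stationary", "uniform"), seed = NULL) {
  root <- match.arg(root)
  if (!is.null(seed)) set.seed(seed)
  free <- stepping_stone_logml(tree, states, model = "free", K = K,
                               alpha = alpha, rung_sweeps = rung_sweeps,
                               rung_burn = rung_burn, rung_thin = rung_thin,
                               prior_mean = prior_mean, root = root)
  eq <- stepping_stone_logml(tree, states, model = "equal", K = K,
                             alpha = alpha, rung_sweeps = rung_sweeps,
                             rung_burn = rung_burn, rung_thin = rung_thin,
                             prior_mean = prior_mean, root = root)
  list(logml_free = free$logml, logml_equal = eq$logml,
       logBF = 2 * (free$logml - eq$logml))
}
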