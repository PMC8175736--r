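# Metropolis-within-Gibbs MCMC over node ages, rates and clock
# hyperparameters.  The hot loop lives in src/dating_mcmc.cpp; this file
# prepares the integer-array view of the tree, the calibration bookkeeping
# and the prior sampler used both for initial states and for
# prior-predictive simulation.
#
# Age prior: calibrated nodes carry their soft-uniform densities; every
# other internal node follows a sequential conditional-uniform prior --
# uniform between its parent's age and the largest fixed age below it
# (calibrated descendants, minimum bounds, or 0 for leaves), taken in
# pre-order.  This conditional is exactly normalised given the calibrated
# ages, so the marginal prior of every calibrated node is its own
# calibration density; the generator (`prior_sample`) and the sampler use
# the same construction, making prior-only MCMC and prior-predictive
# simulation two views of one distribution.

#' MCMC chain settings
#'
#' Defaults follow the study-scale chain (burn-in 200,000; sampling
#' frequency 100; 20,000 samples).  The `"desk"` preset (burn-in 20,000;
#' every 10; 2,000 samples) is the scaled-down configuration used for tests
#' and replicated experiments.
#'
#' @param burn_in burn-in iterations (sweeps); proposal scales adapt only
#'   during burn-in.
#' @param sample_every record every this many sweeps after burn-in.
#' @param n_samples number of recorded samples.
#' @param seed optional integer seed (applied via [set.seed()]).
#' @param prior_only sample from the effective joint prior (likelihood off),
#'   the `usedata = 0` style check.
#' @param mixing_move enable the whole-tree scale moves (ages times c with
#'   rates divided by c, and a joint rates-and-mu rescaling).
#' @param n_mixing how many whole-tree scale proposals per sweep; this is
#'   the slowest posterior direction (the likelihood is invariant along it),
#'   so several cheap attempts per sweep pay off.
#' @param preset `NULL`, `"paper"` (the defaults) or `"desk"`.
#' @return object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(burn_in = 200000, sample_every = 100,
                          n_samples = 20000, seed = NULL, prior_only = FALSE,
                          mixing_move = TRUE, n_mixing = 5, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("paper", "desk"))
    if (preset == "desk") {
      burn_in <- 20000; sample_every <- 25; n_samples <- 2000
    }
  }
  if (burn_in < 0 || sample_every < 1 || n_samples < 1 || n_mixing < 0)
    stop("chain settings must be positive")
  structure(list(burn_in = as.integer(burn_in),
                 sample_every = as.integer(sample_every),
                 n_samples = as.integer(n_samples), seed = seed,
                 prior_only = isTRUE(prior_only),
                 mixing_move = isTRUE(mixing_move),
                 n_mixing = as.integer(n_mixing), preset = preset),
            class = "mcmc_settings")
}

# ---- calibration bookkeeping ------------------------------------------------

# Per-node calibration table and the boundary structure of the sequential
# uniform prior: for every non-calibrated internal node, the calibrated
# descendants visible through non-calibrated paths (refs) and the largest
# constant lower bound (leaf age 0 and minimum-only bounds) on such paths.
cal_layout <- function(tree, calset) {
  phy <- ape::reorder.phylo(as_phylo(tree), "cladewise")
  ntip <- length(phy$tip.label)
  ntot <- ntip + phy$Nnode
  nodes <- vapply(calset, function(cal) resolve_clade(phy, cal$clade), integer(1))
  if (any(nodes <= ntip)) stop("calibrations must resolve to internal nodes")
  if (anyDuplicated(nodes)) stop("more than one calibration per node")
  if (!any(nodes == ntip + 1L)) stop("root calibration required")
  type <- integer(ntot)
  tmin <- tmax <- pl <- pu <- numeric(ntot)
  for (i in seq_along(calset)) {
    cal <- calset[[i]]
    type[nodes[i]] <- if (is_min_only(cal)) 2L else 1L
    tmin[nodes[i]] <- cal$t_min
    tmax[nodes[i]] <- cal$t_max
    pl[nodes[i]] <- cal$p_lower
    pu[nodes[i]] <- if (is.na(cal$p_upper)) 0 else cal$p_upper
  }
  kids <- children_list(phy)
  refs <- vector("list", ntot)
  cst <- numeric(ntot)
  for (i in rev(internal_nodes(phy))) { # post-order on ape numbering needs care
    refs[[i]] <- integer(0); cst[i] <- 0
  }
  # process internal nodes children-first: order by decreasing depth
  depth <- integer(ntot)
  for (k in seq_len(nrow(phy$edge)))
    depth[phy$edge[k, 2]] <- depth[phy$edge[k, 1]] + 1L
  ord <- internal_nodes(phy)[order(depth[internal_nodes(phy)], decreasing = TRUE)]
  for (i in ord) {
    rr <- integer(0); cc <- 0
    for (c in kids[[i]]) {
      if (c <= ntip) next
      if (type[c] == 1L) rr <- c(rr, c)
      else {
        rr <- c(rr, refs[[c]])
        cc <- max(cc, cst[c], if (type[c] == 2L) tmin[c] else 0)
      }
    }
    refs[[i]] <- rr
    cst[i] <- if (type[i] == 2L) max(cc, tmin[i]) else cc
  }
  list(phy = phy, ntip = ntip, ntot = ntot, nodes = nodes, type = type,
       tmin = tmin, tmax = tmax, pl = pl, pu = pu, refs = refs, cst = cst,
       kids = kids, parent = parent_vec(phy))
}

#' Sample node ages from the joint calibration prior
#'
#' Draws calibrated node ages from their soft-uniform densities and every
#' other internal node age from the sequential conditional-uniform prior,
#' rejecting jointly inconsistent draws.  This is the exact distribution the
#' prior-only MCMC targets, and the generative half of prior-predictive
#' simulation.
#'
#' @param tree a [timetree] (topology suffices).
#' @param calset a [calibration_set()] (root calibration required).
#' @param n number of age vectors to draw.
#' @param max_tries rejection attempts per draw before giving up.
#' @return an `n` by n-nodes matrix of ages (Ma); leaf columns are 0.
#' @export
prior_sample <- function(tree, calset, n = 1, max_tries = 1000) {
  lay <- cal_layout(tree, calset)
  cal_by_node <- setNames(as.list(calset), lay$nodes)
  edge <- lay$phy$edge
  ints <- internal_nodes(lay$phy) # cladewise edge order visits parents first
  preord <- unique(edge[, 1])     # internal nodes, parents before children
  out <- matrix(0, n, lay$ntot)
  for (d in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      ages <- numeric(lay$ntot)
      for (i in which(lay$type == 1L))
        ages[i] <- soft_uniform_sample(1, cal_by_node[[as.character(i)]])
      good <- TRUE
      for (i in preord) {
        if (lay$type[i] == 1L) next
        lo <- max(lay$cst[i], ages[lay$refs[[i]]])
        hi <- ages[lay$parent[i]]
        if (!length(hi) || is.na(hi)) hi <- Inf # root is always calibrated
        if (hi <= lo) { good <- FALSE; break }
        ages[i] <- runif(1, lo, hi)
      }
      if (good && all(ages[edge[, 1]] - ages[edge[, 2]] > .age_eps)) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop("could not draw a jointly consistent age vector; ",
                  "check calibration compatibility")
    out[d, ] <- ages
  }
  out
}

# ---- main sampler -----------------------------------------------------------

#' Run the dating MCMC
#'
#' Metropolis-within-Gibbs sampling of internal node ages, among-branch
#' rates and clock hyperparameters given soft-bounded calibrations and an
#' approximate likelihood on branch-length summary statistics.  Moves per
#' sweep: a window slide for every internal node age, a multiplicative slide
#' for the root age, multiplicative updates of every rate and of `mu` and
#' `sigma2`, and a whole-tree mixing move that scales all ages by `c` and
#' divides all rates (and `mu`) by `c` with the matching proposal-density
#' correction.  Proposal scales adapt toward ~30% acceptance during burn-in
#' only.
#'
#' @param tree a [timetree] (topology; ages not required).
#' @param calibrations a [calibration_set()]; the root must be calibrated
#'   with a finite maximum.
#' @param clock a [clock_config()].
#' @param partitions a [partition_data()] or list of them (branch order =
#'   `phy$edge` rows); ignored when `settings$prior_only`.
#' @param settings an [mcmc_settings()].
#' @return object of class `posterior_trace`: matrices `ages` (columns
#'   `t_<node>`) and `rates`, data frame `hyper` (`mu`, `sigma2`), vectors
#'   `loglik` and `logpost`, acceptance rates, and run metadata.
#' @export
run_mcmc <- function(tree, calibrations, clock, partitions = NULL,
                     settings = mcmc_settings()) {
  stopifnot(inherits(clock, "clock_config"), inherits(settings, "mcmc_settings"))
  if (!is.null(settings$seed)) set.seed(settings$seed)
  lay <- cal_layout(tree, calibrations)
  phy <- lay$phy
  ntip <- lay$ntip; ntot <- lay$ntot
  root <- ntip + 1L
  if (lay$type[root] != 1L)
    stop("the root calibration must have a finite maximum bound")
  # branches indexed by child node (ascending, root excluded)
  bnode <- setdiff(seq_len(ntot), root)
  rowmap <- match(bnode, phy$edge[, 2])
  use_lik <- !settings$prior_only
  lik <- list(use = use_lik, bhat = list(), g = list(), H = list())
  if (use_lik) {
    if (is.null(partitions)) stop("partitions required unless prior_only")
    partitions <- as_partition_list(partitions)
    for (p in partitions) {
      if (length(p$b_hat) != length(bnode))
        stop("partition dimension does not match the tree")
      lik$bhat <- c(lik$bhat, list(p$b_hat[rowmap]))
      lik$g <- c(lik$g, list(p$gradient[rowmap]))
      lik$H <- c(lik$H, list(p$hessian[rowmap, rowmap, drop = FALSE]))
    }
  }
  init_ages <- prior_sample(tree, calibrations, 1)[1, ]
  mu0 <- clock$mu_mean
  s20 <- clock$sigma2_mean
  res <- date_mcmc_cpp(
    tree = list(ntip = ntip, ntot = ntot,
                parent = ifelse(is.na(lay$parent), -1L, lay$parent) - 1L,
                children = lapply(lay$kids, function(k) as.integer(k - 1L)),
                bnode = as.integer(bnode - 1L),
                refs = lapply(lay$refs, function(r) as.integer(r - 1L)),
                cst = lay$cst),
    calinfo = list(type = as.integer(lay$type), tmin = lay$tmin,
                   tmax = lay$tmax, pl = lay$pl, pu = lay$pu),
    clock = list(ar = as.integer(clock$model == "AR"), tau0 = clock$tau0,
                 mu_shape = clock$mu_shape,
                 mu_scale = clock$mu_mean / clock$mu_shape,
                 s2_shape = clock$sigma2_shape,
                 s2_scale = clock$sigma2_mean / clock$sigma2_shape),
    lik = lik,
    settings = list(burn = settings$burn_in, every = settings$sample_every,
                    nsamp = settings$n_samples,
                    prior_only = settings$prior_only,
                    mixing = settings$mixing_move,
                    n_mix = max(1L, settings$n_mixing)),
    init_ages = init_ages, init_mu = mu0, init_s2 = s20)
  ints <- internal_nodes(phy)
  colnames(res$ages) <- paste0("t_", ints)
  colnames(res$rates) <- if (clock$model == "AR") paste0("r_node_", seq_len(ntot))
                         else paste0("r_br_", bnode)
  structure(list(ages = res$ages, rates = res$rates,
                 hyper = data.frame(mu = res$mu, sigma2 = res$sigma2),
                 loglik = res$loglik, logpost = res$logpost,
                 accept = res$accept, scales = res$scales,
                 settings = settings, clock = clock,
                 internal_nodes = ints, cal_nodes = lay$nodes,
                 tree = timetree(phy, ages = NULL)),
            class = "posterior_trace")
}

#' @export
print.posterior_trace <- function(x, ...) {
  cat("posterior_trace:", nrow(x$ages), "samples,",
      ncol(x$ages), "node ages,", ncol(x$rates), "rates\n")
  cat("acceptance:", paste(names(x$accept),
                           sprintf("%.2f", x$accept), collapse = ", "), "\n")
  invisible(x)
}

#' Write a posterior trace as TSV
#' @param trace a `posterior_trace`.
#' @param file output path.
#' @export
write_trace <- function(trace, file) {
  tab <- data.frame(trace$ages, trace$hyper, loglik = trace$loglik,
                    logpost = trace$logpost, check.names = FALSE)
  write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

# ---- posterior summaries ----------------------------------------------------

#' Highest posterior density interval
#'
#' The shortest contiguous interval containing `ceiling(mass * N)` of the
#' sorted samples.
#'
#' @param samples numeric vector (length >= 2).
#' @param mass interval mass in (0, 1); default 0.95.
#' @return `c(lower, upper)`.
#' @export
hpd <- function(samples, mass = 0.95) {
  if (length(samples) < 2L) stop("need at least two samples")
  if (!(mass > 0 && mass < 1)) stop("mass must be in (0, 1)")
  x <- sort(samples)
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) return(c(x[1], x[n]))
  w <- x[seq.int(m, n)] - x[seq_len(n - m + 1L)]
  i <- which.min(w)
  c(x[i], x[i + m - 1L])
}

#' Effective sample size of a chain
#'
#' `N / (1 + 2 * sum(rho_k))`, autocorrelations summed up to (excluding) the
#' first non-positive term.
#'
#' @param chain numeric vector, length >= 10.
#' @return effective sample size; 0 with a warning for a constant chain.
#' @export
ess <- function(chain) {
  n <- length(chain)
  if (n < 10L) stop("chain too short for ESS")
  if (sd(chain) == 0) {
    warning("constant chain: ESS undefined, reporting 0")
    return(0)
  }
  rho <- acf(chain, lag.max = min(n - 1L, 2000L), plot = FALSE,
             demean = TRUE)$acf[-1]
  k <- which(rho <= 0)[1]
  s <- if (is.na(k)) sum(rho) else if (k == 1L) 0 else sum(rho[seq_len(k - 1L)])
  n / (1 + 2 * s)
}

#' Compare posterior means from two independent chains
#'
#' The study-style convergence check: per-parameter relative difference of
#' posterior means against a tolerance, plus the correlation of the two mean
#' vectors.
#'
#' @param trace_a,trace_b `posterior_trace` objects (or matrices with the
#'   same column names).
#' @param tol relative tolerance (default 0.05).
#' @return list with a per-parameter data frame (`parameter`, `mean_a`,
#'   `mean_b`, `rel_diff`, `flagged`), the mean-vector `correlation`, and
#'   overall `pass`.
#' @export
two_chain_check <- function(trace_a, trace_b, tol = 0.05) {
  get_mat <- function(tr) {
    if (inherits(tr, "posterior_trace"))
      cbind(tr$ages, mu = tr$hyper$mu, sigma2 = tr$hyper$sigma2)
    else as.matrix(tr)
  }
  a <- get_mat(trace_a); b <- get_mat(trace_b)
  if (!identical(colnames(a), colnames(b)))
    stop("the two traces carry different parameter sets")
  ma <- colMeans(a); mb <- colMeans(b)
  rel <- abs(ma - mb) / pmax(abs(ma + mb) / 2, .Machine$double.eps)
  tab <- data.frame(parameter = colnames(a), mean_a = ma, mean_b = mb,
                    rel_diff = rel, flagged = rel > tol, row.names = NULL)
  list(table = tab,
       correlation = if (length(ma) > 1L) stats::cor(ma, mb) else NA_real_,
       pass = !any(tab$flagged), tol = tol)
}
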