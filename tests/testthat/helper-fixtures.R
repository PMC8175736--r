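# Small builders shared across test files.

toy_tree <- function() parse_newick("((A:1,B:1):1,(C:1,D:1):1);")

# random binary chronogram with labelled tips, for oracle comparisons
random_chronogram <- function(n, root_age = 1000) {
  simulate_bd_tree(n, birth = 3 / root_age, death = 1 / root_age,
                   root_age = root_age)
}

# a small calibrated dataset with exact Gaussian branch-length likelihood
toy_dataset <- function(seed = 1, n = 8, cv = 0.1, clock = clock_config("AR")) {
  set.seed(seed)
  tt <- random_chronogram(n, root_age = 2000)
  phy <- tt$phy
  cals <- calibration_set(
    calibration(phy$tip.label, t_min = 1000, t_max = 2500, name = "root"))
  hy <- sample_hyperpriors(clock, 1)
  rates <- simulate_rates(tt, clock_params(clock$model, hy$mu, hy$sigma2,
                                           tau0 = clock$tau0))
  b <- expected_branch_lengths(tt, rates$branch_rates)
  s <- pmax(cv * b, 1e-6)
  parts <- list(partition_data(b + rnorm(length(b), 0, s),
                               -diag(1 / s^2, length(s))))
  list(tree = tt, calibrations = cals, clock = clock, partitions = parts,
       rates = rates, hyper = hy, b_true = b)
}

# exhaustive Mk2 likelihood by summing over all internal state assignments
mk2_enum_loglik <- function(phy, states, q_ap, q_pa,
                            root = c("stationary", "uniform")) {
  root <- match.arg(root)
  ntip <- length(phy$tip.label)
  ntot <- ntip + phy$Nnode
  par <- rep(NA_integer_, ntot); par[phy$edge[, 2]] <- phy$edge[, 1]
  blen <- numeric(ntot); blen[phy$edge[, 2]] <- phy$edge.length
  q <- q_ap + q_pa
  pi0 <- if (root == "uniform" || q == 0) c(0.5, 0.5) else c(q_pa, q_ap) / q
  tipst <- match(as.character(states)[match(phy$tip.label, names(states))],
                 c("A", "P", "?"))
  ints <- (ntip + 1):ntot
  total <- 0
  for (mask in 0:(2^length(ints) - 1)) {
    st <- integer(ntot)
    for (j in seq_along(ints))
      st[ints[j]] <- bitwAnd(mask %/% 2^(j - 1), 1L) + 1L
    p <- pi0[st[ntip + 1]]
    ok <- TRUE
    for (i in seq_len(ntot)) {
      if (i == ntip + 1) next
      P <- transition_matrix(q_ap, q_pa, blen[i])
      if (i <= ntip) {
        s <- tipst[i]
        pr <- if (s == 3) sum(P[st[par[i]], ]) else P[st[par[i]], s]
      } else pr <- P[st[par[i]], st[i]]
      p <- p * pr
      if (p == 0) { ok <- FALSE; break }
    }
    if (ok) total <- total + p
  }
  log(total)
}

# enumeration likelihood with one internal node clamped to a given state
# (state 1 = A, 2 = P); returns the joint probability, not its log
mk2_enum_clamped <- function(phy, states, q_ap, q_pa, clamp_node, clamp_state) {
  ntip <- length(phy$tip.label)
  ntot <- ntip + phy$Nnode
  par <- rep(NA_integer_, ntot); par[phy$edge[, 2]] <- phy$edge[, 1]
  blen <- numeric(ntot); blen[phy$edge[, 2]] <- phy$edge.length
  q <- q_ap + q_pa
  pi0 <- if (q == 0) c(0.5, 0.5) else c(q_pa, q_ap) / q
  tipst <- match(as.character(states)[match(phy$tip.label, names(states))],
                 c("A", "P", "?"))
  ints <- (ntip + 1):ntot
  total <- 0
  for (mask in 0:(2^length(ints) - 1)) {
    st <- integer(ntot)
    for (j in seq_along(ints))
      st[ints[j]] <- bitwAnd(mask %/% 2^(j - 1), 1L) + 1L
    if (st[clamp_node] != clamp_state) next
    p <- pi0[st[ntip + 1]]
    for (i in seq_len(ntot)) {
      if (i == ntip + 1) next
      P <- transition_matrix(q_ap, q_pa, blen[i])
      pr <- if (i <= ntip) {
        s <- tipst[i]
        if (s == 3) sum(P[st[par[i]], ]) else P[st[par[i]], s]
      } else P[st[par[i]], st[i]]
      p <- p * pr
      if (p == 0) break
    }
    total <- total + p
  }
  total
}
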