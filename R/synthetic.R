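# Synthetic data with the structure the dating analyses assume: an
# ultrametric chronogram made of a calibration-poor (symbiont) clade and a
# calibration-rich (host/mitochondria-analog) clade joined at the root,
# among-branch rate variation from the clock module, Gaussian noise on
# branch-length estimates, soft-bounded calibrations bracketing the true
# ages, and binary host characters evolved under the Mk2 model.

# Birth-death node-depth CDF under the coalescent-point-process view of the
# reconstructed tree, F(t) = birth (1 - e^{-rt}) / (birth - death e^{-rt}),
# r = birth - death; inverted for sampling truncated at the root age.
bd_depth_quantile <- function(u, birth, death, root_age) {
  r <- birth - death
  FT <- birth * (1 - exp(-r * root_age)) / (birth - death * exp(-r * root_age))
  v <- u * FT
  e <- birth * (1 - v) / (birth - v * death)
  -log(e) / r
}

# newick text (no trailing ';') for a conditioned BD clade, plus its crown age
bd_clade_newick <- function(n_tips, birth, death, root_age, labels) {
  if (n_tips == 1L) return(labels[1])
  d <- numeric(n_tips - 1L)
  pos <- sample.int(n_tips - 1L, 1L)
  d[pos] <- root_age
  if (n_tips > 2L)
    d[-pos] <- bd_depth_quantile(runif(n_tips - 2L), birth, death, root_age)
  build <- function(lo, hi) {
    if (lo == hi) return(list(s = labels[lo], age = 0))
    i <- lo + which.max(d[lo:(hi - 1L)]) - 1L
    L <- build(lo, i); R <- build(i + 1L, hi)
    list(s = sprintf("(%s:%.10f,%s:%.10f)", L$s, d[i] - L$age,
                     R$s, d[i] - R$age),
         age = d[i])
  }
  build(1L, n_tips)$s
}

#' Simulate a birth-death chronogram conditioned on size and root age
#'
#' Draws the reconstructed-tree node depths from the coalescent-point-process
#' distribution of a birth-death process conditioned on `n_tips` extant tips
#' and the given crown (root) age, yielding an ultrametric [timetree].
#'
#' @param n_tips number of extant tips (>= 2).
#' @param birth,death per-lineage rates (per Ma), `birth > death >= 0`.
#' @param root_age crown age in Ma.
#' @param labels optional tip labels (default `t1..tn`, shuffled onto the
#'   tree at random).
#' @return an ultrametric [timetree].
#' @export
simulate_bd_tree <- function(n_tips, birth, death = 0, root_age = 1,
                             labels = NULL) {
  if (n_tips < 2L) stop("need at least two tips")
  if (!(birth > death && death >= 0)) stop("need birth > death >= 0")
  if (root_age <= 0) stop("root age must be positive")
  if (is.null(labels)) labels <- paste0("t", seq_len(n_tips))
  labels <- sample(labels)
  nwk <- paste0(bd_clade_newick(n_tips, birth, death, root_age, labels), ";")
  parse_newick(nwk)
}

#' Scenario specification for synthetic dating data sets
#'
#' @param n_symbiont,n_host tip counts of the calibration-poor (symbiont)
#'   and calibration-rich (host-analog) clades.
#' @param root_age true root age in Ma.
#' @param birth,death birth-death rates (per Ma) for both clades.
#' @param clock a [clock_config()]; hyperparameters for each data set are
#'   drawn from its hyperpriors.
#' @param cv coefficient of variation of the Gaussian branch-length
#'   estimation noise (default 10% of the true length).
#' @param n_partitions number of partitions to emit.
#' @param placement `"mito_like"` (internal calibrations carry min and max
#'   bounds), `"cyano_like"` (internal calibrations are minimum-only; the
#'   root carries the only maximum) or `"both"` (emit a matched pair
#'   sharing tree, rates and noise).
#' @param n_internal_cal number of calibrated internal host-clade nodes
#'   (default 4, the number of internal eukaryote calibration points in the
#'   mitochondria-encoded design this generator emulates).
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(n_symbiont = 10, n_host = 10, root_age = 3000,
                          birth = 0.0015, death = 0.0005,
                          clock = clock_config("AR"), cv = 0.1,
                          n_partitions = 2,
                          placement = c("mito_like", "cyano_like", "both"),
                          n_internal_cal = 4) {
  placement <- match.arg(placement)
  stopifnot(n_symbiont >= 2, n_host >= 2, root_age > 0, cv > 0,
            n_partitions >= 1, n_internal_cal >= 1)
  structure(list(n_symbiont = n_symbiont, n_host = n_host,
                 root_age = root_age, birth = birth, death = death,
                 clock = clock, cv = cv, n_partitions = n_partitions,
                 placement = placement, n_internal_cal = n_internal_cal),
            class = "scenario_spec")
}

# all nodes in the subtree rooted at `node` (inclusive)
subtree_nodes <- function(phy, node) {
  kids <- children_list(phy)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    i <- stack[1]; stack <- stack[-1]
    out <- c(out, i)
    stack <- c(stack, kids[[i]])
  }
  out
}

# Gaussian branch-length noise partitions: b_hat ~ N(b_true, diag(sd^2)),
# H = -diag(1/sd^2), g = 0, so the quadratic approximation is the exact
# likelihood of the synthetic data.
make_partitions <- function(b_true, cv, n_partitions, sites = 5000L) {
  lapply(seq_len(n_partitions), function(p) {
    s <- pmax(cv * b_true, 1e-6)
    b_hat <- b_true + rnorm(length(b_true), 0, s)
    partition_data(b_hat = b_hat, hessian = -diag(1 / s^2, length(s)),
                   sites = sites)
  })
}

#' Simulate a complete synthetic dating data set
#'
#' Builds the two-clade chronogram, draws clock hyperparameters from their
#' hyperpriors, simulates rates and noisy branch-length estimates, and
#' constructs calibrations around the true node ages: every calibrated
#' node's bracket contains its true age (minimum at U(0.6, 0.9) and maximum
#' at U(1.1, 1.6) times the true age).  Under `"cyano_like"` placement the
#' internal calibrations keep only their minimum bounds, so the root
#' maximum is the sole upper constraint, as in cyanobacteria-fossil dating.
#'
#' @param spec a [scenario_spec()].
#' @param seed optional seed.
#' @return a list with `tree` (true chronogram), `rates`, `mu`, `sigma2`,
#'   `partitions`, `calibrations` (or `calibrations_mito` and
#'   `calibrations_cyano` when `placement = "both"`), `cal_nodes`,
#'   `symbiont_crown`, `symbiont_nodes`, and the `spec`.
#' @export
simulate_dataset <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!is.null(seed)) set.seed(seed)
  sym_age <- spec$root_age * runif(1, 0.7, 0.9)
  host_age <- spec$root_age * runif(1, 0.7, 0.9)
  sym <- bd_clade_newick(spec$n_symbiont, spec$birth, spec$death, sym_age,
                         sample(paste0("S", seq_len(spec$n_symbiont))))
  host <- bd_clade_newick(spec$n_host, spec$birth, spec$death, host_age,
                          sample(paste0("H", seq_len(spec$n_host))))
  nwk <- sprintf("(%s:%.10f,%s:%.10f);", sym, spec$root_age - sym_age,
                 host, spec$root_age - host_age)
  tree <- parse_newick(nwk)
  phy <- tree$phy
  hyper <- sample_hyperpriors(spec$clock, 1)
  params <- clock_params(spec$clock$model, hyper$mu, hyper$sigma2,
                         tau0 = spec$clock$tau0)
  rates <- simulate_rates(tree, params)
  b_true <- expected_branch_lengths(tree, rates$branch_rates)
  partitions <- make_partitions(b_true, spec$cv, spec$n_partitions)

  root <- root_node(phy)
  sym_crown <- resolve_clade(phy, phy$tip.label[grep("^S", phy$tip.label)])
  host_crown <- resolve_clade(phy, phy$tip.label[grep("^H", phy$tip.label)])
  host_int <- setdiff(subtree_nodes(phy, host_crown), seq_len(n_tips(phy)))
  ncal <- min(spec$n_internal_cal, length(host_int))
  # spread the calibrated nodes over the age range, oldest (crown) included
  ord <- host_int[order(tree$ages[host_int], decreasing = TRUE)]
  cal_nodes <- ord[unique(round(seq(1, length(ord), length.out = ncal)))]
  tip_sets <- lapply(cal_nodes, function(nd) {
    tips <- intersect(subtree_nodes(phy, nd), seq_len(n_tips(phy)))
    phy$tip.label[tips]
  })
  fmin <- runif(length(cal_nodes), 0.6, 0.9)
  fmax <- runif(length(cal_nodes), 1.1, 1.6)
  root_cal <- calibration(phy$tip.label, t_min = min(1000, 0.5 * spec$root_age),
                          t_max = 1.2 * spec$root_age, name = "root",
                          tags = "root")
  build_cals <- function(min_only) {
    cals <- lapply(seq_along(cal_nodes), function(k)
      calibration(tip_sets[[k]],
                  t_min = fmin[k] * tree$ages[cal_nodes[k]],
                  t_max = if (min_only) Inf else fmax[k] * tree$ages[cal_nodes[k]],
                  name = paste0("cal_node_", cal_nodes[k])))
    calibration_set(c(cals, list(root_cal)))
  }
  out <- list(tree = tree, rates = rates, mu = hyper$mu,
              sigma2 = hyper$sigma2, partitions = partitions,
              cal_nodes = cal_nodes, symbiont_crown = sym_crown,
              host_crown = host_crown,
              symbiont_nodes = setdiff(subtree_nodes(phy, sym_crown),
                                       seq_len(n_tips(phy))),
              spec = spec)
  if (spec$placement == "both") {
    out$calibrations_mito <- build_cals(FALSE)
    out$calibrations_cyano <- build_cals(TRUE)
  } else {
    out$calibrations <- build_cals(spec$placement == "cyano_like")
  }
  out
}

#' Write a synthetic data set as plain-text files
#'
#' Emits `tree.nwk`, `calibrations.tsv`, per-partition branch/Hessian TSVs
#' and `truth.json` (true ages, rates, hyperparameters) for recovery
#' scoring.
#'
#' @param ds result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  phy <- ds$tree$phy
  ape::write.tree(phy, file.path(dir, "tree.nwk"))
  cals <- if (!is.null(ds$calibrations)) ds$calibrations else ds$calibrations_mito
  write_calibrations(cals, file.path(dir, "calibrations.tsv"))
  for (p in seq_along(ds$partitions))
    write_partition_data(ds$partitions[[p]], ds$tree, dir, paste0("part", p))
  jsonlite::write_json(
    list(ages = ds$tree$ages, branch_rates = ds$rates$branch_rates,
         mu = ds$mu, sigma2 = ds$sigma2,
         n_partitions = length(ds$partitions)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Simulate binary host states on a tree under the Mk2 model
#'
#' The root state is drawn from the stationary distribution and states
#' evolve down each branch by the exact two-state transition probabilities.
#'
#' @param tree a `phylo` or [timetree] with branch lengths.
#' @param q_ap,q_pa transition rates (per unit branch length).
#' @return a [host_states()] over the tips; the full node states are
#'   attached as attribute `"node_states"`.
#' @export
simulate_host_states <- function(tree, q_ap, q_pa) {
  phy <- ape::reorder.phylo(as_phylo(tree), "cladewise")
  if (is.null(phy$edge.length)) stop("tree must have branch lengths")
  ntip <- length(phy$tip.label)
  ntot <- ntip + phy$Nnode
  st <- integer(ntot) # 0 = A, 1 = P
  q <- q_ap + q_pa
  piP <- if (q > 0) q_ap / q else 0.5
  st[ntip + 1L] <- as.integer(runif(1) < piP)
  for (k in seq_len(nrow(phy$edge))) {
    a <- phy$edge[k, 1]; d <- phy$edge[k, 2]
    P <- transition_matrix(q_ap, q_pa, phy$edge.length[k])
    st[d] <- as.integer(runif(1) < P[st[a] + 1L, 2])
  }
  out <- host_states(setNames(c("A", "P")[st[seq_len(ntip)] + 1L],
                              phy$tip.label))
  attr(out, "node_states") <- c("A", "P")[st + 1L]
  out
}

# ---- packaged benchmark and replicated experiments --------------------------

#' Load the packaged 20-leaf synthetic benchmark
#'
#' A fixed 20-leaf two-clade scenario (10 symbiont + 10 host-analog tips,
#' true root age 2500 Ma) with three soft-bounded calibrations (root
#' 1000-3000 Ma plus two host-clade brackets) and two Gaussian
#' branch-length partitions, shipped as plain-text fixtures.
#'
#' @return list with `tree` (true chronogram), `topology` (ages stripped),
#'   `calibrations`, `partitions`, `truth`, and the default `clock`.
#' @export
benchmark_dataset <- function() {
  dir <- system.file("extdata", "benchmark20", package = "endoclock",
                     mustWork = TRUE)
  tree <- parse_newick(paste(readLines(file.path(dir, "tree.nwk")),
                             collapse = ""))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  parts <- lapply(seq_len(truth$n_partitions), function(p)
    read_partition_data(dir, paste0("part", p), sites = 5000L))
  topo <- tree
  topo$ages <- rep(NA_real_, length(topo$ages))
  list(tree = tree, topology = topo,
       calibrations = read_calibrations(file.path(dir, "calibrations.tsv")),
       partitions = parts, truth = truth, clock = clock_config("AR"))
}

#' Prior-predictive coverage experiment
#'
#' For each seed: draw clock hyperparameters from their hyperpriors and node
#' ages from the joint calibration prior on the benchmark topology, simulate
#' rates and Gaussian branch-length estimates, run the MCMC, and score
#' whether each internal node's true age lies inside its 95% HPD interval.
#' Because data are simulated from the model's own prior-predictive
#' distribution, the pooled fraction should match the nominal 95%.
#'
#' The branch-length noise standard deviations are *fixed constants* of the
#' experiment (`cv` times the packaged benchmark's true branch lengths), not
#' functions of each replicate's drawn state: the Gaussian noise model
#' handed to the sampler must be the exact distribution the data were drawn
#' from, or the nominal coverage guarantee no longer holds.
#'
#' @param seeds integer vector of per-replicate seeds.
#' @param settings an [mcmc_settings()] (the desk preset by default).
#' @param mass credible mass (default 0.95).
#' @param cv branch-length noise level, relative to the benchmark's
#'   reference branch lengths.
#' @param n_partitions partitions per replicate.
#' @return list with `coverage` (pooled fraction), `n_checks`, and the
#'   per-replicate fractions.
#' @export
coverage_experiment <- function(seeds = 1:200,
                                settings = mcmc_settings(preset = "desk"),
                                mass = 0.95, cv = 0.1, n_partitions = 2) {
  bench <- benchmark_dataset()
  topo <- bench$topology
  clock <- bench$clock
  phy <- topo$phy
  ints <- internal_nodes(phy)
  b_ref <- expected_branch_lengths(bench$tree, bench$truth$branch_rates)
  sd_fix <- pmax(cv * b_ref, 1e-6)
  H_fix <- -diag(1 / sd_fix^2, length(sd_fix))
  hits <- total <- 0
  per_rep <- numeric(length(seeds))
  for (k in seq_along(seeds)) {
    set.seed(seeds[k])
    hyper <- sample_hyperpriors(clock, 1)
    ages <- prior_sample(topo, bench$calibrations, 1)[1, ]
    tt <- timetree(phy, ages)
    params <- clock_params(clock$model, hyper$mu, hyper$sigma2,
                           tau0 = clock$tau0)
    rates <- simulate_rates(tt, params)
    b_true <- expected_branch_lengths(tt, rates$branch_rates)
    parts <- lapply(seq_len(n_partitions), function(p)
      partition_data(b_true + rnorm(length(b_true), 0, sd_fix), H_fix,
                     sites = 5000L))
    tr <- run_mcmc(topo, bench$calibrations, clock, parts, settings)
    inside <- logical(length(ints))
    for (i in seq_along(ints)) {
      h <- hpd(tr$ages[, i], mass)
      inside[i] <- ages[ints[i]] >= h[1] && ages[ints[i]] <= h[2]
    }
    hits <- hits + sum(inside)
    total <- total + length(inside)
    per_rep[k] <- mean(inside)
  }
  list(coverage = hits / total, n_checks = total, per_replicate = per_rep)
}

#' Matched root-sweep contrast experiment
#'
#' Generates matched scenario pairs (identical tree, rates and noise;
#' calibrations placed mito-like vs cyano-like), sweeps the root maximum
#' bound over a grid for both, and records how often the mean root-sweep
#' slope of the focal symbiont-clade ages is smaller under mito-like
#' placement -- the synthetic restatement of the claim that
#' endosymbiosis-transferred internal maxima buffer the analysis against an
#' arbitrary root calibration.
#'
#' @param n_pairs number of matched pairs.
#' @param grid increasing grid of root maximum bounds (Ma).
#' @param settings an [mcmc_settings()].
#' @param base_seed seed offset; pair k uses `base_seed + k`.
#' @param spec a [scenario_spec()] with `placement = "both"`.
#' @param n_clades number of focal symbiont-clade nodes tracked (deepest
#'   first).
#' @return list with `fraction_smaller`, and per-pair slopes
#'   (`slope_mito`, `slope_cyano`).
#' @export
sweep_contrast_experiment <- function(n_pairs = 20,
                                      grid = c(3500, 4000, 4500),
                                      settings = mcmc_settings(preset = "desk"),
                                      base_seed = 1000,
                                      spec = scenario_spec(placement = "both"),
                                      n_clades = 4) {
  slope_m <- slope_c <- numeric(n_pairs)
  for (k in seq_len(n_pairs)) {
    ds <- simulate_dataset(spec, seed = base_seed + k)
    nodes <- ds$symbiont_nodes[order(ds$tree$ages[ds$symbiont_nodes],
                                     decreasing = TRUE)]
    clades <- as.list(head(nodes, n_clades))
    st <- settings
    st$seed <- base_seed + k
    sw_m <- root_sweep(ds$tree, ds$calibrations_mito, grid, ds$spec$clock,
                       ds$partitions, st, clades)
    sw_c <- root_sweep(ds$tree, ds$calibrations_cyano, grid, ds$spec$clock,
                       ds$partitions, st, clades)
    slope_m[k] <- mean(sw_m$slopes)
    slope_c[k] <- mean(sw_c$slopes)
  }
  list(fraction_smaller = mean(slope_m < slope_c),
       slope_mito = slope_m, slope_cyano = slope_c)
}
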