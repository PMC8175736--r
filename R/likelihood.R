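# Approximate likelihood of (ages, rates) given per-partition branch-length
# summary statistics: a second-order expansion of the sequence log-likelihood
# around the estimated branch lengths b_hat, with gradient g and curvature
# (Hessian) H, evaluated on the plain branch-length scale.  An exact Poisson
# substitution-count likelihood is provided as a small-scale oracle mode.

#' Per-partition branch-length summary statistics
#'
#' @param b_hat estimated branch lengths (substitutions/site), one per branch
#'   in the tree's `phy$edge` row order.
#' @param hessian curvature matrix of the log-likelihood at `b_hat`
#'   (symmetric; negative-definite for well-behaved estimates).
#' @param gradient gradient at `b_hat` (defaults to zero, the value at an
#'   interior maximum).
#' @param sites number of alignment sites behind the estimates (metadata).
#' @return object of class `partition_data`.
#' @export
partition_data <- function(b_hat, hessian, gradient = NULL, sites = NA_integer_) {
  b_hat <- as.numeric(b_hat)
  nb <- length(b_hat)
  if (is.null(gradient)) gradient <- numeric(nb)
  hessian <- as.matrix(hessian)
  if (length(gradient) != nb || !all(dim(hessian) == nb))
    stop("dimension mismatch between b_hat, gradient and hessian")
  if (max(abs(hessian - t(hessian))) > 1e-8 * max(1, max(abs(hessian))))
    stop("hessian must be symmetric")
  structure(list(b_hat = b_hat, gradient = as.numeric(gradient),
                 hessian = hessian, sites = sites),
            class = "partition_data")
}

as_partition_list <- function(partitions) {
  if (inherits(partitions, "partition_data")) partitions <- list(partitions)
  if (!all(vapply(partitions, inherits, logical(1), "partition_data")))
    stop("'partitions' must be partition_data objects")
  partitions
}

#' Expected branch lengths implied by ages and rates
#'
#' The substitution-length of a branch is its duration (Ma) times its rate
#' (substitutions/site/Ma).
#'
#' @param tree a [timetree] with ages.
#' @param branch_rates per-branch rates, `phy$edge` row order.
#' @return branch lengths (substitutions/site), `phy$edge` row order.
#' @export
expected_branch_lengths <- function(tree, branch_rates) {
  dur <- branch_durations(tree)
  if (length(branch_rates) != length(dur))
    stop("expected one rate per branch")
  dur * branch_rates
}

#' Approximate log-likelihood from branch-length summary statistics
#'
#' `sum_p [ g_p'(b - b_hat_p) + (b - b_hat_p)' H_p (b - b_hat_p) / 2 ]`,
#' the second-order expansion of each partition's sequence log-likelihood
#' around its branch-length estimates (additive constant dropped).
#'
#' @param tree a [timetree] with ages.
#' @param branch_rates per-branch rates, `phy$edge` row order.
#' @param partitions a [partition_data()] or list of them.
#' @return relative log-likelihood (0 at `b = b_hat` when gradients vanish).
#' @export
approx_loglik <- function(tree, branch_rates, partitions) {
  partitions <- as_partition_list(partitions)
  b <- expected_branch_lengths(tree, branch_rates)
  ll <- 0
  for (p in partitions) {
    if (length(p$b_hat) != length(b)) stop("partition/tree dimension mismatch")
    z <- b - p$b_hat
    ll <- ll + sum(p$gradient * z) + 0.5 * sum(z * (p$hessian %*% z))
  }
  if (!is.finite(ll)) stop("non-finite approximate log-likelihood")
  ll
}

#' Exact Poisson substitution-count log-likelihood (oracle mode)
#'
#' Treats the per-branch substitution count as Poisson with mean
#' `sites * branch length`, the exact small-scale stand-in for a full
#' sequence likelihood.
#'
#' @param tree a [timetree] with ages.
#' @param branch_rates per-branch rates, `phy$edge` row order.
#' @param counts non-negative integer substitution counts per branch.
#' @param sites number of sites.
#' @return log-likelihood.
#' @export
poisson_loglik <- function(tree, branch_rates, counts, sites) {
  if (any(counts < 0)) stop("counts must be non-negative")
  b <- expected_branch_lengths(tree, branch_rates)
  if (length(counts) != length(b)) stop("expected one count per branch")
  sum(dpois(counts, sites * b, log = TRUE))
}

#' Write partition data as TSV files
#'
#' Writes `<name>_branches.tsv` (columns `branch`, `child_node`, `b_hat`,
#' `gradient`) and `<name>_hessian.tsv` (dense matrix), the plain-text
#' exchange format for approximate-likelihood inputs.
#'
#' @param part a [partition_data()].
#' @param tree the [timetree] the branches belong to.
#' @param dir output directory.
#' @param name file stem.
#' @export
write_partition_data <- function(part, tree, dir, name) {
  stopifnot(inherits(part, "partition_data"))
  phy <- as_phylo(tree)
  tab <- data.frame(branch = seq_along(part$b_hat),
                    child_node = phy$edge[, 2],
                    b_hat = part$b_hat, gradient = part$gradient)
  write.table(tab, file.path(dir, paste0(name, "_branches.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(part$hessian, file.path(dir, paste0(name, "_hessian.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Read partition data written by [write_partition_data()]
#' @param dir directory.
#' @param name file stem.
#' @param sites optional site count metadata.
#' @return a [partition_data()].
#' @export
read_partition_data <- function(dir, name, sites = NA_integer_) {
  tab <- read.delim(file.path(dir, paste0(name, "_branches.tsv")))
  H <- as.matrix(read.delim(file.path(dir, paste0(name, "_hessian.tsv")),
                            header = FALSE))
  dimnames(H) <- NULL
  partition_data(b_hat = tab$b_hat, hessian = H, gradient = tab$gradient,
                 sites = sites)
}
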