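# Soft-bounded uniform calibration densities.  Inside [t_min, t_max] the
# density is flat with mass 1 - p_lower - p_upper; the lower tail on
# (0, t_min) is a power-form density with mass p_lower, the upper tail on
# (t_max, Inf) an exponential-form density with mass p_upper, each tail
# parameter fixed by continuity of the density at the bound.

#' Fossil calibration with soft uniform bounds
#'
#' A probabilistic age constraint on a clade: a uniform density between a
#' minimum and a maximum bound (Ma), with small "soft" tail masses beyond
#' each bound (2.5% by default) so that conflicting evidence is never
#' assigned zero prior probability.  `t_max = Inf` declares a minimum-only
#' calibration (a hard lower bound with no upper bound of its own, as used in
#' cyanobacteria-style calibration strategies).
#'
#' @param taxa leaf labels defining the clade (or a [clade_spec()]).
#' @param group `"crown"` or `"total"`; see [resolve_clade()].
#' @param t_min,t_max bounds in Ma, `0 < t_min < t_max`.
#' @param p_lower,p_upper tail probabilities below/above the bounds;
#'   `p_lower + p_upper < 1`.  Set both to 0 for hard bounds.
#' @param name optional label.
#' @param tags optional character vector of free-form labels used by dating
#'   scheme presets (see [apply_scheme()]).
#' @return object of class `calibration`.
#' @export
calibration <- function(taxa, group = c("crown", "total"), t_min, t_max,
                        p_lower = 0.025, p_upper = 0.025, name = NULL,
                        tags = character(0)) {
  spec <- if (inherits(taxa, "clade_spec")) taxa else clade_spec(taxa, match.arg(group))
  stopifnot(is.numeric(t_min), is.numeric(t_max), length(t_min) == 1L,
            length(t_max) == 1L)
  if (!(t_min > 0)) stop("t_min must be positive")
  if (!(t_max > t_min)) stop("t_max must exceed t_min")
  if (p_lower < 0 || p_upper < 0 || p_lower + p_upper >= 1)
    stop("tail probabilities must be non-negative with p_lower + p_upper < 1")
  if (!is.finite(t_max)) p_upper <- NA_real_
  structure(list(clade = spec, t_min = t_min, t_max = t_max,
                 p_lower = p_lower, p_upper = p_upper,
                 name = if (is.null(name)) paste(spec$taxa[1], spec$group) else name,
                 tags = tags),
            class = "calibration")
}

is_min_only <- function(cal) !is.finite(cal$t_max)

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("calibration '%s' (%s): %s-%s Ma (tails %s/%s)\n", x$name,
              x$clade$group, format(x$t_min), format(x$t_max),
              format(x$p_lower), format(x$p_upper)))
  invisible(x)
}

#' A set of calibrations
#'
#' @param ... [calibration()] objects (or a single list of them).
#' @return object of class `calibration_set` (a list of calibrations).
#' @export
calibration_set <- function(...) {
  cals <- list(...)
  if (length(cals) == 1L && is.list(cals[[1]]) && !inherits(cals[[1]], "calibration"))
    cals <- cals[[1]]
  if (!all(vapply(cals, inherits, logical(1), "calibration")))
    stop("all elements must be calibration objects")
  structure(cals, class = "calibration_set")
}

# interior density height and tail parameters; used by pdf/cdf/quantile
.soft_pars <- function(cal) {
  if (is_min_only(cal)) stop("minimum-only calibration has no proper density of its own")
  h <- (1 - cal$p_lower - cal$p_upper) / (cal$t_max - cal$t_min)
  list(h = h,
       theta = if (cal$p_lower > 0) h * cal$t_min / cal$p_lower else NA_real_,
       lambda = if (cal$p_upper > 0) h / cal$p_upper else NA_real_)
}

#' Soft-bounded uniform calibration density
#'
#' @param t ages in Ma (positive).
#' @param cal a [calibration()] with finite `t_max`.
#' @param log return the log density (default `TRUE` for `soft_uniform_logpdf`).
#' @return (log) density per Ma, vectorised over `t`.  The density is flat at
#'   `(1 - p_lower - p_upper)/(t_max - t_min)` on the interior, continuous at
#'   both bounds, and integrates to 1 on `(0, Inf)`.
#' @export
soft_uniform_logpdf <- function(t, cal, log = TRUE) {
  stopifnot(inherits(cal, "calibration"))
  if (any(t <= 0)) stop("ages must be positive")
  p <- .soft_pars(cal)
  out <- rep(log(p$h), length(t))
  lo <- t < cal$t_min
  hi <- t > cal$t_max
  out[lo] <- if (cal$p_lower > 0)
    log(cal$p_lower) + log(p$theta) + (p$theta - 1) * log(t[lo]) -
      p$theta * log(cal$t_min) else -Inf
  out[hi] <- if (cal$p_upper > 0)
    log(cal$p_upper) + log(p$lambda) - p$lambda * (t[hi] - cal$t_max) else -Inf
  if (log) out else exp(out)
}

#' Soft-uniform cumulative distribution function
#' @inheritParams soft_uniform_logpdf
#' @return P(age <= t), vectorised.
#' @export
soft_uniform_cdf <- function(t, cal) {
  stopifnot(inherits(cal, "calibration"))
  p <- .soft_pars(cal)
  out <- numeric(length(t))
  lo <- t < cal$t_min & t > 0
  mid <- t >= cal$t_min & t <= cal$t_max
  hi <- t > cal$t_max
  if (cal$p_lower > 0)
    out[lo] <- cal$p_lower * (t[lo] / cal$t_min)^p$theta
  out[mid] <- cal$p_lower + p$h * (t[mid] - cal$t_min)
  out[hi] <- if (cal$p_upper > 0)
    1 - cal$p_upper * exp(-p$lambda * (t[hi] - cal$t_max)) else 1
  out
}

#' Soft-uniform quantile function
#' @param q probabilities in (0, 1).
#' @param cal a [calibration()].
#' @export
soft_uniform_quantile <- function(q, cal) {
  stopifnot(all(q > 0 & q < 1))
  p <- .soft_pars(cal)
  out <- numeric(length(q))
  lo <- q < cal$p_lower
  hi <- q > 1 - cal$p_upper
  mid <- !lo & !hi
  if (any(lo))
    out[lo] <- cal$t_min * (q[lo] / cal$p_lower)^(1 / p$theta)
  out[mid] <- cal$t_min + (q[mid] - cal$p_lower) / p$h
  if (any(hi))
    out[hi] <- cal$t_max - log((1 - q[hi]) / cal$p_upper) / p$lambda
  out
}

#' Draw ages from a soft-uniform calibration density
#'
#' Inverse-CDF sampling by region; uses R's RNG stream, so results are
#' reproducible under [set.seed()].
#'
#' @param n number of draws.
#' @param cal a [calibration()].
#' @return numeric vector of ages (Ma).
#' @export
soft_uniform_sample <- function(n, cal) soft_uniform_quantile(runif(n), cal)

#' Check joint consistency of a calibration set on a tree
#'
#' Resolves every calibration, verifies that the root is calibrated and that
#' no node carries two calibrations, and flags every calibrated descendant
#' whose minimum bound exceeds a calibrated ancestor's maximum bound.  Such
#' pairs have no jointly compatible hard interpretation; because the bounds
#' are soft the joint density stays positive, so violations are returned as
#' warnings rather than errors.
#'
#' @param set a [calibration_set()].
#' @param tree a [timetree] or `phylo`.
#' @return data frame of violations (zero rows when consistent), with the
#'   resolved node ids attached as attribute `"nodes"`.
#' @export
check_consistency <- function(set, tree) {
  stopifnot(inherits(set, "calibration_set"))
  if (length(set) == 0L) stop("empty calibration set (root calibration required)")
  phy <- as_phylo(tree)
  nodes <- vapply(set, function(cal) resolve_clade(phy, cal$clade), integer(1))
  if (anyDuplicated(nodes))
    stop("more than one calibration resolves to the same node")
  root <- length(phy$tip.label) + 1L
  if (!any(nodes == root)) stop("root calibration required")
  par <- parent_vec(phy)
  is_anc <- function(a, d) { # is node a an ancestor of node d?
    while (!is.na(par[d])) { d <- par[d]; if (d == a) return(TRUE) }
    FALSE
  }
  viol <- data.frame(ancestor = character(0), descendant = character(0),
                     anc_t_max = numeric(0), desc_t_min = numeric(0))
  for (i in seq_along(set)) for (j in seq_along(set)) {
    if (i == j || !is.finite(set[[i]]$t_max)) next
    if (is_anc(nodes[i], nodes[j]) && set[[j]]$t_min > set[[i]]$t_max) {
      viol <- rbind(viol, data.frame(
        ancestor = set[[i]]$name, descendant = set[[j]]$name,
        anc_t_max = set[[i]]$t_max, desc_t_min = set[[j]]$t_min))
      warning(sprintf("calibration '%s' (min %g) conflicts with ancestor '%s' (max %g)",
                      set[[j]]$name, set[[j]]$t_min, set[[i]]$name, set[[i]]$t_max))
    }
  }
  attr(viol, "nodes") <- nodes
  viol
}

#' Read calibrations from TSV
#'
#' Columns: `clade_name`, `taxa` (semicolon-separated leaf labels), `group`
#' (`crown`/`total`), `t_min`, `t_max` (`Inf` allowed for minimum-only),
#' `p_lower`, `p_upper`, and optionally `tags` (semicolon-separated).
#'
#' @param file TSV path.
#' @return a [calibration_set()].
#' @export
read_calibrations <- function(file) {
  tab <- read.delim(file, stringsAsFactors = FALSE, comment.char = "#")
  cals <- lapply(seq_len(nrow(tab)), function(i) {
    calibration(taxa = strsplit(tab$taxa[i], ";")[[1]],
                group = tab$group[i],
                t_min = tab$t_min[i], t_max = as.numeric(tab$t_max[i]),
                p_lower = tab$p_lower[i],
                p_upper = if (is.na(tab$p_upper[i])) 0.025 else tab$p_upper[i],
                name = tab$clade_name[i],
                tags = if ("tags" %in% names(tab) && nzchar(tab$tags[i]) &&
                           !is.na(tab$tags[i]))
                  strsplit(tab$tags[i], ";")[[1]] else character(0))
  })
  calibration_set(cals)
}

#' Write calibrations to TSV
#' @param set a [calibration_set()].
#' @param file output path.
#' @export
write_calibrations <- function(set, file) {
  stopifnot(inherits(set, "calibration_set"))
  tab <- do.call(rbind, lapply(set, function(cal) data.frame(
    clade_name = cal$name,
    taxa = paste(cal$clade$taxa, collapse = ";"),
    group = cal$clade$group, t_min = cal$t_min, t_max = cal$t_max,
    p_lower = cal$p_lower, p_upper = cal$p_upper,
    tags = paste(cal$tags, collapse = ";"))))
  write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
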