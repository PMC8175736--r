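# Node numbering follows ape: tips 1..n, root n+1, other internal nodes
# n+2 .. n+Nnode.  Ages are in Ma with extant leaves at 0; every parent is
# strictly older than its children (tolerance .age_eps Ma).

.age_eps <- 1e-9

#' Time-calibrated tree (chronogram) container
#'
#' A `timetree` wraps an [ape::phylo] topology together with a vector of node
#' ages in Ma (million years before present).  Leaves are extant (age 0) and
#' every parent node is strictly older than its children.
#'
#' @param phy a rooted, binary `phylo` object with unique tip labels.
#' @param ages numeric vector of node ages (Ma), in ape node order
#'   (tips first, then internal nodes).  If `NULL` and `phy` has branch
#'   lengths that form an ultrametric tree, ages are derived from node depths;
#'   otherwise ages are left `NA` (topology-only tree).
#' @param tol tolerance used when testing ultrametricity of branch lengths.
#' @return an object of class `timetree` with elements `phy` and `ages`.
#' @export
timetree <- function(phy, ages = NULL, tol = 1e-6) {
  if (!inherits(phy, "phylo")) stop("'phy' must be a phylo object")
  if (!ape::is.rooted(phy)) stop("tree is unrooted (basal polytomy)")
  if (!ape::is.binary(phy)) stop("tree must be fully bifurcating")
  if (anyDuplicated(phy$tip.label)) stop("duplicate leaf labels")
  ntip <- length(phy$tip.label)
  ntot <- ntip + phy$Nnode
  if (is.null(ages)) {
    ages <- rep(NA_real_, ntot)
    if (!is.null(phy$edge.length)) {
      depth <- ape::node.depth.edgelength(phy)
      cand <- max(depth[seq_len(ntip)]) - depth
      if (all(abs(cand[seq_len(ntip)]) < tol * max(1, max(depth)))) {
        cand[seq_len(ntip)] <- 0
        ages <- cand
      }
    }
  } else {
    if (length(ages) != ntot) stop("'ages' must have one entry per node")
    if (any(abs(ages[seq_len(ntip)]) > .age_eps))
      stop("all leaves must have age 0")
    ages[seq_len(ntip)] <- 0
    dur <- ages[phy$edge[, 1]] - ages[phy$edge[, 2]]
    if (any(dur <= .age_eps))
      stop("age(parent) must exceed age(child) on every branch")
    phy$edge.length <- dur
  }
  structure(list(phy = phy, ages = ages), class = "timetree")
}

#' @export
print.timetree <- function(x, ...) {
  n <- length(x$phy$tip.label)
  cat("timetree:", n, "leaves,", x$phy$Nnode, "internal nodes\n")
  if (!anyNA(x$ages))
    cat("root age:", format(x$ages[n + 1L], digits = 6), "Ma\n")
  else cat("ages: not set (topology only)\n")
  invisible(x)
}

as_phylo <- function(tree) if (inherits(tree, "timetree")) tree$phy else tree

n_tips <- function(tree) length(as_phylo(tree)$tip.label)

root_node <- function(tree) n_tips(tree) + 1L

internal_nodes <- function(tree) {
  phy <- as_phylo(tree)
  n <- length(phy$tip.label)
  seq.int(n + 1L, n + phy$Nnode)
}

# parent id per node, NA at the root
parent_vec <- function(tree) {
  phy <- as_phylo(tree)
  p <- rep(NA_integer_, length(phy$tip.label) + phy$Nnode)
  p[phy$edge[, 2]] <- phy$edge[, 1]
  p
}

children_list <- function(tree) {
  phy <- as_phylo(tree)
  split(phy$edge[, 2], factor(phy$edge[, 1],
                              levels = seq_len(length(phy$tip.label) + phy$Nnode)))
}

# per-edge durations in Ma, in phy$edge row order
branch_durations <- function(tree) {
  stopifnot(inherits(tree, "timetree"), !anyNA(tree$ages))
  tree$ages[tree$phy$edge[, 1]] - tree$ages[tree$phy$edge[, 2]]
}

#' Parse a Newick string into a timetree
#'
#' Wraps [ape::read.tree] with the validation required for dating input:
#' balanced parentheses, unique leaf labels and a rooted (binary basal split)
#' topology.  Bracket comments are stripped.  When the branch lengths form an
#' ultrametric tree, node ages (Ma) are derived; otherwise the result carries
#' topology and branch lengths only.
#'
#' @param text a single Newick string.
#' @param dating reject basal polytomies (required for dating); set `FALSE`
#'   to accept any rooted input.
#' @return a [timetree].
#' @export
parse_newick <- function(text, dating = TRUE) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("\\[[^]]*\\]", "", text)
  no <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  nc <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (no != nc) stop("unbalanced parentheses in Newick string")
  if (!grepl(";", text)) stop("missing ';' terminator in Newick string")
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("malformed Newick: ", conditionMessage(e)))
  if (is.null(phy)) stop("malformed Newick string")
  if (anyDuplicated(phy$tip.label)) stop("duplicate leaf labels")
  if (!ape::is.rooted(phy)) stop("input tree is unrooted (basal polytomy)")
  if (dating && !ape::is.binary(phy))
    stop("polytomies are not allowed in dating mode")
  timetree(phy)
}

#' Clade specification
#'
#' A set of leaf names plus a group flag: `"crown"` targets the most recent
#' common ancestor (MRCA) of the names; `"total"` targets the stem, i.e. the
#' parent node of that MRCA.
#'
#' @param taxa character vector of leaf labels (non-empty).
#' @param group `"crown"` or `"total"`.
#' @return an object of class `clade_spec`.
#' @export
clade_spec <- function(taxa, group = c("crown", "total")) {
  group <- match.arg(group)
  taxa <- unique(as.character(taxa))
  if (length(taxa) == 0L || any(!nzchar(taxa))) stop("empty clade specification")
  structure(list(taxa = taxa, group = group), class = "clade_spec")
}

#' Resolve a clade specification to a node id
#'
#' @param tree a [timetree] or `phylo`.
#' @param spec a [clade_spec], or a character vector of taxa (then `group`
#'   applies).
#' @param group used when `spec` is a plain character vector.
#' @return the node id (ape numbering) of the crown MRCA or, for total
#'   groups, of its parent.  Requesting the total group of a clade whose MRCA
#'   is the root is an error.
#' @export
resolve_clade <- function(tree, spec, group = c("crown", "total")) {
  phy <- as_phylo(tree)
  if (!inherits(spec, "clade_spec")) spec <- clade_spec(spec, match.arg(group))
  unknown <- setdiff(spec$taxa, phy$tip.label)
  if (length(unknown))
    stop("unknown taxa: ", paste(unknown, collapse = ", "))
  tips <- match(spec$taxa, phy$tip.label)
  mrca <- if (length(tips) == 1L) tips else ape::getMRCA(phy, tips)
  root <- length(phy$tip.label) + 1L
  if (spec$group == "crown") return(mrca)
  if (mrca == root) stop("total group requested but the MRCA is the root")
  parent_vec(phy)[mrca]
}

# ---- annotated NEXUS output -------------------------------------------------

#' Write a dated tree with per-node age summaries as annotated NEXUS
#'
#' Each internal node carries a metadata comment
#' `[&age_mean=m,age_hpd={lo,hi}]` (mean posterior age and 95% HPD bounds in
#' Ma), the convention used for figure-ready chronograms.  Branch lengths are
#' node-age differences, so the written tree round-trips through
#' [read_annotated_tree()] with topology and ages intact.
#'
#' @param tree a [timetree] with ages set.
#' @param summary data frame with columns `node`, `mean`, `lower`, `upper`
#'   covering every internal node.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_annotated_tree <- function(tree, summary, file) {
  stopifnot(inherits(tree, "timetree"), !anyNA(tree$ages))
  need <- c("node", "mean", "lower", "upper")
  if (!all(need %in% names(summary))) stop("summary needs columns ", paste(need, collapse = ", "))
  ints <- internal_nodes(tree)
  if (!all(ints %in% summary$node))
    stop("summary is missing node(s): ",
         paste(setdiff(ints, summary$node), collapse = ", "))
  bad <- summary$lower > summary$mean | summary$mean > summary$upper
  if (any(bad)) stop("HPD bounds must satisfy lower <= mean <= upper")
  phy <- tree$phy
  ages <- tree$ages
  kids <- children_list(phy)
  idx <- match(seq_along(ages), summary$node)
  fmt <- function(x) sprintf("%.15g", x)
  build <- function(node, parent_age) {
    if (node <= n_tips(phy)) {
      s <- phy$tip.label[node]
    } else {
      ch <- kids[[node]]
      i <- idx[node]
      s <- paste0("(", build(ch[1], ages[node]), ",", build(ch[2], ages[node]), ")",
                  "[&age_mean=", fmt(summary$mean[i]),
                  ",age_hpd={", fmt(summary$lower[i]), ",", fmt(summary$upper[i]), "}]")
    }
    if (!is.na(parent_age)) s <- paste0(s, ":", fmt(parent_age - ages[node]))
    s
  }
  nwk <- paste0(build(root_node(phy), NA_real_), ";")
  writeLines(c("#NEXUS", "BEGIN TREES;",
               paste0("  TREE dated = [&R] ", nwk), "END;"), con = file)
  invisible(file)
}

#' Read a NEXUS tree annotated by [write_annotated_tree()]
#'
#' @param file path written by [write_annotated_tree()].
#' @return a list with elements `tree` (a [timetree]) and `summary`
#'   (data frame `node`, `mean`, `lower`, `upper`).
#' @export
read_annotated_tree <- function(file) {
  lines <- readLines(file)
  tl <- grep("^\\s*TREE\\b", lines, value = TRUE)
  if (length(tl) != 1L) stop("expected exactly one TREE line")
  nwk <- sub(".*?=", "", tl)
  nwk <- sub("\\[&R\\]", "", nwk)
  m <- gregexpr("\\[&[^]]*\\]", nwk)[[1]]
  annos <- if (m[1] == -1) character(0) else regmatches(nwk, list(m))[[1]]
  for (k in seq_along(annos))
    nwk <- sub("\\[&[^]]*\\]", sprintf("__anno%d__", k), nwk)
  phy <- ape::read.tree(text = trimws(nwk))
  tree <- timetree(phy)
  lab <- phy$node.label
  summ <- data.frame(node = integer(0), mean = numeric(0),
                     lower = numeric(0), upper = numeric(0))
  for (i in seq_along(lab)) {
    k <- as.integer(sub("__anno(\\d+)__", "\\1", lab[i]))
    a <- annos[k]
    mean <- as.numeric(sub(".*age_mean=([-0-9.eE+]+).*", "\\1", a))
    hpd <- sub(".*age_hpd=\\{([^}]*)\\}.*", "\\1", a)
    hh <- as.numeric(strsplit(hpd, ",")[[1]])
    summ <- rbind(summ, data.frame(node = n_tips(phy) + i, mean = mean,
                                   lower = hh[1], upper = hh[2]))
  }
  tree$phy$node.label <- NULL
  list(tree = tree, summary = summ)
}
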