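# Amino-acid alignments and 4-state recoding.  Recoding schemes live in
# inst/extdata/recoding/<scheme>.tsv (residue -> code), so a wrong grouping is
# a one-file fix rather than a code change.

.aa_residues <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Alignment container
#'
#' @param seqs named character vector of residue strings, all the same length.
#' @param alphabet `"aa"` (20 amino acids) or `"recoded4"` (4-state recoded);
#'   gap `-` and ambiguity `X` are allowed in both.
#' @return object of class `alignment`.
#' @export
alignment <- function(seqs, alphabet = c("aa", "recoded4")) {
  alphabet <- match.arg(alphabet)
  seqs <- toupper(unlist(seqs))
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named")
  if (length(unique(nchar(seqs))) > 1L)
    stop("all sequences must have equal length")
  structure(seqs, alphabet = alphabet, class = "alignment")
}

#' Read a FASTA amino-acid alignment
#' @param file FASTA path.
#' @param alphabet see [alignment()].
#' @return an [alignment()].
#' @export
read_fasta_alignment <- function(file, alphabet = "aa") {
  rec <- seqinr::read.fasta(file, seqtype = "AA", as.string = TRUE,
                            set.attributes = FALSE)
  alignment(setNames(toupper(unlist(rec)), names(rec)), alphabet = alphabet)
}

#' Write an alignment as FASTA
#' @param aln an [alignment()].
#' @param file output path.
#' @export
write_fasta_alignment <- function(aln, file) {
  seqinr::write.fasta(as.list(unclass(aln)), names = names(aln),
                      file.out = file, nbchar = 80)
  invisible(file)
}

#' Load a recoding table
#'
#' @param scheme `"dayhoff4"` or `"sr4"`.
#' @return data frame with columns `residue` and `code` (20 rows).
#' @export
load_recoding <- function(scheme = c("dayhoff4", "sr4")) {
  scheme <- match.arg(scheme)
  path <- system.file("extdata", "recoding", paste0(scheme, ".tsv"),
                      package = "endoclock", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!setequal(tab$residue, .aa_residues))
    stop("recoding table must cover the 20 amino acids exactly")
  tab
}

#' Recode a 20-state amino-acid alignment to 4 states
#'
#' Collapses the 20 amino acids into four characters (written as nucleotide
#' letters) following the named scheme's published grouping, a standard guard
#' against compositional heterogeneity in deep phylogenetics.  Gaps (`-`) and
#' ambiguities (`X`) are preserved.  An already-recoded alignment is returned
#' unchanged (recoding is idempotent).
#'
#' @param aln an [alignment()] with `alphabet = "aa"`.
#' @param scheme `"dayhoff4"` or `"sr4"`.
#' @param on_unknown `"error"` (default) or `"mask"` (map unknown residues,
#'   e.g. `B`, `Z`, to `X`).
#' @return a 4-state [alignment()] (`alphabet = "recoded4"`).
#' @export
recode_alignment <- function(aln, scheme = c("dayhoff4", "sr4"),
                             on_unknown = c("error", "mask")) {
  stopifnot(inherits(aln, "alignment"))
  on_unknown <- match.arg(on_unknown)
  if (attr(aln, "alphabet") == "recoded4") return(aln)
  scheme <- match.arg(scheme)
  tab <- load_recoding(scheme)
  seqs <- unclass(aln)
  allowed <- c(.aa_residues, "-", "X")
  stray <- setdiff(unique(strsplit(paste(seqs, collapse = ""), "")[[1]]), allowed)
  if (length(stray)) {
    if (on_unknown == "error")
      stop("unknown residue(s): ", paste(stray, collapse = ", "))
    seqs <- chartr(paste(stray, collapse = ""),
                   strrep("X", length(stray)), seqs)
  }
  out <- chartr(paste(tab$residue, collapse = ""),
                paste(tab$code, collapse = ""), seqs)
  out <- alignment(out, alphabet = "recoded4")
  attr(out, "scheme") <- scheme
  out
}
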