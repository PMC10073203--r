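DNA_ALPHA <- c("A", "C", "G", "T", "N", "-")
AA_ALPHA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
              "M", "F", "P", "S", "T", "W", "Y", "V", "*", "X", "-")

#' Default substitution scores for profile alignment
#' @noRd
sub_matrix <- function(type = c("dna", "protein"),
                       match = NULL, mismatch = NULL) {
  type <- match.arg(type)
  if (type == "dna") {
    if (is.null(match)) match <- 1
    if (is.null(mismatch)) mismatch <- -1
    alpha <- DNA_ALPHA
    S <- matrix(mismatch, length(alpha), length(alpha),
                dimnames = list(alpha, alpha))
    diag(S) <- match
    S["N", ] <- 0; S[, "N"] <- 0   # missing data is score-neutral
    S["-", ] <- 0; S[, "-"] <- 0   # residue against an existing gap
  } else {
    if (is.null(match)) match <- 2
    if (is.null(mismatch)) mismatch <- -1
    alpha <- AA_ALPHA
    S <- matrix(mismatch, length(alpha), length(alpha),
                dimnames = list(alpha, alpha))
    diag(S) <- match
    # internal stop placeholder penalised against everything so frames with
    # disruptions still align but stops are not rewarded
    S["*", ] <- -5; S[, "*"] <- -5
    S["X", ] <- 0; S[, "X"] <- 0
    S["-", ] <- 0; S[, "-"] <- 0
  }
  S
}

profile_counts <- function(rows, alpha) {
  mat <- matrix(0, length(alpha), nchar(rows[1]),
                dimnames = list(alpha, NULL))
  for (r in rows) {
    ch <- strsplit(r, "")[[1]]
    idx <- match(ch, alpha)
    if (anyNA(idx)) stop("character outside alphabet: ",
                         paste(unique(ch[is.na(idx)]), collapse = ""))
    for (k in seq_along(idx)) mat[idx[k], k] <- mat[idx[k], k] + 1
  }
  mat
}

merge_alignments <- function(rows1, rows2, S, gap_open, gap_ext, alpha) {
  p1 <- profile_counts(rows1, alpha)
  p2 <- profile_counts(rows2, alpha)
  res <- align_profiles_cpp(p1, p2, S, gap_open, gap_ext,
                            length(rows1), length(rows2))
  expand <- function(rows, path) {
    chs <- lapply(rows, function(r) strsplit(r, "")[[1]])
    vapply(chs, function(ch) {
      out <- character(length(path))
      out[path == 0] <- "-"
      out[path != 0] <- ch[path[path != 0]]
      paste(out, collapse = "")
    }, character(1))
  }
  out <- c(expand(rows1, res$path1), expand(rows2, res$path2))
  attr(out, "score") <- res$score
  out
}

#' Pairwise global alignment with affine gaps
#'
#' Needleman-Wunsch-Gotoh alignment of two sequences; the primitive under
#' the progressive aligner. A gap run of length g costs
#' `gap_open + (g - 1) * gap_ext`.
#'
#' @param a,b Sequences (character scalars).
#' @param type `"dna"` or `"protein"`.
#' @param match,mismatch Substitution scores (defaults +1/-1 for DNA,
#'   +2/-1 for protein).
#' @param gap_open,gap_ext Gap penalties (negative). Defaults -4 and -1.
#' @return Character vector of the two gapped rows with attribute `score`.
#' @export
pairwise_align <- function(a, b, type = c("dna", "protein"),
                           match = NULL, mismatch = NULL,
                           gap_open = -4, gap_ext = -1) {
  type <- match.arg(type)
  alpha <- if (type == "dna") DNA_ALPHA else AA_ALPHA
  S <- sub_matrix(type, match, mismatch)
  merge_alignments(a, b, S, gap_open, gap_ext, alpha)
}

#' Progressive multiple alignment over a guide tree
#'
#' Profiles are merged in post-order of the guide tree (sum-of-pairs column
#' scores, affine gaps), which makes the result deterministic for a fixed
#' input. Without a guide tree, sequences are merged in input order.
#'
#' @param seqs Named character vector of ungapped sequences.
#' @param guide_tree Optional `"phylo"` tree whose tip set covers
#'   `names(seqs)`.
#' @param type `"dna"` or `"protein"`.
#' @param gap_open,gap_ext Affine gap penalties.
#' @return Named character vector of gapped rows (class `"msa"`), all the
#'   same width; ungapping a row recovers its input.
#' @export
align_regions <- function(seqs, guide_tree = NULL, type = c("dna", "protein"),
                          gap_open = -4, gap_ext = -1) {
  type <- match.arg(type)
  if (is.list(seqs) && inherits(seqs, "ortho_region_set")) seqs <- seqs$regions
  if (length(seqs) < 2L) stop("alignment requires at least 2 sequences")
  if (any(!nzchar(seqs))) stop("empty sequence: ",
                               names(seqs)[!nzchar(seqs)][1])
  seqs <- toupper(seqs)
  alpha <- if (type == "dna") DNA_ALPHA else AA_ALPHA
  S <- sub_matrix(type)

  if (is.null(guide_tree)) {
    rows <- seqs[1]
    for (k in 2L:length(seqs))
      rows <- stats::setNames(
        merge_alignments(rows, seqs[k], S, gap_open, gap_ext, alpha),
        c(names(rows), names(seqs)[k]))
  } else {
    gt <- guide_tree
    if (!all(names(seqs) %in% gt$tip.label))
      stop("guide tree is missing sequences: ",
           paste(setdiff(names(seqs), gt$tip.label), collapse = ", "))
    if (length(setdiff(gt$tip.label, names(seqs))))
      gt <- ape::keep.tip(gt, names(seqs))
    rows <- align_clade(gt, length(gt$tip.label) + 1L, seqs, S,
                        gap_open, gap_ext, alpha)
  }
  out <- rows[names(seqs)]
  class(out) <- "msa"
  out
}

align_clade <- function(tree, node, seqs, S, gap_open, gap_ext, alpha) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) {
    return(stats::setNames(seqs[tree$tip.label[node]], tree$tip.label[node]))
  }
  children <- tree$edge[tree$edge[, 1] == node, 2]
  parts <- lapply(children, align_clade, tree = tree, seqs = seqs, S = S,
                  gap_open = gap_open, gap_ext = gap_ext, alpha = alpha)
  rows <- parts[[1]]
  for (k in seq_along(parts)[-1])
    rows <- stats::setNames(
      merge_alignments(rows, parts[[k]], S, gap_open, gap_ext, alpha),
      c(names(rows), names(parts[[k]])))
  rows
}

#' Validate a multiple sequence alignment
#'
#' Checks equal row widths and (optionally) that ungapping each row recovers
#' the corresponding input sequence.
#'
#' @param msa Named character vector of gapped rows.
#' @param inputs Optional named character vector of ungapped inputs.
#' @return `msa`, invisibly; errors on violation.
#' @export
validate_msa <- function(msa, inputs = NULL) {
  if (length(unique(nchar(msa))) != 1L)
    stop("alignment rows have unequal widths")
  if (!is.null(inputs)) {
    for (nm in names(inputs)) {
      if (gsub("-", "", msa[[nm]], fixed = TRUE) != inputs[[nm]])
        stop("ungapped alignment row differs from input: ", nm)
    }
  }
  invisible(msa)
}

#' Read an externally produced FASTA MSA
#'
#' Adapter for plugging in any external aligner that writes FASTA: the file
#' is read, validated with [validate_msa()], and returned in the same shape
#' as [align_regions()] output.
#'
#' @param path FASTA file of equal-width gapped rows.
#' @return Named character vector of gapped rows (class `"msa"`).
#' @export
read_external_msa <- function(path) {
  rows <- read_fasta(path)
  validate_msa(rows)
  class(rows) <- "msa"
  rows
}
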