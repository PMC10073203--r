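# Origin-aware coding signatures: frame-preserving codon alignments,
# hexamer log-likelihood scores, a deciban likelihood-ratio coding scorer,
# 6-frame scanning, and counting-method dN/dS.

GENCODE <- NULL

genetic_code <- function() {
  if (is.null(GENCODE)) {
    gc <- Biostrings::GENETIC_CODE
    names(gc) <- chartr("U", "T", names(gc))
    utils::assignInMyNamespace("GENCODE", gc)
  }
  GENCODE
}

#' Translate a nucleotide sequence in frame +1
#'
#' Internal stops become `*`; codons containing N or gaps become `X`; a
#' trailing partial codon is ignored.
#'
#' @param seq Nucleotide string.
#' @return Amino-acid string.
#' @export
translate_orf <- function(seq) {
  cods <- codon_split(toupper(seq))
  if (!length(cods)) return("")
  gc <- genetic_code()
  aa <- gc[cods]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Build a frame-preserving (codon-aware) nucleotide alignment
#'
#' Sequences are translated in frame +1 (internal stops become a penalised
#' placeholder), the peptides are aligned with the progressive aligner, and
#' the nucleotides are threaded back onto the peptide alignment: each
#' residue expands to its three source nucleotides and each peptide gap to
#' three nucleotide gaps, so every gap run has length 0 mod 3 and the human
#' reading frame is preserved. Trailing 1-2 nt that do not fill a codon are
#' kept per row as a `tail` so that ungapping plus the tail reproduces the
#' input exactly.
#'
#' @param seqs Named nucleotide sequences (must include the reference).
#' @param guide_tree Optional guide tree for the progressive aligner.
#' @param reference Reference (human) row name; its length must be a
#'   multiple of 3.
#' @param remove_ref_gaps Drop codon columns gapped in the reference
#'   (destroys the round-trip property for rows with insertions).
#' @return A `"codon_alignment"`: list(rows, peptides, tails, reference).
#' @export
build_codon_alignment <- function(seqs, guide_tree = NULL,
                                  reference = "human",
                                  remove_ref_gaps = FALSE) {
  if (!reference %in% names(seqs))
    stop("reference sequence '", reference, "' missing")
  if (nchar(seqs[[reference]]) %% 3L != 0L)
    stop("reference sequence length must be a multiple of 3")
  seqs <- toupper(seqs)
  short <- nchar(seqs) < 3L
  if (any(short)) {
    warning("dropping sequences shorter than one codon: ",
            paste(names(seqs)[short], collapse = ", "))
    seqs <- seqs[!short]
  }
  if (length(seqs) < 2L) stop("need at least 2 sequences of >= 3 nt")
  tails <- vapply(seqs, function(s) substr(s, nchar(s) - nchar(s) %% 3L + 1L,
                                           nchar(s)), character(1))
  peps <- vapply(seqs, translate_orf, character(1))
  pep_aln <- align_regions(peps, guide_tree = guide_tree, type = "protein")
  rows <- vapply(names(pep_aln), function(nm) {
    cods <- codon_split(seqs[[nm]])
    ch <- strsplit(pep_aln[[nm]], "")[[1]]
    out <- character(length(ch))
    out[ch == "-"] <- "---"
    out[ch != "-"] <- cods
    paste(out, collapse = "")
  }, character(1))
  ca <- structure(list(rows = rows, peptides = unclass(pep_aln),
                       tails = tails, reference = reference),
                  class = "codon_alignment")
  if (remove_ref_gaps) ca <- remove_reference_gaps(ca)
  ca
}

codon_columns <- function(ca) {
  w <- nchar(ca$rows[1])
  if (w %% 3L != 0L) stop("corrupt codon alignment width")
  lapply(ca$rows, codon_split)
}

rebuild_rows <- function(ca, keep) {
  cods <- codon_columns(ca)
  ca$rows <- vapply(cods, function(cc) paste(cc[keep], collapse = ""),
                    character(1))
  ca$peptides <- vapply(ca$peptides, function(p) {
    paste(strsplit(p, "")[[1]][keep], collapse = "")
  }, character(1))
  ca
}

#' Drop codon columns gapped in the reference row
#' @param ca A `"codon_alignment"`.
#' @return The trimmed `"codon_alignment"` (reference row ungapped).
#' @export
remove_reference_gaps <- function(ca) {
  ref <- codon_split(ca$rows[[ca$reference]])
  rebuild_rows(ca, ref != "---")
}

#' Remove codon columns containing an in-frame stop in any row
#'
#' @param ca A `"codon_alignment"`.
#' @return The stripped alignment (possibly zero columns, with a warning).
#' @export
strip_inframe_stops <- function(ca) {
  cods <- codon_columns(ca)
  hasstop <- Reduce(`|`, lapply(cods, function(cc) cc %in% STOP_CODONS))
  if (all(hasstop)) warning("all codon columns contain a stop in some row")
  rebuild_rows(ca, !hasstop)
}

#' Ungap a codon-alignment row (tail restored)
#' @param ca A `"codon_alignment"`.
#' @param name Row name.
#' @return The original input sequence for that row.
#' @export
ungap_codon_row <- function(ca, name) {
  paste0(gsub("-", "", ca$rows[[name]], fixed = TRUE), ca$tails[[name]])
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("Codon alignment: ", length(x$rows), " rows x ",
      nchar(x$rows[1]) %/% 3L, " codons (reference ", x$reference, ")\n",
      sep = "")
  invisible(x)
}

# ---- hexamer score ------------------------------------------------------

#' Hexamer frequency table
#'
#' In-frame hexamer (dicodon) frequencies with pseudocount smoothing, for
#' use as the coding or noncoding background of [hexamer_score()].
#'
#' @param seqs Character vector of training sequences (frame +1).
#' @param pseudocount Added to every hexamer count.
#' @return Named numeric vector of 4096 frequencies summing to 1.
#' @export
hexamer_table <- function(seqs, pseudocount = 1) {
  nts <- c("A", "C", "G", "T")
  all_hex <- apply(expand.grid(nts, nts, nts, nts, nts, nts,
                               stringsAsFactors = FALSE)[, 6:1], 1, paste,
                   collapse = "")
  counts <- stats::setNames(rep(pseudocount, length(all_hex)), all_hex)
  for (s in toupper(seqs)) {
    if (nchar(s) < 6L) next
    starts <- seq(1L, nchar(s) - 5L, by = 3L)
    hx <- substring(s, starts, starts + 5L)
    hx <- hx[!grepl("[^ACGT]", hx)]
    tb <- table(hx)
    counts[names(tb)] <- counts[names(tb)] + as.numeric(tb)
  }
  counts / sum(counts)
}

#' Hexamer usage log-likelihood score
#'
#' Mean, over in-frame sliding hexamers (step 3), of
#' `log(coding_freq / noncoding_freq)`. Positive values indicate
#' coding-like hexamer usage, negative values noncoding-like.
#'
#' @param orf_seq ORF nucleotide sequence (>= 6 nt).
#' @param coding_table,noncoding_table [hexamer_table()] vectors.
#' @return Numeric score.
#' @export
hexamer_score <- function(orf_seq, coding_table, noncoding_table) {
  s <- toupper(orf_seq)
  if (nchar(s) < 6L) stop("sequence must be at least 6 nt")
  starts <- seq(1L, nchar(s) - 5L, by = 3L)
  hx <- substring(s, starts, starts + 5L)
  hx <- hx[!grepl("[^ACGT]", hx)]
  if (!length(hx)) return(NA_real_)
  mean(log(coding_table[hx] / noncoding_table[hx]))
}

# ---- codon-model likelihood-ratio coding score --------------------------

codon_model_setup <- function() {
  nts <- c("T", "C", "A", "G")
  all64 <- apply(expand.grid(nts, nts, nts, stringsAsFactors = FALSE)[, 3:1],
                 1, paste, collapse = "")
  gc <- genetic_code()
  sense <- all64[gc[all64] != "*"]
  aa <- gc[sense]
  list(sense = sense, aa = aa)
}

# GY-style rate matrix: uniform codon frequencies, single-nt changes only,
# kappa for transitions, omega for nonsynonymous changes; scaled to one
# expected substitution per codon site per unit branch length.
codon_q_eigen <- function(omega, kappa = 2) {
  setup <- codon_model_setup()
  sense <- setup$sense; aa <- setup$aa
  n <- length(sense)
  Q <- matrix(0, n, n)
  transitions <- list(c("A", "G"), c("C", "T"))
  sp <- strsplit(sense, "")
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      diff <- which(sp[[i]] != sp[[j]])
      if (length(diff) != 1L) next
      pair <- sort(c(sp[[i]][diff], sp[[j]][diff]))
      ts <- identical(pair, c("A", "G")) || identical(pair, c("C", "T"))
      r <- (if (ts) kappa else 1) * (if (aa[i] != aa[j]) omega else 1)
      Q[i, j] <- r; Q[j, i] <- r
    }
  }
  diag(Q) <- -rowSums(Q)
  scale <- -mean(diag(Q))
  Q <- Q / scale
  eig <- eigen(Q, symmetric = TRUE)
  list(values = eig$values, vectors = eig$vectors, sense = sense)
}

encode_codon_rows <- function(ca, sense) {
  cods <- codon_columns(ca)
  lapply(cods, function(cc) match(cc, sense))  # NA: gap/N/stop = missing
}

codon_loglik <- function(tree, enc, eig, scale) {
  ntip <- length(tree$tip.label)
  n <- length(eig$sense)
  L <- length(enc[[1]])
  ord <- match(tree$tip.label, names(enc))
  tp <- lapply(ord, function(i) {
    P <- matrix(0, n, L)
    idx <- enc[[i]]
    known <- !is.na(idx)
    P[cbind(idx[known], which(known))] <- 1
    P[, !known] <- 1
    P
  })
  pmat <- function(t) {
    P <- eig$vectors %*% (exp(eig$values * t * scale) * t(eig$vectors))
    P[P < 0] <- 0
    P
  }
  io <- inside_outside(tree, tp, pmat, rep(1 / n, n))
  io$loglik
}

#' Coding score of a codon alignment (deciban scale)
#'
#' The built-in scorer is a likelihood-ratio test under a GY-style codon
#' model with uniform codon frequencies and transition/transversion ratio
#' fixed at 2: the alternative optimises the nonsynonymous/synonymous rate
#' ratio omega (and a tree-scale factor), the null fixes omega = 1. The
#' score is `10 * log10` of the likelihood ratio, comparable against the
#' configured coding thresholds. The `"external"` scorer passes through a
#' precomputed score file (one float per line, or id<TAB>score), which is
#' the authoritative route for scores from externally trained models.
#'
#' @param ca A `"codon_alignment"` (stop codons are stripped internally).
#' @param fitted A `"fitted_tree"` or `"phylo"` with branch lengths
#'   covering the alignment rows.
#' @param scorer `"builtin_dnds_lrt"` or `"external"`.
#' @param external_path Score file for the external adapter.
#' @param orf_id Identifier (used to look up two-column score files).
#' @param frame Frame label recorded in the result.
#' @return A `"coding_score"`: list(orf_id, score, scorer_id, n_species,
#'   frame, omega).
#' @export
coding_score <- function(ca, fitted = NULL,
                         scorer = c("builtin_dnds_lrt", "external"),
                         external_path = NULL, orf_id = NA_character_,
                         frame = "+1") {
  scorer <- match.arg(scorer)
  if (scorer == "external") {
    if (is.null(external_path)) stop("external scorer needs a score file")
    sc <- parse_external_score(external_path, orf_id)
    return(structure(list(orf_id = orf_id, score = sc,
                          scorer_id = "external", n_species = NA_integer_,
                          frame = frame, omega = NA_real_),
                     class = "coding_score"))
  }
  if (length(ca$rows) < 2L) stop("coding score requires at least 2 rows")
  ca <- strip_inframe_stops(ca)
  if (nchar(ca$rows[1]) == 0L) stop("alignment empty after stop stripping")
  tree <- if (inherits(fitted, "fitted_tree")) fitted$tree else fitted
  if (is.null(tree)) stop("builtin scorer requires a tree")
  if (length(setdiff(names(ca$rows), tree$tip.label)))
    stop("tree does not cover alignment rows")
  if (length(setdiff(tree$tip.label, names(ca$rows))))
    tree <- ape::keep.tip(tree, names(ca$rows))
  if (sum(tree$edge.length) <= 0) tree$edge.length[] <- 0.01

  eig1 <- codon_q_eigen(1)
  enc <- encode_codon_rows(ca, eig1$sense)
  if (all(vapply(enc, function(e) all(is.na(e)), logical(1))))
    stop("alignment is all-gap")
  fit_scale <- function(eig) {
    stats::optimize(function(s) codon_loglik(tree, enc, eig, s),
                    c(1e-4, 50), maximum = TRUE, tol = 1e-4)
  }
  null <- fit_scale(eig1)
  best <- list(objective = null$objective, omega = 1)
  opt <- stats::optimize(function(lw) {
    eig <- codon_q_eigen(exp(lw))
    fit_scale(eig)$objective
  }, log(c(1e-3, 10)), maximum = TRUE, tol = 1e-3)
  if (opt$objective > best$objective)
    best <- list(objective = opt$objective, omega = exp(opt$maximum))
  score <- 10 * (best$objective - null$objective) / log(10)
  structure(list(orf_id = orf_id, score = score,
                 scorer_id = "builtin_dnds_lrt",
                 n_species = length(ca$rows), frame = frame,
                 omega = best$omega),
            class = "coding_score")
}

#' @export
print.coding_score <- function(x, ...) {
  cat("Coding score (", x$scorer_id, ", frame ", x$frame, "): ",
      format(x$score, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Parse an external score file
#'
#' Accepts one float per line, or a two-column id<TAB>score table looked up
#' by `orf_id`.
#'
#' @param path Score file.
#' @param orf_id Identifier for two-column files.
#' @return Numeric score.
#' @export
parse_external_score <- function(path, orf_id = NULL) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty score file: ", path)
  if (grepl("\t", lines[1], fixed = TRUE)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ids <- vapply(parts, `[`, character(1), 1L)
    vals <- as.numeric(vapply(parts, `[`, character(1), 2L))
    if (is.null(orf_id)) return(vals[1])
    hit <- match(orf_id, ids)
    if (is.na(hit)) stop("orf id not in score file: ", orf_id)
    return(vals[hit])
  }
  val <- suppressWarnings(as.numeric(lines[1]))
  if (is.na(val)) stop("malformed score file: ", path)
  val
}

#' Score all six reading frames
#'
#' Each frame's sequences are re-derived from the ungapped rows (offsets
#' 0/1/2 on the forward strand, and on the reverse complement), re-threaded
#' into a fresh codon alignment, stop-stripped and scored independently.
#'
#' @param seqs Named ungapped nucleotide sequences (or a
#'   `"codon_alignment"`, whose rows are ungapped first).
#' @param fitted Tree for the builtin scorer.
#' @param reference Reference row.
#' @param orf_id Identifier.
#' @return Named list of `"coding_score"` objects for frames
#'   `+1, +2, +3, -1, -2, -3` (a frame is omitted with a warning when its
#'   alignment is empty after stripping).
#' @export
frame_scan <- function(seqs, fitted, reference = "human",
                       orf_id = NA_character_) {
  if (inherits(seqs, "codon_alignment"))
    seqs <- vapply(names(seqs$rows), function(nm) ungap_codon_row(seqs, nm),
                   character(1))
  frames <- c("+1", "+2", "+3", "-1", "-2", "-3")
  out <- list()
  for (fr in frames) {
    off <- abs(as.integer(substr(fr, 2L, 2L))) - 1L
    fs <- if (startsWith(fr, "-")) revcomp(seqs) else seqs
    fs <- stats::setNames(substring(fs, off + 1L), names(seqs))
    # keep the reference a codon multiple in every frame
    fs[reference] <- substr(fs[reference], 1L,
                            3L * (nchar(fs[reference]) %/% 3L))
    res <- tryCatch({
      ca <- build_codon_alignment(fs, reference = reference)
      coding_score(ca, fitted, orf_id = orf_id, frame = fr)
    }, error = function(e) {
      warning("frame ", fr, " skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) out[[fr]] <- res
  }
  out
}

# ---- Nei-Gojobori counting dN/dS ---------------------------------------

# expected synonymous/nonsynonymous site counts of one codon.
# Changes creating a stop codon are excluded from both numerator and
# denominator (per-position weight still 1, split over non-stop changes).
ng_sites <- function(codon) {
  gc <- genetic_code()
  sp <- strsplit(codon, "")[[1]]
  syn <- 0
  nonsyn <- 0
  for (p in 1:3) {
    alts <- setdiff(c("A", "C", "G", "T"), sp[p])
    cods <- vapply(alts, function(a) {
      x <- sp; x[p] <- a; paste(x, collapse = "")
    }, character(1))
    keep <- gc[cods] != "*"
    if (!any(keep)) next
    fs <- mean(gc[cods[keep]] == gc[codon])
    syn <- syn + fs
    nonsyn <- nonsyn + (1 - fs)
  }
  c(S = syn, N = nonsyn)
}

# synonymous/nonsynonymous differences between two codons, averaged over
# minimal mutational pathways not passing through stop codons (all pathways
# when every one hits a stop).
ng_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(Sd = 0, Nd = 0))
  gc <- genetic_code()
  s1 <- strsplit(c1, "")[[1]]; s2 <- strsplit(c2, "")[[1]]
  pos <- which(s1 != s2)
  paths <- if (length(pos) == 1L) list(pos) else permutations_of(pos)
  score_path <- function(ord) {
    cur <- s1; sd <- 0; nd <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur; nxt[p] <- s2[p]
      a1 <- gc[paste(cur, collapse = "")]
      a2 <- gc[paste(nxt, collapse = "")]
      if (a2 == "*") ok <- FALSE
      if (a1 == a2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(ok = ok, sd = sd, nd = nd)
  }
  res <- lapply(paths, score_path)
  valid <- Filter(function(r) r$ok, res)
  if (!length(valid)) valid <- res
  c(Sd = mean(vapply(valid, `[[`, numeric(1), "sd")),
    Nd = mean(vapply(valid, `[[`, numeric(1), "nd")))
}

permutations_of <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in permutations_of(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

#' Global dN/dS by pairwise Nei-Gojobori counting
#'
#' Counts synonymous/nonsynonymous sites and differences for every row pair
#' over codon columns where both rows have complete, gap-free codons, sums
#' the counts over pairs, and returns
#' `omega = (Nd / N) / (Sd / S)`. Returns `NA` with a `flag` attribute when
#' there are no synonymous differences (`"no synonymous substitutions"`) or
#' no differences at all (`"no substitutions"`). The alignment should be
#' stop-stripped first (see [strip_inframe_stops()]).
#'
#' @param ca A `"codon_alignment"`.
#' @return Numeric omega (or flagged `NA`), with attribute `counts`.
#' @export
global_dnds <- function(ca) {
  if (length(ca$rows) < 2L) stop("dN/dS requires at least 2 rows")
  cods <- codon_columns(ca)
  nms <- names(cods)
  tot <- c(S = 0, N = 0, Sd = 0, Nd = 0)
  any_diff <- FALSE
  for (i in seq_along(nms)[-length(nms)]) {
    for (j in (i + 1L):length(nms)) {
      a <- cods[[i]]; b <- cods[[j]]
      usable <- !grepl("[^ACGT]", a) & !grepl("[^ACGT]", b)
      for (k in which(usable)) {
        sa <- ng_sites(a[k]); sb <- ng_sites(b[k])
        tot["S"] <- tot["S"] + (sa["S"] + sb["S"]) / 2
        tot["N"] <- tot["N"] + (sa["N"] + sb["N"]) / 2
        d <- ng_diffs(a[k], b[k])
        tot["Sd"] <- tot["Sd"] + d["Sd"]
        tot["Nd"] <- tot["Nd"] + d["Nd"]
        if (sum(d) > 0) any_diff <- TRUE
      }
    }
  }
  if (!any_diff) {
    out <- NA_real_
    attr(out, "flag") <- "no substitutions"
    attr(out, "counts") <- tot
    return(out)
  }
  if (tot["Sd"] == 0) {
    out <- NA_real_
    attr(out, "flag") <- "no synonymous substitutions"
    attr(out, "counts") <- tot
    return(out)
  }
  out <- (tot[["Nd"]] / tot[["N"]]) / (tot[["Sd"]] / tot[["S"]])
  attr(out, "counts") <- tot
  out
}
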