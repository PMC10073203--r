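#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and RNA `U` is normalised to `T`. Ambiguity codes
#' other than `N` are rejected; `N` is treated as missing data downstream.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- names(set)
  # keep only the identifier token, as aligners do
  ids <- vapply(strsplit(ids, "[ \t]"), `[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id: ", dup[1])
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  if (any(!nzchar(seqs)))
    stop("empty FASTA record: ", ids[!nzchar(seqs)][1])
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad))
    stop("unsupported characters (only A/C/G/T/N/- allowed) in record: ",
         ids[bad][1])
  names(seqs) <- ids
  seqs
}

#' Write a named character vector as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a tab-separated expression table
#'
#' Expected columns: `orf_id`, `species`, `tissue`, `tpm` (header required,
#' extra columns ignored). Duplicate (orf, species, tissue) triples keep the
#' maximum TPM with a warning, matching how overlapping-transcript expression
#' values are assigned. Missing triples mean "not sampled", not zero.
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with columns orf_id, species, tissue, tpm.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("orf_id", "species", "tissue", "tpm")
  if (!all(need %in% names(df)))
    stop("expression table must have columns: ", paste(need, collapse = ", "))
  df <- df[need]
  if (!is.numeric(df$tpm)) {
    suppressWarnings(tpm <- as.numeric(df$tpm))
    if (anyNA(tpm)) stop("non-numeric tpm value in expression table")
    df$tpm <- tpm
  }
  if (anyNA(df$tpm)) stop("non-numeric tpm value in expression table")
  if (any(df$tpm < 0)) stop("negative TPM value in expression table")
  key <- paste(df$orf_id, df$species, df$tissue, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate (orf, species, tissue) triples: keeping maximum TPM")
    df <- do.call(rbind, lapply(split(df, key), function(g) {
      g[which.max(g$tpm), , drop = FALSE]
    }))
  }
  rownames(df) <- NULL
  df[order(df$orf_id, df$species, df$tissue), , drop = FALSE]
}
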