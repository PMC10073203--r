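#' Genomic interval constructor (0-based, half-open)
#'
#' @param chrom Chromosome/sequence identifier(s).
#' @param start 0-based start(s).
#' @param end End(s), exclusive.
#' @param strand `"+"` or `"-"`.
#' @param name Optional feature name(s).
#' @return `data.frame` with class `"genomic_interval"` rows.
#' @export
genomic_interval <- function(chrom, start, end, strand = "+", name = NA_character_) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end))) stop("non-integer coordinates")
  if (any(start < 0L) || any(start >= end))
    stop("intervals require 0 <= start < end")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   strand = strand, name = as.character(name),
                   stringsAsFactors = FALSE)
  class(df) <- c("genomic_interval", "data.frame")
  df
}

#' Read ORF exons from a BED file
#'
#' BED6 (or BED4+); the name field carries the ORF id. Coordinates stay
#' 0-based half-open.
#'
#' @param path Path to a BED file.
#' @return A `"genomic_interval"` data frame, in file order.
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 4L) stop("BED file needs at least 4 columns (name required)")
  strand <- if (ncol(df) >= 6L) df[[6]] else "+"
  genomic_interval(df[[1]], df[[2]], df[[3]], strand = strand, name = df[[4]])
}

#' Parse MAF alignment blocks
#'
#' Reads the standard multiple-alignment format: blocks introduced by an
#' `a` line, species rows on `s` lines carrying
#' `src start size strand srcSize text`. MAF stores start/size on the source
#' strand; the forward-strand interval of a `-` row is
#' `srcSize - start - size .. srcSize - start`.
#'
#' @param path Path to a MAF file.
#' @return List of blocks. Each block is a list with element `rows`, a
#'   `data.frame` with columns src, species, start, size, strand, src_size,
#'   fwd_start, fwd_end, text. `species` is the part of `src` before the
#'   first `.` (whole `src` when there is no dot).
#' @export
read_maf_blocks <- function(path) {
  lines <- readLines(path, warn = FALSE)
  blocks <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur) || nrow(cur) == 0L) return(NULL)
    if (length(unique(nchar(cur$text))) != 1L)
      stop("inconsistent row lengths within a MAF block")
    list(rows = cur)
  }
  for (ln in lines) {
    if (startsWith(ln, "a")) {
      b <- flush(cur)
      if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
      cur <- data.frame(src = character(), species = character(),
                        start = integer(), size = integer(),
                        strand = character(), src_size = integer(),
                        fwd_start = integer(), fwd_end = integer(),
                        text = character(), stringsAsFactors = FALSE)
    } else if (startsWith(ln, "s")) {
      if (is.null(cur)) stop("MAF 's' line before any 'a' line")
      f <- strsplit(trimws(ln), "[ \t]+")[[1]]
      if (length(f) < 7L) stop("truncated MAF 's' line: ", ln)
      src <- f[2]
      start <- as.integer(f[3]); size <- as.integer(f[4])
      strand <- f[5]; src_size <- as.integer(f[6]); text <- toupper(f[7])
      if (is.na(start) || is.na(size) || is.na(src_size))
        stop("malformed MAF coordinates: ", ln)
      ungapped <- nchar(gsub("-", "", text, fixed = TRUE))
      if (ungapped != size)
        stop("MAF row size does not match ungapped text: ", src)
      if (strand == "+") {
        fs <- start; fe <- start + size
      } else if (strand == "-") {
        fs <- src_size - start - size; fe <- src_size - start
      } else stop("bad MAF strand: ", strand)
      cur <- rbind(cur, data.frame(
        src = src, species = sub("\\..*$", "", src),
        start = start, size = size, strand = strand, src_size = src_size,
        fwd_start = fs, fwd_end = fe, text = text, stringsAsFactors = FALSE))
    }
    # i/e/q and comment lines are ignored
  }
  b <- flush(cur)
  if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
  if (!length(blocks)) stop("no alignment blocks found in ", path)
  blocks
}

#' Write MAF alignment blocks
#'
#' Inverse of [read_maf_blocks()] for blocks produced by this package (used by
#' the fixture-bundle writer).
#'
#' @param blocks List of blocks as returned by [read_maf_blocks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maf_blocks <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (b in blocks) {
    writeLines("a score=0", con)
    r <- b$rows
    for (i in seq_len(nrow(r))) {
      writeLines(sprintf("s %s %d %d %s %d %s", r$src[i], r$start[i],
                         r$size[i], r$strand[i], r$src_size[i], r$text[i]),
                 con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read exon records from a GTF file
#'
#' Minimal reader for the 9-column GTF dialect written by
#' [write_fixture_bundle()] and by common annotation sources: keeps `exon`
#' rows, extracts `transcript_id`, and converts the 1-based closed
#' coordinates to the package-wide 0-based half-open convention.
#'
#' @param path Path to a GTF file.
#' @return `data.frame` with columns seqname, start, end, strand,
#'   transcript_id (start 0-based).
#' @export
read_gtf_exons <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          quote = "", stringsAsFactors = FALSE)
  if (ncol(df) < 9L) stop("GTF requires 9 tab-separated columns")
  df <- df[df[[3]] == "exon", , drop = FALSE]
  tid <- sub('.*transcript_id "([^"]+)".*', "\\1", df[[9]])
  out <- data.frame(seqname = df[[1]], start = as.integer(df[[4]]) - 1L,
                    end = as.integer(df[[5]]), strand = df[[7]],
                    transcript_id = tid, stringsAsFactors = FALSE)
  has_sp <- grepl('species "', df[[9]], fixed = TRUE)
  if (any(has_sp)) {
    out$species <- NA_character_
    out$species[has_sp] <- sub('.*species "([^"]+)".*', "\\1",
                               df[[9]][has_sp])
  }
  out
}
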