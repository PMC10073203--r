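#' Extract the orthologous sequence of one ORF exon from MAF blocks
#'
#' For every species with rows aligned to the human exon, returns the
#' ungapped orthologous nucleotides in human coordinate order. Insertions
#' relative to human inside the exon span are retained (they are genuine
#' sequence of the region). Rows stored on the `-` strand are
#' reverse-complemented, and exons on the `-` human coding strand are
#' returned on the coding strand.
#'
#' When a species has more than one row overlapping the same exon portion
#' (paralogous alignments), the row with the longest aligned span wins and
#' the conflict is reported via `message()`.
#'
#' @param maf_blocks Blocks from [read_maf_blocks()].
#' @param exon One-row [genomic_interval()] of the human exon.
#' @param species_list Optional character vector restricting output species.
#' @param human Human species name as it appears in MAF `src` fields.
#' @return Named list, species -> list(seq = character, provenance =
#'   data.frame(exon_chrom, fwd_start, fwd_end, strand, coverage)). Empty
#'   list (with a warning) when the exon overlaps no block.
#' @export
extract_exon_orthologs <- function(maf_blocks, exon, species_list = NULL,
                                   human = "human") {
  stopifnot(nrow(exon) == 1L)
  pieces <- list()   # species -> list of list(hstart, seq, prov, span)
  for (b in maf_blocks) {
    rows <- b$rows
    h <- which(rows$species == human & rows$src == paste0(human, ".", exon$chrom) |
               rows$species == human & rows$src == human)
    if (!length(h)) next
    h <- h[1]
    if (rows$strand[h] != "+")
      stop("human MAF rows must be stored on the '+' strand")
    ov_start <- max(exon$start, rows$fwd_start[h])
    ov_end <- min(exon$end, rows$fwd_end[h])
    if (ov_start >= ov_end) next
    htext <- strsplit(rows$text[h], "")[[1]]
    hpos <- rep(NA_integer_, length(htext))
    hpos[htext != "-"] <- seq(rows$fwd_start[h], length.out = rows$size[h])
    in_window <- !is.na(hpos) & hpos >= ov_start & hpos < ov_end
    c1 <- which(in_window)[1]
    c2 <- max(which(in_window))
    cols <- c1:c2
    # resolve duplicate species rows: longest aligned span in the window wins
    sp_rows <- split(seq_len(nrow(rows)), rows$species)
    for (sp in names(sp_rows)) {
      if (sp == human && length(sp_rows[[sp]]) > 1L)
        sp_rows[[sp]] <- h
      idxs <- sp_rows[[sp]]
      if (length(idxs) > 1L) {
        spans <- vapply(idxs, function(i) {
          nchar(gsub("-", "", substr(rows$text[i], c1, c2), fixed = TRUE))
        }, integer(1))
        message("paralogous MAF rows for species '", sp,
                "': keeping the longest aligned span")
        idxs <- idxs[which.max(spans)]
        sp_rows[[sp]] <- idxs
      }
    }
    for (sp in names(sp_rows)) {
      if (!is.null(species_list) && !sp %in% union(species_list, human)) next
      i <- sp_rows[[sp]]
      piece <- gsub("-", "", paste(strsplit(rows$text[i], "")[[1]][cols],
                                   collapse = ""), fixed = TRUE)
      if (!nzchar(piece)) next
      if (rows$strand[i] == "-") piece <- revcomp(piece)
      pieces[[sp]] <- c(pieces[[sp]], list(list(
        hstart = ov_start, seq = piece,
        fwd_start = rows$fwd_start[i], fwd_end = rows$fwd_end[i],
        strand = rows$strand[i],
        covered = sum(in_window))))
    }
  }
  if (!length(pieces)) {
    warning("exon ", exon$chrom, ":", exon$start, "-", exon$end,
            " overlaps no alignment block")
    return(list())
  }
  exon_len <- exon$end - exon$start
  out <- lapply(pieces, function(ps) {
    ps <- ps[order(vapply(ps, `[[`, numeric(1), "hstart"))]
    seq <- paste(vapply(ps, `[[`, character(1), "seq"), collapse = "")
    if (exon$strand == "-") seq <- revcomp(seq)
    prov <- data.frame(
      exon_chrom = exon$chrom,
      fwd_start = vapply(ps, `[[`, numeric(1), "fwd_start"),
      fwd_end = vapply(ps, `[[`, numeric(1), "fwd_end"),
      strand = vapply(ps, `[[`, character(1), "strand"),
      coverage = sum(vapply(ps, `[[`, numeric(1), "covered")) / exon_len,
      stringsAsFactors = FALSE)
    list(seq = seq, provenance = prov)
  })
  out
}

#' Stitch per-exon orthologous pieces into one region per species
#'
#' Exon pieces are concatenated in human exon order. Species missing an exon
#' entirely keep the exons they have; the gap is recorded in the provenance
#' table. The human species must be present in every exon map since it
#' defines the region.
#'
#' @param exon_maps List (one per exon, in ORF order) of maps from
#'   [extract_exon_orthologs()].
#' @param orf_id ORF identifier.
#' @param human Human species name.
#' @param min_other_species Minimum number of non-human species for the
#'   region to be usable downstream (flagged, not enforced). Default 4.
#' @return An `"ortho_region_set"`: list with orf_id, human_orf_seq, regions
#'   (named character), provenance (data.frame with exon_index and species),
#'   below_species_minimum flag.
#' @export
stitch <- function(exon_maps, orf_id, human = "human", min_other_species = 4L) {
  if (!length(exon_maps)) stop("no exon maps to stitch")
  for (k in seq_along(exon_maps)) {
    if (!human %in% names(exon_maps[[k]]))
      stop("human missing from exon map ", k, "; human defines the region")
  }
  species <- unique(unlist(lapply(exon_maps, names)))
  regions <- stats::setNames(character(length(species)), species)
  prov <- list()
  for (sp in species) {
    for (k in seq_along(exon_maps)) {
      entry <- exon_maps[[k]][[sp]]
      if (is.null(entry)) {
        prov[[length(prov) + 1L]] <- data.frame(
          species = sp, exon_index = k, fwd_start = NA_real_,
          fwd_end = NA_real_, strand = NA_character_, coverage = 0,
          stringsAsFactors = FALSE)
        next
      }
      regions[sp] <- paste0(regions[sp], entry$seq)
      p <- entry$provenance
      prov[[length(prov) + 1L]] <- data.frame(
        species = sp, exon_index = k,
        fwd_start = p$fwd_start[1], fwd_end = p$fwd_end[nrow(p)],
        strand = p$strand[1], coverage = p$coverage[1],
        stringsAsFactors = FALSE)
    }
  }
  regions <- regions[nzchar(regions)]
  n_other <- sum(names(regions) != human)
  structure(list(
    orf_id = orf_id,
    human_orf_seq = regions[[human]],
    regions = regions,
    provenance = do.call(rbind, prov),
    below_species_minimum = n_other < min_other_species
  ), class = "ortho_region_set")
}

#' @export
print.ortho_region_set <- function(x, ...) {
  cat("Orthologous region set: ", x$orf_id, "\n", sep = "")
  cat("  human ORF length: ", nchar(x$human_orf_seq), " nt\n", sep = "")
  cat("  species (", length(x$regions), "): ",
      paste(names(x$regions), collapse = ", "), "\n", sep = "")
  if (x$below_species_minimum)
    cat("  WARNING: below the minimum non-human species count\n")
  invisible(x)
}

#' Reverse complement of a nucleotide string
#' @noRd
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}
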