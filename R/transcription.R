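# Dating transcriptional activation from three evidence channels and Dollo
# parsimony.

#' Expression/transcription evidence container
#'
#' @param orf_id ORF identifier.
#' @param tpm data.frame(species, tissue, tpm); missing (species, tissue)
#'   pairs mean "not sampled", not zero.
#' @param annotation_overlap Named numeric: per species, the maximum exon
#'   overlap fraction with an annotated transcript.
#' @param sequence_match data.frame(species, query_coverage, evalue): best
#'   transcript-database match per species.
#' @return An `"expression_evidence"` list.
#' @export
expression_evidence <- function(orf_id, tpm = NULL,
                                annotation_overlap = NULL,
                                sequence_match = NULL) {
  if (is.null(tpm))
    tpm <- data.frame(species = character(), tissue = character(),
                      tpm = numeric(), stringsAsFactors = FALSE)
  stopifnot(all(c("species", "tissue", "tpm") %in% names(tpm)))
  if (any(tpm$tpm < 0)) stop("negative TPM")
  if (!is.null(annotation_overlap)) {
    if (is.null(names(annotation_overlap)))
      stop("annotation_overlap must be named by species")
    if (any(annotation_overlap < 0 | annotation_overlap > 1))
      stop("overlap fractions must be in [0, 1]")
  }
  if (!is.null(sequence_match))
    stopifnot(all(c("species", "query_coverage", "evalue") %in%
                  names(sequence_match)))
  structure(list(orf_id = orf_id, tpm = tpm,
                 annotation_overlap = annotation_overlap,
                 sequence_match = sequence_match),
            class = "expression_evidence")
}

#' Species present by annotated-transcript overlap
#'
#' A species is present when its best exon overlap fraction with an
#' annotated transcript reaches the cutoff (default 80%).
#'
#' @param evidence An [expression_evidence()].
#' @param config [pipeline_config()].
#' @return Character vector of species.
#' @export
presence_from_annotation <- function(evidence, config = pipeline_config()) {
  ov <- evidence$annotation_overlap
  if (is.null(ov) || !length(ov)) return(character(0))
  names(ov)[ov >= config$annotation_overlap_fraction]
}

#' Species present by transcript sequence similarity
#'
#' A species is present when the human ORF matches any of its transcripts
#' with at least the required query coverage and at most the E-value cutoff
#' (regardless of genomic position).
#'
#' @param evidence An [expression_evidence()].
#' @param config [pipeline_config()].
#' @return Character vector of species.
#' @export
presence_from_sequence <- function(evidence, config = pipeline_config()) {
  sm <- evidence$sequence_match
  if (is.null(sm) || !nrow(sm)) return(character(0))
  ok <- sm$query_coverage >= config$seq_match_min_coverage &
    sm$evalue <= config$seq_match_max_evalue
  unique(sm$species[ok])
}

max_tpm_by_species <- function(tpm) {
  if (!nrow(tpm)) return(stats::setNames(numeric(0), character(0)))
  tapply(tpm$tpm, tpm$species, max)
}

# count of species descending from the MRCA of the presence set (plus human)
# that are sampled but not present
absent_descendants <- function(tree, present, sampled, human) {
  mrca_lab <- dollo_age(tree, present, human)
  clade <- clade_leaves(tree, mrca_lab, human)
  length(setdiff(intersect(clade, sampled), union(present, human)))
}

#' Species present by expression, with threshold escalation
#'
#' Presence at threshold t is any-tissue TPM >= t. The base threshold is
#' 0.1 TPM; it escalates to 1 TPM when the 0.1 pattern is sparse and
#' phylogenetically inconsistent: escalation requires (a) that the stricter
#' threshold reduce the number of sampled-but-silent species descending
#' from the presence MRCA by at least 50%, and (b) that fewer than 80% of
#' the present species share one expressed tissue (a shared tissue argues
#' the sparse pattern is a genuinely conserved, tissue-specific transcript).
#'
#' @param evidence An [expression_evidence()].
#' @param tree Labelled species tree (for MRCA computations).
#' @param config [pipeline_config()].
#' @param human Focal leaf name.
#' @return List: species (character), threshold_used (0.1 or 1), escalated.
#' @export
presence_from_expression <- function(evidence, tree,
                                     config = pipeline_config(),
                                     human = "human") {
  tpm <- evidence$tpm
  mx <- max_tpm_by_species(tpm)
  sampled <- unique(tpm$species)
  p_low <- names(mx)[mx >= config$tpm_low]
  if (!length(p_low))
    return(list(species = character(0), threshold_used = config$tpm_low,
                escalated = FALSE))
  a_low <- absent_descendants(tree, p_low, sampled, human)
  escalated <- FALSE
  species <- p_low
  threshold <- config$tpm_low
  if (a_low > 0) {
    p_high <- names(mx)[mx >= config$tpm_high]
    a_high <- if (length(p_high))
      absent_descendants(tree, p_high, sampled, human) else 0L
    reduces <- a_high <= (1 - config$escalation_absence_reduction) * a_low
    # largest single-tissue sharing fraction among species present at 0.1
    sub <- tpm[tpm$species %in% p_low & tpm$tpm >= config$tpm_low, ,
               drop = FALSE]
    share <- if (nrow(sub))
      max(tapply(sub$species, sub$tissue,
                 function(s) length(unique(s)))) / length(p_low)
    else 0
    if (reduces && share < config$escalation_shared_tissue_fraction) {
      escalated <- TRUE
      species <- p_high
      threshold <- config$tpm_high
    }
  }
  list(species = species, threshold_used = threshold, escalated = escalated)
}

#' Date transcriptional origin from all evidence channels
#'
#' Presence is the union of the annotation, sequence-similarity and
#' expression channels; the human leaf is unconditionally present (its ORF
#' is transcribed by construction). The origin is the Dollo-parsimony MRCA
#' of the presence set. Missing species contribute neither presence nor
#' absence, so sampling gaps can only make the estimate younger (a lower
#' bound on the true age).
#'
#' @param evidence An [expression_evidence()].
#' @param tree Labelled species tree.
#' @param config [pipeline_config()].
#' @param human Focal leaf name.
#' @return A `"transcription_origin"`: list(orf_id, origin_node,
#'   present_species, tpm_threshold_used, escalated, channels).
#' @export
date_transcription <- function(evidence, tree, config = pipeline_config(),
                               human = "human") {
  ann <- presence_from_annotation(evidence, config)
  seqm <- presence_from_sequence(evidence, config)
  expr <- presence_from_expression(evidence, tree, config, human)
  present <- Reduce(union, list(ann, seqm, expr$species, human))
  channels <- lapply(stats::setNames(present, present), function(sp) {
    ch <- character(0)
    if (sp %in% ann) ch <- c(ch, "annotation")
    if (sp %in% seqm) ch <- c(ch, "sequence")
    if (sp %in% expr$species) ch <- c(ch, "expression")
    ch
  })
  structure(list(orf_id = evidence$orf_id,
                 origin_node = dollo_age(tree, present, human),
                 present_species = sort(present),
                 tpm_threshold_used = expr$threshold_used,
                 escalated = expr$escalated,
                 channels = channels),
            class = "transcription_origin")
}

#' @export
print.transcription_origin <- function(x, ...) {
  cat("Transcription of ", x$orf_id, ": origin at ", x$origin_node,
      " (", length(x$present_species), " species present, TPM cutoff ",
      x$tpm_threshold_used, if (x$escalated) ", escalated" else "",
      ")\n", sep = "")
  invisible(x)
}

#' Annotation overlap fractions from a fixture GTF
#'
#' Computes, per species, the maximum fraction of the orthologous region
#' covered by an annotated exon in the bundle GTF (exon rows carrying a
#' `species` attribute, as written by [write_fixture_bundle()]).
#'
#' @param gtf_path Path to the GTF.
#' @param region_start,region_end 0-based half-open region coordinates per
#'   species; scalars are recycled.
#' @param species Character vector of species to evaluate.
#' @return Named numeric vector of overlap fractions.
#' @export
annotation_overlap_from_gtf <- function(gtf_path, region_start, region_end,
                                        species) {
  ex <- read_gtf_exons(gtf_path)
  if (!"species" %in% names(ex))
    stop("GTF exons carry no species attribute")
  region_start <- rep_len(region_start, length(species))
  region_end <- rep_len(region_end, length(species))
  out <- stats::setNames(numeric(length(species)), species)
  for (i in seq_along(species)) {
    rows <- ex[ex$species == species[i], , drop = FALSE]
    if (!nrow(rows)) next
    ov <- pmax(0, pmin(rows$end, region_end[i]) -
                  pmax(rows$start, region_start[i]))
    out[i] <- max(ov) / (region_end[i] - region_start[i])
  }
  out
}
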