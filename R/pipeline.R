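#' Run the full origin-dating pipeline on one ORF
#'
#' Convenience driver over the stage functions: align the orthologous
#' region on the species tree, fit branch lengths, reconstruct the
#' human-lineage ancestors, call intactness at the configured cutoff (plus
#' the 0.5/0.7/0.8 sensitivity alternates), date the ORF origin, date
#' transcription from the evidence channels, and combine the two into the
#' putative origin.
#'
#' @param sequences Named per-species nucleotide sequences of the
#'   orthologous region (including the human ORF).
#' @param tree Labelled species tree covering the sequence names.
#' @param evidence An [expression_evidence()] for transcription dating.
#' @param config [pipeline_config()].
#' @param orf_id Identifier.
#' @param human Focal leaf name.
#' @param score_coding Compute the builtin coding score on the
#'   descendant-only alignment (slower; needed for the combination
#'   exception). Default FALSE.
#' @param outgroup_hits Optional outgroup proteome hit table (see
#'   [apply_outgroup_homology()]).
#' @return List: msa, fitted, ancestors, calls, orf_origin,
#'   origin_by_cutoff, txn_origin, assignment, properties.
#' @export
run_pipeline <- function(sequences, tree, evidence = NULL,
                         config = pipeline_config(),
                         orf_id = "orf", human = "human",
                         score_coding = FALSE, outgroup_hits = NULL) {
  if (!human %in% names(sequences))
    stop("sequences must include the '", human, "' row")
  tr <- tree
  if (length(setdiff(tr$tip.label, names(sequences))))
    tr <- prune_tree(tr, intersect(tr$tip.label, names(sequences)), human)
  path <- ancestor_path(tr, human)
  msa <- align_regions(sequences[tr$tip.label], guide_tree = tr)
  fitted <- fit_branch_lengths(msa, tr, config$substitution_model)
  ancestors <- reconstruct_ancestors(msa, fitted, targets = path,
                                     human = human)
  human_len <- nchar(sequences[[human]])
  calls_at <- function(cutoff) {
    cfg <- config; cfg$intact_ratio_cutoff <- cutoff
    lapply(ancestors, function(a)
      call_intactness(a$sequence, human_len, cfg, node = a$node))
  }
  calls <- calls_at(config$intact_ratio_cutoff)
  orf_origin <- date_orf_origin(calls, orf_id, config, human)
  if (!is.null(outgroup_hits))
    orf_origin <- apply_outgroup_homology(orf_origin, outgroup_hits, tr,
                                          config, human)
  origin_by_cutoff <- vapply(c(0.5, 0.7, 0.8), function(co) {
    cfg <- config; cfg$intact_ratio_cutoff <- co
    suppressWarnings(suppressMessages(
      date_orf_origin(calls_at(co), orf_id, cfg, human)$origin_node))
  }, character(1))
  names(origin_by_cutoff) <- c("0.5", "0.7", "0.8")

  txn_origin <- if (!is.null(evidence))
    date_transcription(evidence, tr, config, human)
  else structure(list(orf_id = orf_id, origin_node = human,
                      present_species = human,
                      tpm_threshold_used = config$tpm_low,
                      escalated = FALSE, channels = list()),
                 class = "transcription_origin")

  cscore <- NA_real_
  if (score_coding) {
    desc <- intersect(clade_leaves(tr, orf_origin$origin_node, human),
                      names(sequences))
    if (length(desc) >= 2L) {
      ca <- build_codon_alignment(sequences[desc], reference = human,
                                  remove_ref_gaps = TRUE)
      cscore <- tryCatch(
        coding_score(ca, fitted, orf_id = orf_id)$score,
        error = function(e) NA_real_)
    }
  }
  assignment <- combine_origin(orf_origin, txn_origin, tr, cscore, config,
                               human)
  properties <- compute_properties(sequences[[human]], orf_id = orf_id)
  list(msa = msa, fitted = fitted, ancestors = ancestors, calls = calls,
       orf_origin = orf_origin, origin_by_cutoff = origin_by_cutoff,
       txn_origin = txn_origin, assignment = assignment,
       properties = properties)
}

#' Run the pipeline on a fixture-bundle directory
#'
#' Reads the files written by [write_fixture_bundle()] and runs
#' [run_pipeline()] on them.
#'
#' @param dir Bundle directory.
#' @param config [pipeline_config()].
#' @param human Focal leaf name.
#' @param ... Passed to [run_pipeline()].
#' @return The [run_pipeline()] result, plus `truth` (data.frame).
#' @export
run_pipeline_dir <- function(dir, config = pipeline_config(),
                             human = "human", ...) {
  seqs <- read_fasta(file.path(dir, "regions.fa"))
  tree <- read_newick(file.path(dir, "tree.nwk"), human)
  truth <- utils::read.delim(file.path(dir, "truth.tsv"),
                             stringsAsFactors = FALSE)
  expr <- read_expression_table(file.path(dir, "expression.tsv"))
  orf_id <- truth$orf_id[1]
  annot <- NULL
  gtf <- file.path(dir, "transcripts.gtf")
  if (file.exists(gtf) && length(readLines(gtf, warn = FALSE))) {
    starts <- ifelse(tree$tip.label == human, 100L, 0L)
    ends <- starts + nchar(seqs[tree$tip.label])
    annot <- annotation_overlap_from_gtf(gtf, starts, ends, tree$tip.label)
  }
  evidence <- expression_evidence(
    orf_id, tpm = expr[expr$orf_id == orf_id, c("species", "tissue", "tpm")],
    annotation_overlap = annot)
  res <- run_pipeline(seqs, tree, evidence, config, orf_id, human, ...)
  res$truth <- truth
  res
}
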