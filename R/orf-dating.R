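# Dating ORF formation from reconstructed ancestral sequences.

#' Intactness call for one reconstructed ancestor
#'
#' The reading frame is the forward strand from position 1 of the
#' reconstructed sequence (the frame of the human microprotein); no start
#' codon is required. The ancestral ORF length is the number of nucleotides
#' before the first in-frame stop (TAA/TAG/TGA), or the full length when
#' there is none. The ratio denominator is the ancestral length, replaced by
#' the human ORF length when the ancestor is longer than the human ORF.
#' Ancestors shorter than half the human ORF are too short to judge and are
#' flagged `ignored_short` (they are treated as intact by the origin scan
#' but should not anchor ages).
#'
#' @param ancestral_seq Reconstructed ancestral sequence (gaps removed).
#' @param human_orf_len Human ORF length in nt (multiple of 3).
#' @param config [pipeline_config()].
#' @param node Optional ancestor label carried into the call.
#' @return An `"intactness_call"`: list(node, ratio, status,
#'   first_stop_codon_index). `ratio` is `NA` only for `ignored_short`.
#' @export
call_intactness <- function(ancestral_seq, human_orf_len,
                            config = pipeline_config(), node = NA_character_) {
  if (human_orf_len <= 0 || human_orf_len %% 3L != 0L)
    stop("human_orf_len must be a positive multiple of 3")
  seq <- gsub("-", "", toupper(ancestral_seq), fixed = TRUE)
  len <- nchar(seq)
  if (len < config$short_ancestor_fraction * human_orf_len) {
    return(structure(list(node = node, ratio = NA_real_,
                          status = "ignored_short",
                          first_stop_codon_index = NA_integer_),
                     class = "intactness_call"))
  }
  stop_at <- first_stop_pos(seq)
  orf_len <- if (is.na(stop_at)) len else stop_at - 1L
  denom <- if (len > human_orf_len) human_orf_len else len
  ratio <- min(orf_len / denom, 1)
  status <- if (ratio >= config$intact_ratio_cutoff) "intact" else "disrupted"
  structure(list(node = node, ratio = ratio, status = status,
                 first_stop_codon_index = stop_at),
            class = "intactness_call")
}

#' @export
print.intactness_call <- function(x, ...) {
  cat(sprintf("%s: %s (ratio %s)\n",
              ifelse(is.na(x$node), "<ancestor>", x$node), x$status,
              ifelse(is.na(x$ratio), "NA", format(x$ratio, digits = 3))))
  invisible(x)
}

#' Date the origin of an ORF from ordered intactness calls
#'
#' Calls must be ordered from the most recent ancestor to the most ancient.
#' The origin is the most ancient ancestor with an intact ORF
#' (`ignored_short` counts as intact for the scan). The mode is `de_novo`
#' when at least one disrupted ancestor is strictly more ancient than the
#' origin — positive evidence that the ORF formed out of non-ORF sequence —
#' and `undetermined` otherwise (the scan reached the root, or no older
#' ancestor could be reconstructed).
#'
#' @param calls List of `"intactness_call"` objects, recent to ancient.
#' @param orf_id ORF identifier.
#' @param config [pipeline_config()].
#' @param human Label used for the degenerate origin at the human branch.
#' @return An `"orf_origin"`: list(orf_id, origin_node, mode, cutoff_used,
#'   calls, origin_on_short_ancestor, non_monotone, reassigned_by_homology).
#' @export
date_orf_origin <- function(calls, orf_id = NA_character_,
                            config = pipeline_config(), human = "human") {
  if (!length(calls)) stop("at least one intactness call is required")
  status <- vapply(calls, `[[`, character(1), "status")
  nodes <- vapply(calls, function(x) as.character(x$node), character(1))
  intactish <- status %in% c("intact", "ignored_short")
  if (!any(intactish)) {
    warning("no intact ancestor: origin placed on the human branch")
    return(structure(list(orf_id = orf_id, origin_node = human,
                          mode = "undetermined",
                          cutoff_used = config$intact_ratio_cutoff,
                          calls = calls, origin_on_short_ancestor = FALSE,
                          non_monotone = any(status == "intact"),
                          reassigned_by_homology = FALSE),
                     class = "orf_origin"))
  }
  origin_idx <- max(which(intactish))
  origin_node <- nodes[origin_idx]
  de_novo <- any(status[seq_along(status) > origin_idx] == "disrupted")
  # an intact-disrupted-intact pattern means the literal most-ancient-intact
  # rule bridges a disruption; flag it for review
  non_monotone <- any(status[seq_len(origin_idx)] == "disrupted")
  on_short <- status[origin_idx] == "ignored_short"
  if (on_short)
    message("origin for ", orf_id, " lands on a short (ignored) ancestor")
  structure(list(orf_id = orf_id, origin_node = origin_node,
                 mode = if (de_novo) "de_novo" else "undetermined",
                 cutoff_used = config$intact_ratio_cutoff,
                 calls = calls, origin_on_short_ancestor = on_short,
                 non_monotone = non_monotone,
                 reassigned_by_homology = FALSE),
            class = "orf_origin")
}

#' @export
print.orf_origin <- function(x, ...) {
  cat("ORF ", x$orf_id, ": origin at ", x$origin_node, " (", x$mode,
      "), cutoff ", x$cutoff_used, "\n", sep = "")
  if (x$reassigned_by_homology) cat("  reassigned by outgroup homology\n")
  invisible(x)
}

#' Reassign an ORF origin using outgroup proteome hits
#'
#' Protein-similarity hits in species that diverged before the current
#' origin node are evidence that the ORF (or a homolog) is older than
#' reconstruction suggests. Significant hits expand the species set; when
#' their MRCA is more ancient than the current origin, the origin moves
#' there and the de novo status is removed (mode becomes undetermined).
#'
#' @param origin An `"orf_origin"`.
#' @param hit_table data.frame with columns species, evalue, identity,
#'   query_coverage (identity/coverage as fractions).
#' @param tree Labelled species tree.
#' @param config [pipeline_config()].
#' @param human Focal leaf name.
#' @return The (possibly reassigned) `"orf_origin"`.
#' @export
apply_outgroup_homology <- function(origin, hit_table, tree,
                                    config = pipeline_config(),
                                    human = "human") {
  if (is.null(hit_table) || !nrow(hit_table)) return(origin)
  need <- c("species", "evalue", "identity", "query_coverage")
  if (!all(need %in% names(hit_table)))
    stop("hit table must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(hit_table$species, tree$tip.label)
  if (length(bad)) stop("hit species not in tree: ",
                        paste(bad, collapse = ", "))
  sig <- hit_table$evalue <= config$outgroup_hit_max_evalue &
    hit_table$identity >= config$outgroup_hit_min_identity &
    hit_table$query_coverage >= config$outgroup_hit_min_coverage
  if (!any(sig)) return(origin)
  current <- clade_leaves(tree, origin$origin_node, human)
  expanded <- union(current, hit_table$species[sig])
  new_node <- dollo_age(tree, expanded, human)
  path <- ancestor_path(tree, human)
  if (node_age(new_node, path, human) >
      node_age(origin$origin_node, path, human)) {
    origin$origin_node <- new_node
    origin$mode <- "undetermined"
    origin$reassigned_by_homology <- TRUE
  }
  origin
}

#' Flag human-proteome paralogs of a candidate de novo ORF
#'
#' Returns hits against the annotated human proteome passing the
#' significance thresholds, excluding the trivial self-match (100% identity
#' over the full query). Flagged matches are for manual review; the origin
#' is not changed.
#'
#' @param human_hit_table data.frame with columns subject, evalue, identity,
#'   query_coverage.
#' @param config [pipeline_config()].
#' @return The subset of rows to review (possibly empty).
#' @export
check_self_paralogs <- function(human_hit_table,
                                config = pipeline_config()) {
  if (is.null(human_hit_table) || !nrow(human_hit_table))
    return(human_hit_table[0, , drop = FALSE])
  h <- human_hit_table
  sig <- h$evalue <= config$paralog_hit_max_evalue &
    h$identity >= config$paralog_hit_min_identity &
    h$query_coverage >= config$paralog_hit_min_coverage
  self <- h$identity >= 1 & h$query_coverage >= 1
  h[sig & !self, , drop = FALSE]
}
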