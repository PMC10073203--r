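# Combining ORF and transcription origins, sequence properties, and the
# group statistics used to compare origin-age classes.

#' Combine ORF and transcription origins into the putative origin
#'
#' A microprotein needs both an ORF and transcription, so the putative
#' origin defaults to the more recent of the two nodes. The one exception:
#' when ORF formation predates transcription evidence but the
#' descendant-only alignment carries a protein-coding signal above the
#' exception threshold, the ORF origin is used (transcript annotation in
#' other species is too incomplete to overrule a coding signal).
#'
#' @param orf_origin An `"orf_origin"` (or an ancestor label).
#' @param txn_origin A `"transcription_origin"` (or an ancestor label).
#' @param tree Labelled species tree both origins refer to.
#' @param coding_score Deciban coding score computed on the alignment of
#'   species descending from the ORF-origin node, or `NA`.
#' @param config [pipeline_config()].
#' @param human Focal leaf name.
#' @return An `"origin_assignment"`: list(orf_id, orf_origin_node, orf_mode,
#'   txn_origin_node, putative_origin_node, combination_rule,
#'   coding_score_at_orf_origin).
#' @export
combine_origin <- function(orf_origin, txn_origin, tree,
                           coding_score = NA_real_,
                           config = pipeline_config(), human = "human") {
  orf_node <- if (inherits(orf_origin, "orf_origin")) orf_origin$origin_node
              else orf_origin
  orf_mode <- if (inherits(orf_origin, "orf_origin")) orf_origin$mode
              else NA_character_
  orf_id <- if (inherits(orf_origin, "orf_origin")) orf_origin$orf_id
            else NA_character_
  txn_node <- if (inherits(txn_origin, "transcription_origin"))
    txn_origin$origin_node else txn_origin
  path <- ancestor_path(tree, human)
  a_orf <- node_age(orf_node, path, human)
  a_txn <- node_age(txn_node, path, human)
  if (!is.na(coding_score) && a_orf > a_txn &&
      coding_score > config$coding_exception_threshold) {
    put <- orf_node
    rule <- "coding_signal_exception"
  } else {
    put <- if (a_orf <= a_txn) orf_node else txn_node
    rule <- "most_recent_of_two"
  }
  structure(list(orf_id = orf_id, orf_origin_node = orf_node,
                 orf_mode = orf_mode, txn_origin_node = txn_node,
                 putative_origin_node = put, combination_rule = rule,
                 coding_score_at_orf_origin = coding_score),
            class = "origin_assignment")
}

#' @export
print.origin_assignment <- function(x, ...) {
  cat("Putative origin of ", x$orf_id, ": ", x$putative_origin_node,
      " (ORF at ", x$orf_origin_node, ", transcription at ",
      x$txn_origin_node, "; ", x$combination_rule, ")\n", sep = "")
  invisible(x)
}

AROMATIC_AA <- c("F", "W", "Y")
HYDROPHOBIC_AA <- c("A", "V", "L", "I", "M", "F", "W", "C")

#' Sequence and protein properties of an ORF
#'
#' @param orf_seq Human ORF nucleotide sequence (length a multiple of 3,
#'   intact: no internal stop before the final codon).
#' @param orf_id Identifier.
#' @param n_exons Exon count.
#' @param class_label One of `new`, `new_iso`, `upstream`, `downstream`.
#' @param coding_table,noncoding_table Optional hexamer tables; when given,
#'   the hexamer score is included.
#' @return A one-row `data.frame`: orf_id, length_nt, gc_fraction,
#'   aromatic_fraction, hydrophobic_fraction, hexamer_score, n_exons,
#'   class_label.
#' @export
compute_properties <- function(orf_seq, orf_id = NA_character_,
                               n_exons = 1L,
                               class_label = c("new", "new_iso", "upstream",
                                               "downstream"),
                               coding_table = NULL, noncoding_table = NULL) {
  class_label <- match.arg(class_label)
  s <- toupper(orf_seq)
  if (nchar(s) %% 3L != 0L) stop("ORF length must be a multiple of 3")
  aa <- strsplit(translate_orf(s), "")[[1]]
  internal <- aa[-length(aa)]
  if (any(internal == "*"))
    stop("internal stop codon: human ORFs are intact by definition")
  residues <- aa[aa != "*"]
  ch <- strsplit(s, "")[[1]]
  hx <- if (!is.null(coding_table) && !is.null(noncoding_table))
    hexamer_score(s, coding_table, noncoding_table) else NA_real_
  data.frame(orf_id = orf_id, length_nt = nchar(s),
             gc_fraction = sum(ch %in% c("G", "C")) / length(ch),
             aromatic_fraction = sum(residues %in% AROMATIC_AA) /
               length(residues),
             hydrophobic_fraction = sum(residues %in% HYDROPHOBIC_AA) /
               length(residues),
             hexamer_score = hx, n_exons = as.integer(n_exons),
             class_label = class_label, stringsAsFactors = FALSE)
}

#' Group comparisons of ORF properties
#'
#' Two-sided Wilcoxon rank-sum tests for each numeric property between two
#' groups (exact null for small tie-free samples, normal approximation with
#' continuity/tie correction otherwise), plus Spearman rank correlation of
#' each property against ordinal origin-node age when `age` is supplied.
#'
#' @param records data.frame of property records.
#' @param grouping Factor/character of group labels (2 groups, >= 2 records
#'   each).
#' @param properties Numeric property columns to test; defaults to all
#'   numeric columns except identifiers.
#' @param age Optional ordinal age per record for the correlations.
#' @return data.frame: property, wilcoxon_p, spearman_rho, spearman_p, flag.
#' @export
compare_groups <- function(records, grouping, properties = NULL,
                           age = NULL) {
  grouping <- as.factor(as.character(grouping))
  if (nlevels(grouping) != 2L) stop("exactly 2 groups are required")
  if (any(table(grouping) < 2L)) stop("each group needs at least 2 records")
  if (is.null(properties)) {
    properties <- names(records)[vapply(records, is.numeric, logical(1))]
    properties <- setdiff(properties, c("n_exons"))
  }
  out <- lapply(properties, function(p) {
    x <- records[[p]][grouping == levels(grouping)[1]]
    y <- records[[p]][grouping == levels(grouping)[2]]
    flag <- ""
    exact <- length(x) <= 20L && length(y) <= 20L &&
      !anyDuplicated(c(x, y))
    wp <- tryCatch(
      stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value,
      error = function(e) NA_real_)
    rho <- pv <- NA_real_
    if (!is.null(age)) {
      if (stats::sd(records[[p]]) == 0) {
        flag <- "constant property"
      } else {
        ct <- suppressWarnings(
          stats::cor.test(records[[p]], age, method = "spearman"))
        rho <- unname(ct$estimate); pv <- ct$p.value
      }
    }
    data.frame(property = p, wilcoxon_p = wp, spearman_rho = rho,
               spearman_p = pv, flag = flag, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Thin wrapper over the standard test with Yates continuity correction on
#' by default (the correction only ever reduces the statistic).
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @param yates Apply the continuity correction.
#' @return List: statistic, p_value, df.
#' @export
chi_square_2x2 <- function(table, yates = TRUE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("a 2x2 table is required")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal total")
  ht <- stats::chisq.test(table, correct = yates)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

#' Write pipeline report tables
#'
#' Emits a per-ORF TSV (origin nodes, mode, cutoff sensitivity, scores,
#' properties) and a JSON summary of counts per origin node per mode.
#'
#' @param results List of per-ORF result lists as produced by
#'   [run_pipeline()].
#' @param dir Output directory.
#' @return Named character vector of written paths, invisibly.
#' @export
render_report <- function(results, dir) {
  if (!length(results)) stop("no pipeline results to report")
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", dir)
  rows <- lapply(results, function(r) {
    need <- c("assignment", "origin_by_cutoff", "properties")
    miss <- setdiff(need, names(r))
    if (length(miss))
      stop("missing upstream output(s): ", paste(miss, collapse = ", "))
    a <- r$assignment
    data.frame(
      orf_id = a$orf_id,
      orf_origin_node = a$orf_origin_node,
      orf_mode = a$orf_mode,
      txn_origin_node = a$txn_origin_node,
      putative_origin_node = a$putative_origin_node,
      combination_rule = a$combination_rule,
      coding_score = a$coding_score_at_orf_origin,
      origin_cutoff_0.5 = r$origin_by_cutoff[["0.5"]],
      origin_cutoff_0.7 = r$origin_by_cutoff[["0.7"]],
      origin_cutoff_0.8 = r$origin_by_cutoff[["0.8"]],
      length_nt = r$properties$length_nt,
      gc_fraction = r$properties$gc_fraction,
      aromatic_fraction = r$properties$aromatic_fraction,
      hydrophobic_fraction = r$properties$hydrophobic_fraction,
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  paths <- c(orfs = file.path(dir, "orf_origins.tsv"),
             summary = file.path(dir, "summary.json"))
  utils::write.table(tab, paths["orfs"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  counts <- as.data.frame(table(origin = tab$putative_origin_node,
                                mode = tab$orf_mode),
                          stringsAsFactors = FALSE)
  counts <- counts[counts$Freq > 0, , drop = FALSE]
  jsonlite::write_json(
    list(n_orfs = nrow(tab), counts_per_origin_per_mode = counts),
    paths["summary"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
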