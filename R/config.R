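#' Pipeline configuration
#'
#' Bundles every numeric cutoff used across the pipeline. Defaults follow the
#' dating procedure's published operating point; all of them can be overridden
#' per call.
#'
#' @param intact_ratio_cutoff Minimum (ancestral ORF length)/(denominator)
#'   ratio for an ancestor to be called intact. Default 0.70; 0.50 and 0.80
#'   are the standard sensitivity alternates.
#' @param short_ancestor_fraction Ancestors whose reconstructed sequence is
#'   shorter than this fraction of the human ORF are ignored (treated as
#'   intact in the origin scan but flagged). Default 0.50.
#' @param annotation_overlap_fraction Minimum exon overlap fraction with an
#'   annotated transcript for the annotation presence channel. Default 0.80.
#' @param seq_match_min_coverage,seq_match_max_evalue Thresholds for the
#'   transcript sequence-similarity presence channel. Defaults 0.60 and 0.001.
#' @param tpm_low,tpm_high Expression presence thresholds in TPM. Defaults
#'   0.1 and 1.0.
#' @param escalation_absence_reduction Escalate to `tpm_high` when the count
#'   of unexplained absent descendants drops by at least this fraction.
#'   Default 0.50.
#' @param escalation_shared_tissue_fraction Do not escalate when at least this
#'   fraction of present species share one expressed tissue. Default 0.80.
#' @param outgroup_hit_max_evalue,outgroup_hit_min_identity,outgroup_hit_min_coverage
#'   Significance thresholds for outgroup proteome hits used to reassign the
#'   ORF origin node. Defaults 1e-5, 0.40, 0.50.
#' @param paralog_hit_max_evalue,paralog_hit_min_identity,paralog_hit_min_coverage
#'   Significance thresholds for human-proteome self/paralog hits. Defaults
#'   1e-5, 0.50, 0.50.
#' @param coding_call_threshold Deciban coding score at or above which an ORF
#'   is called coding. Default 41.
#' @param coding_exception_threshold Deciban score above which the
#'   coding-signal exception applies when combining origins. Default 10.
#' @param substitution_model `"JC"` or `"GTRG"` for branch-length fitting.
#' @param rng_seed Integer seed recorded in the configuration.
#' @return An object of class `"microorigin_config"` (a validated list).
#' @examples
#' cfg <- pipeline_config(intact_ratio_cutoff = 0.5)
#' cfg$intact_ratio_cutoff
#' @export
pipeline_config <- function(intact_ratio_cutoff = 0.70,
                            short_ancestor_fraction = 0.50,
                            annotation_overlap_fraction = 0.80,
                            seq_match_min_coverage = 0.60,
                            seq_match_max_evalue = 0.001,
                            tpm_low = 0.1,
                            tpm_high = 1.0,
                            escalation_absence_reduction = 0.50,
                            escalation_shared_tissue_fraction = 0.80,
                            outgroup_hit_max_evalue = 1e-5,
                            outgroup_hit_min_identity = 0.40,
                            outgroup_hit_min_coverage = 0.50,
                            paralog_hit_max_evalue = 1e-5,
                            paralog_hit_min_identity = 0.50,
                            paralog_hit_min_coverage = 0.50,
                            coding_call_threshold = 41,
                            coding_exception_threshold = 10,
                            substitution_model = c("JC", "GTRG"),
                            rng_seed = 1L) {
  substitution_model <- match.arg(substitution_model)
  cfg <- list(
    intact_ratio_cutoff = intact_ratio_cutoff,
    short_ancestor_fraction = short_ancestor_fraction,
    annotation_overlap_fraction = annotation_overlap_fraction,
    seq_match_min_coverage = seq_match_min_coverage,
    seq_match_max_evalue = seq_match_max_evalue,
    tpm_low = tpm_low,
    tpm_high = tpm_high,
    escalation_absence_reduction = escalation_absence_reduction,
    escalation_shared_tissue_fraction = escalation_shared_tissue_fraction,
    outgroup_hit_max_evalue = outgroup_hit_max_evalue,
    outgroup_hit_min_identity = outgroup_hit_min_identity,
    outgroup_hit_min_coverage = outgroup_hit_min_coverage,
    paralog_hit_max_evalue = paralog_hit_max_evalue,
    paralog_hit_min_identity = paralog_hit_min_identity,
    paralog_hit_min_coverage = paralog_hit_min_coverage,
    coding_call_threshold = coding_call_threshold,
    coding_exception_threshold = coding_exception_threshold,
    substitution_model = substitution_model,
    rng_seed = as.integer(rng_seed)
  )
  fracs <- c("intact_ratio_cutoff", "short_ancestor_fraction",
             "annotation_overlap_fraction", "seq_match_min_coverage",
             "escalation_absence_reduction",
             "escalation_shared_tissue_fraction",
             "outgroup_hit_min_identity", "outgroup_hit_min_coverage",
             "paralog_hit_min_identity", "paralog_hit_min_coverage")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("config field '%s' must be a single value in [0, 1]", f))
  }
  if (cfg$intact_ratio_cutoff <= 0)
    stop("intact_ratio_cutoff must be in (0, 1]")
  if (!(cfg$tpm_low < cfg$tpm_high))
    stop("tpm_low must be strictly less than tpm_high")
  num <- vapply(cfg[setdiff(names(cfg), "substitution_model")], is.finite,
                logical(1))
  if (!all(num)) stop("all numeric configuration values must be finite")
  class(cfg) <- "microorigin_config"
  cfg
}

#' Read a flat key = value configuration file
#'
#' Lines are `key = value`; `#` starts a comment; unknown keys are an error.
#' Every key absent from the file keeps its [pipeline_config()] default.
#'
#' @param path Path to the configuration file.
#' @return A `"microorigin_config"` object.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      stop("malformed configuration line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(formals(pipeline_config)))
      stop("unknown configuration key: ", key)
    args[[key]] <- if (key == "substitution_model") val else as.numeric(val)
  }
  do.call(pipeline_config, args)
}

#' @export
print.microorigin_config <- function(x, ...) {
  cat("microorigin pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-34s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
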