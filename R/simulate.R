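# Synthetic fixture generation with known ground truth: a labelled
# phylogeny, neutral nucleotide evolution with indels, an ORF-birth event at
# a chosen ancestor (in-frame stops purged below it, enforced above it), and
# a single transcription-gain event with lognormal TPM values per tissue
# plus sub-threshold noise in outgroup species.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Simulation parameters
#'
#' @param substitution_scale Multiplier applied to branch lengths when
#'   evolving sequences (branch lengths are substitutions/site).
#' @param indel_rate Expected indels per site per unit branch length.
#' @param indel_geom_p Geometric length parameter for indels (lengths in
#'   single nucleotides so frameshifts occur).
#' @param mean_log_tpm,sd_log_tpm Lognormal parameters of expressed TPM.
#' @param expressed_tissue_prob Probability each tissue is expressed in a
#'   transcribed species (at least one tissue is always expressed).
#' @param dropout Probability a species below the gain node shows no
#'   expression at all (sampling failure).
#' @param noise_prob Probability an outgroup species receives sub-threshold
#'   noise expression.
#' @param n_confusion_species Number of outgroup species receiving
#'   between-threshold noise in confusion mode.
#' @return A list of class `"sim_params"`.
#' @export
sim_params <- function(substitution_scale = 1, indel_rate = 0.005,
                       indel_geom_p = 0.5, mean_log_tpm = log(5),
                       sd_log_tpm = 1, expressed_tissue_prob = 0.6,
                       dropout = 0, noise_prob = 0.5,
                       n_confusion_species = 6L) {
  structure(as.list(environment()), class = "sim_params")
}

#' Simulate a labelled species tree
#'
#' A pectinate (caterpillar) rooted tree with the focal human leaf at the
#' tip: ancestors on the human path are labelled `N1 ... N(k)` from recent
#' to ancient (the root is `N(n_species - 1)`), so every internal node sits
#' on the human lineage and can host a birth event. Branch lengths are
#' exponential with the given mean.
#'
#' @param n_species Total number of leaves (>= 4, the minimum number of
#'   genomes required for dating).
#' @param seed Integer seed.
#' @param mean_branch_length Mean of the exponential branch lengths
#'   (substitutions/site). Default 0.05.
#' @param human Focal leaf name.
#' @return A rooted `"phylo"` with node labels.
#' @export
simulate_tree <- function(n_species, seed = NULL, mean_branch_length = 0.05,
                          human = "human") {
  if (n_species < 4L)
    stop("at least 4 species are required (orthologous-region minimum)")
  with_seed(seed, {
    nb <- 2L * (n_species - 1L)
    bl <- stats::rexp(nb, rate = 1 / mean_branch_length)
    others <- paste0("sp", seq_len(n_species - 1L))
    nwk <- sprintf("(%s:%.8f,%s:%.8f)N1", human, bl[1], others[1], bl[2])
    b <- 3L
    for (k in seq_len(n_species - 2L)) {
      nwk <- sprintf("(%s:%.8f,%s:%.8f)N%d", nwk, bl[b], others[k + 1L],
                     bl[b + 1L], k + 1L)
      b <- b + 2L
    }
    ape::read.tree(text = paste0(nwk, ";"))
  })
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

codon_split <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# 1-based nt position of the first in-frame stop codon, or NA
first_stop_pos <- function(seq) {
  cods <- codon_split(seq)
  hit <- which(cods %in% STOP_CODONS)
  if (!length(hit)) NA_integer_ else 3L * (hit[1] - 1L) + 1L
}

# remove all in-frame stops by minimal edits (third codon position -> C)
purge_stops <- function(seq) {
  cods <- codon_split(seq)
  hit <- which(cods %in% STOP_CODONS)
  for (h in hit) substr(seq, 3L * h, 3L * h) <- "C"
  seq
}

# force an in-frame stop within the first `frac` of the sequence
ensure_stop <- function(seq, frac = 0.7) {
  ncod <- nchar(seq) %/% 3L
  span <- max(1L, floor(frac * ncod))
  cods <- codon_split(seq)[seq_len(span)]
  if (any(cods %in% STOP_CODONS)) return(seq)
  at <- sample.int(span, 1L)
  substr(seq, 3L * at - 2L, 3L * at) <- sample(STOP_CODONS, 1L)
  seq
}

mutate_seq <- function(seq, t, params) {
  ch <- strsplit(seq, "")[[1]]
  p_sub <- 0.75 * (1 - exp(-4 * t / 3))   # JC probability of change
  hits <- which(stats::runif(length(ch)) < p_sub)
  for (i in hits) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  seq <- paste(ch, collapse = "")
  n_indel <- stats::rpois(1, params$indel_rate * t * nchar(seq))
  for (k in seq_len(n_indel)) {
    len <- stats::rgeom(1, params$indel_geom_p) + 1L
    if (stats::runif(1) < 0.5 && nchar(seq) > len + 3L) {     # deletion
      at <- sample.int(nchar(seq) - len, 1L)
      seq <- paste0(substr(seq, 1L, at - 1L),
                    substr(seq, at + len, nchar(seq)))
    } else {                                                  # insertion
      at <- sample.int(nchar(seq) + 1L, 1L)
      ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = "")
      seq <- paste0(substr(seq, 1L, at - 1L), ins,
                    substr(seq, at, nchar(seq)))
    }
  }
  seq
}

#' Evolve an orthologous region with an ORF-birth event
#'
#' The root sequence carries an in-frame stop inside the first 70% of its
#' length. Sequences evolve down the tree under Jukes-Cantor substitutions
#' with geometric-length indels. On the branch into `birth_node` every
#' in-frame stop is substituted away by a minimal edit, and all nodes below
#' the birth node are likewise kept stop-free; lineages outside the birth
#' clade are kept disrupted (a stop is reinstated if drift removed it),
#' emulating an ORF that is intact only in the descendants of its birth.
#'
#' @param tree Labelled species tree from [simulate_tree()].
#' @param orf_len_nt ORF length, a multiple of 3, at least 33.
#' @param birth_node Ancestor label on the human path (or the human leaf).
#' @param params [sim_params()].
#' @param seed Integer seed.
#' @param human Focal leaf name.
#' @return List: `sequences` (named character, leaves), `truth` (list with
#'   orf_birth_node, true_ancestral_sequences for the human ancestor path,
#'   params).
#' @export
evolve_region <- function(tree, orf_len_nt, birth_node,
                          params = sim_params(), seed = NULL,
                          human = "human") {
  if (orf_len_nt %% 3L != 0L || orf_len_nt < 33L)
    stop("orf_len_nt must be a multiple of 3 and at least 33")
  path <- ancestor_path(tree, human)
  if (!birth_node %in% c(path, human))
    stop("birth_node '", birth_node, "' is not on the human ancestor path")
  with_seed(seed, {
    ntip <- length(tree$tip.label)
    nnode <- ntip + tree$Nnode
    root <- ntip + 1L
    birth_id <- if (birth_node == human) match(human, tree$tip.label)
                else ntip + match(birth_node, tree$node.label)
    below <- if (birth_id <= ntip) birth_id
             else c(birth_id, phangorn_free_descendants(tree, birth_id))
    seqs <- vector("character", nnode)
    seqs[root] <- ensure_stop(paste(
      sample(c("A", "C", "G", "T"), orf_len_nt, replace = TRUE),
      collapse = ""))
    if (root == birth_id) seqs[root] <- purge_stops(seqs[root])
    # the human ORF is an intact reference by definition: no indels on the
    # branches leading to it, so its length stays a codon multiple
    human_tip <- match(human, tree$tip.label)
    human_path_nodes <- c(human_tip,
                          ntip + match(path, tree$node.label))
    edges <- ape::reorder.phylo(tree, "cladewise")
    for (k in seq_len(nrow(edges$edge))) {
      parent <- edges$edge[k, 1]; child <- edges$edge[k, 2]
      par_k <- params
      if (child %in% human_path_nodes) par_k$indel_rate <- 0
      s <- mutate_seq(seqs[parent],
                      edges$edge.length[k] * params$substitution_scale,
                      par_k)
      if (child %in% below) s <- purge_stops(s)
      else if (is.na(first_stop_pos(substr(s, 1L,
                                           3L * floor(0.7 * (nchar(s) %/% 3L))))))
        s <- ensure_stop(s)
      seqs[child] <- s
    }
    leaves <- stats::setNames(seqs[seq_len(ntip)], tree$tip.label)
    anc <- stats::setNames(
      seqs[ntip + match(path, tree$node.label)], path)
    list(sequences = leaves,
         truth = list(orf_birth_node = birth_node,
                      true_ancestral_sequences = anc,
                      params = params))
  })
}

# descendants of an internal node (tips and internals), base implementation
phangorn_free_descendants <- function(tree, node) {
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    cur <- stack[1]; stack <- stack[-1]
    kids <- tree$edge[tree$edge[, 1] == cur, 2]
    out <- c(out, kids)
    stack <- c(stack, kids[kids > length(tree$tip.label)])
  }
  out
}

#' Simulate tissue expression with a single transcription-gain event
#'
#' Species descending from `gain_node` are transcribed: unless dropped out,
#' they receive lognormal TPM (clamped up to the 0.1 TPM presence floor) in
#' at least one tissue. Outgroup species receive either zero or noise:
#' uniform in (0, 0.1) normally, or uniform in (0.1, 1) for the designated
#' confusion species, which exercises the threshold-escalation rule.
#'
#' @param tree Labelled species tree.
#' @param gain_node Ancestor label (or human leaf) where transcription arose.
#' @param tissues Character vector of tissue names.
#' @param params [sim_params()].
#' @param seed Integer seed.
#' @param confusion Logical; plant between-threshold noise in
#'   `params$n_confusion_species` outgroup species.
#' @param human Focal leaf name.
#' @return List: `evidence` (an `"expression_evidence"` list with `tpm`
#'   data.frame), `truth` (txn_gain_node, transcribed_species).
#' @export
simulate_transcription <- function(tree, gain_node, tissues,
                                   params = sim_params(), seed = NULL,
                                   confusion = FALSE, human = "human") {
  path <- ancestor_path(tree, human)
  if (!gain_node %in% c(path, human))
    stop("gain_node '", gain_node, "' is not on the human ancestor path")
  if (!is.character(tissues) || !length(tissues) || anyNA(tissues))
    stop("tissues must be a non-empty character vector")
  with_seed(seed, {
    inclade <- clade_leaves(tree, gain_node, human)
    outg <- setdiff(tree$tip.label, inclade)
    rows <- list()
    transcribed <- character(0)
    tpm_floor <- 0.1
    for (sp in inclade) {
      if (sp != human && stats::runif(1) < params$dropout) next
      transcribed <- c(transcribed, sp)
      expressed <- stats::runif(length(tissues)) < params$expressed_tissue_prob
      if (!any(expressed)) expressed[sample.int(length(tissues), 1L)] <- TRUE
      for (ti in which(expressed)) {
        tpm <- max(stats::rlnorm(1, params$mean_log_tpm, params$sd_log_tpm),
                   tpm_floor)
        rows[[length(rows) + 1L]] <- data.frame(
          species = sp, tissue = tissues[ti], tpm = tpm,
          stringsAsFactors = FALSE)
      }
    }
    confused <- character(0)
    if (confusion && length(outg)) {
      # deterministic placement: alternate outgroups starting farthest from
      # the gain node, so absences interleave with noisy presences
      n <- min(params$n_confusion_species, length(outg))
      ord <- rev(outg)
      confused <- ord[seq(1L, by = 2L, length.out = min(n, ceiling(length(ord) / 2)))]
      if (length(confused) < n)
        confused <- c(confused,
                      setdiff(ord, confused)[seq_len(n - length(confused))])
    }
    for (sp in outg) {
      if (sp %in% confused) {
        ti <- sample.int(length(tissues), 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          species = sp, tissue = tissues[ti],
          tpm = stats::runif(1, tpm_floor, 1), stringsAsFactors = FALSE)
      } else if (stats::runif(1) < params$noise_prob) {
        ti <- sample.int(length(tissues), 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          species = sp, tissue = tissues[ti],
          tpm = stats::runif(1, 0, tpm_floor), stringsAsFactors = FALSE)
      }
    }
    tpm <- if (length(rows)) do.call(rbind, rows)
           else data.frame(species = character(), tissue = character(),
                           tpm = numeric(), stringsAsFactors = FALSE)
    ev <- expression_evidence(orf_id = "sim_orf", tpm = tpm)
    list(evidence = ev,
         truth = list(txn_gain_node = gain_node,
                      transcribed_species = transcribed,
                      confusion_species = confused))
  })
}

#' Simulate a complete fixture (tree, region, expression)
#'
#' @param n_species Number of leaves.
#' @param orf_len_nt ORF length (multiple of 3).
#' @param birth_node,txn_node Ancestor labels; defaults pick mid-path nodes.
#' @param tissues Tissue names.
#' @param params [sim_params()].
#' @param seed Integer seed driving the whole bundle.
#' @param confusion Confusion-mode expression noise.
#' @param mean_branch_length Tree branch-length mean.
#' @param human Focal leaf name.
#' @return List: tree, region (from [evolve_region()]), expression (from
#'   [simulate_transcription()]), orf_id, human.
#' @export
simulate_bundle <- function(n_species = 8L, orf_len_nt = 90L,
                            birth_node = NULL, txn_node = NULL,
                            tissues = c("brain", "heart", "liver",
                                        "kidney", "testis"),
                            params = sim_params(), seed = 1L,
                            confusion = FALSE, mean_branch_length = 0.02,
                            human = "human") {
  tree <- simulate_tree(n_species, seed = seed,
                        mean_branch_length = mean_branch_length,
                        human = human)
  path <- ancestor_path(tree, human)
  if (is.null(birth_node)) birth_node <- path[ceiling(length(path) / 2)]
  if (is.null(txn_node)) txn_node <- path[ceiling(length(path) / 2)]
  region <- evolve_region(tree, orf_len_nt, birth_node, params,
                          seed = seed + 1000L, human = human)
  expr <- simulate_transcription(tree, txn_node, tissues, params,
                                 seed = seed + 2000L, confusion = confusion,
                                 human = human)
  list(tree = tree, region = region, expression = expr,
       orf_id = "sim_orf", human = human)
}

#' Write a fixture bundle to disk
#'
#' Emits the files a full pipeline run consumes: per-species FASTA, the
#' newick tree, a toy single-block MAF of the aligned region, a transcripts
#' GTF for species with inferred transcription, the expression TSV, the
#' ground-truth TSV, and the true ancestral sequences as FASTA. Identical
#' seeds give byte-identical bundles.
#'
#' @param bundle A [simulate_bundle()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  need <- c("tree", "region", "expression", "orf_id")
  if (!all(need %in% names(bundle)))
    stop("incomplete bundle: missing ",
         paste(setdiff(need, names(bundle)), collapse = ", "))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", dir)
  human <- bundle$human %||% "human"
  paths <- c(fasta = file.path(dir, "regions.fa"),
             tree = file.path(dir, "tree.nwk"),
             maf = file.path(dir, "regions.maf"),
             gtf = file.path(dir, "transcripts.gtf"),
             expression = file.path(dir, "expression.tsv"),
             truth = file.path(dir, "truth.tsv"),
             ancestors = file.path(dir, "truth_ancestors.fa"))
  write_fasta(bundle$region$sequences, paths["fasta"])
  write_newick(bundle$tree, paths["tree"])

  msa <- align_regions(bundle$region$sequences, guide_tree = bundle$tree)
  rows <- data.frame(
    src = paste0(names(msa), ".chrS"), species = names(msa),
    start = ifelse(names(msa) == human, 100L, 0L),
    size = nchar(gsub("-", "", msa, fixed = TRUE)),
    strand = "+",
    src_size = 10000L,
    stringsAsFactors = FALSE)
  rows$fwd_start <- rows$start
  rows$fwd_end <- rows$start + rows$size
  rows$text <- as.character(msa)
  write_maf_blocks(list(list(rows = rows)), paths["maf"])

  gtf <- character(0)
  for (sp in bundle$expression$truth$transcribed_species) {
    at <- if (sp == human) 100L else 0L
    len <- nchar(bundle$region$sequences[[sp]])
    gtf <- c(gtf, sprintf(
      "chrS\tsim\texon\t%d\t%d\t.\t+\t.\tgene_id \"%s_g\"; transcript_id \"%s_t1\"; species \"%s\";",
      at + 1L, at + len, sp, sp, sp))
  }
  writeLines(gtf, paths["gtf"])

  tpm <- bundle$expression$evidence$tpm
  expr <- data.frame(orf_id = bundle$orf_id, tpm, stringsAsFactors = FALSE)
  utils::write.table(expr, paths["expression"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- data.frame(orf_id = bundle$orf_id,
                      orf_birth_node = bundle$region$truth$orf_birth_node,
                      txn_gain_node = bundle$expression$truth$txn_gain_node,
                      stringsAsFactors = FALSE)
  utils::write.table(truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_fasta(bundle$region$truth$true_ancestral_sequences,
              paths["ancestors"])
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
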