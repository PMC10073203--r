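# Marginal ancestral sequence reconstruction.
#
# Nucleotide states: inside-outside message passing under the fitted model
# (marginal posterior per node and column, argmax call, alphabetical
# tie-break A<C<G<T). Indel states: a two-state presence/absence chain whose
# gain/loss rates are estimated by ML on the gap pattern, with a Fitch
# parsimony fallback for very short alignments.

# generic inside-outside pass over a tree for an S-state model.
# tip_part: list per tip of S x L matrices. pmat_fun(edge_len) -> S x S.
# prior: length-S root distribution.
inside_outside <- function(tree, tip_part, pmat_fun, prior) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  L <- ncol(tip_part[[1]])
  S <- length(prior)
  tre <- postorder_edges(tree)
  nedge <- nrow(tre$edge)
  down <- vector("list", nnode)
  for (i in seq_len(ntip)) down[[i]] <- tip_part[[i]]
  msgs <- vector("list", nedge)
  pmats <- lapply(tre$edge.length, pmat_fun)
  for (k in seq_len(nedge)) {
    parent <- tre$edge[k, 1]; child <- tre$edge[k, 2]
    msgs[[k]] <- pmats[[k]] %*% down[[child]]
    down[[parent]] <- if (is.null(down[[parent]])) msgs[[k]]
                      else down[[parent]] * msgs[[k]]
  }
  up <- vector("list", nnode)
  up[[root]] <- matrix(prior, S, L)
  kids <- split(seq_len(nedge), tre$edge[, 1])
  for (k in rev(seq_len(nedge))) {
    parent <- tre$edge[k, 1]; child <- tre$edge[k, 2]
    sib <- up[[parent]]
    for (j in kids[[as.character(parent)]])
      if (j != k) sib <- sib * msgs[[j]]
    up[[child]] <- crossprod(pmats[[k]], sib)
  }
  persite <- as.numeric(prior %*% down[[root]])
  list(down = down, up = up, persite = persite,
       loglik = sum(log(pmax(persite, 1e-300))))
}

#' Marginal posteriors of ancestral states at internal nodes
#'
#' @param tree Rooted `"phylo"` with branch lengths.
#' @param alnmat Encoded alignment or named gapped rows.
#' @param model A [subst_model()]; the reconstruction model (JC by default
#'   in the pipeline, independent of the branch-length model).
#' @return List per internal node (named by node label when available) of
#'   4 x L posterior matrices (rows A,C,G,T; columns sum to 1).
#' @export
marginal_posteriors <- function(tree, alnmat, model) {
  if (is.character(alnmat)) alnmat <- encode_alignment(alnmat)
  L <- ncol(alnmat)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  tp <- tip_partials(alnmat[match(tree$tip.label, rownames(alnmat)), ,
                            drop = FALSE])
  runs <- lapply(seq_len(model$rate_cats), function(ct) {
    inside_outside(tree, tp,
                   function(t) model$pmat(t, model$cat_rates[ct]),
                   model$freqs)
  })
  mixlik <- Reduce(`+`, lapply(seq_len(model$rate_cats), function(ct)
    model$cat_weights[ct] * runs[[ct]]$persite))
  out <- vector("list", tree$Nnode)
  for (v in (ntip + 1L):nnode) {
    acc <- matrix(0, 4, L)
    for (ct in seq_len(model$rate_cats)) {
      r <- runs[[ct]]
      raw <- r$down[[v]] * r$up[[v]]
      # joint over (state, category) normalised by the mixture likelihood
      acc <- acc + sweep(raw, 2, model$cat_weights[ct] / mixlik, "*")
    }
    acc <- sweep(acc, 2, colSums(acc), "/")
    rownames(acc) <- NUC
    out[[v - ntip]] <- acc
  }
  if (!is.null(tree$node.label)) names(out) <- tree$node.label
  out
}

# ---- indel (presence/absence) reconstruction ----------------------------

two_state_pmat <- function(t, gain, loss) {
  # states: 1 = absent, 2 = present
  s <- gain + loss
  e <- exp(-s * t)
  matrix(c(loss / s + gain / s * e, gain / s - gain / s * e,
           loss / s - loss / s * e, gain / s + loss / s * e),
         2, 2, byrow = TRUE)
}

presence_tip_partials <- function(presence) {
  L <- ncol(presence)
  lapply(seq_len(nrow(presence)), function(i) {
    P <- matrix(0, 2, L)
    known <- !is.na(presence[i, ])
    P[cbind(presence[i, known] + 1L, which(known))] <- 1
    P[, !known] <- 1
    P
  })
}

indel_posteriors_ml <- function(tree, presence) {
  tp <- presence_tip_partials(presence)
  nll <- function(p) {
    gain <- exp(p[1]); loss <- exp(p[2])
    pi0 <- c(loss, gain) / (gain + loss)
    -inside_outside(tree, tp,
                    function(t) two_state_pmat(max(t, 1e-8), gain, loss),
                    pi0)$loglik
  }
  fit <- stats::optim(c(0, 0), nll, method = "Nelder-Mead",
                      control = list(maxit = 300))
  gain <- exp(fit$par[1]); loss <- exp(fit$par[2])
  pi0 <- c(loss, gain) / (gain + loss)
  io <- inside_outside(tree, tp,
                       function(t) two_state_pmat(max(t, 1e-8), gain, loss),
                       pi0)
  ntip <- length(tree$tip.label)
  lapply(seq_len(tree$Nnode), function(j) {
    v <- ntip + j
    raw <- io$down[[v]] * io$up[[v]]
    raw[2, ] / colSums(raw)   # posterior of "present"
  })
}

indel_posteriors_fitch <- function(tree, presence) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  tre <- postorder_edges(tree)
  root <- ntip + 1L
  L <- ncol(presence)
  out <- matrix(NA_real_, tree$Nnode, L)
  for (col in seq_len(L)) {
    sets <- vector("list", nnode)
    for (i in seq_len(ntip)) {
      sets[[i]] <- if (is.na(presence[i, col])) c(0L, 1L)
                   else presence[i, col]
    }
    for (k in seq_len(nrow(tre$edge))) {
      parent <- tre$edge[k, 1]; child <- tre$edge[k, 2]
      sets[[parent]] <- if (is.null(sets[[parent]])) sets[[child]]
      else {
        inter <- intersect(sets[[parent]], sets[[child]])
        if (length(inter)) inter else union(sets[[parent]], sets[[child]])
      }
    }
    state <- integer(nnode)
    pick <- function(s) if (1L %in% s) 1L else 0L  # ambiguity -> present
    state[root] <- pick(sets[[root]])
    for (k in rev(seq_len(nrow(tre$edge)))) {
      parent <- tre$edge[k, 1]; child <- tre$edge[k, 2]
      if (child > ntip) {
        state[child] <- if (state[parent] %in% sets[[child]]) state[parent]
                        else pick(sets[[child]])
      }
    }
    out[, col] <- state[(ntip + 1L):nnode]
  }
  lapply(seq_len(tree$Nnode), function(j) out[j, ])
}

#' Reconstruct ancestral sequences at the human-lineage ancestors
#'
#' Performs marginal nucleotide reconstruction (argmax per column,
#' alphabetical tie-break) and presence/absence indel reconstruction, then
#' assembles each target ancestor's sequence from the columns reconstructed
#' as present.
#'
#' @param msa Named gapped rows.
#' @param fitted A `"fitted_tree"` from [fit_branch_lengths()] (or a plain
#'   `"phylo"` with branch lengths).
#' @param targets Node labels to reconstruct; default the whole human
#'   ancestor path present in the tree.
#' @param model Reconstruction model (default JC, mirroring the fixed-model
#'   reconstruction stage even when branch lengths were fitted under GTR+G).
#' @param human Focal leaf name.
#' @param indel_min_columns Below this alignment width the indel model falls
#'   back to Fitch parsimony. Default 10.
#' @return List of `"ancestor_profile"` objects: node, sequence,
#'   site_posteriors, indel_posteriors, present, posterior (4 x L matrix).
#' @export
reconstruct_ancestors <- function(msa, fitted, targets = NULL,
                                  model = subst_model("JC"),
                                  human = "human",
                                  indel_min_columns = 10L) {
  tree <- if (inherits(fitted, "fitted_tree")) fitted$tree else fitted
  if (is.character(model)) model <- subst_model(model)
  validate_msa(msa)
  if (is.null(targets)) targets <- ancestor_path(tree, human)
  missing <- setdiff(targets, tree$node.label)
  if (length(missing))
    stop("target node(s) not in tree: ", paste(missing, collapse = ", "))

  alnmat <- encode_alignment(msa)
  post <- marginal_posteriors(tree, alnmat, model)

  chmat <- do.call(rbind, lapply(msa, function(r) strsplit(r, "")[[1]]))
  presence <- matrix(NA_integer_, nrow(chmat), ncol(chmat))
  presence[chmat != "-"] <- 1L
  presence[chmat == "-"] <- 0L
  presence <- presence[match(tree$tip.label, names(msa)), , drop = FALSE]
  ind <- if (ncol(alnmat) < indel_min_columns)
    indel_posteriors_fitch(tree, presence)
  else indel_posteriors_ml(tree, presence)
  names(ind) <- tree$node.label

  lapply(targets, function(lab) {
    pp <- post[[lab]]
    call_idx <- apply(pp, 2, which.max)   # first max: A<C<G<T tie-break
    site_post <- pp[cbind(call_idx, seq_len(ncol(pp)))]
    present <- ind[[lab]] >= 0.5
    seq <- paste(NUC[call_idx][present], collapse = "")
    structure(list(node = lab, sequence = seq,
                   site_posteriors = site_post,
                   indel_posteriors = ind[[lab]],
                   present = present, posterior = pp),
              class = "ancestor_profile")
  })
}

#' @export
print.ancestor_profile <- function(x, ...) {
  cat("Ancestor ", x$node, ": ", nchar(x$sequence), " nt reconstructed (",
      sum(x$present), "/", length(x$present), " columns present)\n", sep = "")
  invisible(x)
}
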