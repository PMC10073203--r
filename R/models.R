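# Nucleotide substitution models and Felsenstein pruning.
#
# Alignments are handled as integer matrices (species x columns) with codes
# 1..4 for A,C,G,T and NA for N or gap (missing data: partial likelihood 1).

NUC <- c("A", "C", "G", "T")

encode_alignment <- function(msa) {
  rows <- lapply(msa, function(r) match(strsplit(r, "")[[1]], NUC))
  mat <- do.call(rbind, rows)
  rownames(mat) <- names(msa)
  mat
}

#' Substitution model specification
#'
#' `"JC"` is Jukes-Cantor. `"GTRG"` is the general time-reversible model
#' with 4-category discrete-gamma rate heterogeneity; `rates` are the six
#' exchangeabilities (AC, AG, AT, CG, CT, GT), `freqs` the stationary base
#' frequencies, `alpha` the gamma shape. Rate matrices are scaled to one
#' expected substitution per site per unit branch length.
#'
#' @param name `"JC"` or `"GTRG"`.
#' @param rates,freqs,alpha GTR+G parameters (ignored for JC).
#' @return A model object with a transition-probability generator.
#' @export
subst_model <- function(name = c("JC", "GTRG"),
                        rates = rep(1, 6), freqs = rep(0.25, 4),
                        alpha = 1) {
  name <- match.arg(name)
  if (name == "JC") {
    m <- list(name = "JC", freqs = rep(0.25, 4), rate_cats = 1,
              cat_rates = 1, cat_weights = 1)
    m$pmat <- function(t, rate = 1) jc_pmat(t * rate)
  } else {
    freqs <- freqs / sum(freqs)
    Q <- matrix(0, 4, 4)
    Q[lower.tri(Q)] <- 0
    pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
    for (k in 1:6) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      Q[i, j] <- rates[k] * freqs[j]
      Q[j, i] <- rates[k] * freqs[i]
    }
    diag(Q) <- -rowSums(Q)
    scale <- -sum(freqs * diag(Q))
    Q <- Q / scale
    # symmetrise for a stable eigendecomposition: B = D^1/2 Q D^-1/2
    d <- sqrt(freqs)
    B <- diag(d) %*% Q %*% diag(1 / d)
    eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
    V <- diag(1 / d) %*% eig$vectors
    Vinv <- t(eig$vectors) %*% diag(d)
    g <- discrete_gamma(alpha, 4)
    m <- list(name = "GTRG", freqs = freqs, rate_cats = 4,
              cat_rates = g, cat_weights = rep(0.25, 4),
              rates = rates, alpha = alpha)
    m$pmat <- function(t, rate = 1) {
      P <- V %*% diag(exp(eig$values * t * rate)) %*% Vinv
      P[P < 0] <- 0
      P
    }
  }
  class(m) <- "subst_model"
  m
}

jc_pmat <- function(t) {
  e <- exp(-4 * t / 3)
  p_same <- 0.25 + 0.75 * e
  p_diff <- 0.25 - 0.25 * e
  P <- matrix(p_diff, 4, 4)
  diag(P) <- p_same
  P
}

# mean rates of the K equal-probability categories of a discrete gamma
discrete_gamma <- function(alpha, k = 4) {
  q <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = alpha,
                     rate = alpha)
  r <- numeric(k)
  for (i in seq_len(k)) {
    r[i] <- k * (stats::pgamma(q[i + 1], shape = alpha + 1, rate = alpha) -
                 stats::pgamma(q[i], shape = alpha + 1, rate = alpha))
  }
  r / mean(r) * 1
}

# tip partial likelihood array: list per tip of 4 x L matrix
tip_partials <- function(alnmat) {
  L <- ncol(alnmat)
  lapply(seq_len(nrow(alnmat)), function(i) {
    P <- matrix(0, 4, L)
    idx <- alnmat[i, ]
    known <- !is.na(idx)
    P[cbind(idx[known], which(known))] <- 1
    P[, !known] <- 1
    P
  })
}

# postorder edge traversal indices for a phylo tree
postorder_edges <- function(tree) {
  ape::reorder.phylo(tree, "postorder")
}

#' Log-likelihood of an alignment on a tree (Felsenstein pruning)
#'
#' @param tree Rooted `"phylo"` with branch lengths.
#' @param alnmat Encoded alignment (see internals) or named gapped rows.
#' @param model A [subst_model()].
#' @param weights Optional per-column pattern weights.
#' @return List: `loglik`, and `down` (per-node partial likelihoods, one
#'   4 x L matrix per node, averaged over rate categories at the root only).
#' @export
tree_loglik <- function(tree, alnmat, model, weights = NULL) {
  if (is.character(alnmat)) alnmat <- encode_alignment(alnmat)
  L <- ncol(alnmat)
  if (L == 0L) stop("alignment has zero columns")
  if (is.null(weights)) weights <- rep(1, L)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  ord <- match(tree$tip.label, rownames(alnmat))
  if (anyNA(ord)) stop("alignment rows do not match tree leaves")
  tp <- tip_partials(alnmat[ord, , drop = FALSE])
  tre <- postorder_edges(tree)
  root <- ntip + 1L
  sitelik <- matrix(0, model$rate_cats, L)
  down_cats <- vector("list", model$rate_cats)
  for (ct in seq_len(model$rate_cats)) {
    rate <- model$cat_rates[ct]
    down <- vector("list", nnode)
    for (i in seq_len(ntip)) down[[i]] <- tp[[i]]
    for (k in seq_len(nrow(tre$edge))) {
      parent <- tre$edge[k, 1]; child <- tre$edge[k, 2]
      P <- model$pmat(tre$edge.length[k], rate)
      msg <- P %*% down[[child]]
      down[[parent]] <- if (is.null(down[[parent]])) msg
                        else down[[parent]] * msg
    }
    sitelik[ct, ] <- model$freqs %*% down[[root]]
    down_cats[[ct]] <- down
  }
  persite <- as.numeric(model$cat_weights %*% sitelik)
  list(loglik = sum(weights * log(persite)),
       down = down_cats, sitelik = sitelik, persite = persite)
}

#' Fit branch lengths on a fixed topology by maximum likelihood
#'
#' Branch lengths are optimised coordinate-wise (Brent on each branch,
#' holding the rest fixed) until the log-likelihood improves by less than a
#' relative tolerance. Gaps and N are treated as missing data.
#'
#' @param msa Named gapped rows (class `"msa"`) or plain named character.
#' @param topology Rooted `"phylo"` whose leaf set equals the row set.
#' @param model `"JC"`, `"GTRG"`, or a [subst_model()] object.
#' @param max_sweeps Maximum coordinate sweeps.
#' @param rel_tol Relative log-likelihood convergence tolerance.
#' @param max_branch Upper bound for a single branch length.
#' @return A `"fitted_tree"`: list(tree, model, log_likelihood).
#' @export
fit_branch_lengths <- function(msa, topology, model = "JC",
                               max_sweeps = 20L, rel_tol = 1e-6,
                               max_branch = 10) {
  if (is.character(model)) model <- subst_model(model)
  alnmat <- encode_alignment(msa)
  if (ncol(alnmat) == 0L) stop("alignment has zero columns")
  if (!setequal(rownames(alnmat), topology$tip.label))
    stop("alignment rows do not match topology leaves")
  # pattern compression
  key <- apply(alnmat, 2, paste, collapse = "\r")
  uniq <- !duplicated(key)
  weights <- as.numeric(table(key)[key[uniq]])
  pat <- alnmat[, uniq, drop = FALSE]

  tree <- topology
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0.1, nrow(tree$edge))
  tree$edge.length[tree$edge.length < 1e-8] <- 1e-8
  ll <- tree_loglik(tree, pat, model, weights)$loglik
  for (sweep in seq_len(max_sweeps)) {
    for (k in seq_len(nrow(tree$edge))) {
      f <- function(b) {
        tr <- tree; tr$edge.length[k] <- b
        tree_loglik(tr, pat, model, weights)$loglik
      }
      opt <- stats::optimize(f, c(1e-9, max_branch), maximum = TRUE,
                             tol = 1e-7)
      if (opt$objective >= ll) {
        tree$edge.length[k] <- opt$maximum
        ll_new <- opt$objective
      } else ll_new <- ll
      ll <- ll_new
    }
    prev <- if (sweep == 1L) -Inf else prev_ll
    prev_ll <- ll
    if (sweep > 1L && abs(ll - prev) <= rel_tol * (abs(ll) + 1e-12)) break
  }
  # branches driven to the floor are reported as zero
  tree$edge.length[tree$edge.length <= 1.5e-8] <- 0
  structure(list(tree = tree, model = model, log_likelihood = ll),
            class = "fitted_tree")
}

#' @export
print.fitted_tree <- function(x, ...) {
  cat("Fitted tree (", x$model$name, "): ",
      length(x$tree$tip.label), " leaves, logL = ",
      format(x$log_likelihood, digits = 8), "\n", sep = "")
  invisible(x)
}
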