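# Independent oracles used across the suite. Each re-derives its quantity
# by brute force, sharing no code with the implementation it checks.

# brute-force marginal posterior at one internal node under JC, by
# enumerating all assignments of states to all internal nodes
brute_marginal_jc <- function(tree, rows, target_lab) {
  jc <- function(t) {
    e <- exp(-4 * t / 3)
    m <- matrix((1 - e) / 4, 4, 4)
    diag(m) <- (1 + 3 * e) / 4
    m
  }
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  states <- lapply(rows, function(r)
    match(strsplit(r, "")[[1]], c("A", "C", "G", "T")))
  L <- length(states[[1]])
  target <- ntip + match(target_lab, tree$node.label)
  internals <- (ntip + 1):nn
  grid <- as.matrix(expand.grid(rep(list(1:4), length(internals))))
  pmats <- lapply(seq_len(nrow(tree$edge)),
                  function(k) jc(tree$edge.length[k]))
  out <- matrix(0, 4, L)
  for (col in seq_len(L)) {
    probs <- numeric(4)
    for (g in seq_len(nrow(grid))) {
      assign <- integer(nn)
      assign[internals] <- grid[g, ]
      p <- 0.25
      for (k in seq_len(nrow(tree$edge))) {
        par <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
        chs <- if (ch <= ntip) states[[tree$tip.label[ch]]][col]
               else assign[ch]
        if (is.na(chs)) next  # missing tip data
        p <- p * pmats[[k]][assign[par], chs]
      }
      probs[assign[target]] <- probs[assign[target]] + p
    }
    out[, col] <- probs / sum(probs)
  }
  out
}

# brute-force Dollo dating: over all nodes whose clade covers the presence
# set, pick the single-gain placement with the fewest implied losses
brute_dollo <- function(tree, present, human = "human") {
  present <- union(present, human)
  ntip <- length(tree$tip.label)
  if (length(present) == 1L) return(human)
  best <- NULL; best_loss <- Inf
  for (v in (ntip + 1L):(ntip + tree$Nnode)) {
    leaves <- ape::extract.clade(tree, v)$tip.label
    if (!all(present %in% leaves)) next
    losses <- length(setdiff(leaves, present))
    if (losses < best_loss) { best_loss <- losses; best <- v }
  }
  tree$node.label[best - ntip]
}

# brute-force affine-gap pairwise alignment score by enumerating all global
# alignments (gap run of length g costs open + (g - 1) * ext)
brute_align_score <- function(a, b, match = 1, mismatch = -1,
                              open = -4, ext = -1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  # state: 0 = none/diag, 1 = gap in b, 2 = gap in a
  rec <- function(i, j, state) {
    if (i > length(a) && j > length(b)) return(0)
    best <- -Inf
    if (i <= length(a) && j <= length(b)) {
      s <- if (a[i] == b[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, 0))
    }
    if (i <= length(a))
      best <- max(best,
                  (if (state == 1) ext else open) + rec(i + 1, j, 1))
    if (j <= length(b))
      best <- max(best,
                  (if (state == 2) ext else open) + rec(i, j + 1, 2))
    best
  }
  rec(1, 1, 0)
}

# exact two-sided rank-sum p-value by enumerating all group assignments
perm_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  obs <- sum(r[seq_along(x)])
  combs <- utils::combn(n, length(x))
  stats <- apply(combs, 2, function(idx) sum(r[idx]))
  centre <- length(x) * (n + 1) / 2
  mean(abs(stats - centre) >= abs(obs - centre) - 1e-9)
}

# exact two-sided Spearman p-value by enumerating permutations of y
perm_spearman_p <- function(x, y) {
  rho_of <- function(yy) stats::cor(rank(x), rank(yy))
  obs <- abs(rho_of(y))
  perms <- permutations_idx(length(y))
  vals <- vapply(perms, function(p) abs(rho_of(y[p])), numeric(1))
  mean(vals >= obs - 1e-9)
}

permutations_idx <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in permutations_idx(n - 1L)) {
    for (k in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = k)
    }
  }
  out
}

# random indel-bearing variants of a base ORF for codon-alignment fixtures
random_indel_family <- function(base, n_seqs = 4L) {
  nts <- c("A", "C", "G", "T")
  out <- character(n_seqs)
  for (i in seq_len(n_seqs)) {
    s <- strsplit(base, "")[[1]]
    n_indel <- if (i == 1L) 0L else sample(0:3, 1)  # reference stays in frame
    for (k in seq_len(n_indel)) {
      if (stats::runif(1) < 0.5 && length(s) > 12) {
        len <- sample(1:5, 1)
        at <- sample(length(s) - len, 1)
        s <- s[-(at:(at + len - 1))]
      } else {
        len <- sample(1:5, 1)
        at <- sample(length(s) + 1, 1)
        s <- append(s, sample(nts, len, replace = TRUE), after = at - 1)
      }
    }
    nsub <- sample(0:4, 1)
    pos <- sample(length(s), min(nsub, length(s)))
    for (p in pos) s[p] <- sample(nts, 1)
    out[i] <- paste(s, collapse = "")
  }
  stats::setNames(out, c("human", paste0("sp", seq_len(n_seqs - 1L))))
}
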