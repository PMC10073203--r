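test_that("tree pruning preserves path metrics and labels", {
  tr <- ape::read.tree(
    text = "(((human:1,chimp:2)N1:3,gorilla:4)N2:5,mouse:6)R;")
  full <- prune_tree(tr, tr$tip.label)
  expect_setequal(full$tip.label, tr$tip.label)
  expect_equal(sum(full$edge.length), sum(tr$edge.length))

  cherry <- prune_tree(tr, c("human", "mouse"))
  expect_setequal(cherry$tip.label, c("human", "mouse"))
  # collapsed branch lengths are path sums: human 1+3+5, mouse 6
  expect_equal(sort(cherry$edge.length), c(6, 9))

  expect_error(prune_tree(tr, c("chimp", "mouse")), "human")
  expect_error(prune_tree(tr, "human"), "fewer than 2")
})

test_that("progressive alignment handles identity, gaps, and validation", {
  ident <- align_regions(c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT"))
  expect_false(any(grepl("-", ident, fixed = TRUE)))

  two <- align_regions(c(a = "ACGT", b = "AGT"))
  expect_equal(sum(strsplit(two[["b"]], "")[[1]] == "-"), 1L)
  validate_msa(two, c(a = "ACGT", b = "AGT"))

  expect_error(align_regions(c(a = "ACGT", b = "")), "empty")
  expect_error(align_regions(c(a = "ACGT")), "at least 2")
})

test_that("pairwise alignment scores match brute-force enumeration", {
  set.seed(11)
  for (rep in 1:12) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(3:7, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(3:7, 1), TRUE),
               collapse = "")
    rows <- pairwise_align(a, b)
    expect_equal(attr(rows, "score"), brute_align_score(a, b),
                 tolerance = 1e-9, label = paste(a, b))
  }
})

test_that("external MSA adapter accepts aligner output", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT-ACGT", ">b", "ACGTTACGT"), f)
  msa <- read_external_msa(f)
  expect_s3_class(msa, "msa")
  writeLines(c(">a", "ACGT-ACGT", ">b", "ACGT"), f)
  expect_error(read_external_msa(f), "unequal")
})

test_that("branch-length fitting recovers the JC closed form", {
  tr <- ape::read.tree(text = "(human:0.05,sp1:0.05)R;")
  same <- c(human = strrep("ACGT", 50), sp1 = strrep("ACGT", 50))
  fit0 <- fit_branch_lengths(same, tr, "JC")
  expect_lt(sum(fit0$tree$edge.length), 1e-6)

  set.seed(7)
  n <- 2000L; p <- 0.1
  base <- sample(c("A", "C", "G", "T"), n, TRUE)
  mut <- base
  idx <- sample(n, round(n * p))
  for (i in idx) mut[i] <- sample(setdiff(c("A", "C", "G", "T"), mut[i]), 1)
  msa <- c(human = paste(base, collapse = ""),
           sp1 = paste(mut, collapse = ""))
  fit <- fit_branch_lengths(msa, tr, "JC")
  expect_equal(sum(fit$tree$edge.length), -(3 / 4) * log(1 - 4 * p / 3),
               tolerance = 1e-3)
  # optimised likelihood is no worse than at the initial lengths
  expect_gte(fit$log_likelihood,
             tree_loglik(tr, msa, subst_model("JC"))$loglik)
})

test_that("fitted likelihoods agree with an independent implementation", {
  skip_if_not_installed("phangorn")
  set.seed(21)
  tr <- simulate_tree(5, seed = 2, mean_branch_length = 0.1)
  reg <- evolve_region(tr, 60, "N2", sim_params(indel_rate = 0), seed = 31)
  msa <- reg$sequences
  ll <- tree_loglik(tr, msa, subst_model("JC"))$loglik
  dat <- phangorn::phyDat(t(sapply(msa, function(s) strsplit(s, "")[[1]])))
  pml <- phangorn::pml(ape::unroot(tr), dat)
  expect_equal(ll, as.numeric(pml$logLik), tolerance = 1e-6)
})

test_that("marginal posteriors match brute-force enumeration", {
  set.seed(5)
  tr <- ape::read.tree(
    text = "((human:0.12,sp1:0.2)N1:0.15,(sp2:0.3,sp3:0.07)N2:0.1)R;")
  rows <- stats::setNames(
    vapply(1:4, function(i)
      paste(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = ""),
      character(1)),
    c("human", "sp1", "sp2", "sp3"))
  mp <- marginal_posteriors(tr, rows, subst_model("JC"))
  for (lab in c("N1", "N2", "R")) {
    expect_lt(max(abs(mp[[lab]] - brute_marginal_jc(tr, rows, lab))), 1e-10)
    expect_equal(colSums(mp[[lab]]), rep(1, 10), tolerance = 1e-9)
  }
})

test_that("three-leaf single-site posterior equals direct enumeration", {
  tr <- ape::read.tree(text = "((human:0.1,sp1:0.1)N1:0.2,sp2:0.3)R;")
  rows <- c(human = "A", sp1 = "A", sp2 = "C")
  mp <- marginal_posteriors(tr, rows, subst_model("JC"))
  expect_lt(max(abs(mp[["R"]] - brute_marginal_jc(tr, rows, "R"))), 1e-10)
  # the shared tip state dominates the cherry ancestor
  expect_identical(unname(which.max(mp[["N1"]][, 1])), 1L)
})

test_that("ancestors of identical cherries reproduce the leaves", {
  tr <- ape::read.tree(text = "((human:0.1,sp1:0.1)N1:0.2,sp2:0.3)R;")
  msa <- c(human = "ACGTACGTACGTACG", sp1 = "ACGTACGTACGTACG",
           sp2 = "ACGTACGTACGTACG")
  prof <- reconstruct_ancestors(msa, tr, targets = c("N1", "R"))
  expect_identical(prof[[1]]$sequence, msa[["human"]])
  expect_identical(prof[[2]]$sequence, msa[["human"]])
  expect_true(all(prof[[1]]$site_posteriors > 0.25))
  expect_error(reconstruct_ancestors(msa, tr, targets = "NX"), "target")
})

test_that("a clade-wide gap reconstructs as absent in the clade ancestor", {
  tr <- ape::read.tree(
    text = paste0("((((human:0.05,sp1:0.05)N1:0.05,sp2:0.05)N2:0.05,",
                  "sp3:0.05)N3:0.05,(sp4:0.05,sp5:0.05)X1:0.05)R;"))
  base <- strrep("ACGTACGTACGT", 2)
  gapped <- paste0(substr(base, 1, 9), "------", substr(base, 16, 24))
  msa <- c(human = gapped, sp1 = gapped, sp2 = gapped, sp3 = base,
           sp4 = base, sp5 = base)
  prof <- reconstruct_ancestors(msa, tr, targets = c("N1", "N2", "N3"))
  for (p in prof) names(p$present) <- NULL
  expect_false(any(prof[[1]]$present[10:15]))  # N1: gap columns absent
  expect_false(any(prof[[2]]$present[10:15]))  # N2 spans only gapped leaves
  expect_true(all(prof[[3]]$present[1:9]))
  expect_true(all(vapply(prof, function(p)
    all(p$indel_posteriors >= 0 & p$indel_posteriors <= 1), logical(1))))
})

test_that("branch lengths on simulated data recover generating lengths", {
  set.seed(33)
  errs <- numeric(6)
  for (r in seq_along(errs)) {
    tr <- simulate_tree(5, seed = 100 + r, mean_branch_length = 0.08)
    reg <- evolve_region(tr, 3000, ancestor_path(tr)[4],
                         sim_params(indel_rate = 0), seed = 200 + r)
    fit <- fit_branch_lengths(reg$sequences, tr, "JC")
    errs[r] <- abs(sum(fit$tree$edge.length) - sum(tr$edge.length)) /
      sum(tr$edge.length)
  }
  expect_lt(stats::median(errs), 0.2)
})

test_that("GTR+G machinery yields valid probabilities and likelihoods", {
  m <- subst_model("GTRG", rates = c(1, 2, 1, 1, 2, 1),
                   freqs = c(0.3, 0.2, 0.2, 0.3), alpha = 0.5)
  P <- m$pmat(0.1, m$cat_rates[2])
  expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-10)
  expect_true(all(P >= 0))
  tr <- ape::read.tree(text = "((human:0.1,sp1:0.1)N1:0.2,sp2:0.3)R;")
  msa <- c(human = "ACGTACGTAC", sp1 = "ACGTACGTAC", sp2 = "ACGGACGTAC")
  ll <- tree_loglik(tr, msa, m)$loglik
  expect_true(is.finite(ll) && ll < 0)
  fit <- fit_branch_lengths(msa, tr, "GTRG", max_sweeps = 3)
  expect_s3_class(fit, "fitted_tree")
})
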