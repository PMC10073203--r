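cfg <- pipeline_config()

test_that("origin combination takes the more recent node, with exception", {
  tr <- simulate_tree(8, seed = 19)
  # recent ORF (N4), ancient transcription (root N7) -> ORF node wins
  a1 <- combine_origin("N4", "N7", tr, config = cfg)
  expect_identical(a1$putative_origin_node, "N4")
  expect_identical(a1$combination_rule, "most_recent_of_two")

  # ancient ORF, human-specific transcription, weak coding -> human branch
  a2 <- combine_origin("N2", "human", tr, coding_score = 5, config = cfg)
  expect_identical(a2$putative_origin_node, "human")

  # same but coding score above the exception threshold -> ORF origin
  a3 <- combine_origin("N2", "human", tr, coding_score = 10.5, config = cfg)
  expect_identical(a3$putative_origin_node, "N2")
  expect_identical(a3$combination_rule, "coding_signal_exception")
  # threshold is strict: exactly 10 does not trigger
  a4 <- combine_origin("N2", "human", tr, coding_score = 10, config = cfg)
  expect_identical(a4$putative_origin_node, "human")

  # the putative origin is never more ancient than the ORF origin
  path <- ancestor_path(tr)
  age <- function(x) if (x == "human") 0L else match(x, path)
  set.seed(27)
  for (rep in 1:20) {
    orf <- sample(c("human", path), 1)
    txn <- sample(c("human", path), 1)
    sc <- sample(c(NA, 5, 50), 1)
    a <- combine_origin(orf, txn, tr, coding_score = sc, config = cfg)
    expect_lte(age(a$putative_origin_node), age(orf))
  }

  expect_error(combine_origin("N4", "Nope", tr, config = cfg),
               "ancestor path")
})

test_that("ORF properties are computed from sequence and translation", {
  p <- compute_properties("ATGTTTTAA", orf_id = "x", class_label = "new")
  expect_equal(p$gc_fraction, 1 / 9)   # one G, no C
  expect_equal(p$aromatic_fraction, 1 / 2)  # residues M, F
  expect_equal(p$hydrophobic_fraction, 1)   # M and F both hydrophobic
  expect_equal(p$length_nt, 9L)

  expect_error(compute_properties("ATGTAATTTTAA", class_label = "new"),
               "internal stop")
  expect_error(compute_properties("ATGTTTT", class_label = "new"),
               "multiple of 3")
  # the 33-nt minimum ORF length is accepted
  p33 <- compute_properties(paste0("ATG", strrep("GCC", 9), "TAA"),
                            class_label = "upstream")
  expect_equal(p33$length_nt, 33L)
  expect_equal(compute_properties(paste0(strrep("GGC", 10), "TAA"),
                                  class_label = "new")$gc_fraction,
               30 / 33, tolerance = 1e-12)
})

test_that("group comparisons match exact permutation enumeration", {
  rec <- data.frame(gc = c(1, 2, 3, 4, 10, 11, 12, 13))
  grp <- rep(c("a", "b"), each = 4)
  res <- compare_groups(rec, grp, properties = "gc")
  expect_equal(res$wilcoxon_p, perm_wilcox_p(rec$gc[1:4], rec$gc[5:8]),
               tolerance = 1e-12)

  # identical groups: exact two-sided p = 1
  rec2 <- data.frame(gc = c(1, 2, 3, 11, 1, 2, 3, 11))
  expect_equal(compare_groups(rec2, grp, properties = "gc")$wilcoxon_p, 1)

  # random small fixtures against the permutation oracle
  set.seed(31)
  for (rep in 1:10) {
    x <- sample(100, 4); y <- sample(200, 4)
    rec3 <- data.frame(gc = c(x, y))
    res3 <- compare_groups(rec3, grp, properties = "gc")
    expect_equal(res3$wilcoxon_p, perm_wilcox_p(x, y), tolerance = 1e-9,
                 label = paste(c(x, y), collapse = ","))
  }

  # perfectly ordered property vs age: rho = 1
  rec4 <- data.frame(gc = 1:8)
  res4 <- compare_groups(rec4, grp, properties = "gc", age = 1:8)
  expect_equal(res4$spearman_rho, 1)

  # Spearman p against permutation enumeration (n = 6, tie-free)
  set.seed(32)
  x <- sample(50, 6); y <- sample(50, 6)
  rec5 <- data.frame(gc = x)
  res5 <- compare_groups(rec5, rep(c("a", "b"), 3), properties = "gc",
                         age = y)
  expect_equal(res5$spearman_p, perm_spearman_p(x, y), tolerance = 1e-9)

  # constant property flagged
  rec6 <- data.frame(gc = rep(2, 8))
  res6 <- compare_groups(rec6, grp, properties = "gc", age = 1:8)
  expect_identical(res6$flag, "constant property")
  expect_true(is.na(res6$spearman_rho))
})

test_that("2x2 chi-square matches direct computation and known values", {
  tab <- matrix(c(44, 111, 156, 404), 2, 2, byrow = TRUE)
  res <- chi_square_2x2(tab, yates = TRUE)
  expect_equal(round(res$p_value, 2), 0.98)

  bal <- chi_square_2x2(matrix(10, 2, 2))
  expect_equal(bal$statistic, 0)
  expect_equal(bal$p_value, 1)

  # yates = FALSE equals the manual expected-count formula
  set.seed(35)
  for (rep in 1:5) {
    t2 <- matrix(sample(5:60, 4), 2, 2)
    exp_counts <- outer(rowSums(t2), colSums(t2)) / sum(t2)
    manual <- sum((t2 - exp_counts)^2 / exp_counts)
    res2 <- chi_square_2x2(t2, yates = FALSE)
    expect_equal(res2$statistic, manual, tolerance = 1e-12)
    # the continuity correction only reduces the statistic
    expect_lte(chi_square_2x2(t2, yates = TRUE)$statistic, res2$statistic)
  }

  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2, 2)), "marginal")
  expect_error(chi_square_2x2(matrix(1:6, 2, 3)), "2x2")
})

test_that("reports carry per-ORF origins and cutoff sensitivity", {
  b <- simulate_bundle(6, 90, birth_node = "N3", txn_node = "N2", seed = 37,
                       params = sim_params(dropout = 0, noise_prob = 0))
  res <- suppressWarnings(suppressMessages(run_pipeline(
    b$region$sequences, b$tree, b$expression$evidence, orf_id = "sim1")))
  d <- withr::local_tempdir()
  paths <- render_report(list(res), d)
  tab <- utils::read.delim(paths[["orfs"]])
  expect_equal(nrow(tab), 1L)
  expect_true(all(c("origin_cutoff_0.5", "origin_cutoff_0.7",
                    "origin_cutoff_0.8", "putative_origin_node") %in%
                  names(tab)))
  js <- jsonlite::read_json(paths[["summary"]])
  expect_equal(js$n_orfs, 1L)
  expect_error(render_report(list(list(assignment = res$assignment)), d),
               "missing upstream")
  expect_error(render_report(list(), d), "no pipeline results")

  # deterministic under a fixed seed
  res2 <- suppressWarnings(suppressMessages(run_pipeline(
    b$region$sequences, b$tree, b$expression$evidence, orf_id = "sim1")))
  d2 <- withr::local_tempdir()
  paths2 <- render_report(list(res2), d2)
  expect_identical(readLines(paths[["orfs"]]), readLines(paths2[["orfs"]]))
})
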