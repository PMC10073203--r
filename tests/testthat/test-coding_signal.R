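test_that("codon alignments preserve frame and round-trip inputs", {
  seqs <- c(human = "ATGGCTGCTAAAGCTTGG", sp1 = "ATGGCTGCTAAAGCTTGG",
            sp2 = "ATGGCTGCTAAAGCTTGG")
  ca <- build_codon_alignment(seqs)
  expect_false(any(grepl("-", ca$rows, fixed = TRUE)))

  # a 3-nt deletion becomes a single 3-gap run
  del <- c(human = "ATGGCTGCTAAAGCTTGG", sp1 = "ATGGCTAAAGCTTGG")
  cad <- build_codon_alignment(del)
  gaps <- gregexpr("-+", cad$rows[["sp1"]])[[1]]
  expect_equal(attr(gaps, "match.length"), 3L)

  # round trip and translate-backthread identity on random indel fixtures
  set.seed(20)
  for (rep in 1:10) {
    fam <- random_indel_family("ATGGCTAAAGCTTGGTGCGATCACGGTACC", 4)
    ca2 <- build_codon_alignment(fam)
    for (nm in names(fam)) {
      expect_identical(ungap_codon_row(ca2, nm), fam[[nm]])
      expect_identical(translate_orf(gsub("-", "", ca2$rows[[nm]])),
                       gsub("-", "", ca2$peptides[[nm]]))
    }
    runs <- unlist(lapply(ca2$rows, function(r) {
      g <- gregexpr("-+", r)[[1]]
      if (g[1] == -1) integer(0) else attr(g, "match.length")
    }))
    expect_true(all(runs %% 3L == 0L))
  }

  expect_error(build_codon_alignment(c(human = "ATGG", sp1 = "ATGGCT")),
               "multiple of 3")
  expect_warning(
    expect_error(build_codon_alignment(c(human = "ATGGCT", sp1 = "AT")),
                 "at least 2"),
    "shorter")
})

test_that("reference-gap removal leaves the reference ungapped", {
  seqs <- c(human = "ATGGCTAAAGCT", sp1 = "ATGGCTCCCAAAGCT")
  ca <- build_codon_alignment(seqs, remove_ref_gaps = TRUE)
  expect_false(grepl("-", ca$rows[["human"]], fixed = TRUE))
  expect_equal(nchar(ca$rows[["human"]]), 12L)
})

test_that("stop stripping removes whole codon columns and is idempotent", {
  seqs <- c(human = "ATGGCTTGCAAAGCTCAC", sp1 = "ATGGCTTGAAAAGCTCAC")
  ca <- build_codon_alignment(seqs)
  st <- strip_inframe_stops(ca)
  expect_equal(nchar(st$rows[[1]]), nchar(ca$rows[[1]]) - 3L)
  expect_identical(st$rows[["human"]], "ATGGCTAAAGCTCAC")
  st2 <- strip_inframe_stops(st)
  expect_identical(st2$rows, st$rows)

  allstop <- build_codon_alignment(c(human = "TGA", sp1 = "TAA"))
  expect_warning(empty <- strip_inframe_stops(allstop), "all codon columns")
  expect_equal(nchar(empty$rows[[1]]), 0L)
})

test_that("hexamer scores behave as a log-likelihood ratio", {
  ht <- hexamer_table("ATGGCTGCTAAAGCTTGGTGC")
  expect_equal(hexamer_score("ATGGCTGCTAAA", ht, ht), 0)

  # 9-nt sequence with two in-frame hexamers at ratios 2 and 0.5
  seq <- "ATGGCTAAA"
  coding <- noncoding <- hexamer_table(character(0))
  coding["ATGGCT"] <- 2 * noncoding["ATGGCT"]
  coding["GCTAAA"] <- 0.5 * noncoding["GCTAAA"]
  expect_equal(hexamer_score(seq, coding, noncoding),
               mean(c(log(2), log(0.5))), tolerance = 1e-12)
  expect_error(hexamer_score("ATG", ht, ht), "at least 6")

  # sequences sampled from the coding table score positive
  set.seed(23)
  train_coding <- vapply(1:40, function(i)
    paste(sample(c("A", "C", "G"), 300, TRUE, prob = c(0.5, 0.3, 0.2)),
          collapse = ""), character(1))
  train_nc <- vapply(1:40, function(i)
    paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = ""),
    character(1))
  ct <- hexamer_table(train_coding)
  nt <- hexamer_table(train_nc)
  draws <- vapply(1:50, function(i) {
    s <- paste(sample(c("A", "C", "G"), 300, TRUE, prob = c(0.5, 0.3, 0.2)),
               collapse = "")
    hexamer_score(s, ct, nt)
  }, numeric(1))
  expect_gte(mean(draws > 0), 0.95)

  # additivity: score of a concatenation is the weighted mean of the parts
  a <- "ATGGCTGCTAAA"; b <- "TGGTGCGATCAC"
  na <- (nchar(a) - 3) / 3; nb <- (nchar(b) - 3) / 3  # hexamer counts
  joint <- hexamer_score(paste0(a, b), ct, nt)
  parts <- (na * hexamer_score(a, ct, nt) + hexamer_score(b, ct, nt) * nb +
            hexamer_score(paste0(substr(a, nchar(a) - 2, nchar(a)),
                                 substr(b, 1, 3)), ct, nt)) / (na + nb + 1)
  expect_equal(joint, parts, tolerance = 1e-12)
})

test_that("the builtin coding score is zero for identical rows", {
  seqs <- c(human = strrep("ATGGCTAAAGCTTGGTGC", 2),
            sp1 = strrep("ATGGCTAAAGCTTGGTGC", 2))
  tr <- ape::read.tree(text = "(human:0.05,sp1:0.05)R;")
  ca <- build_codon_alignment(seqs)
  cs <- coding_score(ca, tr)
  expect_equal(cs$score, 0, tolerance = 1e-3)
  single <- structure(list(rows = c(human = "ATGGCT"),
                           peptides = c(human = "MA"),
                           tails = c(human = ""), reference = "human"),
                      class = "codon_alignment")
  expect_error(coding_score(single, tr), "at least 2 rows")
})

test_that("synonymous-only divergence yields omega near zero, score > 0", {
  # third-position synonymous changes only (4-fold degenerate codons)
  h <- paste(rep(c("GCT", "GGT", "CCT", "ACT", "GTT", "CGT"), 4),
             collapse = "")
  s1 <- paste(rep(c("GCC", "GGA", "CCG", "ACC", "GTA", "CGG"), 4),
              collapse = "")
  s2 <- paste(rep(c("GCA", "GGC", "CCA", "ACG", "GTC", "CGA"), 4),
              collapse = "")
  tr <- ape::read.tree(text = "((human:0.2,sp1:0.2)N1:0.1,sp2:0.3)R;")
  ca <- build_codon_alignment(c(human = h, sp1 = s1, sp2 = s2))
  cs <- coding_score(ca, tr)
  expect_lt(cs$omega, 0.05)
  expect_gt(cs$score, 0)

  # row-order invariance
  ca2 <- build_codon_alignment(c(sp2 = s2, human = h, sp1 = s1))
  cs2 <- coding_score(ca2, tr)
  expect_equal(cs$score, cs2$score, tolerance = 1e-4)
})

test_that("the external adapter passes scores through", {
  f <- withr::local_tempfile()
  writeLines("-54.3", f)
  cs <- coding_score(NULL, scorer = "external", external_path = f)
  expect_equal(cs$score, -54.3)

  writeLines(c("orfA\t12.5", "orfB\t-3.25"), f)
  expect_equal(parse_external_score(f, "orfB"), -3.25)
  expect_error(parse_external_score(f, "orfC"), "not in score file")
})

test_that("frame scanning labels six frames and finds planted signal", {
  set.seed(26)
  h <- paste(rep(c("GCT", "GGT", "CCT", "ACT"), 5), collapse = "")
  s1 <- paste(rep(c("GCC", "GGA", "CCG", "ACA"), 5), collapse = "")
  tr <- ape::read.tree(text = "(human:0.2,sp1:0.2)R;")
  fs <- suppressWarnings(frame_scan(c(human = h, sp1 = s1), tr))
  expect_setequal(names(fs), c("+1", "+2", "+3", "-1", "-2", "-3"))
  expect_identical(unique(vapply(fs, `[[`, character(1), "frame")),
                   names(fs))
  # the synonymous constraint was planted in +1
  scores <- vapply(fs, `[[`, numeric(1), "score")
  expect_identical(names(which.max(scores)), "+1")
  # consistency with the single-frame call
  ca <- build_codon_alignment(c(human = h, sp1 = s1))
  expect_equal(fs[["+1"]]$score, coding_score(ca, tr)$score,
               tolerance = 1e-6)
})

test_that("Nei-Gojobori counting matches hand-enumerated pathways", {
  # TTT (Phe) vs TTA (Leu): single nonsynonymous difference
  tr_rows <- c(human = "TTT", sp1 = "TTA")
  ca <- build_codon_alignment(tr_rows)
  om <- global_dnds(ca)
  cnt <- attr(om, "counts")
  expect_equal(unname(cnt["Nd"]), 1)
  expect_equal(unname(cnt["Sd"]), 0)
  # hand enumeration of sites: TTT -> positions 1,2 fully nonsynonymous;
  # position 3: TTC synonymous, TTA/TTG nonsynonymous => S = 1/3
  s_ttt <- 1 / 3
  # TTA -> position 1: CTA syn, ATA/GTA nonsyn => 1/3; position 2 nonsyn
  # (TAA/TGA stops excluded, TCA nonsyn => 0/1); position 3: TTG syn,
  # TTC/TTT nonsyn => 1/3
  s_tta <- 1 / 3 + 0 + 1 / 3
  expect_equal(unname(cnt["S"]), (s_ttt + s_tta) / 2, tolerance = 1e-12)
  expect_true(is.na(om) &&
              attr(om, "flag") == "no synonymous substitutions")

  # synonymous-only pair: omega = 0
  ca2 <- build_codon_alignment(c(human = "GCTGGT", sp1 = "GCCGGA"))
  expect_equal(as.numeric(global_dnds(ca2)), 0)

  # identical rows: flagged NA
  ca3 <- build_codon_alignment(c(human = "GCTGGT", sp1 = "GCTGGT"))
  om3 <- global_dnds(ca3)
  expect_true(is.na(om3) && attr(om3, "flag") == "no substitutions")

  # two-step pathway averaging: TTT vs GTA
  ca4 <- build_codon_alignment(c(human = "TTT", sp1 = "GTA"))
  cnt4 <- attr(global_dnds(ca4), "counts")
  # paths TTT->GTT->GTA (nonsyn, syn is false: F->V->V: nonsyn then syn)
  # and TTT->TTA->GTA (F->L->V: nonsyn, nonsyn); average Sd = 0.5, Nd = 1.5
  expect_equal(unname(cnt4["Sd"]), 0.5)
  expect_equal(unname(cnt4["Nd"]), 1.5)
})
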