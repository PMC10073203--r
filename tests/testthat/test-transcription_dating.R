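cfg <- pipeline_config()

test_that("annotation-overlap presence uses the 80% boundary inclusively", {
  ev <- expression_evidence("o", annotation_overlap = c(
    chimp = 0.80, gorilla = 0.79, mouse = 1.0))
  expect_setequal(presence_from_annotation(ev, cfg), c("chimp", "mouse"))
  expect_length(presence_from_annotation(expression_evidence("o"), cfg), 0L)
})

test_that("sequence-match presence applies both thresholds", {
  sm <- data.frame(species = c("a", "b", "c"),
                   query_coverage = c(0.60, 0.59, 0.90),
                   evalue = c(1e-3, 1e-9, 1e-2))
  ev <- expression_evidence("o", sequence_match = sm)
  expect_identical(presence_from_sequence(ev, cfg), "a")
})

# hand-built escalation fixture on a 16-leaf pectinate tree:
# transcribed clade is {human..sp3} (gain at N3); six outgroups carry
# between-threshold noise so P(0.1) reaches the root with A(0.1) = 6;
# at 1 TPM only {human, sp3} remain, leaving A(1.0) = 2.
confusion_evidence <- function(shared_tissue = FALSE) {
  tissues_for <- function(i) {
    if (shared_tissue) "liver" else paste0("t", i)
  }
  rows <- list(
    data.frame(species = "human", tissue = "liver", tpm = 5),
    data.frame(species = "sp1", tissue = tissues_for(1), tpm = 0.5),
    data.frame(species = "sp2", tissue = tissues_for(2), tpm = 0.5),
    data.frame(species = "sp3", tissue = "liver", tpm = 5))
  noisy <- paste0("sp", c(5, 7, 9, 11, 13, 15))
  for (k in seq_along(noisy))
    rows[[length(rows) + 1]] <- data.frame(
      species = noisy[k],
      tissue = if (shared_tissue && k <= 5) "liver" else paste0("n", k),
      tpm = 0.5)
  for (sp in paste0("sp", c(4, 6, 8, 10, 12, 14)))
    rows[[length(rows) + 1]] <- data.frame(species = sp, tissue = "liver",
                                           tpm = 0)
  expression_evidence("o", tpm = do.call(rbind, rows))
}

test_that("the TPM threshold escalates on sparse, tissue-scattered patterns", {
  tr <- simulate_tree(16, seed = 8)
  ev <- confusion_evidence(shared_tissue = FALSE)
  # fixture arithmetic: A(0.1) = 6, A(1.0) = 2, shared-tissue share 0.3
  res <- presence_from_expression(ev, tr, cfg)
  expect_true(res$escalated)
  expect_equal(res$threshold_used, 1.0)
  expect_setequal(res$species, c("human", "sp3"))
  expect_identical(dollo_age(tr, res$species), "N3")

  # same counts, but presences share one tissue -> cutoff maintained
  ev2 <- confusion_evidence(shared_tissue = TRUE)
  sub <- ev2$tpm[ev2$tpm$tpm >= 0.1, ]
  expect_gte(max(table(sub$tissue)) / length(unique(sub$species)), 0.8)
  res2 <- presence_from_expression(ev2, tr, cfg)
  expect_false(res2$escalated)
  expect_equal(res2$threshold_used, 0.1)
  expect_identical(dollo_age(tr, res2$species), "N15")  # inflated by noise
})

test_that("clean patterns keep the 0.1 TPM cutoff", {
  tr <- simulate_tree(8, seed = 9)
  tpm <- rbind(
    data.frame(species = c("human", "sp1", "sp2"), tissue = "brain",
               tpm = c(3, 0.2, 1.5)),
    data.frame(species = c("sp5", "sp6"), tissue = "brain", tpm = 0.05))
  res <- presence_from_expression(expression_evidence("o", tpm = tpm), tr,
                                  cfg)
  expect_false(res$escalated)
  expect_setequal(res$species, c("human", "sp1", "sp2"))
})

test_that("escalation only ever shrinks the presence set", {
  set.seed(14)
  tr <- simulate_tree(12, seed = 10)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    tpm <- data.frame(
      species = sample(tr$tip.label, n),
      tissue = sample(c("brain", "liver", "heart"), n, TRUE),
      tpm = stats::runif(n, 0, 3))
    ev <- expression_evidence("o", tpm = tpm)
    res <- presence_from_expression(ev, tr, cfg)
    p_low <- names(which(tapply(tpm$tpm, tpm$species, max) >= 0.1))
    expect_true(all(res$species %in% p_low))
  }
})

test_that("Dollo dating equals brute-force single-gain placement", {
  expect_identical(dollo_age(simulate_tree(6, seed = 3), "human"), "human")
  tr <- simulate_tree(8, seed = 12)
  expect_identical(dollo_age(tr, tr$tip.label), "N7")
  expect_error(dollo_age(tr, "notaspecies"), "not in tree")

  trees <- list(tr,
                ape::read.tree(text = paste0(
                  "(((human:1,sp1:1)N1:1,(sp2:1,sp3:1)X1:1)N2:1,",
                  "((sp4:1,sp5:1)X2:1,sp6:1)X3:1)R;")))
  for (t in trees) {
    others <- setdiff(t$tip.label, "human")
    for (k in 1:min(6, length(others))) {
      sets <- utils::combn(others, k, simplify = FALSE)
      for (s in sets) {
        expect_identical(dollo_age(t, s), brute_dollo(t, s),
                         label = paste(s, collapse = ","))
      }
    }
  }
})

test_that("channel union drives transcription dating", {
  tr <- simulate_tree(8, seed = 15)
  ev <- expression_evidence(
    "o",
    tpm = data.frame(species = "sp3", tissue = "brain", tpm = 2),
    annotation_overlap = c(sp1 = 0.9),
    sequence_match = data.frame(species = "sp2", query_coverage = 0.8,
                                evalue = 1e-6))
  res <- date_transcription(ev, tr, cfg)
  expect_setequal(res$present_species, c("human", "sp1", "sp2", "sp3"))
  expect_identical(res$origin_node, "N3")
  expect_identical(res$channels[["sp2"]], "sequence")
  expect_identical(res$channels[["sp3"]], "expression")

  empty <- date_transcription(expression_evidence("o"), tr, cfg)
  expect_identical(empty$origin_node, "human")
})

test_that("adding evidence to a channel never makes the origin younger", {
  tr <- simulate_tree(10, seed = 16)
  path <- c(human = 0L,
            stats::setNames(seq_along(ancestor_path(tr)), ancestor_path(tr)))
  ev <- expression_evidence(
    "o", annotation_overlap = c(sp2 = 0.9, sp4 = 0.95))
  base_age <- path[[date_transcription(ev, tr, cfg)$origin_node]]
  for (extra in c("sp1", "sp6", "sp9")) {
    ov <- c(ev$annotation_overlap, stats::setNames(0.9, extra))
    ev2 <- expression_evidence("o", annotation_overlap = ov)
    expect_gte(path[[date_transcription(ev2, tr, cfg)$origin_node]],
               base_age)
  }
})

test_that("planted transcription gains are recovered without noise", {
  hit <- 0
  for (i in 1:20) {
    tr <- simulate_tree(9, seed = 300 + i)
    gain <- sample(ancestor_path(tr), 1)
    sim <- simulate_transcription(
      tr, gain, c("brain", "liver"),
      sim_params(dropout = 0, noise_prob = 0), seed = 400 + i)
    res <- date_transcription(sim$evidence, tr, cfg)
    if (res$origin_node == gain) hit <- hit + 1
  }
  expect_equal(hit, 20L)
})

test_that("with dropout the estimate is a lower bound on the true age", {
  set.seed(18)
  exact <- 0; n_rep <- 60
  for (i in 1:n_rep) {
    tr <- simulate_tree(10, seed = 500 + i)
    path <- ancestor_path(tr)
    gain <- sample(path, 1)
    p <- sim_params(dropout = stats::runif(1, 0, 0.2), noise_prob = 0.5)
    sim <- simulate_transcription(tr, gain, c("brain", "liver"), p,
                                  seed = 600 + i)
    res <- date_transcription(sim$evidence, tr, cfg)
    age <- function(x) if (x == "human") 0L else match(x, path)
    expect_lte(age(res$origin_node), age(gain))
    if (res$origin_node == gain) exact <- exact + 1
  }
  expect_gte(exact / n_rep, 0.8)
})
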