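test_that("experiment scale labels split at 100 associations", {
  expect_identical(label_scale(100), "small_scale")
  expect_identical(label_scale(101), "high_throughput")
  expect_identical(label_scale(1), "small_scale")
  expect_identical(label_scale(c(50, 5000)),
                   c("small_scale", "high_throughput"))
})

# A small corpus with known scale/compartment structure.
gold_fixture <- function() {
  ints <- list(
    # one small-scale experiment among large ones: positive
    bi("A1", "A2", evidence = list(ev("1", scale = 5000L),
                                   ev("2", scale = 80L))),
    # all high-throughput, disjoint compartments: negative
    bi("B1", "B2", evidence = list(ev("3", scale = 5000L))),
    bi("B3", "B4", evidence = list(ev("4", scale = 200L))),
    # all high-throughput but compartments overlap: excluded
    bi("C1", "C2", evidence = list(ev("5", scale = 5000L))),
    # all high-throughput, one protein unannotated: excluded
    bi("D1", "D2", evidence = list(ev("6", scale = 5000L))),
    # more positives so the balanced draw can happen
    bi("E1", "E2", evidence = list(ev("7", scale = 10L))),
    bi("E3", "E4", evidence = list(ev("8", scale = 100L))))
  ctx <- annotation_context(compartments = data.frame(
    protein = c("B1", "B2", "B3", "B4", "C1", "C2", "D1"),
    compartment = c("nucleus", "membrane", "nucleus", "cytoplasm",
                    "nucleus", "nucleus", "nucleus")))
  list(ints = ints, ctx = ctx)
}

test_that("gold standard applies the scale and compartment rules", {
  fx <- gold_fixture()
  gold <- build_gold_standard(fx$ints, fx$ctx, seed = 1L)
  expect_identical(gold$negatives, c("B1|B2", "B3|B4"))
  expect_length(gold$positives, 2L)  # balanced to the negative count
  expect_identical(gold$n_positive_pool, 3L)
  expect_true(all(gold$positives %in% c("A1|A2", "E1|E2", "E3|E4")))
  # no overlap between the sets
  expect_length(intersect(gold$positives, gold$negatives), 0L)
})

test_that("gold standard sampling is seed-deterministic; negatives never move", {
  fx <- gold_fixture()
  g1 <- build_gold_standard(fx$ints, fx$ctx, seed = 7L)
  g2 <- build_gold_standard(fx$ints, fx$ctx, seed = 7L)
  expect_identical(g1, g2)
  g3 <- build_gold_standard(fx$ints, fx$ctx, seed = 8L)
  expect_identical(g1$negatives, g3$negatives)
})

test_that("an empty negative set is a clear error", {
  ints <- list(bi("A", "B", evidence = list(ev("1", scale = 10L))))
  expect_error(build_gold_standard(ints, annotation_context(), seed = 1L),
               class = "ppiscore_domain_error")
})

test_that("ROC handles separation, constancy and the worked tie-free case", {
  perfect <- roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_identical(perfect$auc, 1)
  constant <- roc_auc(c(1, 0, 1, 0), rep(0.5, 4))
  expect_identical(constant$auc, 0.5)
  mixed <- roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))
  expect_equal(mixed$auc, 0.75)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), class = "ppiscore_domain_error")
})

test_that("ROC curves run from (0,0) to (1,1) with monotone rates", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(10:60, 1)
    labels <- c(1, 0, stats::rbinom(n, 1, 0.4))
    scores <- round(stats::runif(n + 2), 1)  # heavy ties
    roc <- roc_auc(labels, scores)
    expect_identical(roc$points$fpr[1], 0)
    expect_identical(roc$points$tpr[1], 0)
    expect_identical(utils::tail(roc$points$fpr, 1), 1)
    expect_identical(utils::tail(roc$points$tpr, 1), 1)
    expect_true(all(diff(roc$points$fpr) >= 0))
    expect_true(all(diff(roc$points$tpr) >= 0))
  }
})

test_that("trapezoidal AUC equals the pairwise-comparison statistic", {
  set.seed(23)
  for (rep in 1:25) {
    n <- sample(10:200, 1)
    labels <- c(1, 0, stats::rbinom(n, 1, 0.5))
    scores <- sample(seq(0, 1, by = 0.05), n + 2, replace = TRUE)
    expect_equal(roc_auc(labels, scores)$auc, pairwise_auc(labels, scores),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(29)
  labels <- c(1, 0, stats::rbinom(80, 1, 0.5))
  scores <- round(stats::runif(82), 2)
  ours <- roc_auc(labels, scores)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("compare_scores ranks a label-revealing score at 1 and noise at 0.5", {
  fx <- gold_fixture()
  scored <- score_interactions(fx$ints, fx$ctx)
  # plant two synthetic score columns: one perfect, one constant
  keys <- mapply(pair_key, scored$id_a, scored$id_b)
  gold <- build_gold_standard(fx$ints, fx$ctx, seed = 1L)
  scored$oracle_score <- as.numeric(keys %in% gold$positives)
  scored$constant_score <- 0.5
  res <- compare_scores(scored, fx$ints, fx$ctx, seed = 1L,
                        score_cols = c("oracle_score", "constant_score"))
  expect_identical(res$auc[res$score == "oracle_score"], 1)
  expect_identical(res$auc[res$score == "constant_score"], 0.5)
})
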