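test_that("publication component saturates at seven distinct publications", {
  expect_identical(publication_score(7), 1)
  expect_identical(publication_score(0), 0)
  expect_equal(publication_score(3), 3 / 7)
  expect_identical(publication_score(8), 1)
  scores <- publication_score(0:10)
  expect_true(all(diff(scores) >= 0))
  expect_true(all(diff(scores[1:8]) > 0))  # strictly increasing up to saturation
  expect_error(publication_score(-1), class = "ppiscore_domain_error")
  # a different saturation count moves the knee
  expect_identical(publication_score(3, method_score_config(
    publication_saturation = 3L)), 1)
})

test_that("single-category detection component follows the closed form", {
  cfg <- method_score_config()
  # one publication, biophysical (weight 1): 1 * min(1,7)/7
  one <- list(ev("1", methods = "surface plasmon resonance"))
  expect_equal(detection_method_score(one, cfg), 1 / 7)
  # n publications, same category: weight * min(n,7)/7
  for (n in c(2, 5, 7, 9)) {
    items <- lapply(seq_len(n), function(i)
      ev(as.character(i), methods = "pull down"))
    expect_equal(detection_method_score(items, cfg),
                 cfg$category_scores[["biochemical"]] * min(n, 7) / 7)
  }
})

test_that("mixed categories give the frequency-weighted mean times saturation", {
  cfg <- method_score_config()
  items <- list(ev("1", methods = "surface plasmon resonance"),
                ev("2", methods = "fluorescence microscopy"))
  expect_equal(detection_method_score(items, cfg),
               mean(c(1.0, 0.33)) * 2 / 7)
  # all-unknown evidence scores at the unknown weight, scaled by saturation
  unk <- lapply(1:8, function(i) ev(as.character(i), methods = "mystery assay"))
  expect_equal(detection_method_score(unk, cfg),
               cfg$category_scores[["unknown"]])
})

test_that("one publication contributes a category at most once", {
  cfg <- method_score_config()
  # the same pubmed with two biochemical sub-methods: one occurrence
  a <- list(ev("1", methods = c("pull down", "coimmunoprecipitation")))
  b <- list(ev("1", methods = "pull down"))
  expect_equal(detection_method_score(a, cfg), detection_method_score(b, cfg))
  # but two different categories from one pubmed both count
  c_ <- list(ev("1", methods = c("pull down", "two hybrid")))
  expect_equal(detection_method_score(c_, cfg),
               mean(c(1.0, 0.66)) * 2 / 7)
})

test_that("type component mirrors the method aggregation and never drops when support grows", {
  cfg <- method_score_config()
  one <- list(ev("1", types = "direct interaction"))
  expect_equal(interaction_type_score(one, cfg), 1 / 7)
  unk <- list(ev("1", types = "unknown"))
  expect_equal(interaction_type_score(unk, cfg), 0.05 / 7)
  # adding another publication of the same type never decreases the component
  prev <- 0
  for (n in 1:10) {
    items <- lapply(seq_len(n), function(i)
      ev(as.character(i), types = "physical association"))
    cur <- interaction_type_score(items, cfg)
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("scoring refuses unmerged evidence", {
  dup <- list(ev("1"), ev("1", methods = "two hybrid"))
  expect_error(detection_method_score(dup), class = "ppiscore_domain_error")
  expect_error(interaction_type_score(dup), class = "ppiscore_domain_error")
})

test_that("method score is the mean of its components and stays in bounds", {
  it <- bi("A", "B", evidence = list(
    ev("1", types = "direct interaction", methods = "surface plasmon resonance"),
    ev("2", types = "physical association", methods = "pull down"),
    ev("3", types = "association", methods = "two hybrid")))
  ms <- method_score(it)
  expect_equal(ms$total, (ms$detection + ms$type + ms$publication) / 3)
  expect_equal(ms$publication, 3 / 7)
  # empty evidence is a defined floor, not an error
  ms0 <- method_score(binary_interaction("A", "B", 9606L, list()))
  expect_identical(ms0$total, 0)
})

test_that("duplicating every evidence item through another database leaves scores unchanged", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(1:6, 1)
    items <- lapply(seq_len(n), function(i)
      ev(as.character(i),
         types = sample(c("direct interaction", "physical association",
                          "association", "unknown"), 1),
         methods = sample(c("pull down", "two hybrid", "mystery assay",
                            "fluorescence microscopy"), 1),
         dbs = "dbA"))
    mirrored <- lapply(items, function(e)
      evidence_item(e$pubmed_id, e$types, e$methods, e$scale, "dbB"))
    base <- method_score(binary_interaction("A", "B", 9606L, items))
    infl <- method_score(binary_interaction("A", "B", 9606L,
                                            c(items, mirrored)))
    expect_equal(infl$total, base$total)
    expect_equal(infl$detection, base$detection)
    expect_equal(infl$type, base$type)
  }
})

test_that("all components stay within [0, 1] for random evidence sets", {
  set.seed(13)
  methods_pool <- c("pull down", "two hybrid", "surface plasmon resonance",
                    "fluorescence microscopy", "junk term")
  types_pool <- c("direct interaction", "physical association",
                  "association", "unknown")
  for (rep in 1:40) {
    n <- sample(1:12, 1)
    items <- lapply(seq_len(n), function(i)
      ev(as.character(i),
         types = sample(types_pool, sample(1:2, 1)),
         methods = sample(methods_pool, sample(1:2, 1)),
         scale = sample(c(1L, 1000L), 1)))
    ms <- method_score(binary_interaction("A", "B", 9606L, items))
    for (v in c(ms$detection, ms$type, ms$publication, ms$total)) {
      expect_gte(v, 0)
      expect_lte(v, 1)
    }
  }
})

test_that("adding top-weight evidence never decreases any component", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(1:8, 1)
    items <- lapply(seq_len(n), function(i)
      ev(as.character(i),
         types = sample(c("physical association", "association", "unknown"), 1),
         methods = sample(c("two hybrid", "mystery assay"), 1)))
    extra <- ev("999", types = "direct interaction",
                methods = "surface plasmon resonance")
    before <- method_score(binary_interaction("A", "B", 9606L, items))
    after <- method_score(binary_interaction("A", "B", 9606L,
                                             c(items, list(extra))))
    expect_gte(after$detection, before$detection)
    expect_gte(after$type, before$type)
    expect_gte(after$publication, before$publication)
    expect_gte(after$total, before$total)
  }
})
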