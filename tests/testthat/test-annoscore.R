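test_that("feature extraction reads domain pairs, shared GO terms and interologs", {
  ctx <- small_context()
  f12 <- extract_features(bi("P1", "P2"), ctx)
  expect_true(f12$has_interacting_domains)   # (PF00001, PF00002) is listed
  expect_true(f12$shares_go_term)            # GO:0005634 shared
  expect_false(f12$has_homologous_interaction)

  f13 <- extract_features(bi("P1", "P3"), ctx)
  expect_false(f13$has_interacting_domains)  # (PF00001, PF00009) not listed
  expect_false(f13$shares_go_term)
  expect_true(f13$has_homologous_interaction)

  # an entirely unannotated protein contributes empty sets: all false
  f <- extract_features(bi("P1", "Q_UNANNOTATED"), ctx)
  expect_false(any(unlist(f)))
})

test_that("feature extraction is symmetric in the pair", {
  ctx <- small_context()
  for (pr in list(c("P1", "P2"), c("P1", "P3"), c("P2", "P4"))) {
    expect_identical(extract_features(bi(pr[1], pr[2]), ctx),
                     extract_features(bi(pr[2], pr[1]), ctx))
  }
})

test_that("GO aspect restriction narrows sharing", {
  ctx_c <- annotation_context(
    go = data.frame(protein = c("P1", "P2"), term = c("GO:1", "GO:1"),
                    aspect = c("F", "F")),
    go_aspects = "C")
  expect_false(extract_features(bi("P1", "P2"), ctx_c)$shares_go_term)
})

test_that("the default likelihood table gives the 0.163 no-feature baseline", {
  none <- list(has_interacting_domains = FALSE, shares_go_term = FALSE,
               has_homologous_interaction = FALSE)
  lr <- likelihood_ratio(none)
  expect_equal(lr, 0.163, tolerance = 1e-9)
  expect_equal(annotation_score(lr), 0.163 / 1.163, tolerance = 1e-9)
})

test_that("product mode multiplies per-feature likelihood ratios", {
  cfg <- annotation_config(present_lr = c(domains = 10, go = 2, homology = 3),
                           absent_lr = c(domains = 0.6, go = 0.7,
                                         homology = 0.8))
  f <- list(has_interacting_domains = TRUE, shares_go_term = FALSE,
            has_homologous_interaction = FALSE)
  expect_equal(likelihood_ratio(f, cfg), 10 * 0.7 * 0.8)
})

test_that("likelihood ratio is monotone over all 8 feature combinations", {
  combos <- expand.grid(d = c(FALSE, TRUE), g = c(FALSE, TRUE),
                        h = c(FALSE, TRUE))
  lrs <- apply(combos, 1, function(r)
    likelihood_ratio(list(has_interacting_domains = r[1],
                          shares_go_term = r[2],
                          has_homologous_interaction = r[3])))
  for (i in 1:8) for (j in 1:8)
    if (all(combos[i, ] <= combos[j, ])) expect_lte(lrs[i], lrs[j])
  # all three features present has the maximum ratio
  expect_identical(which.max(lrs), 8L)
})

test_that("explicit 8-row tables are supported and validated", {
  tab <- c(none = 0.2, domains = 3, go = 0.8, homology = 0.9,
           "domains+go" = 5, "domains+homology" = 6, "go+homology" = 2,
           "domains+go+homology" = 20)
  cfg <- annotation_config(mode = "explicit_table", table = tab)
  expect_equal(likelihood_ratio(list(has_interacting_domains = TRUE,
                                     shares_go_term = TRUE,
                                     has_homologous_interaction = FALSE),
                                cfg), 5)
  # violating monotonicity is a config error
  bad <- tab; bad[["domains+go+homology"]] <- 0.1
  expect_error(annotation_config(mode = "explicit_table", table = bad),
               class = "ppiscore_domain_error")
  # the no-feature ratio must sit below 1
  bad2 <- tab; bad2[["none"]] <- 1.5
  expect_error(annotation_config(mode = "explicit_table", table = bad2),
               class = "ppiscore_domain_error")
})

test_that("the LR-to-score mapping is increasing with the fixed point at 1", {
  expect_identical(annotation_score(1), 0.5)
  expect_lt(annotation_score(1e-6), 1e-5)
  expect_gt(annotation_score(1e6), 0.999)
  lrs <- c(0.01, 0.1, 0.5, 1, 2, 10, 100)
  expect_true(all(diff(annotation_score(lrs)) > 0))
  expect_error(annotation_score(0), class = "ppiscore_domain_error")
  expect_error(annotation_score(-2), class = "ppiscore_domain_error")
})

test_that("score > 0.5 is equivalent to LR > 1 for random valid tables", {
  set.seed(47)
  for (rep in 1:100) {
    absent <- stats::runif(3, 0.2, 0.95)
    present <- absent * stats::runif(3, 1, 30)
    cfg <- try(annotation_config(
      present_lr = stats::setNames(present, c("domains", "go", "homology")),
      absent_lr = stats::setNames(absent, c("domains", "go", "homology"))),
      silent = TRUE)
    if (inherits(cfg, "try-error")) next  # all-absent product above 1
    combos <- expand.grid(d = c(FALSE, TRUE), g = c(FALSE, TRUE),
                          h = c(FALSE, TRUE))
    for (i in 1:8) {
      lr <- likelihood_ratio(list(has_interacting_domains = combos$d[i],
                                  shares_go_term = combos$g[i],
                                  has_homologous_interaction = combos$h[i]),
                             cfg)
      expect_identical(annotation_score(lr) > 0.5, lr > 1)
    }
  }
})

test_that("annotate_interaction ties features, ratio and score together", {
  res <- annotate_interaction(bi("P1", "P2"), small_context())
  cfg <- annotation_config()
  expect_equal(res$likelihood_ratio,
               cfg$present_lr[["domains"]] * cfg$present_lr[["go"]] *
                 cfg$absent_lr[["homology"]])
  expect_equal(res$score, res$likelihood_ratio / (1 + res$likelihood_ratio))
  expect_gt(res$score, 0.5)
})
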