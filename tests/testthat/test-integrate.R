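# Brute-force role-rule oracle for complex expansion: every unordered
# member pair in which at least one member is a bait.
brute_force_spoke <- function(k, p) {
  roles <- c(rep("bait", k), rep("prey", p))
  n <- 0L
  for (i in seq_along(roles)) for (j in seq_along(roles))
    if (i < j && (roles[i] == "bait" || roles[j] == "bait")) n <- n + 1L
  n
}

test_that("spoke expansion follows the bait rule for all small complexes", {
  for (k in 0:6) for (p in 0:(6 - k)) {
    if (k + p < 2) next
    rec <- complex_record(baits = sprintf("B%d", seq_len(k)),
                          preys = sprintf("P%d", seq_len(p)))
    pairs <- spoke_expand(rec)
    expect_length(pairs, k * p + k * (k - 1) / 2)
    expect_length(pairs, brute_force_spoke(k, p))
  }
})

test_that("spoke examples: bait pairing, bait-bait edges, bait-less rejection", {
  ids <- function(pairs) sort(vapply(pairs, function(x)
    pair_key(x$a$source_id, x$b$source_id), character(1)))
  expect_identical(ids(spoke_expand(complex_record("B", c("P1", "P2")))),
                   c("B|P1", "B|P2"))
  expect_identical(ids(spoke_expand(complex_record(c("B1", "B2"), "P"))),
                   c("B1|B2", "B1|P", "B2|P"))
  expect_length(spoke_expand(complex_record(character(), c("P1", "P2", "P3"))),
                0L)
  # evidence is copied to every emitted pair
  pairs <- spoke_expand(complex_record("B", c("P1", "P2"),
                                       evidence = list(ev("99"))))
  for (pr in pairs) expect_identical(pr$evidence[[1]]$pubmed_id, "99")
})

test_that("physicality filter keeps whitelisted evidence and prunes the rest", {
  mk <- function(...) spoke_expand(binary_record("A", "B", evidence = list(...)))[[1]]
  keep <- filter_physical(mk(ev("1", types = "physical association",
                               methods = "two hybrid")))
  expect_true(keep$keep)

  gen <- filter_physical(mk(ev("1", types = "physical association",
                               methods = "genetic interference")))
  expect_false(gen$keep)
  expect_identical(gen$reason, "genetic_method")

  colo <- filter_physical(mk(ev("1", types = "colocalization")))
  expect_false(colo$keep)
  expect_identical(colo$reason, "indirect_type")

  # mixed evidence: failing items are pruned, record kept
  mixed <- filter_physical(mk(ev("1", types = "colocalization"),
                              ev("2", types = "direct interaction")))
  expect_true(mixed$keep)
  expect_length(mixed$pair$evidence, 1L)
  expect_identical(mixed$pair$evidence[[1]]$pubmed_id, "2")

  # unknown type is not evidence of indirectness
  unk <- filter_physical(mk(ev("1", types = "unknown")))
  expect_true(unk$keep)
})

test_that("protein and same-species filters reject with the right reason", {
  pr <- function(kind_b = "protein", taxon_b = 9606L)
    spoke_expand(binary_record("A", "B", taxon_b = taxon_b,
                               kind_b = kind_b))[[1]]
  expect_true(filter_protein_same_species(pr())$keep)
  cs <- filter_protein_same_species(pr(taxon_b = 10090L))
  expect_false(cs$keep)
  expect_identical(cs$reason, "cross_species")
  np <- filter_protein_same_species(pr(kind_b = "non_protein"))
  expect_false(np$keep)
  expect_identical(np$reason, "non_protein")
})

test_that("canonicalization maps via the table and rejects unmapped identifiers", {
  pair <- spoke_expand(binary_record("geneid:944988", "P2"))[[1]]
  ok <- canonicalize(pair, c("geneid:944988" = "P0A7L0", "P2" = "P2"))
  expect_true(ok$keep)
  expect_identical(ok$pair$a$canonical_id, "P0A7L0")
  miss <- canonicalize(pair, c("P2" = "P2"))
  expect_false(miss$keep)
  expect_identical(miss$reason, "unmappable_id")
  # NULL mapping treats identifiers as already canonical
  expect_identical(canonicalize(pair, NULL)$pair$a$canonical_id,
                   "geneid:944988")
})

test_that("deduplication merges symmetric pairs and unions their evidence", {
  res <- integrate_records(list(
    binary_record("A", "B", evidence = list(ev("111", dbs = "dbA"))),
    binary_record("B", "A", evidence = list(ev("111", dbs = "dbB"))),
    binary_record("A", "B", evidence = list(ev("222")))),
    min_species = 1L)
  expect_length(res$interactions, 1L)
  it <- res$interactions[[1]]
  expect_identical(it$key, "A|B")
  expect_identical(vapply(it$evidence, `[[`, character(1), "pubmed_id"),
                   c("111", "222"))
  expect_setequal(it$evidence[[1]]$source_dbs, c("dbA", "dbB"))
  expect_identical(unname(res$report$counters["duplicate"]), 2L)
})

test_that("species threshold drops species at the boundary", {
  recs <- c(
    lapply(1:10, function(i) binary_record(sprintf("A%d", i), "AX",
                                           taxon_a = 9606L)),
    lapply(1:9, function(i) binary_record(sprintf("B%d", i), "BX",
                                          taxon_a = 10090L)))
  res <- integrate_records(recs, min_species = 10L)
  expect_identical(unique(vapply(res$interactions, `[[`, integer(1), "taxon")),
                   9606L)
  expect_identical(res$census$retained, c(TRUE, FALSE))
  expect_identical(unname(res$report$counters["species_below_threshold"]), 9L)
  # min_count = 1 is the identity
  res1 <- integrate_records(recs, min_species = 1L)
  expect_length(res1$interactions, 19L)
})

test_that("every expanded pair is accounted for as accepted or rejected", {
  recs <- list(
    binary_record("A", "B"),
    binary_record("A", "C", taxon_b = 10090L),
    binary_record("A", "D", kind_b = "non_protein"),
    binary_record("E", "F", evidence = list(ev("9", types = "colocalization"))),
    complex_record("B", c("C", "D", "E")),
    complex_record(character(), c("X", "Y", "Z")))
  n_expanded <- sum(vapply(recs, function(r) length(spoke_expand(r)),
                           integer(1)))
  res <- integrate_records(recs, min_species = 1L)
  accepted_instances <- n_expanded - sum(res$report$counters[
    c("non_protein", "cross_species", "indirect_type", "genetic_method",
      "unmappable_id")])
  expect_identical(length(res$interactions),
                   accepted_instances -
                     unname(res$report$counters["duplicate"]) -
                     unname(res$report$counters["species_below_threshold"]))
  # the bait-less complex is reported as a whole-record rejection
  expect_identical(unname(res$report$counters["no_bait_complex"]), 1L)
})

test_that("integration is order-insensitive and idempotent", {
  recs <- list(
    binary_record("A", "B", evidence = list(ev("1", scale = 300L))),
    binary_record("B", "A", evidence = list(ev("2"))),
    binary_record("C", "D"),
    complex_record("E", c("F", "G")),
    binary_record("H", "H"))
  res1 <- integrate_records(recs, min_species = 1L)
  set.seed(5)
  res2 <- integrate_records(sample(recs), min_species = 1L)
  keys1 <- vapply(res1$interactions, `[[`, character(1), "key")
  expect_identical(keys1, vapply(res2$interactions, `[[`, character(1), "key"))
  expect_identical(res1$census, res2$census)

  # writing the result as MITAB and re-integrating reproduces it exactly
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mitab(res1$interactions, path)
  res3 <- integrate_records(read_mitab(path, "mitab27")$records,
                            min_species = 1L)
  expect_identical(keys1, vapply(res3$interactions, `[[`, character(1), "key"))
  expect_identical(
    lapply(res1$interactions, function(i)
      vapply(i$evidence, `[[`, character(1), "pubmed_id")),
    lapply(res3$interactions, function(i)
      vapply(i$evidence, `[[`, character(1), "pubmed_id")))
  expect_identical(lapply(res1$interactions, evidence_scales),
                   lapply(res3$interactions, evidence_scales))
})
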