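# Shared builders for small in-code fixtures.

ev <- function(pm, types = "physical association", methods = "pull down",
               scale = 1L, dbs = "dbA") {
  evidence_item(pm, types = types, methods = methods, scale = scale,
                source_dbs = dbs)
}

bi <- function(a, b, taxon = 9606L, evidence = list(ev("1"))) {
  binary_interaction(a, b, taxon, evidence)
}

# A record whose participants carry explicit roles.
complex_record <- function(baits, preys, taxon = 9606L,
                           evidence = list(ev("1"))) {
  parts <- c(
    lapply(baits, function(id) protein_ref(id, taxon, role = "bait")),
    lapply(preys, function(id) protein_ref(id, taxon, role = "prey")))
  interaction_record(parts, evidence, source_db = "dbA")
}

binary_record <- function(a, b, taxon_a = 9606L, taxon_b = taxon_a,
                          kind_a = "protein", kind_b = "protein",
                          evidence = list(ev("1")), db = "dbA") {
  interaction_record(
    list(protein_ref(a, taxon_a, molecule_kind = kind_a),
         protein_ref(b, taxon_b, molecule_kind = kind_b)),
    evidence, source_db = db)
}

# Context with a handful of annotations; unnamed proteins stay unannotated.
small_context <- function() {
  annotation_context(
    domains = data.frame(protein = c("P1", "P2", "P3"),
                         domain = c("PF00001", "PF00002", "PF00009")),
    go = data.frame(protein = c("P1", "P2", "P2", "P4"),
                    term = c("GO:0005634", "GO:0005634", "GO:0003677",
                             "GO:0005737"),
                    aspect = c("C", "C", "F", "C")),
    compartments = data.frame(protein = c("P1", "P2", "P3", "P4"),
                              compartment = c("nucleus", "nucleus",
                                              "membrane", "cytoplasm")),
    domain_pairs = data.frame(domain_a = "PF00001", domain_b = "PF00002"),
    homologs = data.frame(id_a = "P1", id_b = "P3",
                          homolog_a = "H1", homolog_b = "H3",
                          taxon = "10090"))
}

mitab25_row <- function(ida = "uniprotkb:P1", idb = "uniprotkb:P2",
                        method = 'psi-mi:"MI:0018"(two hybrid)',
                        pubmed = "pubmed:111",
                        taxa = "taxid:83333", taxb = taxa,
                        type = 'psi-mi:"MI:0915"(physical association)',
                        db = "dbA", conf = "scale:1") {
  f <- rep("-", 15)
  f[1] <- ida; f[2] <- idb; f[7] <- method; f[9] <- pubmed
  f[10] <- taxa; f[11] <- taxb; f[12] <- type; f[13] <- db; f[15] <- conf
  paste(f, collapse = "\t")
}

# Brute-force pairwise AUC: P(score+ > score-) + P(equal)/2.
pairwise_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}
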