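# Synthetic corpus generator.
#
# Emits, fully determined by a seed, everything the pipeline consumes: one
# MITAB file per synthetic source database (with planted cross-database
# duplicates and invalid vocabulary terms), a compact PSI-MI XML file of
# co-purification complexes, the sidecar annotation tables, and a ground
# truth table.  Interactions are planted as genuine or spurious; evidence
# depth, experiment scale, detection-method mix and the three annotation
# features are all enriched in genuine interactions, so reliability scores
# are informative but imperfect.  The evidence model mimics the shape of
# real integrated interactomes, where most interactions rest on a single
# publication and most come from high-throughput experiments.
#
# Alongside the generator, expected_integration() recomputes the exact
# post-integration state (surviving pairs, publication counts, rejection
# counters) from the ground truth by direct brute-force application of the
# integration rules; it shares no code with the pipeline and serves as its
# oracle.

#' Synthetic corpus configuration
#'
#' @param seed integer; the generator is fully determined by it.
#' @param n_proteins,n_taxa,n_interactions corpus dimensions.
#' @param true_fraction fraction of interactions planted as genuine.
#' @param self_pair_prob probability an interaction is a self-pair.
#' @param complex_fraction fraction of the interaction budget delivered as
#'   co-purification complexes rather than binary records.
#' @param n_databases number of synthetic source databases.
#' @param duplication_prob probability each extra database re-reports a
#'   (pair, publication) record.
#' @param pub_lambda_true,pub_lambda_false Poisson rates for publications
#'   beyond the first.
#' @param small_scale_prob_true,small_scale_prob_false probability a
#'   publication is small-scale (<= 100 associations).
#' @param method_probs_true,method_probs_false detection-method category
#'   mix per publication.
#' @param type_probs_true,type_probs_false interaction-type mix.
#' @param p_domains_true,p_domains_false,p_go_true,p_go_false,
#'   p_homology_true,p_homology_false annotation-feature planting rates.
#' @param compartment_overlap_true probability a genuine pair is forced to
#'   share a cellular compartment.
#' @param cross_species_fraction,non_protein_fraction,
#'   colocalization_fraction,genetic_fraction,no_bait_fraction,
#'   unmappable_fraction planted problem records, as fractions of
#'   `n_interactions`.
#' @param invalid_term_fraction fraction of clean record instances whose
#'   method term is replaced by an unrecognized string.
#' @return a `synth_config` list.
#' @export
synth_config <- function(
    seed = 1L,
    n_proteins = 300L, n_taxa = 3L, n_interactions = 800L,
    true_fraction = 0.5,
    self_pair_prob = 0.02,
    complex_fraction = 0.10,
    n_databases = 3L,
    duplication_prob = 0.3,
    pub_lambda_true = 0.35, pub_lambda_false = 0.05,
    small_scale_prob_true = 0.6, small_scale_prob_false = 0.05,
    method_probs_true = c("biophysical" = 0.25, "biochemical" = 0.35,
                          "protein complementation assay" = 0.20,
                          "imaging technique" = 0.10, "unknown" = 0.10),
    method_probs_false = c("biophysical" = 0.05, "biochemical" = 0.15,
                           "protein complementation assay" = 0.35,
                           "imaging technique" = 0.25, "unknown" = 0.20),
    type_probs_true = c("direct interaction" = 0.35,
                        "physical association" = 0.45, "association" = 0.20),
    type_probs_false = c("direct interaction" = 0.05,
                         "physical association" = 0.35, "association" = 0.60),
    p_domains_true = 0.5, p_domains_false = 0.08,
    p_go_true = 0.6, p_go_false = 0.15,
    p_homology_true = 0.4, p_homology_false = 0.05,
    compartment_overlap_true = 0.75,
    cross_species_fraction = 0.03,
    non_protein_fraction = 0.02,
    colocalization_fraction = 0.03,
    genetic_fraction = 0.03,
    no_bait_fraction = 0.02,
    unmappable_fraction = 0.02,
    invalid_term_fraction = 0.05) {
  cfg <- as.list(environment())
  probs <- unlist(cfg[grepl("^p_|prob|fraction", names(cfg))])
  if (any(probs < 0 | probs > 1))
    stop_domain("all probabilities and fractions must lie in [0, 1]")
  if (cfg$n_proteins < 2L || cfg$n_taxa < 1L || cfg$n_interactions < 1L)
    stop_domain("corpus dimensions must be positive")
  structure(cfg, class = "synth_config")
}

# Representative term emitted for each detection-method category.
SYNTH_METHOD_TERMS <- c(
  "biophysical" = 'psi-mi:"MI:0107"(surface plasmon resonance)',
  "biochemical" = 'psi-mi:"MI:0096"(pull down)',
  "protein complementation assay" = 'psi-mi:"MI:0018"(two hybrid)',
  "imaging technique" = 'psi-mi:"MI:0416"(fluorescence microscopy)',
  "unknown" = 'psi-mi:"MI:0045"(experimental interaction detection)')

SYNTH_TYPE_TERMS <- c(
  "direct interaction" = 'psi-mi:"MI:0407"(direct interaction)',
  "physical association" = 'psi-mi:"MI:0915"(physical association)',
  "association" = 'psi-mi:"MI:0914"(association)')

#' Generate a synthetic corpus
#'
#' @param config a [synth_config()].
#' @param dir output directory (created if missing).
#' @return invisibly, a list with `dir`, the file paths (`mitab` per
#'   database, `xml`, sidecar tables) and `ground_truth` (see details).
#'   The ground truth carries one row per planted record instance
#'   (`instances`), the complex definitions (`complexes`), the planted
#'   interaction statuses (`interactions`) and the configuration.
#' @export
generate_corpus <- function(config, dir) {
  stopifnot(inherits(config, "synth_config"))
  max_pairs <- config$n_proteins * (config$n_proteins + 1) / 2
  if (config$n_interactions > max_pairs)
    stop_domain("more interactions requested than protein pairs available")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gt <- with_preserved_seed(config$seed, build_ground_truth(config))
  write_corpus_files(gt, dir)
}

build_ground_truth <- function(cfg) {
  n <- cfg$n_proteins
  proteins <- data.frame(
    canonical = sprintf("SYNP%06d", seq_len(n)),
    alias = sprintf("SYNS%06d", seq_len(n)),
    taxon = 9000L + sample.int(cfg$n_taxa, n, replace = TRUE),
    stringsAsFactors = FALSE)

  # -- interaction sampling: unordered within-taxon pairs, no repeats ------
  n_complex_budget <- round(cfg$complex_fraction * cfg$n_interactions)
  n_binary <- cfg$n_interactions - n_complex_budget
  used <- character()
  sample_pair <- function() {
    for (attempt in 1:200) {
      i <- sample.int(n, 1L)
      j <- if (stats::runif(1) < cfg$self_pair_prob) i else {
        cand <- which(proteins$taxon == proteins$taxon[i])
        if (length(cand) < 2L) next
        sample(setdiff(cand, i), 1L)
      }
      if (proteins$taxon[i] != proteins$taxon[j]) next
      key <- pair_key(proteins$canonical[i], proteins$canonical[j])
      if (!key %in% used) { used <<- c(used, key); return(c(i, j)) }
    }
    stop_domain("could not sample enough distinct within-species pairs")
  }

  interactions <- list()
  add_interaction <- function(i, j, status, origin) {
    interactions[[length(interactions) + 1L]] <<- data.frame(
      key = pair_key(proteins$canonical[i], proteins$canonical[j]),
      a = i, b = j, taxon = proteins$taxon[i], status = status,
      origin = origin, stringsAsFactors = FALSE)
  }

  for (k in seq_len(n_binary)) {
    ij <- sample_pair()
    add_interaction(ij[1], ij[2], stats::runif(1) < cfg$true_fraction, "binary")
  }

  # -- complexes: 1-2 baits, 2-4 preys, one publication each ---------------
  complexes <- list()
  pmid_counter <- 0L
  next_pmid <- function() {
    pmid_counter <<- pmid_counter + 1L
    sprintf("PM%06d", pmid_counter)
  }
  n_complexes <- 0L
  complex_pairs <- 0L
  attempts <- 0L
  while (complex_pairs < n_complex_budget && attempts < 1000L) {
    attempts <- attempts + 1L
    k_bait <- sample(1:2, 1L)
    p_prey <- sample(2:4, 1L)
    taxon <- 9000L + sample.int(cfg$n_taxa, 1L)
    members <- which(proteins$taxon == taxon)
    if (length(members) < k_bait + p_prey) next
    sel <- sample(members, k_bait + p_prey)
    baits <- sel[seq_len(k_bait)]
    preys <- sel[-seq_len(k_bait)]
    scale <- if (stats::runif(1) < 0.2) sample(5:100, 1L) else sample(101:3000, 1L)
    cx <- list(baits = baits, preys = preys, taxon = taxon,
               pubmed = next_pmid(),
               type = sample(c("physical association", "association"), 1L),
               method = "biochemical", scale = scale, db = "syndb1",
               has_bait = TRUE)
    # spoke pairs: every unordered member pair with at least one bait
    pairs <- expand_complex_pairs(baits, preys)
    new_keys <- apply(pairs, 1, function(r)
      pair_key(proteins$canonical[r[1]], proteins$canonical[r[2]]))
    if (anyDuplicated(c(used, new_keys))) next
    used <- c(used, new_keys)
    n_complexes <- n_complexes + 1L
    complexes[[n_complexes]] <- cx
    for (r in seq_len(nrow(pairs)))
      add_interaction(pairs[r, 1], pairs[r, 2],
                      stats::runif(1) < 0.8, "complex")
    complex_pairs <- complex_pairs + nrow(pairs)
  }
  interactions <- do.call(rbind, interactions)

  # -- evidence for binary interactions ------------------------------------
  instances <- list()
  add_instance <- function(src_a, src_b, can_a, can_b, taxon_a, taxon_b,
                           kind_a, kind_b, pubmed, type, method, scale, db,
                           planted_class, invalid_method = FALSE) {
    instances[[length(instances) + 1L]] <<- data.frame(
      src_a = src_a, src_b = src_b, can_a = can_a, can_b = can_b,
      taxon_a = taxon_a, taxon_b = taxon_b, kind_a = kind_a, kind_b = kind_b,
      pubmed = pubmed, type = type, method = method, scale = scale, db = db,
      planted_class = planted_class, invalid_method = invalid_method,
      stringsAsFactors = FALSE)
  }
  dbs <- sprintf("syndb%d", seq_len(cfg$n_databases))
  invalid_counter <- 0L

  bin <- interactions[interactions$origin == "binary", , drop = FALSE]
  for (r in seq_len(nrow(bin))) {
    i <- bin$a[r]; j <- bin$b[r]
    status <- bin$status[r]
    lambda <- if (status) cfg$pub_lambda_true else cfg$pub_lambda_false
    n_pubs <- 1L + stats::rpois(1L, lambda)
    mp <- if (status) cfg$method_probs_true else cfg$method_probs_false
    tp <- if (status) cfg$type_probs_true else cfg$type_probs_false
    ssp <- if (status) cfg$small_scale_prob_true else cfg$small_scale_prob_false
    for (p in seq_len(n_pubs)) {
      pm <- next_pmid()
      cat_ <- sample(names(mp), 1L, prob = mp)
      type_ <- sample(names(tp), 1L, prob = tp)
      scale <- if (stats::runif(1) < ssp) sample(1:100, 1L)
               else sample(101:5000, 1L)
      method_term <- SYNTH_METHOD_TERMS[[cat_]]
      invalid <- stats::runif(1) < cfg$invalid_term_fraction
      # primary database plus duplicating extras
      primary <- sample(dbs, 1L)
      extra <- if (cfg$n_databases > 1L)
        setdiff(dbs, primary)[stats::runif(cfg$n_databases - 1L) <
                                cfg$duplication_prob]
      else character()
      report_dbs <- unique(c(primary, extra))
      for (db in report_dbs) {
        if (invalid) {
          invalid_counter <- invalid_counter + 1L
          method_out <- sprintf("obsolete-method-%04d", invalid_counter)
        } else method_out <- method_term
        add_instance(proteins$alias[i], proteins$alias[j],
                     proteins$canonical[i], proteins$canonical[j],
                     proteins$taxon[i], proteins$taxon[j],
                     "protein", "protein",
                     pm, SYNTH_TYPE_TERMS[[type_]], method_out, scale, db,
                     "clean", invalid_method = invalid)
      }
    }
  }

  # -- planted problem records ---------------------------------------------
  n_of <- function(frac) round(frac * cfg$n_interactions)
  pick2 <- function(same_taxon = TRUE) {
    repeat {
      i <- sample.int(n, 1L)
      cand <- if (same_taxon) which(proteins$taxon == proteins$taxon[i])
              else which(proteins$taxon != proteins$taxon[i])
      cand <- setdiff(cand, i)
      if (length(cand)) return(c(i, sample(cand, 1L)))
    }
  }
  for (k in seq_len(n_of(cfg$cross_species_fraction))) {
    ij <- pick2(same_taxon = FALSE)
    add_instance(proteins$alias[ij[1]], proteins$alias[ij[2]],
                 proteins$canonical[ij[1]], proteins$canonical[ij[2]],
                 proteins$taxon[ij[1]], proteins$taxon[ij[2]],
                 "protein", "protein", next_pmid(),
                 SYNTH_TYPE_TERMS[["physical association"]],
                 SYNTH_METHOD_TERMS[["biochemical"]],
                 sample(1:5000, 1L), sample(dbs, 1L), "cross_species")
  }
  for (k in seq_len(n_of(cfg$non_protein_fraction))) {
    ij <- pick2()
    add_instance(proteins$alias[ij[1]], sprintf("chebi:CHEBI:%05d", k),
                 proteins$canonical[ij[1]], NA_character_,
                 proteins$taxon[ij[1]], proteins$taxon[ij[1]],
                 "protein", "non_protein", next_pmid(),
                 SYNTH_TYPE_TERMS[["physical association"]],
                 SYNTH_METHOD_TERMS[["biochemical"]],
                 sample(1:5000, 1L), sample(dbs, 1L), "non_protein")
  }
  for (k in seq_len(n_of(cfg$colocalization_fraction))) {
    ij <- pick2()
    add_instance(proteins$alias[ij[1]], proteins$alias[ij[2]],
                 proteins$canonical[ij[1]], proteins$canonical[ij[2]],
                 proteins$taxon[ij[1]], proteins$taxon[ij[2]],
                 "protein", "protein", next_pmid(),
                 'psi-mi:"MI:0403"(colocalization)',
                 SYNTH_METHOD_TERMS[["imaging technique"]],
                 sample(1:5000, 1L), sample(dbs, 1L), "colocalization")
  }
  for (k in seq_len(n_of(cfg$genetic_fraction))) {
    ij <- pick2()
    add_instance(proteins$alias[ij[1]], proteins$alias[ij[2]],
                 proteins$canonical[ij[1]], proteins$canonical[ij[2]],
                 proteins$taxon[ij[1]], proteins$taxon[ij[2]],
                 "protein", "protein", next_pmid(),
                 SYNTH_TYPE_TERMS[["physical association"]],
                 'psi-mi:"MI:0254"(genetic interference)',
                 sample(1:5000, 1L), sample(dbs, 1L), "genetic")
  }
  for (k in seq_len(n_of(cfg$unmappable_fraction))) {
    ij <- pick2()
    add_instance(sprintf("SYNU%04d", k), proteins$alias[ij[2]],
                 NA_character_, proteins$canonical[ij[2]],
                 proteins$taxon[ij[2]], proteins$taxon[ij[2]],
                 "protein", "protein", next_pmid(),
                 SYNTH_TYPE_TERMS[["physical association"]],
                 SYNTH_METHOD_TERMS[["biochemical"]],
                 sample(1:5000, 1L), sample(dbs, 1L), "unmappable")
  }
  # no-bait complexes (all participants preys)
  no_bait <- list()
  for (k in seq_len(n_of(cfg$no_bait_fraction))) {
    taxon <- 9000L + sample.int(cfg$n_taxa, 1L)
    members <- which(proteins$taxon == taxon)
    if (length(members) < 3L) next
    sel <- sample(members, 3L)
    no_bait[[length(no_bait) + 1L]] <-
      list(baits = integer(), preys = sel, taxon = taxon,
           pubmed = next_pmid(), type = "physical association",
           method = "biochemical", scale = sample(101:3000, 1L),
           db = "syndb1", has_bait = FALSE)
  }

  instances <- do.call(rbind, instances)

  # -- annotation sidecars --------------------------------------------------
  anno <- plant_annotations(cfg, proteins, interactions)

  list(config = cfg, proteins = proteins, interactions = interactions,
       instances = instances, complexes = c(complexes, no_bait),
       n_invalid_instances = sum(instances$invalid_method),
       domains = anno$domains, go = anno$go, compartments = anno$compartments,
       domain_pairs = anno$domain_pairs, homologs = anno$homologs,
       id_mapping = data.frame(source_id = proteins$alias,
                               canonical_id = proteins$canonical,
                               stringsAsFactors = FALSE))
}

# Unordered member pairs of a complex with at least one bait: the spoke rule
# stated combinatorially.
expand_complex_pairs <- function(baits, preys) {
  members <- c(baits, preys)
  is_bait <- c(rep(TRUE, length(baits)), rep(FALSE, length(preys)))
  out <- NULL
  for (i in seq_along(members)) {
    for (j in seq_along(members)) {
      if (i < j && (is_bait[i] || is_bait[j]))
        out <- rbind(out, c(members[i], members[j]))
    }
  }
  out
}

plant_annotations <- function(cfg, proteins, interactions) {
  n <- nrow(proteins)
  domains <- list(); go <- list(); compartments <- list()
  domain_pairs <- NULL; homologs <- NULL
  bg_domains <- sprintf("BD%03d", 1:30)
  bg_go <- sprintf("GO:%07d", 1:60)
  comp_pool <- c("nucleus", "cytoplasm", "membrane", "mitochondrion",
                 "endoplasmic reticulum", "extracellular")
  for (i in seq_len(n)) {
    acc <- proteins$canonical[i]
    domains[[acc]] <- sample(bg_domains, sample(0:2, 1L))
    go[[acc]] <- sample(bg_go, sample(0:2, 1L))
    compartments[[acc]] <- sample(comp_pool, sample(1:2, 1L))
  }
  for (r in seq_len(nrow(interactions))) {
    a <- proteins$canonical[interactions$a[r]]
    b <- proteins$canonical[interactions$b[r]]
    status <- interactions$status[r]
    if (stats::runif(1) < (if (status) cfg$p_domains_true else cfg$p_domains_false)) {
      d1 <- sprintf("PD%04dA", r); d2 <- sprintf("PD%04dB", r)
      domains[[a]] <- c(domains[[a]], d1)
      domains[[b]] <- c(domains[[b]], d2)
      domain_pairs <- rbind(domain_pairs,
                            data.frame(domain_a = d1, domain_b = d2,
                                       stringsAsFactors = FALSE))
    }
    if (stats::runif(1) < (if (status) cfg$p_go_true else cfg$p_go_false)) {
      term <- sprintf("GO:%07d", 1000000L + r)
      go[[a]] <- c(go[[a]], term)
      go[[b]] <- c(go[[b]], term)
    }
    if (stats::runif(1) < (if (status) cfg$p_homology_true else cfg$p_homology_false)) {
      homologs <- rbind(homologs,
                        data.frame(id_a = a, id_b = b,
                                   homolog_a = sprintf("HOMA%04d", r),
                                   homolog_b = sprintf("HOMB%04d", r),
                                   taxon = "9999", stringsAsFactors = FALSE))
    }
    if (status && stats::runif(1) < cfg$compartment_overlap_true &&
        length(intersect(compartments[[a]], compartments[[b]])) == 0L) {
      compartments[[b]] <- unique(c(compartments[[b]], compartments[[a]][1]))
    }
  }
  to_df <- function(lst, value) {
    rows <- lapply(names(lst), function(k) {
      v <- unique(lst[[k]])
      if (length(v) == 0L) return(NULL)
      df <- data.frame(protein = k, stringsAsFactors = FALSE)
      df <- df[rep(1, length(v)), , drop = FALSE]
      df[[value]] <- v
      df
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) out <- data.frame(protein = character())
    rownames(out) <- NULL
    out
  }
  list(domains = to_df(domains, "domain"), go = to_df(go, "term"),
       compartments = to_df(compartments, "compartment"),
       domain_pairs = domain_pairs %||%
         data.frame(domain_a = character(), domain_b = character()),
       homologs = homologs %||%
         data.frame(id_a = character(), id_b = character(),
                    homolog_a = character(), homolog_b = character(),
                    taxon = character()))
}

write_corpus_files <- function(gt, dir) {
  cfg <- gt$config
  dbs <- sprintf("syndb%d", seq_len(cfg$n_databases))
  mitab_paths <- stats::setNames(
    file.path(dir, sprintf("%s.mitab.tsv", dbs)), dbs)
  inst <- gt$instances
  for (db in dbs) {
    rows <- inst[inst$db == db, , drop = FALSE]
    lines <- character(nrow(rows))
    for (r in seq_len(nrow(rows))) {
      x <- rows[r, ]
      f <- rep("-", MITAB25_NCOL)
      f[1] <- if (startsWith(x$src_a, "chebi:")) x$src_a
              else paste0("synthdb:", x$src_a)
      f[2] <- if (startsWith(x$src_b, "chebi:")) x$src_b
              else paste0("synthdb:", x$src_b)
      f[7] <- x$method
      f[9] <- paste0("pubmed:", x$pubmed)
      f[10] <- paste0("taxid:", x$taxon_a)
      f[11] <- paste0("taxid:", x$taxon_b)
      f[12] <- x$type
      f[13] <- db
      f[15] <- paste0("scale:", x$scale)
      lines[r] <- paste(f, collapse = "\t")
    }
    writeLines(c("# synthetic MITAB 2.5", lines), mitab_paths[[db]])
  }
  xml_path <- file.path(dir, "complexes.xml")
  write_complex_xml(gt, xml_path)
  sidecars <- list(domains = gt$domains, go = gt$go,
                   compartments = gt$compartments,
                   domain_pairs = gt$domain_pairs, homologs = gt$homologs,
                   id_mapping = gt$id_mapping)
  sidecar_paths <- character()
  for (nm in names(sidecars)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    write_sidecar_tsv(sidecars[[nm]], p)
    sidecar_paths[nm] <- p
  }
  truth_path <- file.path(dir, "ground_truth.tsv")
  write_sidecar_tsv(gt$interactions[, c("key", "taxon", "status", "origin")],
                    truth_path)
  invisible(list(dir = dir, mitab = mitab_paths, xml = xml_path,
                 sidecars = sidecar_paths, ground_truth_file = truth_path,
                 ground_truth = gt))
}

# Compact PSI-MI XML 2.5 for the planted complexes (including the
# bait-less ones).
write_complex_xml <- function(gt, path) {
  proteins <- gt$proteins
  members <- sort(unique(unlist(lapply(gt$complexes,
                                       function(cx) c(cx$baits, cx$preys)))))
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             '<entrySet level="2" version="5">', ' <entry>',
             '  <source><names><shortLabel>syndb1</shortLabel></names></source>')
  lines <- c(lines, "  <interactorList>")
  for (i in members) {
    lines <- c(lines, sprintf(
      '   <interactor id="i%d"><names><shortLabel>%s</shortLabel></names><xref><primaryRef db="synthdb" id="%s"/></xref><interactorType><names><shortLabel>protein</shortLabel></names></interactorType><organism ncbiTaxId="%d"/></interactor>',
      i, esc(proteins$alias[i]), esc(proteins$alias[i]), proteins$taxon[i]))
  }
  lines <- c(lines, "  </interactorList>", "  <experimentList>")
  for (k in seq_along(gt$complexes)) {
    cx <- gt$complexes[[k]]
    lines <- c(lines, sprintf(
      '   <experimentDescription id="e%d"><bibref><xref><primaryRef db="pubmed" id="%s"/></xref></bibref><interactionDetectionMethod><names><shortLabel>%s</shortLabel></names></interactionDetectionMethod><attributeList><attribute name="scale">%d</attribute></attributeList></experimentDescription>',
      k, cx$pubmed, cx$method, cx$scale))
  }
  lines <- c(lines, "  </experimentList>", "  <interactionList>")
  for (k in seq_along(gt$complexes)) {
    cx <- gt$complexes[[k]]
    plines <- character()
    for (i in cx$baits) plines <- c(plines, sprintf(
      '    <participant><interactorRef>i%d</interactorRef><experimentalRoleList><experimentalRole><names><shortLabel>bait</shortLabel></names></experimentalRole></experimentalRoleList></participant>', i))
    for (i in cx$preys) plines <- c(plines, sprintf(
      '    <participant><interactorRef>i%d</interactorRef><experimentalRoleList><experimentalRole><names><shortLabel>prey</shortLabel></names></experimentalRole></experimentalRoleList></participant>', i))
    lines <- c(lines, sprintf('   <interaction id="x%d">', k),
               sprintf('    <experimentList><experimentRef>e%d</experimentRef></experimentList>', k),
               "    <participantList>", plines, "    </participantList>",
               sprintf('    <interactionType><names><shortLabel>%s</shortLabel></names></interactionType>', cx$type),
               "   </interaction>")
  }
  lines <- c(lines, "  </interactionList>", " </entry>", "</entrySet>")
  writeLines(lines, path)
  invisible(path)
}

#' Read a generated corpus and run the integration pipeline
#'
#' Convenience wrapper: reads every MITAB file and the complex XML file of
#' a generated corpus directory, loads the identifier mapping, and runs
#' [integrate_records()].
#'
#' @param dir corpus directory from [generate_corpus()].
#' @param min_species per-species minimum interaction count.
#' @return the [integrate_records()] result.
#' @export
integrate_corpus <- function(dir, min_species = 10L) {
  records <- list()
  for (p in sort(list.files(dir, pattern = "\\.mitab\\.tsv$",
                            full.names = TRUE)))
    records <- c(records, read_mitab(p, "mitab25")$records)
  xml <- file.path(dir, "complexes.xml")
  if (file.exists(xml)) records <- c(records, read_psimi_xml(xml))
  idmap <- read_sidecar_tsv(file.path(dir, "id_mapping.tsv"))
  integrate_records(records, id_mapping = idmap, min_species = min_species)
}

#' Brute-force expected integration state from ground truth
#'
#' Recomputes, independently of the pipeline, what integration must
#' produce: complexes are expanded by enumerating all member pairs with at
#' least one bait; each record instance is then passed through the
#' physicality, protein/species and mappability rules in pipeline order;
#' survivors are grouped by canonical pair key with distinct supporting
#' publications counted per key; and the per-species threshold is applied.
#'
#' @param gt ground truth from [generate_corpus()].
#' @param min_species per-species minimum interaction count.
#' @return list with `interactions` data.frame (`key`, `taxon`,
#'   `n_pubmed`), `counters` (named integer vector over rejection reasons)
#'   and `n_term_remapped`.
#' @export
expected_integration <- function(gt, min_species = 10L) {
  counters <- stats::setNames(integer(length(REJECT_REASONS)), REJECT_REASONS)
  inst <- gt$instances
  rows <- list()
  for (r in seq_len(nrow(inst))) {
    x <- inst[r, ]
    rows[[length(rows) + 1L]] <- data.frame(
      can_a = x$can_a, can_b = x$can_b, taxon_a = x$taxon_a,
      taxon_b = x$taxon_b, kind_a = x$kind_a, kind_b = x$kind_b,
      pubmed = x$pubmed, class = x$planted_class, stringsAsFactors = FALSE)
  }
  proteins <- gt$proteins
  for (cx in gt$complexes) {
    if (!cx$has_bait) {
      counters[["no_bait_complex"]] <- counters[["no_bait_complex"]] + 1L
      next
    }
    members <- c(cx$baits, cx$preys)
    is_bait <- c(rep(TRUE, length(cx$baits)), rep(FALSE, length(cx$preys)))
    for (i in seq_along(members)) for (j in seq_along(members)) {
      if (i < j && (is_bait[i] || is_bait[j]))
        rows[[length(rows) + 1L]] <- data.frame(
          can_a = proteins$canonical[members[i]],
          can_b = proteins$canonical[members[j]],
          taxon_a = cx$taxon, taxon_b = cx$taxon,
          kind_a = "protein", kind_b = "protein",
          pubmed = cx$pubmed, class = "clean", stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  survive <- rep(TRUE, nrow(df))
  for (r in seq_len(nrow(df))) {
    cls <- df$class[r]
    if (cls == "colocalization") {
      counters[["indirect_type"]] <- counters[["indirect_type"]] + 1L
      survive[r] <- FALSE
    } else if (cls == "genetic") {
      counters[["genetic_method"]] <- counters[["genetic_method"]] + 1L
      survive[r] <- FALSE
    } else if (cls == "non_protein") {
      counters[["non_protein"]] <- counters[["non_protein"]] + 1L
      survive[r] <- FALSE
    } else if (cls == "cross_species") {
      counters[["cross_species"]] <- counters[["cross_species"]] + 1L
      survive[r] <- FALSE
    } else if (cls == "unmappable") {
      counters[["unmappable_id"]] <- counters[["unmappable_id"]] + 1L
      survive[r] <- FALSE
    }
  }
  kept <- df[survive, , drop = FALSE]
  keys <- mapply(pair_key, kept$can_a, kept$can_b, USE.NAMES = FALSE)
  counters[["duplicate"]] <- nrow(kept) - length(unique(keys))
  agg <- data.frame(key = keys, taxon = kept$taxon_a, pubmed = kept$pubmed,
                    stringsAsFactors = FALSE)
  per_key <- split(agg, agg$key)
  out <- data.frame(
    key = names(per_key),
    taxon = vapply(per_key, function(g) g$taxon[1], integer(1)),
    n_pubmed = vapply(per_key, function(g) length(unique(g$pubmed)),
                      integer(1)),
    stringsAsFactors = FALSE)
  tab <- table(out$taxon)
  low <- as.integer(names(tab)[tab < min_species])
  counters[["species_below_threshold"]] <- sum(out$taxon %in% low)
  out <- out[!out$taxon %in% low, , drop = FALSE]
  out <- out[order(out$key), , drop = FALSE]
  rownames(out) <- NULL
  list(interactions = out, counters = counters,
       n_term_remapped = gt$n_invalid_instances)
}
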