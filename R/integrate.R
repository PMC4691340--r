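# Integration pipeline: raw source records -> deduplicated physical binary
# interactions.
#
# Fixed stage order: term normalization, spoke expansion of complexes,
# physicality filter, protein/same-species filter, identifier
# canonicalization, deduplication, per-species minimum-count threshold.
# The stage order affects only which reason a doomed pair is rejected
# under, never the surviving set.  Every expanded pair ends up exactly once
# in the accepted set or in the reject report.

REJECT_REASONS <- c("non_protein", "cross_species", "indirect_type",
                    "genetic_method", "no_bait_complex", "unmappable_id",
                    "duplicate", "species_below_threshold")

#' Expand an interaction record into binary pairs (spoke model)
#'
#' Binary records pass through unchanged.  A complex is expanded by pairing
#' every prey with the bait; with several baits, all bait-bait pairs are
#' also emitted (baits are assumed to bind each other) but never prey-prey
#' pairs.  A complex with no bait cannot be expanded and yields no pairs.
#' With `k` baits and `p` preys the expansion has `k*p + k*(k-1)/2` pairs.
#'
#' @param record an [interaction_record()].
#' @return list of pair lists (`a`, `b` protein refs, `evidence`,
#'   `source_db`); the record's evidence is copied onto every emitted pair.
#' @export
spoke_expand <- function(record) {
  parts <- record$participants
  mk <- function(a, b) list(a = a, b = b, evidence = record$evidence,
                            source_db = record$source_db)
  if (length(parts) == 1L)   # declared self-interaction
    return(list(mk(parts[[1]], parts[[1]])))
  roles <- vapply(parts, `[[`, character(1), "role")
  if (length(parts) == 2L && !all(roles %in% c("bait", "prey")))
    return(list(mk(parts[[1]], parts[[2]])))
  baits <- parts[roles == "bait"]
  preys <- parts[roles != "bait"]
  if (length(parts) == 2L && length(baits) >= 1L)
    return(list(mk(parts[[1]], parts[[2]])))
  if (length(baits) == 0L) return(list())
  out <- list()
  if (length(baits) >= 2L) {
    for (i in seq_len(length(baits) - 1L))
      for (j in seq(i + 1L, length(baits)))
        out[[length(out) + 1L]] <- mk(baits[[i]], baits[[j]])
  }
  for (b in baits)
    for (p in preys)
      out[[length(out) + 1L]] <- mk(b, p)
  out
}

#' Physicality filter for one pair
#'
#' An evidence item is admissible when none of its interaction types is a
#' recognized indirect type (colocalization, genetic, predicted), its types
#' either intersect the physical whitelist (association, physical
#' association, direct interaction) or are all the sentinel `"unknown"`,
#' and none of its detection methods is genetic interference.  Inadmissible
#' evidence is pruned; a pair left with no evidence is rejected, under
#' `indirect_type` if any item failed on its type and `genetic_method`
#' otherwise.
#'
#' @param pair an expanded pair (see [spoke_expand()]); evidence terms must
#'   be normalized.
#' @return list `(keep, pair, reason)`; `pair` has pruned evidence when
#'   kept, `reason` is `NA` or the rejection reason.
#' @export
filter_physical <- function(pair) {
  type_fail <- FALSE
  keep_items <- logical(length(pair$evidence))
  for (i in seq_along(pair$evidence)) {
    ev <- pair$evidence[[i]]
    bad_type <- any(type_is_indirect(ev$types)) ||
      !(any(ev$types %in% PHYSICAL_TYPE_WHITELIST) || all(ev$types == MI_UNKNOWN))
    bad_method <- any(!method_is_physical(ev$methods))
    if (bad_type) type_fail <- TRUE
    keep_items[i] <- !bad_type && !bad_method
  }
  if (!any(keep_items)) {
    reason <- if (type_fail || length(pair$evidence) == 0L) "indirect_type"
              else "genetic_method"
    return(list(keep = FALSE, pair = pair, reason = reason))
  }
  pair$evidence <- pair$evidence[keep_items]
  list(keep = TRUE, pair = pair, reason = NA_character_)
}

#' Protein and same-species filter for one pair
#'
#' @param pair an expanded pair.
#' @return list `(keep, pair, reason)`: rejected under `non_protein` when
#'   either participant is not a protein, else `cross_species` when the two
#'   taxa differ.
#' @export
filter_protein_same_species <- function(pair) {
  if (pair$a$molecule_kind != "protein" || pair$b$molecule_kind != "protein")
    return(list(keep = FALSE, pair = pair, reason = "non_protein"))
  if (pair$a$taxon != pair$b$taxon)
    return(list(keep = FALSE, pair = pair, reason = "cross_species"))
  list(keep = TRUE, pair = pair, reason = NA_character_)
}

#' Canonicalize the identifiers of one pair
#'
#' @param pair an expanded pair.
#' @param id_mapping named character vector `source_id -> canonical_id`, or
#'   `NULL` to treat identifiers as already canonical.
#' @return list `(keep, pair, reason)`; pairs with an unmapped identifier
#'   are rejected under `unmappable_id`.
#' @export
canonicalize <- function(pair, id_mapping = NULL) {
  map1 <- function(ref) {
    if (!is.na(ref$canonical_id)) return(ref$canonical_id)
    if (is.null(id_mapping)) return(ref$source_id)
    unname(id_mapping[ref$source_id])
  }
  ca <- map1(pair$a)
  cb <- map1(pair$b)
  if (is.na(ca) || is.na(cb))
    return(list(keep = FALSE, pair = pair, reason = "unmappable_id"))
  pair$a$canonical_id <- ca
  pair$b$canonical_id <- cb
  list(keep = TRUE, pair = pair, reason = NA_character_)
}

#' Deduplicate canonicalized pairs into binary interactions
#'
#' Groups pairs by order-invariant pair key and merges their evidence per
#' publication.
#'
#' @param pairs list of canonicalized expanded pairs.
#' @return list of [binary_interaction()]s sorted by pair key; the length
#'   equals the number of distinct pair keys.
#' @export
deduplicate <- function(pairs) {
  if (length(pairs) == 0L) return(list())
  keys <- vapply(pairs, function(p)
    pair_key(p$a$canonical_id, p$b$canonical_id), character(1))
  groups <- split(pairs, keys)
  out <- lapply(groups, function(grp) {
    binary_interaction(grp[[1]]$a$canonical_id, grp[[1]]$b$canonical_id,
                       grp[[1]]$a$taxon,
                       evidence = unlist(lapply(grp, `[[`, "evidence"),
                                         recursive = FALSE))
  })
  unname(out[order(names(groups))])
}

#' Apply the per-species minimum interaction count
#'
#' @param interactions list of [binary_interaction()]s.
#' @param min_count minimum number of interactions a species needs to be
#'   retained (default 10).
#' @return list with `interactions` (retained, original order) and `census`
#'   data.frame (`taxon`, `count`, `retained`).
#' @export
species_threshold <- function(interactions, min_count = 10L) {
  if (length(interactions) == 0L)
    return(list(interactions = list(),
                census = data.frame(taxon = integer(), count = integer(),
                                    retained = logical())))
  taxa <- vapply(interactions, `[[`, integer(1), "taxon")
  counts <- table(taxa)
  census <- data.frame(taxon = as.integer(names(counts)),
                       count = as.integer(counts),
                       stringsAsFactors = FALSE)
  census$retained <- census$count >= min_count
  census <- census[order(census$taxon), , drop = FALSE]
  rownames(census) <- NULL
  keep_taxa <- census$taxon[census$retained]
  list(interactions = interactions[taxa %in% keep_taxa], census = census)
}

# Normalize every evidence item's term sets against the vocabulary registry;
# unrecognized terms become "unknown" and are counted as remap events.
normalize_record_terms <- function(records) {
  n_remapped <- 0L
  records <- lapply(records, function(rec) {
    rec$evidence <- lapply(rec$evidence, function(ev) {
      tm <- normalize_terms(ev$types, "type")
      mm <- normalize_terms(ev$methods, "method")
      n_remapped <<- n_remapped + tm$n_remapped + mm$n_remapped
      evidence_item(ev$pubmed_id, types = tm$names, methods = mm$names,
                    scale = ev$scale, source_dbs = ev$source_dbs)
    })
    rec
  })
  list(records = records, n_remapped = n_remapped)
}

#' Run the full integration pipeline
#'
#' @param records list of [interaction_record()]s from all sources.
#' @param id_mapping named character vector `source_id -> canonical_id`
#'   (or data.frame with `source_id`, `canonical_id` columns), or `NULL`
#'   when identifiers are already canonical.
#' @param min_species minimum interactions per species (default 10).
#' @return list with:
#'   * `interactions`: list of [binary_interaction()]s sorted by pair key;
#'   * `census`: per-species counts and retention;
#'   * `report`: a `filter_report` with per-reason counters (over expanded
#'     pairs; `no_bait_complex` counts whole records), the number of
#'     term-remap events, and a data.frame of rejected pairs.
#' @export
integrate_records <- function(records, id_mapping = NULL, min_species = 10L) {
  if (is.data.frame(id_mapping))
    id_mapping <- stats::setNames(as.character(id_mapping$canonical_id),
                                  as.character(id_mapping$source_id))
  norm <- normalize_record_terms(records)
  counters <- stats::setNames(integer(length(REJECT_REASONS)), REJECT_REASONS)
  rejected <- list()
  note_reject <- function(pair, reason) {
    counters[[reason]] <<- counters[[reason]] + 1L
    rejected[[length(rejected) + 1L]] <<- data.frame(
      id_a = pair$a$source_id, id_b = pair$b$source_id,
      reason = reason, stringsAsFactors = FALSE)
  }

  surviving <- list()
  for (rec in norm$records) {
    pairs <- spoke_expand(rec)
    if (length(pairs) == 0L) {
      counters[["no_bait_complex"]] <- counters[["no_bait_complex"]] + 1L
      rejected[[length(rejected) + 1L]] <- data.frame(
        id_a = rec$participants[[1]]$source_id, id_b = NA_character_,
        reason = "no_bait_complex", stringsAsFactors = FALSE)
      next
    }
    for (pair in pairs) {
      st <- filter_physical(pair)
      if (!st$keep) { note_reject(pair, st$reason); next }
      pair <- st$pair
      st <- filter_protein_same_species(pair)
      if (!st$keep) { note_reject(pair, st$reason); next }
      st <- canonicalize(pair, id_mapping)
      if (!st$keep) { note_reject(pair, st$reason); next }
      surviving[[length(surviving) + 1L]] <- st$pair
    }
  }

  interactions <- deduplicate(surviving)
  counters[["duplicate"]] <- length(surviving) - length(interactions)
  thr <- species_threshold(interactions, min_count = min_species)
  counters[["species_below_threshold"]] <-
    length(interactions) - length(thr$interactions)

  report <- structure(list(
    counters = counters,
    n_term_remapped = norm$n_remapped,
    rejected = if (length(rejected)) do.call(rbind, rejected) else
      data.frame(id_a = character(), id_b = character(),
                 reason = character(), stringsAsFactors = FALSE)),
    class = "filter_report")
  list(interactions = thr$interactions, census = thr$census, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter report>\n")
  for (r in names(x$counters))
    cat(sprintf("  %-24s %d\n", r, x$counters[[r]]))
  cat(sprintf("  %-24s %d\n", "term_remapped", x$n_term_remapped))
  invisible(x)
}
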