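# Shared data model: protein references, evidence items, raw interaction
# records and canonical binary interactions.  Records are plain lists with a
# class attribute; corpora are lists of records.

#' Construct a protein reference
#'
#' @param source_id identifier as found in the input file.
#' @param taxon NCBI taxonomy identifier (positive integer).
#' @param canonical_id canonical accession, or `NA` when not yet mapped.
#' @param molecule_kind `"protein"` or `"non_protein"`.
#' @param role participant role: `"bait"`, `"prey"` or `"neutral"`.
#' @return a `protein_ref` object.
#' @export
protein_ref <- function(source_id, taxon,
                        canonical_id = NA_character_,
                        molecule_kind = c("protein", "non_protein"),
                        role = c("neutral", "bait", "prey")) {
  molecule_kind <- match.arg(molecule_kind)
  role <- match.arg(role)
  if (!nzchar(source_id)) stop_malformed("protein reference with empty source_id")
  taxon <- as.integer(taxon)
  if (is.na(taxon) || taxon <= 0L) stop_malformed("protein reference requires a positive taxon")
  if (!is.na(canonical_id) && !nzchar(canonical_id))
    stop_malformed("canonical_id, when present, must be non-empty")
  structure(list(source_id = source_id, canonical_id = canonical_id,
                 taxon = taxon, molecule_kind = molecule_kind, role = role),
            class = "protein_ref")
}

#' Construct an evidence item
#'
#' One publication's support for an interaction: the Pubmed ID, the unique
#' sets of interaction-type and detection-method terms that publication
#' contributed (possibly the sentinel `"unknown"`), the experiment scale
#' (number of associations the publication reports) and the source databases
#' it came through.
#'
#' @param pubmed_id non-empty string.
#' @param types,methods character vectors of term names; empty input becomes
#'   `"unknown"`.
#' @param scale positive integer experiment scale; defaults to 1.
#' @param source_dbs character vector of database names.
#' @return an `evidence_item` object.
#' @export
evidence_item <- function(pubmed_id, types = character(), methods = character(),
                          scale = 1L, source_dbs = character()) {
  if (is.na(pubmed_id) || !nzchar(pubmed_id))
    stop_malformed("evidence item requires a non-empty pubmed_id")
  scale <- as.integer(scale)
  if (is.na(scale) || scale < 1L) stop_malformed("evidence scale must be >= 1")
  types <- as_term_set(types)
  methods <- as_term_set(methods)
  if (length(types) == 0L) types <- MI_UNKNOWN
  if (length(methods) == 0L) methods <- MI_UNKNOWN
  structure(list(pubmed_id = as.character(pubmed_id), types = types,
                 methods = methods, scale = scale,
                 source_dbs = as_term_set(source_dbs)),
            class = "evidence_item")
}

#' Construct a raw interaction record
#'
#' A record as read from a source file: two or more participants (one for a
#' declared self-interaction) with roles, plus evidence items.
#'
#' @param participants list of [protein_ref()] objects.
#' @param evidence list of [evidence_item()] objects.
#' @param source_db database name the record came from.
#' @return an `interaction_record` object.
#' @export
interaction_record <- function(participants, evidence, source_db = "") {
  if (length(participants) < 1L)
    stop_malformed("interaction record requires at least one participant")
  structure(list(participants = participants, evidence = evidence,
                 source_db = source_db),
            class = "interaction_record")
}

#' Order-invariant key for a protein pair
#'
#' Deduplication compares interactions as unordered pairs of canonical
#' accessions; `pair_key("A","B")` and `pair_key("B","A")` are identical and
#' self-pairs are allowed.
#'
#' @param a,b canonical accession strings (non-empty).
#' @return a single string key; the sorted pair joined by `"|"`.
#' @export
#' @examples
#' pair_key("P1", "P2") == pair_key("P2", "P1")
pair_key <- function(a, b) {
  if (length(a) != 1L || length(b) != 1L || is.na(a) || is.na(b) ||
      !nzchar(a) || !nzchar(b))
    stop_malformed("pair_key requires two non-empty identifiers")
  if (a <= b) paste(a, b, sep = "|") else paste(b, a, sep = "|")
}

#' Merge evidence items by publication
#'
#' Collapses a list of evidence items to one item per distinct Pubmed ID.
#' Within a publication, type, method and source-database sets are unioned
#' across databases, and the experiment scale is the maximum reported.
#' Merging first is what makes the method-based score immune to the same
#' publication arriving through several source databases.
#'
#' @param items list of [evidence_item()] objects.
#' @return list of merged evidence items, sorted by `pubmed_id`.
#' @export
merge_evidence <- function(items) {
  if (length(items) == 0L) return(list())
  ids <- vapply(items, function(e) e$pubmed_id, character(1))
  out <- lapply(split(items, ids), function(grp) {
    evidence_item(
      pubmed_id = grp[[1]]$pubmed_id,
      types = unlist(lapply(grp, `[[`, "types")),
      methods = unlist(lapply(grp, `[[`, "methods")),
      scale = max(vapply(grp, `[[`, integer(1), "scale")),
      source_dbs = unlist(lapply(grp, `[[`, "source_dbs"))
    )
  })
  unname(out[order(names(out))])
}

#' Construct a canonical binary interaction
#'
#' @param id_a,id_b canonical accessions (order irrelevant; self allowed).
#' @param taxon shared NCBI taxonomy id.
#' @param evidence list of evidence items; merged by pubmed on construction.
#' @return a `binary_interaction` object with members `id_a <= id_b`.
#' @export
binary_interaction <- function(id_a, id_b, taxon, evidence = list()) {
  key <- pair_key(id_a, id_b)
  ids <- strsplit(key, "|", fixed = TRUE)[[1]]
  # self-pair key "A|A" splits into two identical members
  structure(list(id_a = ids[1], id_b = ids[2], taxon = as.integer(taxon),
                 evidence = merge_evidence(evidence), key = key),
            class = "binary_interaction")
}

#' @export
print.binary_interaction <- function(x, ...) {
  cat(sprintf("<interaction> %s -- %s  taxon:%d  publications:%d\n",
              x$id_a, x$id_b, x$taxon, length(x$evidence)))
  invisible(x)
}

n_publications <- function(interaction) length(interaction$evidence)

evidence_scales <- function(interaction)
  vapply(interaction$evidence, `[[`, integer(1), "scale")
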