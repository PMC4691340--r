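# Sidecar annotation tables.
#
# The annotation scorer consults knowledge tables that travel next to the
# interaction data as headered, tab-separated, UTF-8 text with '#' comment
# lines: protein-to-Pfam-domain, protein-to-GO-term (with aspect),
# protein-to-compartment, interacting-domain-pair, homologous-interaction
# and identifier-mapping tables.  All protein keys are canonical accessions
# after loading; domain pairs and homolog keys are stored order-invariantly.

#' Build an annotation context from in-memory tables
#'
#' @param domains data.frame (`protein`, `domain`): Pfam domains per protein.
#' @param go data.frame (`protein`, `term`, optional `aspect`): GO terms.
#' @param compartments data.frame (`protein`, `compartment`).
#' @param domain_pairs data.frame (`domain_a`, `domain_b`): Pfam domain pairs
#'   observed to bind in 3D structures.
#' @param homologs data.frame (`id_a`, `id_b`, `homolog_a`, `homolog_b`,
#'   optional `taxon`): known interactions between homologs of a pair, in
#'   the same or another species.
#' @param id_mapping data.frame (`source_id`, `canonical_id`).
#' @param go_aspects optional character vector restricting GO sharing to
#'   particular aspects (e.g. `c("C","F")`); `NULL` uses all terms.
#' @return an `annotation_context` with set-valued lookups keyed by
#'   accession (and by pair key for domain pairs and homologs).
#' @export
annotation_context <- function(domains = NULL, go = NULL, compartments = NULL,
                               domain_pairs = NULL, homologs = NULL,
                               id_mapping = NULL, go_aspects = NULL) {
  to_sets <- function(df, key, value) {
    if (is.null(df) || nrow(df) == 0L) return(list())
    lapply(split(as.character(df[[value]]), as.character(df[[key]])), as_term_set)
  }
  if (!is.null(go) && !is.null(go_aspects) && "aspect" %in% names(go))
    go <- go[go$aspect %in% go_aspects, , drop = FALSE]
  dp <- character()
  if (!is.null(domain_pairs) && nrow(domain_pairs) > 0L)
    dp <- unique(mapply(pair_key, as.character(domain_pairs$domain_a),
                        as.character(domain_pairs$domain_b), USE.NAMES = FALSE))
  hm <- list()
  if (!is.null(homologs) && nrow(homologs) > 0L) {
    keys <- mapply(pair_key, as.character(homologs$id_a),
                   as.character(homologs$id_b), USE.NAMES = FALSE)
    hp <- mapply(pair_key, as.character(homologs$homolog_a),
                 as.character(homologs$homolog_b), USE.NAMES = FALSE)
    hm <- lapply(split(hp, keys), unique)
  }
  im <- character()
  if (!is.null(id_mapping) && nrow(id_mapping) > 0L)
    im <- stats::setNames(as.character(id_mapping$canonical_id),
                          as.character(id_mapping$source_id))
  structure(list(domains = to_sets(domains, "protein", "domain"),
                 go = to_sets(go, "protein", "term"),
                 compartments = to_sets(compartments, "protein", "compartment"),
                 domain_pairs = dp, homologs = hm, id_mapping = im),
            class = "annotation_context")
}

read_sidecar_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, quote = "",
                    colClasses = "character", fileEncoding = "UTF-8")
}

write_sidecar_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an annotation context from a directory of sidecar TSV files
#'
#' Recognized file names: `domains.tsv`, `go.tsv`, `compartments.tsv`,
#' `domain_pairs.tsv`, `homologs.tsv`, `id_mapping.tsv`; missing files give
#' empty tables.
#'
#' @param dir directory path.
#' @param go_aspects see [annotation_context()].
#' @return an `annotation_context`.
#' @export
read_annotation_context <- function(dir, go_aspects = NULL) {
  rd <- function(name) {
    p <- file.path(dir, name)
    if (file.exists(p)) read_sidecar_tsv(p) else NULL
  }
  annotation_context(domains = rd("domains.tsv"), go = rd("go.tsv"),
                     compartments = rd("compartments.tsv"),
                     domain_pairs = rd("domain_pairs.tsv"),
                     homologs = rd("homologs.tsv"),
                     id_mapping = rd("id_mapping.tsv"),
                     go_aspects = go_aspects)
}
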