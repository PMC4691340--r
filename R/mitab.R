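# PSI-MITAB input and output.
#
# The reader supports the 15-column MITAB 2.5 core and the 42-column MITAB
# 2.7 layout (only the core columns are interpreted; the rest are carried
# but ignored).  Identifier fields follow the "db:accession" convention;
# term fields accept both the full 'psi-mi:"MI:0018"(two hybrid)' form and
# bare names.  Experiment scale, which plain MITAB does not carry, is read
# from a "scale:N" entry in the confidence column when present and defaults
# to 1.

MITAB25_NCOL <- 15L
MITAB27_NCOL <- 42L

# Identifier prefixes recognized as non-protein molecules.
NON_PROTEIN_PREFIXES <- c("chebi", "chembl compound", "pubchem", "rnacentral",
                          "ddbj/embl/genbank nucleotide", "dna", "rna")

#' Read interaction records from a PSI-MITAB file
#'
#' @param path file path; lines starting with `#` are skipped.
#' @param dialect `"mitab25"` (15 columns) or `"mitab27"` (42 columns).
#' @return list with `records` (list of [interaction_record()]s, one per
#'   well-formed row) and `rejects` (data.frame of rows that could not be
#'   parsed, with `row` and `reason`).  A row with the wrong column count is
#'   a dialect error and aborts the read; a row with an unparseable taxon is
#'   collected in `rejects` instead.
#' @export
read_mitab <- function(path, dialect = c("mitab25", "mitab27")) {
  dialect <- match.arg(dialect)
  ncol_expected <- if (dialect == "mitab25") MITAB25_NCOL else MITAB27_NCOL
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  records <- vector("list", length(lines))
  rejects <- list()
  kept <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) != ncol_expected)
      stop_malformed(sprintf(
        "row %d has %d columns; %s expects %d", i, length(f), dialect, ncol_expected))
    taxon_a <- parse_mitab_taxid(f[10])
    taxon_b <- parse_mitab_taxid(f[11])
    if (is.na(taxon_a) || is.na(taxon_b)) {
      rejects[[length(rejects) + 1L]] <-
        data.frame(row = i, reason = "unparseable_taxon", stringsAsFactors = FALSE)
      next
    }
    ida <- parse_mitab_id(f[1])
    idb <- parse_mitab_id(f[2])
    if (!nzchar(ida$accession) || !nzchar(idb$accession)) {
      rejects[[length(rejects) + 1L]] <-
        data.frame(row = i, reason = "missing_identifier", stringsAsFactors = FALSE)
      next
    }
    pubmed <- parse_mitab_pubmed(f[9])
    if (!nzchar(pubmed)) {
      rejects[[length(rejects) + 1L]] <-
        data.frame(row = i, reason = "missing_pubmed", stringsAsFactors = FALSE)
      next
    }
    source_db <- parse_term_string(f[13])$name
    if (!nzchar(source_db)) source_db <- gsub("^-$", "", f[13])
    ev <- evidence_item(
      pubmed_id = pubmed,
      types = mitab_field_values(f[12]),
      methods = mitab_field_values(f[7]),
      scale = parse_mitab_scale(f[15]),
      source_dbs = source_db)
    kept <- kept + 1L
    records[[kept]] <- interaction_record(
      participants = list(
        protein_ref(ida$accession, taxon_a,
                    molecule_kind = molecule_kind_for(ida$db), role = "neutral"),
        protein_ref(idb$accession, taxon_b,
                    molecule_kind = molecule_kind_for(idb$db), role = "neutral")),
      evidence = list(ev),
      source_db = source_db)
  }
  list(records = records[seq_len(kept)],
       rejects = if (length(rejects)) do.call(rbind, rejects) else
         data.frame(row = integer(), reason = character(), stringsAsFactors = FALSE))
}

molecule_kind_for <- function(db) {
  if (tolower(db) %in% NON_PROTEIN_PREFIXES) "non_protein" else "protein"
}

parse_mitab_id <- function(field) {
  field <- strsplit(field, "|", fixed = TRUE)[[1]][1]
  if (is.na(field) || field == "-" || !nzchar(field))
    return(list(db = "", accession = ""))
  parts <- strsplit(field, ":", fixed = TRUE)[[1]]
  if (length(parts) < 2L) return(list(db = "unknown", accession = field))
  list(db = parts[1], accession = paste(parts[-1], collapse = ":"))
}

parse_mitab_taxid <- function(field) {
  m <- regmatches(field, regexpr("taxid:(-?[0-9]+)", field))
  if (length(m) == 0L) return(NA_integer_)
  v <- suppressWarnings(as.integer(sub("taxid:", "", m)))
  if (is.na(v) || v <= 0L) NA_integer_ else v
}

parse_mitab_pubmed <- function(field) {
  m <- regmatches(field, regexpr("pubmed:([^|]+)", field))
  if (length(m) == 1L) return(sub("pubmed:", "", m))
  if (field != "-" && nzchar(field)) return(strsplit(field, "|", fixed = TRUE)[[1]][1])
  ""
}

parse_mitab_scale <- function(field) {
  m <- regmatches(field, regexpr("scale:([0-9]+)", field))
  if (length(m) == 1L) as.integer(sub("scale:", "", m)) else 1L
}

# A '|'-separated term field; each entry kept verbatim for later validation.
mitab_field_values <- function(field) {
  if (is.na(field) || field == "-" || !nzchar(field)) return(character())
  strsplit(field, "|", fixed = TRUE)[[1]]
}

#' Write scored interactions to a TSV file
#'
#' @param scored data.frame from [score_interactions()].
#' @param path output path.
#' @return number of rows written (header excluded).  Output is sorted by
#'   pair key with scores serialized to 6 decimals, so identical inputs give
#'   byte-identical files.
#' @export
write_scored_tsv <- function(scored, path) {
  df <- scored
  num <- c("annotation_score", "method_score", "combined_score")
  for (col in num) df[[col]] <- sprintf("%.6f", df[[col]])
  if (nrow(df) > 0L) {
    keys <- mapply(pair_key, df$id_a, df$id_b)
    df <- df[order(keys), , drop = FALSE]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  nrow(df)
}

#' Read a scored-interaction TSV file
#'
#' @param path file written by [write_scored_tsv()].
#' @return data.frame with the same columns.
#' @export
read_scored_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c(id_a = "character", id_b = "character"))
}

#' Write binary interactions as MITAB 2.7
#'
#' One row per evidence item, with confidence-column entries for the three
#' scores (when supplied) and the experiment scale.
#'
#' @param interactions list of [binary_interaction()]s.
#' @param path output path.
#' @param scored optional data.frame from [score_interactions()]; when given,
#'   `annotation`/`method`/`combined` key:value entries are added to the
#'   confidence column.
#' @return number of rows written.
#' @export
write_mitab <- function(interactions, path, scored = NULL) {
  score_key <- NULL
  if (!is.null(scored) && nrow(scored) > 0L)
    score_key <- stats::setNames(
      sprintf("annotation:%.6f|method:%.6f|combined:%.6f",
              scored$annotation_score, scored$method_score, scored$combined_score),
      mapply(pair_key, scored$id_a, scored$id_b))
  ord <- order(vapply(interactions, `[[`, character(1), "key"))
  rows <- character()
  for (it in interactions[ord]) {
    for (ev in it$evidence) {
      conf <- paste0("scale:", ev$scale)
      if (!is.null(score_key) && !is.na(score_key[it$key]))
        conf <- paste(conf, score_key[it$key], sep = "|")
      f <- rep("-", MITAB27_NCOL)
      f[1] <- paste0("uniprotkb:", it$id_a)
      f[2] <- paste0("uniprotkb:", it$id_b)
      f[7] <- paste(vapply(ev$methods, format_term, character(1)), collapse = "|")
      f[9] <- paste0("pubmed:", ev$pubmed_id)
      f[10] <- paste0("taxid:", it$taxon)
      f[11] <- paste0("taxid:", it$taxon)
      f[12] <- paste(vapply(ev$types, format_term, character(1)), collapse = "|")
      f[13] <- if (length(ev$source_dbs)) paste(ev$source_dbs, collapse = "|") else "-"
      f[15] <- conf
      rows <- c(rows, paste(f, collapse = "\t"))
    }
  }
  writeLines(rows, path)
  length(rows)
}

format_term <- function(name) {
  reg <- mi_term_registry()
  j <- match(name, reg$name)
  if (!is.na(j)) sprintf('psi-mi:"%s"(%s)', reg$accession[j], name) else name
}
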