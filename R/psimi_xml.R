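# Compact PSI-MI XML 2.5 reader.
#
# Supported subset: entrySet/entry with an interactorList, an
# experimentList of experimentDescription elements (bibref pubmed xref,
# interactionDetectionMethod, optional attribute name="scale"), and an
# interactionList whose interactions reference interactors and experiments
# by id (the "compact" form).  The expanded form, in which interactors and
# experiments are inlined under each interaction, is not supported.

#' Read interaction records from a compact PSI-MI XML 2.5 file
#'
#' Complex records keep bait/prey roles from the participants'
#' `experimentalRole` elements; participants without a role are `neutral`.
#' An interaction without a named `interactionType` gets the type set
#' `{"unknown"}`.
#'
#' @param path XML file path.
#' @return list of [interaction_record()]s.
#' @export
read_psimi_xml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  records <- list()
  for (entry in xml2::xml_find_all(doc, ".//entry")) {
    source_db <- xml2::xml_text(xml2::xml_find_first(
      entry, "./source/names/shortLabel"))
    if (is.na(source_db)) source_db <- ""
    interactors <- parse_xml_interactors(entry)
    experiments <- parse_xml_experiments(entry)
    for (ix in xml2::xml_find_all(entry, "./interactionList/interaction")) {
      records[[length(records) + 1L]] <-
        parse_xml_interaction(ix, interactors, experiments, source_db)
    }
  }
  records
}

parse_xml_interactors <- function(entry) {
  out <- list()
  for (node in xml2::xml_find_all(entry, "./interactorList/interactor")) {
    id <- xml2::xml_attr(node, "id")
    acc_node <- xml2::xml_find_first(node, "./xref/primaryRef")
    db <- xml2::xml_attr(acc_node, "db")
    acc <- xml2::xml_attr(acc_node, "id")
    if (is.na(acc) || !nzchar(acc))
      acc <- xml2::xml_text(xml2::xml_find_first(node, "./names/shortLabel"))
    taxon <- xml2::xml_attr(
      xml2::xml_find_first(node, "./organism"), "ncbiTaxId")
    kind_node <- xml2::xml_find_first(node, "./interactorType/names/shortLabel")
    kind_label <- tolower(xml2::xml_text(kind_node))
    kind <- if (!is.na(kind_label) && nzchar(kind_label) &&
                !grepl("protein|peptide", kind_label)) "non_protein"
            else molecule_kind_for(db %||% "")
    taxon_int <- suppressWarnings(as.integer(taxon))
    if (is.na(taxon_int) || taxon_int <= 0L)
      stop_malformed("interactor ", id, " lacks a usable ncbiTaxId")
    out[[id]] <- list(accession = acc, taxon = taxon_int, kind = kind)
  }
  out
}

parse_xml_experiments <- function(entry) {
  out <- list()
  for (node in xml2::xml_find_all(entry, "./experimentList/experimentDescription")) {
    id <- xml2::xml_attr(node, "id")
    pubmed <- xml2::xml_attr(xml2::xml_find_first(
      node, "./bibref/xref/primaryRef[@db='pubmed']"), "id")
    if (is.na(pubmed))
      pubmed <- xml2::xml_attr(xml2::xml_find_first(
        node, "./bibref/xref/primaryRef"), "id")
    method <- xml2::xml_text(xml2::xml_find_first(
      node, "./interactionDetectionMethod/names/shortLabel"))
    method_acc <- xml2::xml_attr(xml2::xml_find_first(
      node, "./interactionDetectionMethod/xref/primaryRef"), "id")
    scale <- xml2::xml_text(xml2::xml_find_first(
      node, "./attributeList/attribute[@name='scale']"))
    scale <- suppressWarnings(as.integer(scale))
    out[[id]] <- list(
      pubmed = pubmed %||% NA_character_,
      method = if (!is.na(method_acc) && nzchar(method_acc)) method_acc
               else if (!is.na(method)) method else "",
      scale = if (is.na(scale)) 1L else scale)
  }
  out
}

parse_xml_interaction <- function(ix, interactors, experiments, source_db) {
  participants <- list()
  for (p in xml2::xml_find_all(ix, "./participantList/participant")) {
    ref <- xml2::xml_text(xml2::xml_find_first(p, "./interactorRef"))
    info <- interactors[[ref]]
    if (is.null(info))
      stop_malformed("dangling interactorRef '", ref, "'")
    role_label <- tolower(xml2::xml_text(xml2::xml_find_first(
      p, "./experimentalRoleList/experimentalRole/names/shortLabel")))
    role <- if (is.na(role_label) || !nzchar(role_label)) "neutral"
            else if (grepl("bait", role_label)) "bait"
            else if (grepl("prey", role_label)) "prey"
            else "neutral"
    participants[[length(participants) + 1L]] <-
      protein_ref(info$accession, info$taxon,
                  molecule_kind = info$kind, role = role)
  }
  type <- xml2::xml_text(xml2::xml_find_first(
    ix, "./interactionType/names/shortLabel"))
  type_acc <- xml2::xml_attr(xml2::xml_find_first(
    ix, "./interactionType/xref/primaryRef"), "id")
  types <- if (!is.na(type_acc) && nzchar(type_acc)) type_acc
           else if (!is.na(type) && nzchar(type)) type
           else MI_UNKNOWN
  evidence <- list()
  for (ref_node in xml2::xml_find_all(ix, "./experimentList/experimentRef")) {
    ref <- xml2::xml_text(ref_node)
    exp <- experiments[[ref]]
    if (is.null(exp))
      stop_malformed("dangling experimentRef '", ref, "'")
    if (is.na(exp$pubmed) || !nzchar(exp$pubmed))
      stop_malformed("experiment '", ref, "' lacks a pubmed reference")
    evidence[[length(evidence) + 1L]] <- evidence_item(
      pubmed_id = exp$pubmed, types = types, methods = exp$method,
      scale = exp$scale, source_dbs = source_db)
  }
  if (length(evidence) == 0L)
    evidence <- list(evidence_item("NA", types = types))
  interaction_record(participants, evidence, source_db)
}
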