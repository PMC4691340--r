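# PSI-MI controlled-vocabulary support.
#
# Interaction data carries detection-method and interaction-type terms from
# the PSI-MI controlled vocabulary (MI accessions).  Scoring needs only a
# flat view of that vocabulary: which terms are recognized, which scoring
# category a detection method belongs to, and which interaction types denote
# a physical association.  The registry below is a static snapshot of the
# branches the scorer uses; sub-methods inherit the category (and hence the
# score) of their parent method category.  Terms absent from the registry are
# normalized to the sentinel "unknown".

MI_UNKNOWN <- "unknown"

# Detection-method scoring categories.
MI_METHOD_CATEGORIES <- c(
  "biophysical", "protein complementation assay", "biochemical",
  "post-transcriptional interference", "imaging technique"
)

# kind: "method" or "type".  category: scoring category for methods; for
# types the category is the normalized type name itself.  physical: for
# types, whether the term denotes a physical interaction; for methods,
# whether the method is admissible evidence of a physical interaction
# (everything experimental except genetic interference).
mi_term_registry <- function() {
  if (!is.null(.ppiscore_cache$registry)) return(.ppiscore_cache$registry)
  m <- function(acc, name, category, physical = TRUE)
    data.frame(accession = acc, name = name, kind = "method",
               category = category, physical = physical,
               stringsAsFactors = FALSE)
  t <- function(acc, name, physical)
    data.frame(accession = acc, name = name, kind = "type",
               category = name, physical = physical,
               stringsAsFactors = FALSE)
  .ppiscore_cache$registry <- rbind(
    # method category roots
    m("MI:0013", "biophysical",                       "biophysical"),
    m("MI:0090", "protein complementation assay",     "protein complementation assay"),
    m("MI:0401", "biochemical",                       "biochemical"),
    m("MI:0255", "post transcriptional interference", "post-transcriptional interference"),
    m("MI:0428", "imaging technique",                 "imaging technique"),
    m("MI:0254", "genetic interference",              MI_UNKNOWN, physical = FALSE),
    # common sub-methods, mapped to their parent category
    m("MI:0018", "two hybrid",                        "protein complementation assay"),
    m("MI:0397", "two hybrid array",                  "protein complementation assay"),
    m("MI:0112", "ubiquitin reconstruction",          "protein complementation assay"),
    m("MI:0004", "affinity chromatography technology","biochemical"),
    m("MI:0006", "anti bait coimmunoprecipitation",   "biochemical"),
    m("MI:0007", "anti tag coimmunoprecipitation",    "biochemical"),
    m("MI:0019", "coimmunoprecipitation",             "biochemical"),
    m("MI:0096", "pull down",                         "biochemical"),
    m("MI:0676", "tandem affinity purification",      "biochemical"),
    m("MI:0114", "x-ray crystallography",             "biophysical"),
    m("MI:0107", "surface plasmon resonance",         "biophysical"),
    m("MI:0077", "nuclear magnetic resonance",        "biophysical"),
    m("MI:0416", "fluorescence microscopy",           "imaging technique"),
    m("MI:0663", "confocal microscopy",               "imaging technique"),
    # ontology root: experimental but carries no category information
    m("MI:0045", "experimental interaction detection", MI_UNKNOWN),
    # interaction types
    t("MI:0407", "direct interaction",    TRUE),
    t("MI:0915", "physical association",  TRUE),
    t("MI:0914", "association",           TRUE),
    t("MI:0403", "colocalization",        FALSE),
    t("MI:0208", "genetic interaction",   FALSE),
    t("MI:1110", "predicted interaction", FALSE)
  )
  .ppiscore_cache$registry
}

.ppiscore_cache <- new.env(parent = emptyenv())

# Interaction types admitted as physical evidence.
PHYSICAL_TYPE_WHITELIST <- c("association", "physical association", "direct interaction")

#' Normalize a controlled-vocabulary term
#'
#' Looks a term up in the static PSI-MI registry snapshot, by MI accession
#' first and by (case-insensitive) name otherwise, and returns its normalized
#' name.  Unrecognized terms map to the sentinel `"unknown"`; interaction
#' data frequently carries obsolete or free-text terms, and downgrading them
#' to `"unknown"` (rather than dropping the evidence) lets them participate
#' in scoring with the minimal weight.
#'
#' @param terms character vector of raw term strings; each may be an MI
#'   accession (`"MI:0018"`), a plain name (`"two hybrid"`), or the combined
#'   MITAB form `psi-mi:"MI:0018"(two hybrid)`.
#' @param kind `"method"` or `"type"`.
#' @return list with `names` (normalized term names, same length) and
#'   `n_remapped` (how many inputs were not recognized and became
#'   `"unknown"`).
#' @export
normalize_terms <- function(terms, kind = c("method", "type")) {
  kind <- match.arg(kind)
  reg <- mi_term_registry()
  reg <- reg[reg$kind == kind, ]
  out <- character(length(terms))
  remapped <- 0L
  for (i in seq_along(terms)) {
    p <- parse_term_string(terms[[i]])
    hit <- NA_integer_
    if (nzchar(p$accession)) {
      j <- match(p$accession, reg$accession)
      if (!is.na(j)) hit <- j
    }
    if (is.na(hit) && nzchar(p$name)) {
      j <- match(tolower(p$name), reg$name)
      if (!is.na(j)) hit <- j
    }
    if (is.na(hit)) {
      out[i] <- MI_UNKNOWN
      if (!identical(tolower(p$name), MI_UNKNOWN)) remapped <- remapped + 1L
    } else {
      out[i] <- reg$name[hit]
    }
  }
  list(names = out, n_remapped = remapped)
}

# Split 'psi-mi:"MI:0018"(two hybrid)' / "MI:0018" / "two hybrid" into parts.
parse_term_string <- function(x) {
  x <- trimws(as.character(x %||% ""))
  if (!nzchar(x) || x == "-") return(list(accession = "", name = ""))
  acc <- ""
  name <- x
  macc <- regmatches(x, regexpr("MI:[0-9]{4}", x))
  if (length(macc) == 1L) acc <- macc
  mname <- regmatches(x, regexpr("\\(([^)]*)\\)", x))
  if (length(mname) == 1L) {
    name <- sub("^\\(", "", sub("\\)$", "", mname))
  } else if (nzchar(acc)) {
    name <- ""
  }
  list(accession = acc, name = trimws(name))
}

#' Scoring category of a detection-method term
#'
#' @param methods character vector of normalized method names.
#' @return character vector of category names; unrecognized or uncategorized
#'   methods give `"unknown"`.
#' @export
method_category <- function(methods) {
  reg <- mi_term_registry()
  reg <- reg[reg$kind == "method", ]
  j <- match(methods, reg$name)
  out <- ifelse(is.na(j), MI_UNKNOWN, reg$category[j])
  out[!out %in% MI_METHOD_CATEGORIES] <- MI_UNKNOWN
  out
}

# TRUE for methods admissible as physical-interaction evidence (normalized
# names).  The unknown sentinel is admissible: an unrecognized method is not
# evidence of a genetic experiment.
method_is_physical <- function(methods) {
  reg <- mi_term_registry()
  reg <- reg[reg$kind == "method", ]
  j <- match(methods, reg$name)
  ifelse(is.na(j), TRUE, reg$physical[j])
}

# TRUE for types recognized as explicitly non-physical (colocalization,
# genetic, predicted); the unknown sentinel is not in this set.
type_is_indirect <- function(types) {
  reg <- mi_term_registry()
  reg <- reg[reg$kind == "type", ]
  j <- match(types, reg$name)
  ifelse(is.na(j), FALSE, !reg$physical[j])
}
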