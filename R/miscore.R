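# Method-based score.
#
# Experimental evidence is summarized into three components, each in [0,1]:
#
#   * publication component: min(n, s)/s over the n distinct supporting
#     publications, saturating at s = 7 publications;
#   * detection-method component: the frequency-weighted mean of the category
#     scores over distinct (publication, category) occurrences, multiplied by
#     the same saturation factor applied to the occurrence count;
#   * interaction-type component: the same aggregation over interaction-type
#     occurrences.
#
# The method-based score is the arithmetic mean of the three components.
# Evidence must be merged per publication before scoring: counting one
# (publication, term) occurrence at most once is what stops the score from
# inflating when the same experiment is reported by several databases.

#' Publication component of the method-based score
#'
#' @param n_publications number of distinct supporting publications.
#' @param config a [method_score_config()].
#' @return `min(n, s)/s` where `s` is the saturation count (default 7): 0
#'   with no publications, exactly 1 at `s` or more.
#' @export
#' @examples
#' publication_score(7)  # 1
#' publication_score(3)  # 3/7
publication_score <- function(n_publications, config = method_score_config()) {
  n <- as.numeric(n_publications)
  if (any(is.na(n)) || any(n < 0)) stop_domain("publication count must be >= 0")
  s <- config$publication_saturation
  pmin(n, s) / s
}

# Shared aggregation for the method and type components: distinct
# (publication, term-class) occurrences are tallied per class; the component
# is the frequency-weighted mean of the class scores times the saturation
# factor on the total occurrence count.
occurrence_component <- function(evidence, classes_of, scores, config) {
  check_merged(evidence)
  if (length(evidence) == 0L)
    return(list(component = 0, occurrences = 0L))
  occ <- unlist(lapply(evidence, function(e) unique(classes_of(e))))
  counts <- table(occ)
  s_c <- scores[names(counts)]
  s_c[is.na(s_c)] <- scores[["unknown"]]
  n_total <- sum(counts)
  wmean <- sum(as.numeric(counts) * s_c) / n_total
  sat <- min(n_total, config$publication_saturation) / config$publication_saturation
  list(component = wmean * sat, occurrences = n_total)
}

check_merged <- function(evidence) {
  ids <- vapply(evidence, `[[`, character(1), "pubmed_id")
  if (anyDuplicated(ids))
    stop_domain("evidence must be merged (one item per pubmed_id) before scoring")
  invisible(TRUE)
}

#' Detection-method component of the method-based score
#'
#' @param evidence list of merged [evidence_item()]s (unique pubmed IDs).
#' @param config a [method_score_config()].
#' @return numeric in `[0,1]`.
#' @export
detection_method_score <- function(evidence, config = method_score_config()) {
  occurrence_component(
    evidence,
    classes_of = function(e) method_category(e$methods),
    scores = config$category_scores,
    config = config)$component
}

#' Interaction-type component of the method-based score
#'
#' @inheritParams detection_method_score
#' @return numeric in `[0,1]`.
#' @export
interaction_type_score <- function(evidence, config = method_score_config()) {
  occurrence_component(
    evidence,
    classes_of = function(e) {
      tt <- e$types
      tt[!tt %in% names(config$type_scores)] <- MI_UNKNOWN
      tt
    },
    scores = config$type_scores,
    config = config)$component
}

#' Method-based score of an interaction
#'
#' @param interaction a [binary_interaction()] (evidence already merged).
#' @param config a [method_score_config()].
#' @return a `method_score` list with `detection`, `type`, `publication`
#'   components and their arithmetic mean `total`, all in `[0,1]`.
#' @export
method_score <- function(interaction, config = method_score_config()) {
  ev <- interaction$evidence
  detection <- detection_method_score(ev, config)
  type <- interaction_type_score(ev, config)
  publication <- publication_score(length(ev), config)
  structure(list(detection = detection, type = type,
                 publication = publication,
                 total = (detection + type + publication) / 3),
            class = "method_score")
}
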