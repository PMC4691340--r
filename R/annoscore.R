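# Annotation-based score.
#
# Three boolean features of the interacting proteins are extracted from
# sidecar annotation tables:
#
#   * the proteins carry Pfam domains known to bind each other in 3D
#     structures of protein complexes;
#   * the proteins share at least one Gene Ontology term;
#   * an interaction between homologs of the two proteins exists, in the
#     same or another species (an interolog).
#
# Each feature contributes a likelihood ratio; ratios combine under a
# naive-Bayes (conditional independence) assumption by multiplication, or
# via an explicit 8-row table.  The default calibration puts the no-feature
# combination at LR = 0.163.  A likelihood ratio maps to a score in (0,1) by
# lr/(1+lr), so score > 0.5 exactly when LR > 1.

#' Extract annotation features for an interaction
#'
#' @param interaction a [binary_interaction()] with canonical accessions.
#' @param context an [annotation_context()] of sidecar tables.
#' @return list of three booleans: `has_interacting_domains`,
#'   `shares_go_term`, `has_homologous_interaction`.  Proteins absent from a
#'   table contribute the empty annotation set, so an unannotated protein
#'   yields all-false features.
#' @export
extract_features <- function(interaction, context) {
  a <- interaction$id_a
  b <- interaction$id_b
  dom_a <- context$domains[[a]] %||% character()
  dom_b <- context$domains[[b]] %||% character()
  has_domains <- FALSE
  if (length(dom_a) && length(dom_b) && length(context$domain_pairs)) {
    cand <- unique(as.character(outer(dom_a, dom_b, Vectorize(pair_key))))
    has_domains <- any(cand %in% context$domain_pairs)
  }
  go_a <- context$go[[a]] %||% character()
  go_b <- context$go[[b]] %||% character()
  shares_go <- length(intersect(go_a, go_b)) > 0L
  has_homolog <- pair_key(a, b) %in% names(context$homologs) &&
    length(context$homologs[[pair_key(a, b)]]) > 0L
  list(has_interacting_domains = has_domains,
       shares_go_term = shares_go,
       has_homologous_interaction = has_homolog)
}

#' Likelihood ratio of a feature combination
#'
#' @param features list of the three feature booleans (see
#'   [extract_features()]).
#' @param config an [annotation_config()].
#' @return positive likelihood ratio.  In product mode the per-feature
#'   present/absent LRs multiply; in explicit-table mode the 8-way
#'   combination is looked up directly.
#' @export
likelihood_ratio <- function(features, config = annotation_config()) {
  if (identical(config$mode, "explicit_table")) {
    key <- combo_key(features)
    lr <- config$table[[key]]
    if (is.null(lr) || is.na(lr))
      stop_domain("likelihood table has no entry for combination '", key, "'")
    lr <- as.numeric(lr)
  } else {
    on <- c(isTRUE(features$has_interacting_domains),
            isTRUE(features$shares_go_term),
            isTRUE(features$has_homologous_interaction))
    lr <- prod(ifelse(on, config$present_lr, config$absent_lr))
  }
  if (!is.finite(lr) || lr <= 0)
    stop_domain("likelihood ratio must be positive")
  lr
}

#' Map a likelihood ratio to an annotation score
#'
#' The default mapping is `lr / (1 + lr)`: strictly increasing on (0, 1)
#' with `annotation_score(1) == 0.5`, so a score above 0.5 is equivalent to
#' a likelihood ratio above 1.  An explicit LR-to-score table in the
#' configuration overrides the default by stepwise lookup (the largest
#' tabulated `lr` not exceeding the input).
#'
#' @param lr positive likelihood ratio (vectorized).
#' @param config an [annotation_config()].
#' @return score in `(0, 1)`.
#' @export
#' @examples
#' annotation_score(1)      # 0.5
#' annotation_score(0.163)  # 0.163/1.163
annotation_score <- function(lr, config = annotation_config()) {
  lr <- as.numeric(lr)
  if (any(!is.finite(lr)) || any(lr <= 0))
    stop_domain("likelihood ratio must be positive")
  if (!is.null(config$score_map)) {
    sm <- config$score_map[order(config$score_map$lr), ]
    idx <- findInterval(lr, sm$lr)
    if (any(idx == 0L)) stop_domain("lr below the explicit score map range")
    return(sm$score[idx])
  }
  lr / (1 + lr)
}

#' Annotation-based score of an interaction
#'
#' @param interaction a [binary_interaction()].
#' @param context an [annotation_context()].
#' @param config an [annotation_config()].
#' @return an `annotation_score` list with the feature vector, the combined
#'   likelihood ratio and the mapped score.
#' @export
annotate_interaction <- function(interaction, context,
                                 config = annotation_config()) {
  features <- extract_features(interaction, context)
  lr <- likelihood_ratio(features, config)
  structure(list(features = features, likelihood_ratio = lr,
                 score = annotation_score(lr, config)),
            class = "annotation_score")
}
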