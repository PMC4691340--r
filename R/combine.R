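# Combined interaction score and confidence classification.

#' Combined interaction score
#'
#' The geometric mean of the annotation-based and method-based scores.
#'
#' @param annotation,method scores in `[0,1]` (vectorized).
#' @return `sqrt(annotation * method)`; symmetric, 0 when either input is 0.
#' @export
#' @examples
#' combined_score(0.5, 0.485)
combined_score <- function(annotation, method) {
  if (any(!is.finite(annotation)) || any(annotation < 0) || any(annotation > 1) ||
      any(!is.finite(method)) || any(method < 0) || any(method > 1))
    stop_domain("scores must lie in [0, 1]")
  sqrt(annotation * method)
}

#' Classify an interaction's confidence
#'
#' The high-confidence call is strict on the combined score
#' (`combined > 0.281` by default); the per-score flags are non-strict
#' (`annotation >= 0.5`, `method >= 0.485`) and are reported for
#' transparency but do not by themselves grant high confidence unless
#' `either_flag_high` is enabled in the cutoffs.
#'
#' @param annotation,method scores in `[0,1]`.
#' @param cutoffs a [score_cutoffs()].
#' @return a `score_set` list: the three scores, the two per-score flags and
#'   the `high_confidence` call.
#' @export
classify_scores <- function(annotation, method, cutoffs = score_cutoffs()) {
  combined <- combined_score(annotation, method)
  annotation_flag <- annotation >= cutoffs$annotation
  method_flag <- method >= cutoffs$method
  high <- combined > cutoffs$combined
  if (isTRUE(cutoffs$either_flag_high))
    high <- high | annotation_flag | method_flag
  structure(list(annotation = annotation, method = method, combined = combined,
                 annotation_flag = annotation_flag, method_flag = method_flag,
                 high_confidence = high),
            class = "score_set")
}

#' Score a set of interactions
#'
#' Runs the annotation scorer, the method scorer and the combined classifier
#' over every interaction; every interaction receives a full score set.
#'
#' @param interactions list of [binary_interaction()]s.
#' @param context an [annotation_context()].
#' @param config score configuration: list with `method`, `annotation`,
#'   `cutoffs` (see [read_score_config()]); defaults throughout.
#' @return data.frame with one row per interaction: identifiers, taxon,
#'   publication counts, the three scores, flags and the high-confidence
#'   call.
#' @export
score_interactions <- function(interactions, context,
                               config = list(method = method_score_config(),
                                             annotation = annotation_config(),
                                             cutoffs = score_cutoffs())) {
  rows <- lapply(interactions, function(it) {
    ms <- method_score(it, config$method)
    as_ <- annotate_interaction(it, context, config$annotation)
    cls <- classify_scores(as_$score, ms$total, config$cutoffs)
    scales <- evidence_scales(it)
    data.frame(
      id_a = it$id_a, id_b = it$id_b, taxon = it$taxon,
      n_publications = length(it$evidence),
      n_small_scale = sum(scales <= 100L),
      annotation_score = as_$score,
      method_score = ms$total,
      combined_score = cls$combined,
      annotation_flag = cls$annotation_flag,
      method_flag = cls$method_flag,
      high_confidence = cls$high_confidence,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(id_a = character(), id_b = character(),
                      taxon = integer(), n_publications = integer(),
                      n_small_scale = integer(), annotation_score = numeric(),
                      method_score = numeric(), combined_score = numeric(),
                      annotation_flag = logical(), method_flag = logical(),
                      high_confidence = logical(), stringsAsFactors = FALSE)
  if (nrow(out) > 0L) {
    keys <- mapply(pair_key, out$id_a, out$id_b)
    out <- out[order(keys), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
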