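# Score evaluation: gold-standard construction from experiment scale and
# cellular compartments, ROC curves and AUC.

#' Label an experiment's scale
#'
#' @param scale number of associations reported by the experiment
#'   (vectorized).
#' @param cutoff small-scale boundary (default 100).
#' @return `"small_scale"` for `scale <= cutoff`, else `"high_throughput"`.
#' @export
label_scale <- function(scale, cutoff = 100L) {
  ifelse(scale <= cutoff, "small_scale", "high_throughput")
}

#' Build balanced gold-standard positive and negative sets
#'
#' Positives are interactions supported by at least one small-scale
#' experiment (scale <= 100 associations).  Negatives are interactions
#' supported only by high-throughput experiments whose proteins have known,
#' disjoint cellular compartments; a protein with no compartment annotation
#' cannot enter the negative set, since absence of annotation is not
#' evidence of different localization.  The positive set is then
#' down-sampled uniformly without replacement to the size of the negative
#' set.
#'
#' @param interactions list of [binary_interaction()]s.
#' @param context an [annotation_context()] carrying the compartment table.
#' @param seed integer seed for the balanced sampling.
#' @param scale_cutoff small-scale boundary (default 100).
#' @return a `gold_standard` list: `positives` and `negatives` (character
#'   vectors of pair keys, equal length), `n_positive_pool` (positives
#'   before sampling) and `seed`.
#' @export
build_gold_standard <- function(interactions, context, seed = 1L,
                                scale_cutoff = 100L) {
  keys <- vapply(interactions, `[[`, character(1), "key")
  is_pos <- logical(length(interactions))
  is_neg <- logical(length(interactions))
  for (i in seq_along(interactions)) {
    it <- interactions[[i]]
    scales <- evidence_scales(it)
    if (any(scales <= scale_cutoff)) {
      is_pos[i] <- TRUE
    } else {
      ca <- context$compartments[[it$id_a]] %||% character()
      cb <- context$compartments[[it$id_b]] %||% character()
      is_neg[i] <- length(ca) > 0L && length(cb) > 0L &&
        length(intersect(ca, cb)) == 0L
    }
  }
  negatives <- keys[is_neg]
  positives_pool <- keys[is_pos]
  if (length(negatives) == 0L)
    stop_domain("gold standard has no negatives: no all-high-throughput ",
                "interaction with disjoint annotated compartments")
  if (length(positives_pool) < length(negatives))
    stop_domain("gold standard has fewer positives (", length(positives_pool),
                ") than negatives (", length(negatives), ")")
  positives <- with_preserved_seed(seed,
    sample(positives_pool, length(negatives), replace = FALSE))
  structure(list(positives = sort(positives), negatives = sort(negatives),
                 n_positive_pool = length(positives_pool), seed = seed),
            class = "gold_standard")
}

#' ROC curve and AUC
#'
#' Sweeps all distinct score values as thresholds (ties grouped into one
#' step) and accumulates true- and false-positive rates; the AUC is the
#' trapezoidal area under the resulting curve, which equals the
#' Mann-Whitney pairwise statistic P(score+ > score-) + P(equal)/2.
#'
#' @param labels binary vector (1/TRUE = positive).
#' @param scores numeric vector, same length.
#' @return a `roc_result` list: `thresholds` (descending), `points`
#'   data.frame (`fpr`, `tpr`, from (0,0) to (1,1)) and `auc`.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(as.logical(labels))
  if (length(labels) != length(scores))
    stop_domain("labels and scores must have equal length")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop_domain("ROC needs both classes present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  thresholds <- unique(s)
  tp <- cumsum(l)
  fp <- cumsum(1L - l)
  last_of_group <- cumsum(rle(s)$lengths)
  tpr <- c(0, tp[last_of_group] / n_pos)
  fpr <- c(0, fp[last_of_group] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = thresholds,
                 points = data.frame(fpr = fpr, tpr = tpr),
                 auc = auc),
            class = "roc_result")
}

#' Compare scores on a balanced gold standard
#'
#' Evaluates each score column on the union of gold positives and
#' negatives; optionally repeats the balanced positive draw to attach a
#' spread to each AUC.
#'
#' @param scored data.frame from [score_interactions()].
#' @param interactions the scored [binary_interaction()]s (for evidence and
#'   pair keys).
#' @param context an [annotation_context()] with compartments.
#' @param seed integer seed for the balanced draw(s).
#' @param score_cols score columns to compare.
#' @param repeats number of balanced draws (default 1); with more than one,
#'   AUC is reported as the mean over draws with its standard deviation.
#' @return data.frame (`score`, `auc`, `auc_sd`, `n_positive`,
#'   `n_negative`).
#' @export
compare_scores <- function(scored, interactions, context, seed = 1L,
                           score_cols = c("annotation_score", "method_score",
                                          "combined_score"),
                           repeats = 1L) {
  keys <- mapply(pair_key, scored$id_a, scored$id_b, USE.NAMES = FALSE)
  aucs <- matrix(NA_real_, nrow = repeats, ncol = length(score_cols),
                 dimnames = list(NULL, score_cols))
  gold <- NULL
  for (r in seq_len(repeats)) {
    gold <- build_gold_standard(interactions, context, seed = seed + r - 1L)
    eval_keys <- c(gold$positives, gold$negatives)
    lab <- c(rep(1L, length(gold$positives)), rep(0L, length(gold$negatives)))
    idx <- match(eval_keys, keys)
    for (col in score_cols)
      aucs[r, col] <- roc_auc(lab, scored[[col]][idx])$auc
  }
  data.frame(score = score_cols,
             auc = colMeans(aucs),
             auc_sd = apply(aucs, 2, stats::sd),
             n_positive = length(gold$positives),
             n_negative = length(gold$negatives),
             row.names = NULL, stringsAsFactors = FALSE)
}
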