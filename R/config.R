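# Score configuration.  All scoring weights and cutoffs are configuration,
# not constants: the method-score category weights stand in for the PSI-MI
# community defaults, the annotation likelihood ratios are calibrated so the
# no-feature combination yields the published baseline of 0.163, and the
# high-confidence cutoffs default to 0.485 (method), 0.5 (annotation) and
# 0.281 (combined).

#' Default method-score configuration
#'
#' @param category_scores named numeric vector in `[0,1]`: score per
#'   detection-method category (plus `"unknown"`).
#' @param type_scores named numeric vector in `[0,1]`: score per interaction
#'   type (plus `"unknown"`).
#' @param publication_saturation number of distinct publications at which the
#'   publication component saturates at 1 (default 7).
#' @param cutoff method-score value at or above which the method flag is set
#'   (default 0.485).
#' @return a `method_score_config` list.
#' @export
method_score_config <- function(
    category_scores = c("biophysical" = 1.0,
                        "biochemical" = 1.0,
                        "protein complementation assay" = 0.66,
                        "imaging technique" = 0.33,
                        "post-transcriptional interference" = 0.33,
                        "unknown" = 0.05),
    type_scores = c("direct interaction" = 1.0,
                    "physical association" = 0.75,
                    "association" = 0.33,
                    "unknown" = 0.05),
    publication_saturation = 7L,
    cutoff = 0.485) {
  stopifnot(all(category_scores >= 0 & category_scores <= 1),
            all(type_scores >= 0 & type_scores <= 1),
            "unknown" %in% names(category_scores),
            "unknown" %in% names(type_scores))
  if (category_scores[["unknown"]] > min(category_scores) ||
      type_scores[["unknown"]] > min(type_scores))
    stop_domain("the 'unknown' score must not exceed any known-category score")
  publication_saturation <- as.integer(publication_saturation)
  if (is.na(publication_saturation) || publication_saturation < 1L)
    stop_domain("publication_saturation must be >= 1")
  structure(list(category_scores = category_scores, type_scores = type_scores,
                 publication_saturation = publication_saturation,
                 cutoff = cutoff),
            class = "method_score_config")
}

#' Default annotation-score configuration
#'
#' The default likelihood table works in naive-Bayes product mode: each of
#' the three features contributes a present or absent likelihood ratio and
#' the three contributions multiply.  The absent LRs are the cube root of
#' 0.163, so an interaction with no feature support gets the baseline
#' likelihood ratio 0.163.  The present LRs order the features by
#' discriminative power, interacting domain pairs strongest.
#'
#' @param mode `"naive_bayes_product"` (default) or `"explicit_table"`.
#' @param present_lr,absent_lr named numeric vectors over features
#'   `domains`, `go`, `homology` (product mode).
#' @param table named numeric vector of 8 likelihood ratios keyed by feature
#'   combination (explicit mode); keys are `"none"` or `+`-joined sorted
#'   feature names, e.g. `"domains+go"`.
#' @param score_map optional data.frame (`lr`, `score`) overriding the
#'   default `lr/(1+lr)` mapping by stepwise lookup.
#' @param cutoff annotation-score value at or above which the annotation flag
#'   is set (default 0.5).
#' @return an `annotation_config` list.
#' @export
annotation_config <- function(
    mode = c("naive_bayes_product", "explicit_table"),
    present_lr = c(domains = 14.0, go = 3.0, homology = 4.0),
    absent_lr = c(domains = 0.163^(1/3), go = 0.163^(1/3), homology = 0.163^(1/3)),
    table = NULL,
    score_map = NULL,
    cutoff = 0.5) {
  mode <- match.arg(mode)
  features <- c("domains", "go", "homology")
  cfg <- structure(list(mode = mode,
                        present_lr = present_lr[features],
                        absent_lr = absent_lr[features],
                        table = table, score_map = score_map, cutoff = cutoff),
                   class = "annotation_config")
  validate_likelihood_table(cfg)
  cfg
}

# Enumerate the 8 feature combinations and check table invariants: all LRs
# positive, the no-feature LR below 1, and monotone non-decreasing along the
# feature partial order.
validate_likelihood_table <- function(cfg) {
  combos <- feature_combinations()
  lrs <- vapply(seq_len(nrow(combos)), function(i)
    likelihood_ratio(as.list(combos[i, ]), cfg), numeric(1))
  if (any(!is.finite(lrs)) || any(lrs <= 0))
    stop_domain("likelihood ratios must be positive and finite")
  if (lrs[1] >= 1)
    stop_domain("the no-feature likelihood ratio must be below 1")
  for (i in seq_len(nrow(combos))) {
    for (j in seq_len(nrow(combos))) {
      if (all(combos[i, ] <= combos[j, ]) && lrs[i] > lrs[j] + 1e-12)
        stop_domain("likelihood ratios must be non-decreasing as features are added")
    }
  }
  invisible(lrs)
}

feature_combinations <- function() {
  expand.grid(has_interacting_domains = c(FALSE, TRUE),
              shares_go_term = c(FALSE, TRUE),
              has_homologous_interaction = c(FALSE, TRUE))
}

combo_key <- function(features) {
  on <- c("domains", "go", "homology")[c(isTRUE(features$has_interacting_domains),
                                         isTRUE(features$shares_go_term),
                                         isTRUE(features$has_homologous_interaction))]
  if (length(on) == 0L) "none" else paste(sort(on), collapse = "+")
}

#' Default score cutoffs
#'
#' @param combined combined-score cutoff; the high-confidence call is strict
#'   (`combined > cutoff`), default 0.281.
#' @param annotation annotation flag cutoff, non-strict (`>= 0.5`).
#' @param method method flag cutoff, non-strict (`>= 0.485`).
#' @param either_flag_high when `TRUE`, an interaction is also called high
#'   confidence when either individual score passes its own cutoff; off by
#'   default.
#' @return a `score_cutoffs` list.
#' @export
score_cutoffs <- function(combined = 0.281, annotation = 0.5, method = 0.485,
                          either_flag_high = FALSE) {
  structure(list(combined = combined, annotation = annotation, method = method,
                 either_flag_high = either_flag_high),
            class = "score_cutoffs")
}

#' Read score configuration from a JSON file
#'
#' The file may contain any of the keys `method`, `annotation`, `cutoffs`;
#' omitted keys fall back to the package defaults.
#'
#' @param path JSON file path.
#' @return list with elements `method`, `annotation`, `cutoffs`.
#' @export
read_score_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- method_score_config()
  method <- if (is.null(raw$method)) defaults else
    method_score_config(
      category_scores = unlist(raw$method$category_scores) %||%
        defaults$category_scores,
      type_scores = unlist(raw$method$type_scores) %||% defaults$type_scores,
      publication_saturation = raw$method$publication_saturation %||% 7L,
      cutoff = raw$method$cutoff %||% 0.485)
  annotation <- if (is.null(raw$annotation)) annotation_config() else
    annotation_config(
      mode = raw$annotation$mode %||% "naive_bayes_product",
      present_lr = unlist(raw$annotation$present_lr) %||%
        c(domains = 14.0, go = 3.0, homology = 4.0),
      absent_lr = unlist(raw$annotation$absent_lr) %||%
        c(domains = 0.163^(1/3), go = 0.163^(1/3), homology = 0.163^(1/3)),
      table = if (!is.null(raw$annotation$table)) unlist(raw$annotation$table),
      cutoff = raw$annotation$cutoff %||% 0.5)
  cutoffs <- if (is.null(raw$cutoffs)) score_cutoffs() else
    score_cutoffs(combined = raw$cutoffs$combined %||% 0.281,
                  annotation = raw$cutoffs$annotation %||% 0.5,
                  method = raw$cutoffs$method %||% 0.485,
                  either_flag_high = isTRUE(raw$cutoffs$either_flag_high))
  list(method = method, annotation = annotation, cutoffs = cutoffs)
}

#' Write score configuration to a JSON file
#'
#' @param config list as returned by [read_score_config()], or built from
#'   [method_score_config()], [annotation_config()] and [score_cutoffs()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_score_config <- function(config, path) {
  out <- list(
    method = list(
      category_scores = as.list(config$method$category_scores),
      type_scores = as.list(config$method$type_scores),
      publication_saturation = config$method$publication_saturation,
      cutoff = config$method$cutoff),
    annotation = list(
      mode = config$annotation$mode,
      present_lr = as.list(config$annotation$present_lr),
      absent_lr = as.list(config$annotation$absent_lr),
      cutoff = config$annotation$cutoff),
    cutoffs = list(combined = config$cutoffs$combined,
                   annotation = config$cutoffs$annotation,
                   method = config$cutoffs$method,
                   either_flag_high = config$cutoffs$either_flag_high))
  if (!is.null(config$annotation$table))
    out$annotation$table <- as.list(config$annotation$table)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
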