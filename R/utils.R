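#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_preserved_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable set representation: unique, sorted character vector.
as_term_set <- function(x) {
  x <- as.character(x)
  x <- x[!is.na(x) & nzchar(x)]
  sort(unique(x))
}

stop_domain <- function(...) {
  stop(errorCondition(paste0(...), class = c("ppiscore_domain_error", "error")))
}

stop_malformed <- function(...) {
  stop(errorCondition(paste0(...), class = c("ppiscore_malformed_record", "error")))
}
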