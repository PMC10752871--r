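# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded operations never clobber the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

# Stop with a classed condition so callers/tests can distinguish contract
# violations (domain errors) from malformed inputs (format errors).
stop_domain <- function(...) {
  stop(errorCondition(paste0(...), class = c("forumstylo_domain_error", "error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("forumstylo_format_error", "error")))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
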