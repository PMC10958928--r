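# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Signal a netformula input/validation error
#'
#' All user-facing validation failures carry the condition class
#' `"nf_error"` so callers (and the command-line driver) can distinguish
#' bad input from programming errors.
#'
#' @param ... passed to [sprintf()] to build the message.
#' @param class extra condition classes, prepended to `"nf_error"`.
#' @keywords internal
nf_stop <- function(..., class = character()) {
  stop(errorCondition(sprintf(...), class = c(class, "nf_error")))
}

nf_warn <- function(...) {
  warning(warningCondition(sprintf(...), class = "nf_warning"))
}

# Trim leading/trailing whitespace and collapse internal runs of spaces.
# Case-preserving: no synonym resolution is attempted.
normalize_herb <- function(x) {
  gsub("[[:space:]]+", " ", trimws(as.character(x)))
}

# Deterministic evaluation under a seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    nf_stop("'%s' must be a single non-missing number", name)
}
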