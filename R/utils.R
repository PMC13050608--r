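# Classed error helpers: the CLI maps these onto exit codes, and tests
# assert on the classes rather than on message wording.

stopUsage <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("scpop_usage_error", "scpop_error")))
}

stopInput <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("scpop_input_error", "scpop_error")))
}

stopConfig <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("scpop_config_error", "scpop_error")))
}

stopTransform <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("scpop_transform_error", "scpop_error")))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

.assertFlag <- function(x, what) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stopUsage("'%s' must be TRUE or FALSE", what)
  x
}

.assertString <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    stopUsage("'%s' must be a non-empty string", what)
  x
}

.assertNumber <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopUsage("'%s' must be a single number", what)
  as.numeric(x)
}
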