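#' @keywords internal
"_PACKAGE"

## classed conditions so the CLI can map them to exit codes
## (2 = usage/format error, 3 = statistical precondition failure)
cp_format_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("covpower_format_error", "covpower_error")))
}

cp_stat_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("covpower_stat_error", "covpower_error")))
}

cp_structure_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("covpower_structure_error",
                                             "covpower_format_error", "covpower_error")))
}

#' Derive a child random seed deterministically
#'
#' All stochastic stages of the pipeline derive their own seeds from a single
#' top-level seed plus a stage key, so whole runs are reproducible from one
#' integer while stages stay statistically independent.
#'
#' @param seed integer top-level seed.
#' @param ... additional integer keys identifying the stage.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  keys <- c(seed, ...)
  x <- 0
  for (v in keys) {
    x <- (x * 69069 + (as.numeric(v) %% 2147483647) + 1) %% 2147483647
  }
  as.integer(x)
}

cp_log <- function(..., quiet = FALSE) {
  if (!quiet) message(...)
}
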