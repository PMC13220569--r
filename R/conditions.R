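#' @keywords internal
"_PACKAGE"

# Structured conditions: every user-facing failure carries a class so callers
# (and the command-line driver) can distinguish schema problems, validation
# problems, positivity gaps and bad simulation configs.

ps_abort <- function(message, class, ...) {
  cond <- structure(
    class = c(class, "poststrat_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

abort_schema <- function(message, ...) ps_abort(message, "poststrat_schema_error", ...)
abort_validation <- function(message, ...) ps_abort(message, "poststrat_validation_error", ...)
abort_config <- function(message, ...) ps_abort(message, "poststrat_config_error", ...)

#' Signal a positivity failure
#'
#' Positivity failures (population cells with no sampled units, reference
#' cells with no units at the requested treatment level, ...) are raised as
#' structured errors of class `poststrat_positivity_error` carrying the
#' offending cells in the `cells` field, rather than returning `NaN`.
#'
#' @param message Human-readable description.
#' @param cells A data frame of offending covariate cells.
#' @param ... Further fields stored on the condition.
#' @keywords internal
abort_positivity <- function(message, cells = NULL, ...) {
  ps_abort(message, "poststrat_positivity_error", cells = cells, ...)
}

format_cells <- function(cells, max = 10L) {
  if (is.null(cells) || nrow(cells) == 0L) return("<none>")
  labs <- apply(cells, 1L, function(r) paste(r, collapse = "/"))
  if (length(labs) > max) {
    labs <- c(labs[seq_len(max)], sprintf("... (%d more)", length(labs) - max))
  }
  paste(labs, collapse = ", ")
}
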