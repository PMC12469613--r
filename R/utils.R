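# Internal helpers: structured conditions, colour-coded messaging, numerics.

eb_abort <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "eb_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

eb_warning <- function(class, msg, ...) {
  warning(structure(
    class = c(class, "eb_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

.eb_use_colour <- function() {
  isTRUE(getOption("ebstage.colour", default = interactive()))
}

.eb_col <- function(txt, code) {
  if (.eb_use_colour()) paste0("\033[", code, "m", txt, "\033[0m") else txt
}

#' @keywords internal
eb_info <- function(...) message(.eb_col(paste0(...), "32"))

#' @keywords internal
eb_warn_msg <- function(...) message(.eb_col(paste0(...), "33"))

#' @keywords internal
eb_err_msg <- function(...) message(.eb_col(paste0(...), "31"))

# Numerically stable log(sum(exp(x))) over rows of a matrix.
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# Deterministic order: primary descending, secondary ascending, name last.
order_desc_then <- function(primary, secondary, names) {
  order(-primary, secondary, names, method = "radix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
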