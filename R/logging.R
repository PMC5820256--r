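#' Pipeline logging
#'
#' Every pipeline stage logs input counts, parameter values and output counts
#' through this single hook; nothing is dropped silently. Verbosity is
#' controlled by \code{options(optotract.verbose = TRUE/FALSE)} (default
#' \code{FALSE}: messages suppressed, warnings always emitted).
#'
#' @param ... parts pasted into the log line.
#' @param level \code{"info"} or \code{"warn"}.
#' @return invisibly, the formatted line.
#' @keywords internal
ot_log <- function(..., level = "info") {
  line <- paste0("[optotract] ", paste0(..., collapse = ""))
  if (identical(level, "warn")) {
    warning(line, call. = FALSE)
  } else if (isTRUE(getOption("optotract.verbose", FALSE))) {
    message(line)
  }
  invisible(line)
}
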