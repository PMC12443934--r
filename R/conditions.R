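# Classed conditions so callers (and the CLI) can map failures to exit codes.

pqa_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "phantomqa_error"),
                      call = call))
}

stop_validation <- function(msg) pqa_stop(msg, "phantomqa_validation_error")
stop_usage      <- function(msg) pqa_stop(msg, "phantomqa_usage_error")
stop_capacity   <- function(msg) pqa_stop(msg, "phantomqa_capacity_error")
stop_geometry   <- function(msg) pqa_stop(msg, "phantomqa_geometry_error")
stop_detection  <- function(msg) pqa_stop(msg, "phantomqa_detection_error")
stop_placement  <- function(msg) pqa_stop(msg, "phantomqa_placement_error")
stop_format     <- function(msg) pqa_stop(msg, "phantomqa_format_error")
stop_io         <- function(msg) pqa_stop(msg, "phantomqa_io_error")
stop_insufficient <- function(msg) pqa_stop(msg, "phantomqa_insufficient_data_error")

# Logging: messages to stderr only, never stdout, so piped output stays clean.
.pqa_log_level <- new.env(parent = emptyenv())
.pqa_log_level$level <- "info"

.level_rank <- c(debug = 1L, info = 2L, warning = 3L, error = 4L, quiet = 5L)

#' Set the logging verbosity
#'
#' Log messages go to standard error so that machine-readable results written
#' to standard output are never interleaved with diagnostics.
#'
#' @param level one of `"debug"`, `"info"`, `"warning"`, `"error"`, `"quiet"`.
#' @return the previous level, invisibly.
#' @export
pqa_log_level <- function(level = c("info", "debug", "warning", "error", "quiet")) {
  level <- match.arg(level)
  old <- .pqa_log_level$level
  .pqa_log_level$level <- level
  invisible(old)
}

pqa_log <- function(msg, level = "info") {
  if (.level_rank[[level]] >= .level_rank[[.pqa_log_level$level]]) {
    cat(sprintf("[%s] %s\n", level, msg), file = stderr())
  }
  invisible(NULL)
}
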