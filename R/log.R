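# Minimal leveled, line-oriented logger.  Controlled by
# options(ecosoc.log_level = "debug"|"info"|"warn"|"error"|"off").

.log_priorities <- c(debug = 10L, info = 20L, warn = 30L, error = 40L, off = 99L)

eh_log_threshold <- function() {
  lvl <- getOption("ecosoc.log_level", "info")
  .log_priorities[[match.arg(lvl, names(.log_priorities))]]
}

#' Emit a leveled log line
#'
#' Writes `[LEVEL] message` to the message stream when `level` is at or above
#' the threshold set by `options(ecosoc.log_level = ...)` (default `"info"`).
#'
#' @param level One of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @param fmt A [sprintf()] format string.
#' @param ... Values interpolated into `fmt`.
#' @return Invisibly, the formatted line (or `NULL` if suppressed).
#' @export
eh_log <- function(level = "info", fmt, ...) {
  level <- match.arg(level, c("debug", "info", "warn", "error"))
  if (.log_priorities[[level]] < eh_log_threshold()) return(invisible(NULL))
  line <- sprintf("[%s] %s", toupper(level), sprintf(fmt, ...))
  message(line)
  invisible(line)
}
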