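# Lightweight structured logging.  Every pipeline phase logs record counts
# in/out so "never silently drops rows" is auditable from the log alone.
# Levels: debug < info < warn.  Controlled by option "clklink.log_level"
# (default "warn" so library use is quiet; the CLI raises it to "info").

.log_levels <- c(debug = 1L, info = 2L, warn = 3L)

clk_log_level <- function() {
  lv <- getOption("clklink.log_level", "warn")
  if (!lv %in% names(.log_levels)) lv <- "warn"
  lv
}

clk_log <- function(level, ...) {
  if (.log_levels[[level]] < .log_levels[[clk_log_level()]]) return(invisible())
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", level, "] ",
                paste0(..., collapse = ""))
  message(msg)
  invisible()
}

# Data-content errors get their own condition class so the CLI can map them
# to exit code 2 (vs 1 for usage errors).
stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("clklink_data_error", "error")))
}

stop_usage <- function(...) {
  stop(errorCondition(paste0(...), class = c("clklink_usage_error", "error")))
}
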