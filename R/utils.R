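#' @keywords internal
"_PACKAGE"

## Logging: plain stderr messages with levels, controlled by
## options(entiresist.log_level = "DEBUG"|"INFO"|"WARN"|"NONE").
.log_levels <- c(DEBUG = 1L, INFO = 2L, WARN = 3L, NONE = 4L)

ers_log <- function(level, ...) {
  threshold <- getOption("entiresist.log_level", "WARN")
  if (.log_levels[[level]] >= .log_levels[[threshold]]) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

#' Derive a stable per-component seed from a master seed
#'
#' Each named component gets its own stream so that adding a component to a
#' simulation never perturbs the random numbers drawn by earlier ones.
#'
#' @param master integer master seed.
#' @param component character label of the random stream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
spawn_seed <- function(master, component) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(component))
  m <- 2147483647 # 2^31 - 1, keeps arithmetic exact in doubles
  h <- 0
  for (ch in utf8ToInt(component)) h <- (h * 131 + ch) %% m
  as.integer((abs(master) %% m + h * 7919) %% m)
}

## stop() with sprintf formatting, no call in the condition
ers_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

ers_warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
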