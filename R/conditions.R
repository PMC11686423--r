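# Structured conditions and logging shared across the pipeline.

aa_error <- function(class, message, ...) {
  structure(
    class = c(class, "aa_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
}

#' @noRd
stop_parse <- function(smiles, why = "Open Babel could not parse the SMILES") {
  stop(aa_error("aa_parse_error", sprintf("%s: '%s'", why, smiles),
                smiles = smiles))
}

stop_config <- function(message) stop(aa_error("aa_config_error", message))

stop_argument <- function(message) stop(aa_error("aa_argument_error", message))

stop_mcs_timeout <- function(budget) {
  stop(aa_error("aa_mcs_timeout",
                sprintf("MCS search exceeded the %gs time budget", budget)))
}

# Log levels: DEBUG < INFO < WARN; controlled by options(aascore.log_level=).
.log_levels <- c(DEBUG = 10L, INFO = 20L, WARN = 30L, OFF = 99L)

aa_log <- function(level, fmt, ...) {
  threshold <- getOption("aascore.log_level", "WARN")
  if (.log_levels[[level]] >= .log_levels[[threshold]]) {
    message(sprintf("[aascore %s] %s", level, sprintf(fmt, ...)))
  }
  invisible(NULL)
}
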