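# Classed conditions so callers (and the command-line wrapper) can map
# failures to config / data / analysis categories.

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("tetracond_config_error", "tetracond_error")))
}

stop_data <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("tetracond_data_error", "tetracond_error")))
}

stop_analysis <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("tetracond_analysis_error", "tetracond_error")))
}
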