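# Classed conditions so callers can distinguish bad configuration from bad
# data from genuine model failures.

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("rughc_config_error", "rughc_error")))
}

stop_data <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("rughc_data_error", "rughc_error")))
}

stop_classification <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("rughc_classification_error", "rughc_error")))
}

stop_model <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("rughc_model_error", "rughc_error")))
}

stop_parse <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("rughc_parse_error", "rughc_error")))
}
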