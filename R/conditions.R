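# Structured error conditions so callers (and the command-line front end)
# can distinguish usage, parse and degenerate-data failures.

occl_error <- function(msg, class, call. = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "occl_error", "error"),
                      call = call.))
}

occl_range_error <- function(msg) occl_error(msg, "occl_range_error")
occl_degenerate_error <- function(msg) occl_error(msg, "occl_degenerate_error")
occl_parse_error <- function(msg) occl_error(msg, "occl_parse_error")
occl_extraction_error <- function(msg) occl_error(msg, "occl_extraction_error")
occl_insufficient_data_error <- function(msg)
  occl_error(msg, "occl_insufficient_data_error")
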