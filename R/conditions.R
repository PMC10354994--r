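# Classed conditions so callers (and tests) can distinguish failure modes.
# Classes in use:
#   tpp_schema_error     missing required field/column
#   tpp_integrity_error  duplicate ids, orphan records, fixture drift
#   tpp_value_error      unparseable enum token, inadmissible rating level
#   tpp_usage_error      contract misuse (mismatched ids, unresolved sheets)
#   tpp_config_error     invalid generator/scoring configuration
#   tpp_degenerate_error degenerate input (e.g. all-unknown sheet)
#   tpp_io_error         unreadable/unwritable path

tpp_error <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "tpp_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
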