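# Condition helpers. All package errors carry a condition class so callers
# (and the CLI) can dispatch on failure kind rather than matching messages.

bn_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "bn_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

bn_parse_error      <- function(msg, line = NA_integer_)
  bn_stop("bn_parse_error", msg, line = line)
bn_validation_error <- function(msg) bn_stop("bn_validation_error", msg)
bn_unknown_node     <- function(node)
  bn_stop("bn_unknown_node", sprintf("unknown node: '%s'", node), node = node)
bn_usage_error      <- function(msg) bn_stop("bn_usage_error", msg)
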