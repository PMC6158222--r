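# Structured conditions: every package error carries class c(<specific>, "nsc_error")
# so callers (and the CLI) can distinguish user/validation errors from bugs.

nsc_abort <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "nsc_error", "error")))
}

is_identifier <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) &&
    grepl("^[A-Za-z_][A-Za-z0-9_]*$", x)
}

assert_identifier <- function(x, what) {
  if (!is_identifier(x)) {
    nsc_abort(sprintf("%s must be an identifier (letters, digits, underscore; not starting with a digit), got %s",
                      what, deparse(substitute(x))),
              "nsc_invalid_identifier")
  }
  x
}

assert_scalar_number <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    nsc_abort(sprintf("%s must be a single number", what), "nsc_invalid_argument")
  }
  as.numeric(x)
}

# empty named list, serializes as a JSON object {}
named_list <- function() structure(list(), names = character(0))
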