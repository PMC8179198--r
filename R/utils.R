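# Internal input checking helpers. All errors carry a subclass so callers and
# tests can distinguish user error ("widenedpipe_input_error") from domain
# violations of the model math ("widenedpipe_domain_error").

abort_input <- function(msg) abort(msg, class = "widenedpipe_input_error")
abort_domain <- function(msg) abort(msg, class = "widenedpipe_domain_error")

check_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_input(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (finite && !is.finite(x)) {
    abort_input(sprintf("`%s` must be finite.", name))
  }
  if (positive && x <= 0) {
    abort_input(sprintf("`%s` must be strictly positive (got %g).", name, x))
  }
  invisible(x)
}

check_numeric_vec <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x)) {
    abort_input(sprintf("`%s` must be a non-empty numeric vector without NAs.", name))
  }
  if (positive && any(x <= 0)) {
    abort_input(sprintf("`%s` must be strictly positive everywhere.", name))
  }
  invisible(x)
}

match_model <- function(model, choices = PROFILE_MODELS) {
  if (!is.character(model) || length(model) != 1L || !model %in% choices) {
    abort_input(sprintf(
      "Unknown profile model '%s'; expected one of: %s.",
      paste(model, collapse = ","), paste(choices, collapse = ", ")
    ))
  }
  model
}
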