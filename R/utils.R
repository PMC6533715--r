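# internal helpers shared across modules

abort_domain <- function(msg, ...) {
  rlang::abort(msg, class = "esitools_domain_error", ...)
}

abort_malformed <- function(msg, ...) {
  rlang::abort(msg, class = "esitools_malformed_input", ...)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# evaluate expr under a temporary RNG state; NULL seed leaves the RNG alone
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  withr::with_seed(as.integer(seed), force(expr))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopifnot_scalar_prob <- function(x, name) {
  if (!is_number(x) || x < 0 || x > 1)
    abort_domain(sprintf("`%s` must be a single value in [0, 1], got %s",
                         name, format(x)))
  invisible(x)
}
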