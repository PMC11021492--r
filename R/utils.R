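# internal helpers shared across modules

abort_bad_arg <- function(msg) {
  rlang::abort(msg, class = "ribbonhelix_domain_error")
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_lower = TRUE, allow_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_bad_arg(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (allow_lower) x >= lower else x > lower
  hi_ok <- if (allow_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    abort_bad_arg(sprintf(
      "`%s` = %g is outside its allowed range %s%g, %g%s.",
      name, x, if (allow_lower) "[" else "(", lower, upper,
      if (allow_upper) "]" else ")"
    ))
  }
  x
}

check_count <- function(x, name, lower = 1L) {
  check_number(x, name, lower = lower)
  if (x != as.integer(x)) {
    abort_bad_arg(sprintf("`%s` must be a whole number.", name))
  }
  as.integer(x)
}

# seeded evaluation that does not disturb the caller's RNG state;
# a NULL seed leaves the global stream untouched
with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
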