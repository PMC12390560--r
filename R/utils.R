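# Internal helpers: argument checks and seed plumbing.

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         closed_lower = TRUE, closed_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (closed_lower) x >= lower else x > lower
  hi_ok <- if (closed_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must be in %s%g, %g%s (got %g).",
      name, if (closed_lower) "[" else "(", lower, upper,
      if (closed_upper) "]" else ")", x
    ))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  check_number(x, name, lower = lower)
  if (x != round(x)) abort(sprintf("`%s` must be a whole number.", name))
  as.integer(x)
}

# Deterministic stream of child seeds from one base seed; kept below 2^31 so
# they stay valid R integer seeds.
derive_seed <- function(base, index) {
  base <- as.double(base)
  index <- as.double(index)
  as.integer((abs(base) * 48271 + index * 1000003 + 12345) %% 2147483563) + 1L
}

local_seed <- function(seed, env = parent.frame()) {
  withr::local_seed(as.integer(seed), .local_envir = env)
}

new_tensloop_error <- function(msg, class) {
  abort(msg, class = c(class, "tensloop_error"))
}
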