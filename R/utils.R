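# Internal validation helpers. All user-facing errors funnel through these so
# messages are uniform across modules.

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         allow_lower = TRUE, allow_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  lo_ok <- if (allow_lower) x >= lower else x > lower
  hi_ok <- if (allow_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok)
    stop(sprintf("'%s' = %g is outside its admissible range %s%g, %g%s",
                 name, x,
                 if (allow_lower) "[" else "(", lower, upper,
                 if (allow_upper) "]" else ")"),
         call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != as.integer(x) || x < lower)
    stop(sprintf("'%s' must be an integer >= %d", name, lower), call. = FALSE)
  as.integer(x)
}

# w = 0 gives a degenerate equilibrium: no environmental information ever
# enters the group, the estimate correlation tends to 1 and (for gamma > 0)
# the target error grows without bound.
check_w_positive <- function(w, name = "w") {
  check_scalar(w, name, lower = 0, upper = 1)
  if (w == 0)
    stop(sprintf(
      "degenerate equilibrium: '%s' = 0 admits no finite equilibrium (no environmental information enters the group)",
      name), call. = FALSE)
  invisible(w)
}

#' @noRd
logit <- function(p) log(p / (1 - p))

#' @noRd
inv_logit <- function(x) 1 / (1 + exp(-x))
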