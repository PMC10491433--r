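#' @keywords internal
"_PACKAGE"

# Millisecond <-> second helpers. All internal computation is in seconds
# (double precision); millisecond values appear only at API surfaces.
ms <- function(x) x / 1000
to_ms <- function(x) x * 1000

# abort with a classed condition so callers can distinguish validation,
# format and parameter errors
rc_stop <- function(msg, class = "rc_error", ...) {
  stop(structure(
    class = c(class, "rc_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

rc_assert <- function(cond, msg, class = "rc_validation_error") {
  if (!isTRUE(cond)) rc_stop(msg, class = class)
  invisible(TRUE)
}

# seed handling: all stochastic entry points take `seed`; NULL leaves the
# caller's RNG stream untouched
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    rc_assert(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
              "seed must be a single finite number", "rc_parameter_error")
    set.seed(as.integer(seed))
  }
  expr
}

# derive a child seed from a parent seed and a stream index, staying within
# 32-bit integer range
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 7907 * k) %% 2147483647)
}

# truncated normal sampler via inverse CDF (exact, vectorised)
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) return(pmin(pmax(rep(mean, n), lower), upper))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
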