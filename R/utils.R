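#' @keywords internal
"_PACKAGE"

# Error constructors: every user-facing failure carries a condition class so
# the CLI can map it to an exit code (2 usage, 1 data/validation).
ps_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "pleioscan_error")))
}

stop_format <- function(msg) ps_stop(msg, "pleioscan_format_error")
stop_validation <- function(msg) ps_stop(msg, "pleioscan_validation_error")
stop_domain <- function(msg) ps_stop(msg, "pleioscan_domain_error")
stop_usage <- function(msg) ps_stop(msg, "pleioscan_usage_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with a temporary RNG state seeded at `seed`; the caller's
# .Random.seed is restored on exit so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_domain("seed must be a single finite number")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Draws from MVN(0, Sigma) via the upper Cholesky factor; Sigma may be
# rank-deficient after a PSD repair, so fall back to an eigen square root.
rmvn0 <- function(n, Sigma) {
  p <- ncol(Sigma)
  L <- tryCatch(chol(Sigma), error = function(e) NULL)
  Z <- matrix(stats::rnorm(n * p), n, p)
  if (!is.null(L)) return(Z %*% L)
  ee <- eigen(Sigma, symmetric = TRUE)
  Z %*% (t(ee$vectors) * sqrt(pmax(ee$values, 0)))
}

# Reverse cumulative sum (sum from i to end), numerically exact enough for
# tail masses down to the double floor.
revcumsum <- function(x) rev(cumsum(rev(x)))

# Two-sided normal tail of a z-score, clipped below at the smallest positive
# normalized double so downstream logs stay finite.
two_sided_p <- function(z) {
  pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop_domain(sprintf("%s must be an integer >= %d", name, min))
  as.integer(x)
}
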