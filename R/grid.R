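# The threshold grid shared by both score functions: a geometric sequence of
# p-value thresholds alpha from the Bonferroni level 0.05/p up to 0.05, with
# matched |z| thresholds gamma = qnorm(1 - alpha/2).

#' Build the alpha / gamma threshold grid
#'
#' Defaults follow the recommended geometric sequence of length 200 from
#' `0.05/p` (Bonferroni; guarantees at least PheWAS power for independent
#' traits) to `0.05` (caps the search space).
#'
#' @param p Number of traits (sets the default lower bound).
#' @param length Grid length (default 200).
#' @param lower,upper Grid endpoints in (0, 1), `lower <= upper`.
#' @return Object of class `alpha_grid` with increasing `alphas`, decreasing
#'   `gammas`, and `p_traits = p`.
#' @export
#' @examples
#' g <- make_alpha_grid(50)
#' range(g$alphas)   # 0.001 .. 0.05
make_alpha_grid <- function(p, length = 200L, lower = 0.05 / p, upper = 0.05) {
  p <- assert_count(p, "p")
  length <- assert_count(length, "length")
  if (!is.finite(lower) || !is.finite(upper) || lower <= 0 || upper >= 1)
    stop_domain("grid endpoints must satisfy 0 < lower <= upper < 1")
  if (lower > upper) stop_domain("lower > upper")
  alphas <- if (length == 1L || lower == upper) {
    rep((lower + upper) / 2, length)
  } else {
    exp(seq(log(lower), log(upper), length.out = length))
  }
  alphas[1] <- lower; alphas[length] <- upper
  structure(list(alphas = alphas,
                 gammas = stats::qnorm(1 - alphas / 2),
                 p_traits = p,
                 length = length, lower = lower, upper = upper),
            class = "alpha_grid")
}

# Stable identity string for caching null distributions.
grid_key <- function(grid) {
  sprintf("L%d_lo%.17g_up%.17g", grid$length, grid$lower, grid$upper)
}

#' @export
print.alpha_grid <- function(x, ...) {
  cat(sprintf("<alpha_grid> length %d, alpha in [%g, %g], p=%d\n",
              x$length, x$lower, x$upper, x$p_traits))
  invisible(x)
}
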