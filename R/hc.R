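# Higher-criticism score function and its linear-time maximization.
#
# F_HC,alpha(S) = (N_alpha(S) - alpha|S|) / sqrt(|S| alpha (1 - alpha)),
# N_alpha(S) = #{j in S : p*_j < alpha} (strict), is the standardized excess
# of small p-values in S. Its priority function is the indicator
# I(p* < alpha), so at fixed alpha the optimum over all 2^p - 1 subsets is a
# prefix of traits sorted by priority (strong LTSS property).

#' Higher-criticism score of a trait subset
#'
#' @param p_star Whitened two-sided p-values (full length-p vector).
#' @param alpha Threshold in (0, 1).
#' @param subset Non-empty integer vector of trait indices.
#' @return The score `F_HC,alpha(subset)`.
#' @export
hc_score <- function(p_star, alpha, subset) {
  if (length(subset) == 0) stop_domain("subset must be non-empty")
  if (alpha <= 0 || alpha >= 1) stop_domain("alpha must be in (0, 1)")
  k <- length(subset)
  N <- sum(p_star[subset] < alpha)
  (N - alpha * k) / sqrt(k * alpha * (1 - alpha))
}

#' Linear-time subset scan with the higher-criticism score
#'
#' For each grid alpha, traits are sorted by the priority indicator
#' `I(p* < alpha)` (ties broken by ascending `p*`, then ascending trait
#' index) and the score is evaluated at every prefix; the grid-wide maximum
#' and its subset are returned. The selected subset always contains at least
#' one trait. Grid-level ties keep the smallest grid index; the maximum
#' statistic is unaffected by tie-breaking.
#'
#' @param p_star Whitened p-values (length p, finite, in (0, 1]).
#' @param grid An [make_alpha_grid()] object.
#' @return List: `statistic` (H_HC), `subset` (trait indices, priority
#'   order), `grid_index`, `alpha`, `k`, and `trace` (per-grid data.frame
#'   with the best prefix size and score).
#' @export
ltss_maximize_hc <- function(p_star, grid) {
  p_star <- as.numeric(p_star)
  p <- length(p_star)
  if (p < 1 || any(!is.finite(p_star))) stop_domain("p_star must be finite")
  L <- grid$length
  best_stat <- rep(-Inf, L); best_k <- integer(L)
  # Priority order ignoring alpha: ascending p*, ties by index. The
  # indicator sort for any alpha refines to this same order because
  # I(p* < alpha) is monotone in p*.
  ord <- order(p_star, seq_len(p))
  ps_sorted <- p_star[ord]
  ks <- seq_len(p)
  for (i in seq_len(L)) {
    a <- grid$alphas[i]
    N <- cumsum(ps_sorted < a)
    f <- (N - a * ks) / sqrt(ks * a * (1 - a))
    j <- which.max(f)
    best_stat[i] <- f[j]; best_k[i] <- j
  }
  gi <- which.max(best_stat)
  list(statistic = best_stat[gi],
       subset = ord[seq_len(best_k[gi])],
       grid_index = gi,
       alpha = grid$alphas[gi],
       k = best_k[gi],
       trace = data.frame(grid_index = seq_len(L), alpha = grid$alphas,
                          best_k = best_k, best_stat = best_stat))
}

# Vectorized H_HC over many null draws. Exploits that at fixed alpha the
# optimal prefix is all traits with p* < alpha when any exist (the score
# rises with k up to N_alpha and falls beyond), giving
#   H = max_i sqrt(N_i (1 - alpha_i) / alpha_i)  when N_L >= 1,
#   H = -sqrt(alpha_1 / (1 - alpha_1))           when no p* < any alpha_i,
# where N_i = #{p* < alpha_i}. For p*_(j) the sorted p-values, the best grid
# alpha at which N = j is achieved is the smallest alpha_i > p*_(j).
# Equivalence with ltss_maximize_hc is asserted in the test suite.
hc_stat_matrix <- function(pstar_mat, grid) {
  B <- nrow(pstar_mat); p <- ncol(pstar_mat)
  sorted <- matrix(pstar_mat[order(row(pstar_mat), pstar_mat)], B, p,
                   byrow = TRUE)
  # index of first grid alpha strictly greater than each sorted p*
  idx <- findInterval(as.vector(t(sorted)), grid$alphas) + 1L
  idx <- matrix(idx, B, p, byrow = TRUE)
  valid <- idx <= grid$length
  a <- matrix(grid$alphas[pmin(idx, grid$length)], B, p)
  j <- matrix(rep(seq_len(p), each = B), B, p)
  h <- sqrt(j * (1 - a) / a)
  h[!valid] <- -Inf
  out <- h[, 1]
  for (jj in seq_len(p)[-1]) out <- pmax(out, h[, jj])
  nosig <- -sqrt(grid$alphas[1] / (1 - grid$alphas[1]))
  pmax(out, nosig)
}

#' PheWAS minimum-p baseline
#'
#' Bonferroni-corrected per-trait testing on the raw (unwhitened) z-scores:
#' trait j is selected iff its two-sided p-value is below `level / n_tests`;
#' the null is rejected iff any trait is selected.
#'
#' @param z A [zvec()] or numeric vector of raw z-scores.
#' @param n_tests Total number of tests to correct for (>= p; e.g. traits
#'   times variants when several variants are examined).
#' @param level Family-wise error level (default 0.05).
#' @return List: `selected` (trait indices), `reject` (logical),
#'   `threshold` (per-test p-value cutoff).
#' @export
phewas_minp <- function(z, n_tests, level = 0.05) {
  zv <- if (inherits(z, "zvec")) z$z else as.numeric(z)
  n_tests <- assert_count(n_tests, "n_tests")
  if (n_tests < length(zv)) stop_domain("n_tests must be >= number of traits")
  thr <- level / n_tests
  pv <- two_sided_p(zv)
  sel <- which(pv < thr)
  list(selected = sel, reject = length(sel) > 0, threshold = thr)
}
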