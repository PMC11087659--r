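# Truncated chi-squared score function and its linear-time maximization.
#
# For a |z| threshold gamma, the subset score is
#   M_gamma(S) = sum_{j in S} I(|z*_j| > gamma) z*_j^2,
# scored by F_TC,gamma(S) = -log P(M >= m | H0) where M is the same sum over
# |S| iid standard normals. The priority function is I(|z*|>gamma) z*^2, so
# the optimum at fixed gamma is again a prefix of the priority sort.
#
# Null tail of M for k summands: each term is 0 with probability 1 - a
# (a = P(|z| > gamma)) and otherwise a gamma^2-left-truncated chi-squared(1).
# Two evaluators are provided:
#   * "convolution" (default, deterministic): binomial mixture over the
#     number of exceedances j, with the j-fold convolution of the truncated
#     chi-squared computed on a lattice (j = 1 in closed form; large j by a
#     moment-matched gamma approximation). Deterministic and history-free:
#     lattice parameters depend only on (gamma, magnitude bucket of m).
#   * "mc": cached seeded Monte-Carlo sample per (k, gamma), for
#     cross-validation of the convolution path.

.pkg_cache <- new.env(parent = emptyenv())

.TC_LATTICE_G <- 4096L   # lattice points per magnitude bucket
.TC_JMAX_CONV <- 25L     # exact convolution up to this many exceedances

# Magnitude bucket: smallest power-of-two ceiling >= max(m, 64). Evaluations
# depend only on (gamma, bucket), never on call history.
.tc_bucket <- function(m) max(64, 2^ceiling(log2(max(m, 1) * 1.0000001)))

# Lattice masses of the gamma^2-left-truncated chi-squared(1), conditional on
# exceedance; point i (i = 0..G) carries the mass of ((i-.5)h, (i+.5)h].
.tc_entry <- function(gamma, mmax) {
  key <- sprintf("tcconv_g%.15g_m%.10g", gamma, mmax)
  ent <- .pkg_cache[[key]]
  if (!is.null(ent)) return(ent)
  G <- .TC_LATTICE_G
  h <- mmax / G
  a <- 2 * stats::pnorm(-gamma)
  edges <- (seq_len(G + 1L) - 1.5) * h  # lower edges of bins 0..G
  lo <- pmax(edges[-(G + 1L)], gamma^2)
  hi <- edges[-1L]
  mass <- pmax(stats::pchisq(hi, 1) - stats::pchisq(pmin(lo, hi), 1), 0) / a
  ent <- new.env(parent = emptyenv())
  ent$h <- h; ent$G <- G; ent$a <- a; ent$gamma <- gamma
  ent$pmf <- list(mass)
  ent$overflow <- stats::pchisq(hi[G], 1, lower.tail = FALSE) / a
  ent$surv <- list(.tc_surv_lattice(mass, ent$overflow[1]))
  .pkg_cache[[key]] <- ent
  ent
}

# survLattice[i] = P(S >= (i - 1.5) h) (lower edge of bin i-1), i = 1..G+1.
.tc_surv_lattice <- function(mass, overflow) {
  c(revcumsum(mass), 0) + overflow
}

# Linear convolution via power-of-two padded FFT (stats::convolve pads to
# 2n-1, which is rarely a friendly FFT length).
.conv_fft <- function(x, y) {
  n <- length(x) + length(y) - 1L
  N <- 2^ceiling(log2(n))
  fx <- stats::fft(c(x, numeric(N - length(x))))
  fy <- stats::fft(c(y, numeric(N - length(y))))
  Re(stats::fft(fx * fy, inverse = TRUE))[seq_len(n)] / N
}

# Extend an entry's convolutions up to j summands.
.tc_extend <- function(ent, j) {
  while (length(ent$pmf) < j) {
    jj <- length(ent$pmf) + 1L
    cv <- .conv_fft(ent$pmf[[jj - 1L]], ent$pmf[[1L]])
    cv <- pmax(cv, 0)  # FFT round-off
    G1 <- ent$G + 1L
    keep <- cv[seq_len(G1)]
    over <- 1 - sum(keep)  # all off-lattice mass lies beyond mmax
    ent$pmf[[jj]] <- keep
    ent$overflow[jj] <- over
    ent$surv[[jj]] <- .tc_surv_lattice(keep, over)
  }
  invisible(ent)
}

# P(S_j >= m) with S_j a sum of j iid truncated chi-squared terms;
# vectorized over m (all m must share the entry's lattice).
.tc_Qj <- function(m, j, gamma, ent) {
  res <- rep(1, length(m))
  act <- m > j * gamma^2
  if (!any(act)) return(res)
  ma <- m[act]
  if (j == 1L) {
    # closed form: P(z^2 >= m | |z| > gamma) for m > gamma^2
    res[act] <- 2 * stats::pnorm(-sqrt(ma)) / ent$a
    return(res)
  }
  if (j > .TC_JMAX_CONV) {
    res[act] <- .tc_Qj_gamma_approx(ma, j, gamma)
    return(res)
  }
  .tc_extend(ent, j)
  s <- ent$surv[[j]]
  h <- ent$h
  # lattice point whose bin ((i-.5)h, (i+.5)h] contains m (0-based)
  i <- floor(ma / h + 0.5)
  over <- i >= ent$G
  v <- numeric(length(ma))
  v[over] <- ent$overflow[j]
  if (any(!over)) {
    io <- i[!over]
    frac <- (ma[!over] - (io - 0.5) * h) / h
    v[!over] <- pmax(s[io + 1L] - ent$pmf[[j]][io + 1L] * frac, 0)
  }
  res[act] <- v
  res
}

# Vectorized -log P(M_k >= m) over paired (m, k) vectors at one gamma.
.tc_tail_conv_vec <- function(m, k, gamma) {
  out <- numeric(length(m))
  pos <- which(m > 0)
  if (!length(pos)) return(out)
  bkt <- vapply(m[pos], .tc_bucket, numeric(1))
  for (b in unique(bkt)) {
    ent <- .tc_entry(gamma, b)
    sel <- pos[bkt == b]
    for (kk in unique(k[sel])) {
      ss <- sel[k[sel] == kk]
      w <- stats::dbinom(seq_len(kk), kk, ent$a)
      pr <- numeric(length(ss))
      for (j in seq_len(kk))
        pr <- pr + w[j] * .tc_Qj(m[ss], j, gamma, ent)
      pr <- pmin(pmax(pr, .Machine$double.xmin), 1)
      out[ss] <- -log(pr)
    }
  }
  out
}

# Central moments of the truncated chi-squared(1) (conditional on |z|>gamma),
# from the closed-form upper partial moments of z^2.
.tc_cond_moments <- function(gamma) {
  a <- 2 * stats::pnorm(-gamma)
  phi <- stats::dnorm(gamma)
  tail <- stats::pnorm(gamma, lower.tail = FALSE)
  m1 <- 2 * (gamma * phi + tail) / a
  m2 <- 2 * (gamma^3 * phi + 3 * gamma * phi + 3 * tail) / a
  m3 <- 2 * (gamma^5 * phi + 5 * gamma^3 * phi + 15 * gamma * phi +
               15 * tail) / a
  list(mean = m1, var = m2 - m1^2,
       mu3 = m3 - 3 * m1 * m2 + 2 * m1^3)
}

# Three-moment shifted-gamma approximation for large j (ranking use only;
# the outer Monte-Carlo null calibrates the final p-values). Vectorized in m.
.tc_Qj_gamma_approx <- function(m, j, gamma) {
  mo <- .tc_cond_moments(gamma)
  mu <- j * mo$mean; v <- j * mo$var; mu3 <- j * mo$mu3
  skew <- mu3 / v^1.5
  if (skew <= 0) return(stats::pnorm(m, mu, sqrt(v), lower.tail = FALSE))
  shape <- 4 / skew^2
  scale <- sqrt(v / shape)
  loc <- mu - shape * scale
  ifelse(m <= loc, 1,
         stats::pgamma(m - loc, shape = shape, scale = scale,
                       lower.tail = FALSE))
}

.tc_tail_conv <- function(m, k, gamma) {
  .tc_tail_conv_vec(m, k, gamma)[1]
}

.tc_tail_mc <- function(m, k, gamma, draws = 200000L) {
  if (m <= 0) return(0)
  key <- sprintf("tcmc_g%.15g_k%d_n%d", gamma, k, draws)
  M <- .pkg_cache[[key]]
  if (is.null(M)) {
    a <- 2 * stats::pnorm(-gamma)
    seed <- (7654321L + 97L * k + abs(round(gamma * 1e5))) %% 2147483647L
    M <- with_seed(seed, {
      js <- stats::rbinom(draws, k, a)
      tot <- sum(js)
      out <- numeric(draws)
      if (tot > 0) {
        u <- stats::runif(tot) * a
        C <- stats::qnorm(1 - u / 2)^2
        s <- rowsum(C, rep.int(seq_len(draws), js))
        out[as.integer(rownames(s))] <- s[, 1]
      }
      sort(out)
    })
    .pkg_cache[[key]] <- M
  }
  cnt <- length(M) - findInterval(m, M, left.open = TRUE)
  phat <- max(cnt, 1) / length(M)  # resolution floor 1/draws
  -log(phat)
}

#' Negative log null tail of the truncated chi-squared subset score
#'
#' Returns `-log P(M >= m)` where `M` is the sum of `k` iid terms, each equal
#' to `z^2` when `|z| > gamma` (z standard normal) and 0 otherwise.
#' `m = 0` returns 0 exactly (the tail probability is 1).
#'
#' @param m Observed subset score (`>= 0`).
#' @param k Number of traits in the subset (`>= 1`).
#' @param gamma `|z|` threshold (`>= 0`).
#' @param method `"convolution"` (deterministic; default) or `"mc"` (cached
#'   seeded Monte-Carlo sample, for cross-validation).
#' @param draws Monte-Carlo sample size for `method = "mc"`.
#' @return The score `F_TC,gamma` as a non-negative number.
#' @export
#' @examples
#' tc_tail_neglog(4, k = 1, gamma = 1)   # -log P(|z| >= 2) ~ 3.09
tc_tail_neglog <- function(m, k, gamma, method = c("convolution", "mc"),
                           draws = 200000L) {
  method <- match.arg(method)
  if (m < 0 || !is.finite(m)) stop_domain("m must be finite and >= 0")
  k <- assert_count(k, "k")
  if (gamma < 0) stop_domain("gamma must be >= 0")
  if (method == "mc") .tc_tail_mc(m, k, gamma, draws)
  else .tc_tail_conv(m, k, gamma)
}

# Core TC scan shared by the user-facing maximizer and the null simulator.
# Only prefixes up to the number of exceedances are scored: adding a trait
# with zero priority keeps m fixed while enlarging the null sum, which can
# only lower -log P.
.tc_scan_core <- function(z_star, grid, want_trace = FALSE) {
  z2 <- z_star^2
  p <- length(z2)
  ord <- order(-z2, seq_len(p))
  v <- z2[ord]
  cum <- cumsum(v)
  L <- grid$length
  g2 <- grid$gammas^2
  ne <- findInterval(-g2, sort(-v), left.open = TRUE)  # count v > g2, strict
  best_stat <- numeric(L); best_k <- rep(1L, L)
  for (i in seq_len(L)) {
    n_e <- ne[i]
    if (n_e == 0L) next  # M = 0 for every subset: F = 0, k = 1 tie-break
    ks <- seq_len(n_e)
    f <- .tc_tail_conv_vec(cum[ks], ks, grid$gammas[i])
    j <- which.max(f)
    if (f[j] > 0) { best_stat[i] <- f[j]; best_k[i] <- j }
  }
  gi <- which.max(best_stat)
  out <- list(statistic = best_stat[gi],
              subset = ord[seq_len(best_k[gi])],
              grid_index = gi,
              gamma = grid$gammas[gi],
              k = best_k[gi])
  if (want_trace)
    out$trace <- data.frame(grid_index = seq_len(L), gamma = grid$gammas,
                            n_exceed = ne, best_k = best_k,
                            best_stat = best_stat)
  out
}

#' Linear-time subset scan with the truncated chi-squared score
#'
#' For each grid gamma, traits are sorted by descending priority
#' `I(|z*| > gamma) z*^2` (ties by ascending trait index) and
#' `F_TC = -log P(M >= m)` is evaluated at each prefix; the grid-wide
#' maximum and its subset are returned. With no exceedance anywhere the
#' statistic is 0 and the single highest-priority trait is returned.
#'
#' @param z_star Whitened z-scores (finite).
#' @param grid An [make_alpha_grid()] object (its `gammas` are used).
#' @return List: `statistic` (H_TC), `subset` (trait indices, priority
#'   order), `grid_index`, `gamma`, `k`, `trace`.
#' @export
ltss_maximize_tc <- function(z_star, grid) {
  z_star <- as.numeric(z_star)
  if (length(z_star) < 1 || any(!is.finite(z_star)))
    stop_domain("z_star must be finite")
  .tc_scan_core(z_star, grid, want_trace = TRUE)
}

#' Exhaustive subset scan (test oracle)
#'
#' Evaluates the score of every non-empty subset at every grid value; the
#' true maximum for up to 20 traits. Quadratic-exponential cost: intended
#' only for validating the linear-time scan.
#'
#' @param p_star Whitened p-values (for `method = "hc"`).
#' @param z_star Whitened z-scores (for `method = "tc"`).
#' @param grid An [make_alpha_grid()] object.
#' @param method `"hc"` or `"tc"`.
#' @return List: `statistic`, `subset` (ascending trait indices),
#'   `grid_index`, `k`.
#' @export
exhaustive_scan <- function(p_star = NULL, z_star = NULL, grid,
                            method = c("hc", "tc")) {
  method <- match.arg(method)
  x <- if (method == "hc") p_star else z_star
  if (is.null(x)) stop_domain("provide p_star (hc) or z_star (tc)")
  p <- length(x)
  if (p > 20) ps_stop("exhaustive scan capped at p = 20",
                      "pleioscan_refusal_error")
  nsub <- 2^p - 1
  mask <- matrix(FALSE, nsub, p)
  for (j in seq_len(p)) mask[, j] <- bitwAnd(seq_len(nsub), bitwShiftL(1L, j - 1L)) > 0
  ks <- rowSums(mask)
  # Subsets are enumerated over traits reordered by descending z^2 so that
  # each subset score is accumulated in the same (descending) order as the
  # linear-time scan's prefix sums: addition is commutative, but bitwise
  # score equality requires a fixed summation order.
  ordv <- if (method == "tc") order(-z_star^2, seq_len(p)) else seq_len(p)
  best <- -Inf; best_sub <- NULL; best_gi <- NA_integer_
  for (i in seq_len(grid$length)) {
    if (method == "hc") {
      a <- grid$alphas[i]
      N <- as.vector(mask %*% (p_star < a))
      f <- (N - a * ks) / sqrt(ks * a * (1 - a))
    } else {
      g <- grid$gammas[i]
      v <- z_star[ordv]^2
      Gpr <- ifelse(v > g^2, v, 0)
      m <- rowSums(mask * rep(Gpr, each = nsub))
      f <- numeric(nsub)  # m = 0 scores 0
      pos <- which(m > 0)
      if (length(pos)) {
        # score depends on (m, k) only: evaluate unique pairs per k
        for (kk in unique(ks[pos])) {
          ss <- pos[ks[pos] == kk]
          um <- unique(m[ss])
          fu <- .tc_tail_conv_vec(um, rep(kk, length(um)), g)
          f[ss] <- fu[match(m[ss], um)]
        }
      }
    }
    j <- which.max(f)
    if (f[j] > best) { best <- f[j]; best_sub <- sort(ordv[mask[j, ]]); best_gi <- i }
  }
  list(statistic = best, subset = best_sub, grid_index = best_gi,
       k = length(best_sub))
}

# Clear all internal caches (testing / memory management helper).
clear_caches <- function() {
  rm(list = ls(envir = .pkg_cache), envir = .pkg_cache)
  invisible(NULL)
}
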