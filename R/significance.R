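# Null calibration. Both scan statistics are maximized over correlated grid
# thresholds, so their null laws are non-standard; they are simulated once
# per (p, grid, B, seed) -- the null depends on nothing else, because the
# whitened z-scores are iid standard normal under H0 -- and reused across
# variants. H_HC additionally admits an exact analytic tail via a
# boundary-crossing recursion for uniform order statistics.

#' Simulate the joint null distribution of the scan statistics
#'
#' Draws `B` vectors of `p` iid standard normal z-scores (the null is already
#' white, so no whitening is involved), runs both linear-time scans on each,
#' and records the paired statistics. Results are cached in memory, and
#' optionally on disk, keyed by `(p, grid, B, seed)`; a cache hit returns the
#' identical object without recomputation.
#'
#' @param p Number of traits.
#' @param grid An [make_alpha_grid()] object.
#' @param B Number of Monte-Carlo draws (>= 100).
#' @param seed RNG seed (bit-for-bit reproducibility).
#' @param cache_dir Optional directory for a TSV-backed cache.
#' @param verbose Log cache hits to stderr.
#' @return Object of class `null_distribution`: sorted `h_hc`, `h_tc`,
#'   unsorted `joint` (B x 2 matrix), and the defining key fields.
#' @export
simulate_null <- function(p, grid, B = 10000L, seed = 1L, cache_dir = NULL,
                          verbose = FALSE) {
  p <- assert_count(p, "p")
  B <- assert_count(B, "B", min = 100L)
  seed <- assert_count(seed, "seed", min = 0L)
  key <- sprintf("null_p%d_%s_B%d_seed%d", p, grid_key(grid), B, seed)
  hit <- .pkg_cache[[key]]
  if (!is.null(hit)) {
    if (verbose) message("null cache hit (memory): ", key)
    return(hit)
  }
  if (!is.null(cache_dir)) {
    f <- file.path(cache_dir, paste0(key, ".tsv"))
    if (file.exists(f)) {
      if (verbose) message("null cache hit (disk): ", f)
      df <- utils::read.delim(f, sep = "\t", comment.char = "#")
      nd <- .null_distribution(p, grid, B, seed, key,
                               cbind(df$h_hc, df$h_tc))
      .pkg_cache[[key]] <- nd
      return(nd)
    }
  }
  Z <- with_seed(seed, matrix(stats::rnorm(B * p), B, p))
  h_hc <- hc_stat_matrix(two_sided_p(Z), grid)
  h_tc <- vapply(seq_len(B), function(b)
    .tc_scan_core(Z[b, ], grid)$statistic, numeric(1))
  nd <- .null_distribution(p, grid, B, seed, key, cbind(h_hc, h_tc))
  .pkg_cache[[key]] <- nd
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    f <- file.path(cache_dir, paste0(key, ".tsv"))
    con <- file(f, "w")
    writeLines(sprintf("# pleioscan null cache p=%d grid=%s B=%d seed=%d",
                       p, grid_key(grid), B, seed), con)
    utils::write.table(
      data.frame(h_hc = format(h_hc, digits = 17, trim = TRUE),
                 h_tc = format(h_tc, digits = 17, trim = TRUE)),
      con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  nd
}

.null_distribution <- function(p, grid, B, seed, key, joint) {
  colnames(joint) <- c("h_hc", "h_tc")
  structure(list(p_traits = p, grid = grid, grid_hash = grid_key(grid),
                 B = B, seed = seed, key = key,
                 h_hc = sort(joint[, 1]), h_tc = sort(joint[, 2]),
                 joint = joint),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> p=%d, B=%d, seed=%d, grid %s\n",
              x$p_traits, x$B, x$seed, x$grid_hash))
  invisible(x)
}

#' Monte-Carlo p-value against simulated null draws
#'
#' Default `"strict"` convention: `(#\{h_b > h_obs\} + 1) / (B + 1)`, bounded
#' below by `1/(B+1)`. Ties at the observed value are excluded because the
#' higher-criticism null is discrete with a large atom (mass about
#' `1 - (1 - 0.05/p)^p`, the Bonferroni event) at its top value; counting
#' ties would drive the test's size at level 0.05 down to a few per mille.
#' `"conservative"` counts ties (`#\{h_b >= h_obs\}`; valid under any
#' discreteness, at the price of that conservatism). `"eq13"` is the literal
#' fraction of null draws strictly below the observed statistic (the
#' complement of a tail probability), kept only for reproduction purposes.
#'
#' @param h_obs Observed statistic.
#' @param null_draws Numeric vector of null statistics (sorted or not).
#' @param convention `"strict"` (default), `"conservative"`, or `"eq13"`.
#' @return The p-value (for `"eq13"`, the literal complement fraction).
#' @export
mc_pvalue <- function(h_obs, null_draws,
                      convention = c("strict", "conservative", "eq13")) {
  convention <- match.arg(convention)
  if (length(null_draws) < 1) stop_domain("need at least one null draw")
  if (is.unsorted(null_draws)) null_draws <- sort(null_draws)
  B <- length(null_draws)
  n_below <- findInterval(h_obs, null_draws, left.open = TRUE)  # strictly <
  n_le <- findInterval(h_obs, null_draws)                       # <=
  switch(convention,
         eq13 = n_below / B,
         conservative = (B - n_below + 1) / (B + 1),
         strict = (B - n_le + 1) / (B + 1))
}

#' Analytic tail probability of the higher-criticism scan statistic
#'
#' Under H0 the whitened p-values are iid uniform, and `H_HC > h` (for
#' `h > 0`) iff the p-value counting process crosses the boundary
#' `N_alpha >= floor(h^2 alpha/(1-alpha)) + 1` at some grid alpha. The
#' non-crossing probability is computed exactly by a Markov recursion on the
#' counts over the grid thresholds (counts in disjoint intervals of (0,1)
#' are conditionally binomial). The strict tail `P(H > h)` matches the
#' default `"strict"` convention of [mc_pvalue()]; see there for why ties
#' are excluded.
#'
#' @param h_obs Observed H_HC.
#' @param p Number of traits.
#' @param grid An [make_alpha_grid()] object.
#' @return `P(H_HC > h_obs)` under the null; `NA` with a warning when
#'   `p > 5000` (use [mc_pvalue()] instead).
#' @export
hc_pvalue_analytic <- function(h_obs, p, grid) {
  p <- assert_count(p, "p")
  if (p > 5000) {
    warning("p > 5000: analytic HC tail is numerically impractical; use MC")
    return(NA_real_)
  }
  if (!is.finite(h_obs)) return(if (h_obs > 0) 0 else 1)
  a <- grid$alphas
  nosig <- -sqrt(a[1] / (1 - a[1]))
  aL <- a[grid$length]
  if (h_obs < nosig) return(1)
  if (h_obs <= 0) return(1 - (1 - aL)^p)
  # smallest count at alpha_i achieving F > h strictly (at least 1 trait);
  # x within rounding error of an integer is treated as attaining equality
  x <- h_obs^2 * a / (1 - a)
  n_min <- pmax(1, floor(x * (1 + 1e-12) + 1e-12) + 1)
  m_allow <- n_min - 1          # largest non-crossing count
  con <- which(m_allow < p)     # only constraining thresholds matter
  if (length(con) == 0) return(0)  # boundary unreachable never happens here
  # deduplicate equal alphas (degenerate grids), keeping tightest bound
  au <- a[con]; mu <- m_allow[con]
  keep <- !duplicated(au)
  au2 <- au[keep]
  mu2 <- vapply(split(mu, match(au, au2)), min, numeric(1))
  v <- 1; counts <- 0L  # state: P(N = counts, no crossing)
  a_prev <- 0
  for (i in seq_along(au2)) {
    q <- (au2[i] - a_prev) / (1 - a_prev)
    mi <- mu2[i]
    new_counts <- 0:mi
    vn <- numeric(mi + 1L)
    for (s in seq_along(counts)) {
      cs <- counts[s]
      add <- new_counts[new_counts >= cs] - cs
      vn[cs + add + 1L] <- vn[cs + add + 1L] +
        v[s] * stats::dbinom(add, p - cs, q)
    }
    v <- vn; counts <- new_counts; a_prev <- au2[i]
  }
  max(0, min(1, 1 - sum(v)))
}

#' Combine the HC and TC tests
#'
#' Reported p-values for each statistic are compared and the combined
#' statistic is their minimum. Its null distribution preserves the HC/TC
#' dependence: each null draw is converted to a pair of pooled pseudo
#' p-values (strict exceedance counts against all `B` draws) and the
#' per-draw minima form the combined null. Ties between `p_HC` and `p_TC`
#' award the subset to HC.
#'
#' @param h_hc_obs,h_tc_obs Observed statistics.
#' @param null A [simulate_null()] object built with the same `p` and grid.
#' @param p_hc,p_tc Optional externally computed p-values (e.g. analytic HC);
#'   defaults to conservative MC against `null`.
#' @param eq13 Use the literal complement convention for the reported
#'   marginal p-values (reproduction only; the combined ranking is unchanged).
#' @return List: `p_HC`, `p_TC`, `H_combined` (`= min(p_HC, p_TC)`),
#'   `p_combined`, `winner` (`"hc"` or `"tc"`).
#' @export
combined_test <- function(h_hc_obs, h_tc_obs, null, p_hc = NULL, p_tc = NULL,
                          eq13 = FALSE) {
  if (!inherits(null, "null_distribution"))
    stop_validation("null must come from simulate_null()")
  conv <- if (eq13) "eq13" else "strict"
  p_hc <- p_hc %||% mc_pvalue(h_hc_obs, null$h_hc, conv)
  p_tc <- p_tc %||% mc_pvalue(h_tc_obs, null$h_tc, conv)
  B <- null$B
  # pooled within-sample pseudo p-values (strict: #{h' > h}/B, so a draw is
  # never its own tie; exchangeable with the observed variant's count)
  ps_hc_b <- (B - rank(null$joint[, 1], ties.method = "max")) / B
  ps_tc_b <- (B - rank(null$joint[, 2], ties.method = "max")) / B
  h_comb_b <- pmin(ps_hc_b, ps_tc_b)
  B_le_hc <- findInterval(h_hc_obs, null$h_hc)
  B_le_tc <- findInterval(h_tc_obs, null$h_tc)
  h_comb_obs <- min(B - B_le_hc, B - B_le_tc) / B
  p_combined <- (sum(h_comb_b < h_comb_obs) + 1) / (B + 1)
  list(p_HC = p_hc, p_TC = p_tc,
       H_combined = min(p_hc, p_tc),
       p_combined = p_combined,
       winner = if (p_hc <= p_tc) "hc" else "tc")
}

#' Scan one variant and test its significance
#'
#' The full pipeline for one z-score vector: optional trait pruning, PSD
#' repair of the correlation matrix, ZCA-cor whitening, both linear-time
#' scans, and the combined significance test against a (cached) simulated
#' null. A pure function of its inputs and `seed`.
#'
#' @param z A [zvec()] or numeric z-score vector. Traits with missing z are
#'   dropped with a warning and the scan runs at the effective p (the default
#'   grid lower bound is recomputed).
#' @param R A [trait_cor()] matching the trait order of `z`.
#' @param grid Optional [make_alpha_grid()]; default built for the effective
#'   number of traits.
#' @param null Optional precomputed [simulate_null()]; must match p and grid.
#' @param B,seed Null simulation size and seed (used when `null` is NULL).
#' @param hc_pvalue `"analytic"` (default; exact) or `"mc"`.
#' @param eq13 Report literal complement-convention marginal p-values.
#' @param max_abs_cor Optional pruning threshold: among any trait pair with
#'   `|R| >` this value the later trait is dropped before scanning (off by
#'   default).
#' @param diag_cor_threshold Interpretability flag threshold on
#'   `cor(z*_j, z_j)` (default 0.7).
#' @param eigenfloor Eigenvalue floor for PSD repair / whitening.
#' @param cache_dir Optional on-disk null cache directory.
#' @return Object of class `scan_result`.
#' @export
scan_and_test <- function(z, R, grid = NULL, null = NULL, B = 10000L,
                          seed = 1L, hc_pvalue = c("analytic", "mc"),
                          eq13 = FALSE, max_abs_cor = NULL,
                          diag_cor_threshold = 0.7, eigenfloor = 1e-8,
                          cache_dir = NULL) {
  hc_pvalue <- match.arg(hc_pvalue)
  variant_id <- if (inherits(z, "zvec")) z$variant_id else "variant"
  zv <- if (inherits(z, "zvec")) z$z else as.numeric(z)
  trait_ids <- if (inherits(z, "zvec")) z$trait_ids else
    R$trait_ids[seq_along(zv)]
  if (length(zv) != length(R$trait_ids))
    stop_validation("z and R dimensions differ")
  if (inherits(z, "zvec") && !identical(z$trait_ids, R$trait_ids))
    stop_validation("z and R trait orders differ")

  keep <- which(!is.na(zv))
  dropped <- setdiff(seq_along(zv), keep)
  if (length(dropped)) {
    warning(sprintf("dropping %d trait(s) with missing z: %s",
                    length(dropped),
                    paste(trait_ids[dropped], collapse = ", ")))
  }
  if (!is.null(max_abs_cor)) {
    Rk <- R$R[keep, keep, drop = FALSE]
    prune <- logical(length(keep))
    for (jj in seq_along(keep)[-1]) {
      if (any(abs(Rk[seq_len(jj - 1), jj])[!prune[seq_len(jj - 1)]] >
                max_abs_cor))
        prune[jj] <- TRUE
    }
    if (any(prune)) {
      warning(sprintf("pruning %d highly correlated trait(s)", sum(prune)))
      keep <- keep[!prune]
    }
  }
  if (length(keep) < 1) stop_validation("no usable traits left")
  p_eff <- length(keep)
  zv <- zv[keep]
  Reff <- repair_psd(trait_cor(R$R[keep, keep, drop = FALSE],
                               R$trait_ids[keep], source = R$source),
                     eigenfloor)
  grid <- grid %||% make_alpha_grid(p_eff)

  wh <- zca_cor_whiten(zv, Reff, eigenfloor, diag_cor_threshold)
  hc <- ltss_maximize_hc(wh$p_star, grid)
  tc <- .tc_scan_core(wh$z_star, grid, want_trace = TRUE)

  null <- null %||% simulate_null(p_eff, grid, B = B, seed = seed,
                                  cache_dir = cache_dir)
  if (null$p_traits != p_eff || null$grid_hash != grid_key(grid))
    stop_validation("null distribution does not match p or grid")

  p_hc <- NULL
  if (hc_pvalue == "analytic" && p_eff <= 5000)
    p_hc <- hc_pvalue_analytic(hc$statistic, p_eff, grid)
  ct <- combined_test(hc$statistic, tc$statistic, null, p_hc = p_hc,
                      eq13 = eq13)
  S_comb <- if (ct$winner == "hc") hc$subset else tc$subset
  structure(list(
    variant_id = variant_id,
    trait_ids = Reff$trait_ids,
    H_HC = hc$statistic, p_HC = ct$p_HC, S_HC = hc$subset,
    H_TC = tc$statistic, p_TC = ct$p_TC, S_TC = tc$subset,
    H_combined = ct$H_combined, p_combined = ct$p_combined,
    S_combined = S_comb, winner = ct$winner,
    diag_cor = wh$diag_cor, flagged = wh$flagged,
    dropped_traits = trait_ids[dropped],
    provenance = list(p = p_eff, grid_length = grid$length,
                      grid_lower = grid$lower, grid_upper = grid$upper,
                      B = null$B, seed = null$seed,
                      correlation_source = Reff$source,
                      eigenfloor_applied = Reff$eigenfloor_applied,
                      hc_pvalue = if (is.null(p_hc)) "mc" else "analytic")),
    class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result> %s (p=%d traits)\n", x$variant_id,
              length(x$trait_ids)))
  cat(sprintf("  HC:  H=%.4f p=%.4g |S|=%d\n", x$H_HC, x$p_HC, length(x$S_HC)))
  cat(sprintf("  TC:  H=%.4f p=%.4g |S|=%d\n", x$H_TC, x$p_TC, length(x$S_TC)))
  cat(sprintf("  combined: p=%.4g winner=%s selected: %s\n",
              x$p_combined, x$winner,
              paste(x$trait_ids[x$S_combined], collapse = ", ")))
  invisible(x)
}
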