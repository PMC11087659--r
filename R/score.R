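# Genetic-score extension: rebuild the score-level association z-statistic
# for each trait from per-SNP summary statistics, the score weights, and
# reference-panel LD, then feed the ordinary scan. For the score
# X_gs = sum_l c_l X_l regressed on trait y (n individuals):
#   beta_gs = (X'X)^-1 X'y,  se^2 = sigma2 / X'X,
#   sigma2  = (y'y - beta_gs X'y) / (n - q),
# where X'X is reconstructed from reference LD, (X'y)_l = n s_l^2 beta_l
# from the per-SNP marginal estimates, and y'y from the per-SNP OLS identity
# aggregated by the median.

#' Build a genetic-score model from weights and reference dosages
#'
#' @param weights A `score_weights` data.frame ([read_score_weights()] or
#'   equivalent with columns `variant_id`, `effect_allele`, `other_allele`,
#'   `weight`).
#' @param dosages Reference-panel matrix (individuals x q) of effect-allele
#'   dosages, columns ordered/named as in `weights`.
#' @return Object of class `score_model`: `variant_ids`, `weights`, alleles,
#'   `ld` (q x q covariance of centred dosages, 1/(n_ref - 1) denominator),
#'   `snp_var` (its diagonal), `n_ref`.
#' @export
score_model <- function(weights, dosages) {
  d <- as.matrix(dosages)
  if (ncol(d) != nrow(weights))
    stop_validation("dosage columns must match score SNPs")
  if (!is.null(colnames(d)) &&
      !identical(colnames(d), as.character(weights$variant_id)))
    d <- d[, as.character(weights$variant_id), drop = FALSE]
  if (nrow(d) < 2) stop_domain("reference panel needs >= 2 individuals")
  ld <- stats::cov(d)  # centred, 1/(n_ref - 1)
  sv <- diag(ld)
  if (any(sv <= 0))
    stop_validation(sprintf("zero-variance reference SNP(s): %s",
      paste(weights$variant_id[sv <= 0], collapse = ", ")))
  structure(list(variant_ids = as.character(weights$variant_id),
                 weights = as.numeric(weights$weight),
                 effect_allele = weights$effect_allele,
                 other_allele = weights$other_allele,
                 ld = ld, snp_var = sv, n_ref = nrow(d)),
            class = "score_model")
}

#' Convert logistic GWAS coefficients to the linear-model scale
#'
#' First-order approximation for small effects: the linear-scale coefficient
#' and SE are the logistic ones multiplied by `f = r / (1 + r)^2` where
#' `r = n_control / n_case` is the control:case ratio (equal to
#' `exp(-intercept)` of the marginal logistic fit). The z-score is invariant.
#'
#' @param b,se_b Logistic regression coefficient and standard error.
#' @param n_case,n_control Case and control counts (both > 0).
#' @return List with `beta` and `se` on the linear scale.
#' @export
#' @examples
#' logistic_to_linear(0.4, 0.1, 500, 500)  # f = 1/4
logistic_to_linear <- function(b, se_b, n_case, n_control) {
  n_case <- assert_count(n_case, "n_case")
  n_control <- assert_count(n_control, "n_control")
  if (any(se_b <= 0)) stop_domain("se_b must be positive")
  r <- n_control / n_case
  f <- r / (1 + r)^2
  list(beta = f * b, se = f * se_b)
}

#' Estimate y'y from per-SNP summary statistics
#'
#' Each SNP yields `n^2 s_l^2 se_l^2 + n s_l^2 beta_l^2` (the OLS identity
#' for a centred outcome); the estimates are aggregated by their median.
#'
#' @param beta,se Per-SNP marginal coefficients and SEs (linear scale).
#' @param s2 Per-SNP genotype variances from the reference panel.
#' @param n Trait sample size.
#' @return The median y'y estimate.
#' @export
estimate_yty <- function(beta, se, s2, n) {
  if (length(beta) < 1) stop_domain("need at least one SNP")
  if (any(s2 <= 0)) stop_domain("SNP variances must be positive")
  stats::median(n^2 * s2 * se^2 + n * s2 * beta^2)
}

#' Score-level association statistics for one trait
#'
#' @param summary_df data.frame of per-SNP summary statistics for one trait:
#'   columns `variant_id`, `beta`, `se`, optionally `effect_allele` /
#'   `other_allele` for harmonization against the score's alleles (swapped
#'   alleles flip the sign of beta).
#' @param score A [score_model()].
#' @param n Sample size of the trait.
#' @param trait_id Optional label.
#' @param df Residual degrees of freedom: `"n_minus_q"` (default, as in the
#'   summary-statistic derivation) or `"n_minus_1"` (single-predictor
#'   regression).
#' @return Object of class `score_association`: `beta_gs`, `se_gs`, `z_gs`,
#'   `yty_estimate`, `n_used`.
#' @export
score_association <- function(summary_df, score, n, trait_id = "trait",
                              df = c("n_minus_q", "n_minus_1")) {
  df <- match.arg(df)
  n <- assert_count(n, "n")
  q <- length(score$weights)
  if (n <= q) stop_domain("n must exceed the number of score SNPs")
  idx <- match(score$variant_ids, summary_df$variant_id)
  if (anyNA(idx))
    ps_stop(sprintf("summary statistics missing for SNP(s): %s",
                    paste(score$variant_ids[is.na(idx)], collapse = ", ")),
            "pleioscan_lookup_error")
  beta <- as.numeric(summary_df$beta[idx])
  se <- as.numeric(summary_df$se[idx])
  if (any(se <= 0)) stop_validation("non-positive se in summary statistics")
  if (all(c("effect_allele", "other_allele") %in% names(summary_df))) {
    ea <- toupper(summary_df$effect_allele[idx])
    oa <- toupper(summary_df$other_allele[idx])
    sea <- toupper(score$effect_allele); soa <- toupper(score$other_allele)
    same <- ea == sea & oa == soa
    swap <- ea == soa & oa == sea
    if (any(!same & !swap))
      stop_validation(sprintf("allele mismatch for SNP(s): %s",
        paste(score$variant_ids[!same & !swap], collapse = ", ")))
    beta[swap] <- -beta[swap]
  }
  cvec <- score$weights
  xtx <- n * drop(crossprod(cvec, score$ld %*% cvec))
  if (xtx <= 0) stop_validation("score has zero variance in the reference")
  xty_l <- n * score$snp_var * beta
  xty <- sum(cvec * xty_l)
  beta_gs <- xty / xtx
  yty <- estimate_yty(beta, se, score$snp_var, n)
  dof <- if (df == "n_minus_q") n - q else n - 1
  sigma2 <- (yty - beta_gs * xty) / dof
  if (sigma2 <= 0)
    stop_validation(paste0("non-positive residual variance estimate (y'y = ",
                           format(yty), "): summary statistics and reference ",
                           "panel appear inconsistent"))
  se_gs <- sqrt(sigma2 / xtx)
  structure(list(trait_id = trait_id, beta_gs = beta_gs, se_gs = se_gs,
                 z_gs = beta_gs / se_gs, yty_estimate = yty, n_used = n),
            class = "score_association")
}

#' Scan a genetic score against all traits
#'
#' Builds the score-level z-statistic for every trait (converting binary
#' traits from the logistic to the linear scale first; the z is invariant)
#' and runs [scan_and_test()] with the same trait correlation matrix used
#' for single variants, valid because under the null the z-score covariance
#' of the score equals that of a single SNP.
#'
#' @param summaries Named list (one element per trait, ordered as in `meta`)
#'   of per-SNP summary data.frames as in [score_association()].
#' @param score A [score_model()].
#' @param meta List of [trait_meta()] giving per-trait type and sample sizes.
#' @param R A [trait_cor()] in the same trait order.
#' @param score_id Variant id used for the result (default `"score"`).
#' @param ... Passed to [scan_and_test()].
#' @return A `scan_result`; the per-trait `score_association`s are attached
#'   as attribute `"associations"`.
#' @export
score_scan <- function(summaries, score, meta, R, score_id = "score", ...) {
  if (inherits(meta, "trait_meta")) meta <- list(meta)
  trait_ids <- vapply(meta, `[[`, "", "trait_id")
  if (length(summaries) != length(meta))
    stop_validation("one summary table per trait is required")
  assoc <- vector("list", length(meta))
  for (j in seq_along(meta)) {
    m <- meta[[j]]
    sm <- summaries[[j]]
    if (m$trait_type == "binary") {
      conv <- logistic_to_linear(sm$beta, sm$se, m$n_case, m$n_control)
      sm$beta <- conv$beta; sm$se <- conv$se
    }
    assoc[[j]] <- score_association(sm, score, m$n, trait_id = m$trait_id)
  }
  zv <- zvec(score_id, trait_ids, vapply(assoc, `[[`, 0, "z_gs"))
  res <- scan_and_test(zv, R, ...)
  attr(res, "associations") <- assoc
  res
}
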