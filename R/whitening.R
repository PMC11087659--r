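# ZCA-cor whitening. With R the null correlation of the z-scores, the
# whitener is the unique symmetric inverse square root W = R^(-1/2): among
# all whitening transforms it maximizes the sum of correlations between each
# whitened coordinate and its original, which keeps the scanned traits
# interpretable.

# Symmetric matrix powers via eigendecomposition with an eigenvalue floor.
.sym_power <- function(R, power, eigenfloor = 1e-8) {
  ee <- eigen(R, symmetric = TRUE)
  lam <- ee$values
  # half-floor tolerance: diagonal renormalization after a repair can nudge
  # a floored eigenvalue marginally below the floor
  if (min(lam) < eigenfloor / 2 && power < 0)
    ps_stop(paste0("correlation matrix is singular (min eigenvalue ",
                   format(min(lam)), "); repair it with repair_psd() or ",
                   "prune near-duplicate traits"),
            "pleioscan_singular_error")
  lam <- pmax(lam, eigenfloor)
  M <- ee$vectors %*% (lam^power * t(ee$vectors))
  (M + t(M)) / 2
}

#' ZCA-cor whitening of a z-score vector
#'
#' Computes `z* = R^(-1/2) z` with the symmetric (eigendecomposition) inverse
#' square root, the two-sided p-values `p* = 2(1 - Phi(|z*|))`, and the
#' implied per-trait correlation `cor(z*_j, z_j) = (R^(1/2))_jj` used as an
#' interpretability diagnostic (traits below `diag_cor_threshold` are
#' flagged, not removed).
#'
#' @param z A [zvec()] or numeric vector (no missing values).
#' @param R A [trait_cor()] (positive definite after [repair_psd()]).
#' @param eigenfloor Eigenvalue floor used in the matrix square roots.
#' @param diag_cor_threshold Flagging threshold for `diag_cor` (default 0.7).
#' @return Object of class `whitened_z`: `z_star`, `p_star`, `whitener` (W),
#'   `diag_cor`, `flagged` (trait indices with `diag_cor` below threshold).
#' @export
#' @examples
#' R <- trait_cor(matrix(c(1, .5, .5, 1), 2))
#' zca_cor_whiten(c(1, 1), R)
zca_cor_whiten <- function(z, R, eigenfloor = 1e-8, diag_cor_threshold = 0.7) {
  zv <- if (inherits(z, "zvec")) z$z else as.numeric(z)
  if (inherits(z, "zvec") && !identical(z$trait_ids, R$trait_ids))
    stop_validation("zvec trait order does not match the correlation matrix")
  if (any(!is.finite(zv))) stop_domain("non-finite z-scores")
  if (length(zv) != nrow(R$R)) stop_validation("z length != dim(R)")
  W <- .sym_power(R$R, -0.5, eigenfloor)
  Rhalf <- .sym_power(R$R, 0.5, eigenfloor)
  z_star <- drop(W %*% zv)
  diag_cor <- diag(Rhalf)
  structure(list(z_star = z_star,
                 p_star = whitened_pvalues(z_star),
                 whitener = W,
                 diag_cor = diag_cor,
                 flagged = which(diag_cor < diag_cor_threshold)),
            class = "whitened_z")
}

#' Two-sided p-values for whitened z-scores
#'
#' `p*_j = 2(1 - Phi(|z*_j|))`, clipped below at the smallest positive
#' normalized double so that `log(p*)` stays finite.
#'
#' @param z_star Numeric vector of whitened z-scores.
#' @return Numeric vector of p-values in (0, 1].
#' @export
whitened_pvalues <- function(z_star) {
  if (any(!is.finite(z_star))) stop_domain("non-finite z*")
  two_sided_p(z_star)
}
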