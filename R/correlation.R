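# Estimation of the p x p null correlation of per-trait z-scores. Under the
# null, cor(z_j1, z_j2) equals the phenotypic correlation sigma_j1j2 scaled
# by sample overlap n12/sqrt(n1*n2); with a panel of null SNPs it is
# estimated empirically as the Pearson correlation of z columns.

#' Construct a trait correlation matrix object
#'
#' @param R p x p symmetric correlation matrix (unit diagonal).
#' @param trait_ids Trait identifiers; defaults to colnames or T1..Tp.
#' @param source One of `"null_snps"`, `"individual"`, `"supplied"`.
#' @param eigenfloor_applied Logical flag set by [repair_psd()].
#' @return Object of class `trait_cor`.
#' @export
trait_cor <- function(R, trait_ids = NULL,
                      source = c("supplied", "null_snps", "individual"),
                      eigenfloor_applied = FALSE) {
  source <- match.arg(source)
  R <- as.matrix(R)
  p <- nrow(R)
  if (ncol(R) != p) stop_validation("R must be square")
  if (max(abs(R - t(R))) > 1e-10) stop_validation("R must be symmetric")
  R <- (R + t(R)) / 2
  if (max(abs(diag(R) - 1)) > 1e-12) stop_validation("R must have unit diagonal")
  trait_ids <- trait_ids %||% colnames(R) %||% paste0("T", seq_len(p))
  dimnames(R) <- list(trait_ids, trait_ids)
  structure(list(trait_ids = as.character(trait_ids), R = R, source = source,
                 eigenfloor_applied = isTRUE(eigenfloor_applied)),
            class = "trait_cor")
}

#' @export
print.trait_cor <- function(x, ...) {
  cat(sprintf("<trait_cor> %d traits, source=%s, eigenfloor_applied=%s\n",
              nrow(x$R), x$source, x$eigenfloor_applied))
  invisible(x)
}

#' Select null SNPs by GWAS p-value
#'
#' A SNP is "null" when it shows no association with any trait; the default
#' keeps SNP k iff p_kj > threshold for every trait j. `per_trait` instead
#' returns a keep-mask applied pairwise inside [estimate_z_correlation()].
#'
#' @param pvals K x p matrix of GWAS p-values in (0, 1].
#' @param threshold Exclusion threshold (default 0.05).
#' @param mode `"all_traits"` (index vector) or `"per_trait"` (K x p mask).
#' @return Integer index vector, or logical matrix for `per_trait`.
#' @export
select_null_snps <- function(pvals, threshold = 0.05,
                             mode = c("all_traits", "per_trait")) {
  mode <- match.arg(mode)
  pvals <- as.matrix(pvals)
  if (any(is.na(pvals)) && mode == "all_traits")
    pvals[is.na(pvals)] <- 1  # missing p cannot exclude a SNP
  if (any(pvals <= 0 | pvals > 1, na.rm = TRUE))
    stop_domain("p-values must lie in (0, 1]")
  keep <- pvals > threshold
  if (mode == "per_trait") return(keep)
  idx <- which(rowSums(!keep) == 0L)
  if (length(idx) == 0L)
    ps_stop("no SNP passes the null filter", "pleioscan_insufficient_data")
  if (length(idx) < 10L)
    warning(sprintf("only %d null SNP(s) survive the filter", length(idx)))
  idx
}

#' Empirical z-score correlation from a null-SNP panel
#'
#' Pearson correlation of each pair of trait columns over pairwise-complete
#' null SNPs; the diagonal is forced to 1.
#'
#' @param panel A `null_z_panel`.
#' @param mask Optional K x p logical keep-mask (from
#'   `select_null_snps(..., mode = "per_trait")`).
#' @return A [trait_cor()] with `source = "null_snps"`.
#' @export
estimate_z_correlation <- function(panel, mask = NULL) {
  z <- panel$z
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(z)))
      stop_validation("mask dimensions must match the panel")
    z[!mask] <- NA_real_
  }
  p <- ncol(z)
  sds <- apply(z, 2, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sds) | sds == 0))
    stop_validation(sprintf("constant z column for trait(s): %s",
      paste(panel$trait_ids[!is.finite(sds) | sds == 0], collapse = ", ")))
  nonmiss <- !is.na(z)
  joint <- crossprod(nonmiss)
  if (any(joint < 2))
    ps_stop("some trait pair has <2 jointly non-missing null SNPs",
            "pleioscan_insufficient_data")
  R <- suppressWarnings(stats::cor(z, use = "pairwise.complete.obs"))
  diag(R) <- 1
  trait_cor(R, panel$trait_ids, source = "null_snps")
}

#' z-score correlation under partial sample overlap
#'
#' For two traits measured on overlapping but non-identical samples, the null
#' z-score correlation is `(n12 / sqrt(n1 * n2)) * sigma12`.
#'
#' @param n1,n2 Per-trait sample sizes.
#' @param n12 Overlap size, `0 <= n12 <= min(n1, n2)`.
#' @param sigma12 Phenotypic correlation, `|sigma12| <= 1`.
#' @return The implied z-score correlation.
#' @export
overlap_correlation <- function(n1, n2, n12, sigma12) {
  n1 <- assert_count(n1, "n1"); n2 <- assert_count(n2, "n2")
  n12 <- assert_count(n12, "n12", min = 0L)
  if (n12 > min(n1, n2)) stop_domain("n12 exceeds min(n1, n2)")
  if (abs(sigma12) > 1) stop_domain("|sigma12| must be <= 1")
  n12 / sqrt(as.numeric(n1) * n2) * sigma12
}

#' Residual trait correlation from individual-level data
#'
#' Fits a separate per-trait regression of the (column-centred) trait on the
#' (centred) genotype and returns the correlation of the residual covariance
#' `crossprod(residuals) / (n - 1)`.
#'
#' @param traits n x p numeric matrix of trait values.
#' @param genotype Length-n genotype (allele dose) vector.
#' @return A [trait_cor()] with `source = "individual"`.
#' @export
estimate_sigma_individual <- function(traits, genotype) {
  Y <- as.matrix(traits)
  n <- nrow(Y)
  if (n < 3) stop_domain("need at least 3 individuals")
  if (length(genotype) != n) stop_validation("genotype length mismatch")
  x <- genotype - mean(genotype)
  sxx <- sum(x^2)
  if (sxx == 0) stop_domain("zero-variance genotype")
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  beta <- drop(crossprod(x, Yc)) / sxx
  res <- Yc - outer(x, beta)
  Sigma <- crossprod(res) / (n - 1)
  if (any(diag(Sigma) == 0))
    stop_validation("zero residual variance for some trait")
  trait_cor(stats::cov2cor(Sigma), colnames(Y), source = "individual")
}

#' Repair a correlation matrix to positive semidefiniteness
#'
#' Clips eigenvalues at `eigenfloor`, reassembles, and renormalizes the
#' diagonal to 1. A no-op (up to symmetrization) when all eigenvalues are
#' already above the floor. Whitening needs an invertible square root, hence
#' the strictly positive default floor.
#'
#' @param R Symmetric matrix (or `trait_cor`).
#' @param eigenfloor Smallest allowed eigenvalue (default 1e-8).
#' @return A [trait_cor()] with `eigenfloor_applied` set when clipping occurred.
#' @export
repair_psd <- function(R, eigenfloor = 1e-8) {
  tc <- inherits(R, "trait_cor")
  ids <- if (tc) R$trait_ids else NULL
  src <- if (tc) R$source else "supplied"
  M <- if (tc) R$R else as.matrix(R)
  if (max(abs(M - t(M))) > 1e-10) stop_validation("matrix not symmetric")
  M <- (M + t(M)) / 2
  ee <- eigen(M, symmetric = TRUE)
  if (min(ee$values) >= eigenfloor) {
    out <- trait_cor(M, ids, source = src)
    out$eigenfloor <- eigenfloor
    return(out)
  }
  lam <- pmax(ee$values, eigenfloor)
  M2 <- ee$vectors %*% (lam * t(ee$vectors))
  M2 <- (M2 + t(M2)) / 2
  M2 <- stats::cov2cor(M2)
  M2 <- (M2 + t(M2)) / 2
  out <- trait_cor(M2, ids, source = src, eigenfloor_applied = TRUE)
  out$eigenfloor <- eigenfloor
  out
}

#' Keep every m-th null SNP (optional thinning)
#' @param panel A `null_z_panel`.
#' @param every Keep SNPs 1, 1+every, 1+2*every, ...
#' @return Thinned `null_z_panel`.
#' @export
thin_null_panel <- function(panel, every = 1L) {
  every <- assert_count(every, "every")
  idx <- seq(1L, length(panel$snp_ids), by = every)
  null_z_panel(panel$snp_ids[idx], panel$trait_ids,
               panel$z[idx, , drop = FALSE])
}

#' Write / read a trait correlation matrix as TSV
#' @param R A `trait_cor`.
#' @param path Output path.
#' @export
write_trait_cor <- function(R, path) {
  df <- data.frame(trait_id = R$trait_ids, R$R, check.names = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trait_cor
#' @export
read_trait_cor <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  trait_cor(M, as.character(df[[1]]), source = "supplied")
}
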