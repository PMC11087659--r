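# Synthetic multi-trait GWAS generator with known truth, plus the selection
# and power metrics used to evaluate the methods. One replicate: a genotype
# x ~ Binomial(2, maf) for n individuals, trait errors drawn row-iid from
# MVN(0, Sigma), Y = x beta + eps (columns centred), then per-trait marginal
# GWAS summary statistics (OLS; logistic for binary traits).

#' Trait error covariance presets
#'
#' `exchangeable`: unit variances, constant correlation `rho`.
#' `block_diagonal`: equal-sized blocks with within-block correlation `rho`.
#'
#' @param p Number of traits.
#' @param rho Correlation magnitude.
#' @param blocks Number of blocks (block_diagonal).
#' @return p x p covariance matrix.
#' @export
sigma_exchangeable <- function(p, rho = 0.3) {
  if (rho < -1 / (p - 1) || rho >= 1) stop_domain("invalid rho")
  S <- matrix(rho, p, p); diag(S) <- 1
  S
}

#' @rdname sigma_exchangeable
#' @export
sigma_block_diagonal <- function(p, rho = 0.3, blocks = 5L) {
  blocks <- assert_count(blocks, "blocks")
  S <- diag(p)
  sizes <- rep(p %/% blocks, blocks)
  sizes[seq_len(p %% blocks)] <- sizes[seq_len(p %% blocks)] + 1L
  at <- 1L
  for (b in sizes) {
    idx <- at:(at + b - 1L)
    S[idx, idx] <- rho
    at <- at + b
  }
  diag(S) <- 1
  S
}

#' Synthetic stand-in for a large biobank trait covariance
#'
#' A reproducible synthetic covariance with the qualitative features of a
#' real deeply-phenotyped biobank correlation matrix: correlated blocks of
#' related traits of varying size plus weak global correlation. It is a
#' synthetic construct, not derived from any real cohort.
#'
#' @param p Number of traits (default 754).
#' @param seed RNG seed.
#' @return p x p correlation matrix.
#' @export
synthetic_biobank_sigma <- function(p = 754L, seed = 20L) {
  p <- assert_count(p, "p")
  with_seed(seed, {
    S <- matrix(0.05, p, p)
    at <- 1L
    while (at <= p) {
      b <- min(sample(3:25, 1), p - at + 1L)
      rho <- stats::runif(1, 0.2, 0.7)
      idx <- at:(at + b - 1L)
      S[idx, idx] <- rho
      at <- at + b
    }
    diag(S) <- 1
    repair_psd(S, eigenfloor = 1e-4)$R
  })
}

#' Simulation configuration
#'
#' @param n Individuals per replicate.
#' @param p Number of traits.
#' @param maf Minor allele frequency in (0, 0.5].
#' @param Sigma p x p trait error covariance, or a preset name
#'   (`"exchangeable"`, `"block_diagonal"`) combined with `rho`.
#' @param beta Length-p effect vector; the true subset is
#'   `S0 = which(beta != 0)`.
#' @param trait_types Per-trait `"continuous"` (default) or `"binary"`.
#' @param prevalence Case fraction for binary traits (latent threshold).
#' @param n_reps Replicates per scenario.
#' @param B_null Null-distribution draws shared across replicates.
#' @param seed Master seed; replicate r uses `seed + r`.
#' @param rho Correlation magnitude for preset Sigmas.
#' @param level Test level used for power (default 0.05).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n = 5000L, p = 50L, maf = 0.3,
                       Sigma = "exchangeable", beta = numeric(p),
                       trait_types = rep("continuous", p),
                       prevalence = 0.5, n_reps = 100L, B_null = 2000L,
                       seed = 1L, rho = 0.3, level = 0.05) {
  n <- assert_count(n, "n"); p <- assert_count(p, "p")
  if (maf <= 0 || maf > 0.5) stop_domain("maf must be in (0, 0.5]")
  if (is.character(Sigma)) {
    Sigma <- switch(match.arg(Sigma, c("exchangeable", "block_diagonal")),
                    exchangeable = sigma_exchangeable(p, rho),
                    block_diagonal = sigma_block_diagonal(p, rho))
  }
  Sigma <- as.matrix(Sigma)
  if (nrow(Sigma) != p || ncol(Sigma) != p) stop_validation("Sigma must be p x p")
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop_validation("Sigma is not positive semidefinite")
  if (length(beta) != p) stop_validation("beta must have length p")
  if (length(trait_types) != p) stop_validation("trait_types must have length p")
  if (!all(trait_types %in% c("continuous", "binary")))
    stop_validation("trait_types must be continuous/binary")
  structure(list(n = n, p = p, maf = maf, Sigma = Sigma, beta = beta,
                 S0 = which(beta != 0), trait_types = trait_types,
                 prevalence = prevalence,
                 n_reps = assert_count(n_reps, "n_reps"),
                 B_null = assert_count(B_null, "B_null", min = 100L),
                 seed = assert_count(seed, "seed", min = 0L),
                 level = level),
            class = "sim_config")
}

#' Canonical scenario presets
#'
#' Two ready-made configurations matching the evaluation settings the
#' package documents. Effect sizes are stated in per-trait expected z-score
#' units and converted via `beta = z_target / sqrt(n * 2 * maf * (1 - maf))`
#' (the non-centrality of the marginal Wald z for unit error variance).
#'
#' * `"sparse"`: p = 50 exchangeable traits (rho = 0.3), 2 truly associated
#'   traits with expected |z| of 4 - a strong but unsaturated sparse signal.
#' * `"dense"`: the non-sparse reversal setting - all 50 traits carry the
#'   same homogeneous effect with expected |z| of 2.5, individually
#'   sub-significant.
#'
#' @param type `"sparse"` or `"dense"`.
#' @param p,n,maf,rho,n_reps,B_null,seed,level As in [sim_config()].
#' @param s0 Number of truly associated traits (sparse preset).
#' @param z_target Expected per-trait z-score of an associated trait.
#' @return A [sim_config()].
#' @export
scenario_config <- function(type = c("sparse", "dense"), p = 50L, n = 5000L,
                            maf = 0.3, rho = 0.3,
                            s0 = if (type == "sparse") 2L else p,
                            z_target = if (type == "sparse") 4 else 2.5,
                            n_reps = 500L, B_null = 2000L, seed = 1L,
                            level = 0.05) {
  type <- match.arg(type)
  beta_unit <- z_target / sqrt(n * 2 * maf * (1 - maf))
  beta <- numeric(p)
  beta[seq_len(s0)] <- beta_unit
  sim_config(n = n, p = p, maf = maf, Sigma = "exchangeable", beta = beta,
             n_reps = n_reps, B_null = B_null, seed = seed, rho = rho,
             level = level)
}

#' Generate one synthetic dataset
#'
#' @param config A [sim_config()].
#' @param rep_seed Seed for this replicate.
#' @return List: `genotype` (length n), `traits` (n x p, columns centred;
#'   binary columns in 0/1), `S0` (true trait indices).
#' @export
generate_dataset <- function(config, rep_seed) {
  with_seed(rep_seed, {
    n <- config$n; p <- config$p
    x <- stats::rbinom(n, 2, config$maf)
    eps <- rmvn0(n, config$Sigma)
    Y <- outer(x, config$beta) + eps
    Y <- scale(Y, center = TRUE, scale = FALSE)
    bin <- which(config$trait_types == "binary")
    for (j in bin) {
      thr <- stats::quantile(Y[, j], 1 - config$prevalence)
      Y[, j] <- as.numeric(Y[, j] > thr)
    }
    list(genotype = x, traits = Y, S0 = config$S0)
  })
}

#' Per-trait marginal GWAS summary statistics
#'
#' Continuous traits: OLS of the trait on the genotype (with intercept,
#' equivalent to centring both). Binary traits: logistic regression MLE.
#' Complete separation in a logistic fit flags the record (`flagged = TRUE`,
#' statistics set to NA) instead of failing.
#'
#' @param genotype Length-n dose vector (non-constant).
#' @param traits n x p trait matrix.
#' @param trait_types Per-trait `"continuous"` / `"binary"`.
#' @return data.frame with columns `trait_id`, `beta`, `se`, `z`, `pval`,
#'   `flagged`.
#' @export
summarize_gwas <- function(genotype, traits,
                           trait_types = rep("continuous", ncol(traits))) {
  Y <- as.matrix(traits)
  n <- nrow(Y)
  x <- genotype - mean(genotype)
  sxx <- sum(x^2)
  if (sxx == 0) stop_domain("constant genotype")
  ids <- colnames(Y) %||% paste0("T", seq_len(ncol(Y)))
  beta <- se <- z <- pv <- rep(NA_real_, ncol(Y))
  flag <- rep(FALSE, ncol(Y))
  cont <- trait_types == "continuous"
  if (any(cont)) {
    Yc <- scale(Y[, cont, drop = FALSE], center = TRUE, scale = FALSE)
    b <- drop(crossprod(x, Yc)) / sxx
    rss <- colSums(Yc^2) - b^2 * sxx
    s2 <- rss / (n - 2)
    beta[cont] <- b
    se[cont] <- sqrt(s2 / sxx)
  }
  for (j in which(!cont)) {
    fit <- suppressWarnings(
      stats::glm(Y[, j] ~ genotype, family = stats::binomial()))
    co <- summary(fit)$coefficients
    if (!fit$converged || nrow(co) < 2 || co[2, 2] > 100) {
      flag[j] <- TRUE
      next
    }
    beta[j] <- co[2, 1]; se[j] <- co[2, 2]
  }
  z <- beta / se
  pv <- two_sided_p(z)
  pv[is.na(z)] <- NA_real_
  data.frame(trait_id = ids, beta = beta, se = se, z = z, pval = pv,
             flagged = flag, stringsAsFactors = FALSE)
}

#' Trait-selection metrics
#'
#' Size, precision `|S* n S0| / |S*|`, recall `|S* n S0| / |S0|`, and
#' Jaccard `|S* n S0| / |S* u S0|`. With `S0` empty, precision is 0 and
#' recall is undefined (NA); with `S*` empty, size is 0 and precision NA.
#'
#' @param S_star Selected trait indices.
#' @param S0 True trait indices.
#' @return List: `size`, `precision`, `recall`, `jaccard`.
#' @export
evaluate_selection <- function(S_star, S0) {
  S_star <- unique(S_star); S0 <- unique(S0)
  inter <- length(intersect(S_star, S0))
  uni <- length(union(S_star, S0))
  list(size = length(S_star),
       precision = if (length(S_star)) inter / length(S_star) else NA_real_,
       recall = if (length(S0)) inter / length(S0) else NA_real_,
       jaccard = if (uni) inter / uni else 0)
}

#' Run a simulation scenario
#'
#' Generates `n_reps` datasets, computes summary statistics, scans each with
#' the HC, TC and combined tests (whitening against the true trait
#' correlation implied by `Sigma`) and the PheWAS minimum-p baseline, and
#' averages the selection metrics and rejection rates. The null distribution
#' is simulated once and shared across replicates.
#'
#' @param config A [sim_config()].
#' @param verbose Print a progress dot every 50 replicates.
#' @return Object of class `metrics_report`: data.frame with one row per
#'   method (`traitscan_hc`, `traitscan_tc`, `traitscan_combined`, `phewas`)
#'   and columns `size`, `precision`, `recall`, `jaccard`, `power`,
#'   `n_reps`, `seed`.
#' @export
run_scenario <- function(config, verbose = FALSE) {
  p <- config$p
  R <- trait_cor(stats::cov2cor(config$Sigma), source = "supplied")
  grid <- make_alpha_grid(p)
  null <- simulate_null(p, grid, B = config$B_null, seed = config$seed)
  methods <- c("traitscan_hc", "traitscan_tc", "traitscan_combined", "phewas")
  acc <- lapply(methods, function(m)
    list(size = numeric(0), precision = numeric(0), recall = numeric(0),
         jaccard = numeric(0), reject = logical(0)))
  names(acc) <- methods
  push <- function(m, sel, reject) {
    ev <- evaluate_selection(sel, config$S0)
    acc[[m]]$size <<- c(acc[[m]]$size, ev$size)
    acc[[m]]$precision <<- c(acc[[m]]$precision, ev$precision)
    acc[[m]]$recall <<- c(acc[[m]]$recall, ev$recall)
    acc[[m]]$jaccard <<- c(acc[[m]]$jaccard, ev$jaccard)
    acc[[m]]$reject <<- c(acc[[m]]$reject, reject)
  }
  for (r in seq_len(config$n_reps)) {
    dat <- generate_dataset(config, config$seed + r)
    sm <- summarize_gwas(dat$genotype, dat$traits, config$trait_types)
    z <- sm$z
    z[sm$flagged] <- NA_real_
    res <- suppressWarnings(
      scan_and_test(z, R, grid = grid, null = null, hc_pvalue = "mc"))
    lev <- config$level
    push("traitscan_hc", res$S_HC, res$p_HC <= lev)
    push("traitscan_tc", res$S_TC, res$p_TC <= lev)
    push("traitscan_combined", res$S_combined, res$p_combined <= lev)
    ph <- phewas_minp(z[!is.na(z)], n_tests = p, level = lev)
    push("phewas", ph$selected, ph$reject)
    if (verbose && r %% 50 == 0) cat(".")
  }
  if (verbose) cat("\n")
  rows <- lapply(methods, function(m) {
    a <- acc[[m]]
    data.frame(method = m,
               size = mean(a$size),
               precision = mean(a$precision, na.rm = TRUE),
               recall = mean(a$recall, na.rm = TRUE),
               jaccard = mean(a$jaccard),
               power = mean(a$reject),
               n_reps = config$n_reps,
               seed = config$seed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("metrics_report", "data.frame")
  out
}
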