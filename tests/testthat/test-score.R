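# Individual-level oracle helpers: simulate genotypes and a trait, compute
# marginal per-SNP OLS summary statistics, and reconstruct the score-level
# z from summary data to compare with direct regression.

sim_score_data <- function(n = 5000, q = 3, maf = c(0.2, 0.3, 0.4),
                           beta = c(0.08, 0, -0.05), seed = 1) {
  withr_seed(seed, {
    X <- sapply(seq_len(q), function(l) rbinom(n, 2, maf[l]))
    y <- drop(X %*% beta) + rnorm(n)
    y <- y - mean(y)
    list(X = X, y = y)
  })
}

marginal_ols <- function(X, y) {
  n <- nrow(X)
  t(apply(X, 2, function(x) {
    xc <- x - mean(x)
    b <- sum(xc * y) / sum(xc^2)
    rss <- sum((y - mean(y) - b * xc)^2)
    se <- sqrt(rss / (n - 2) / sum(xc^2))
    c(beta = b, se = se)
  }))
}

make_score <- function(X_ref, weights, ids = paste0("rs", seq_along(weights))) {
  w <- data.frame(variant_id = ids,
                  effect_allele = rep("A", length(weights)),
                  other_allele = rep("G", length(weights)),
                  weight = weights)
  class(w) <- c("score_weights", "data.frame")
  colnames(X_ref) <- ids
  score_model(w, X_ref)
}

test_that("logistic-to-linear conversion: factors and z invariance", {
  eq <- logistic_to_linear(0.4, 0.1, 500, 500)
  expect_equal(eq$beta, 0.4 / 4)
  expect_equal(eq$se, 0.1 / 4)
  r3 <- logistic_to_linear(1, 1, 250, 750)  # r = 3 -> f = 3/16
  expect_equal(r3$beta, 3 / 16)
  conv <- logistic_to_linear(0.37, 0.21, 123, 456)
  # z invariant up to one ulp (common factor cancels)
  expect_equal(conv$beta / conv$se, 0.37 / 0.21, tolerance = 1e-14)
  expect_error(logistic_to_linear(1, 1, 0, 10),
               class = "pleioscan_domain_error")
})

test_that("y'y estimation: median aggregation and individual-level oracle", {
  expect_equal(estimate_yty(0.1, 0.05, 0.4, 100),
               100^2 * 0.4 * 0.05^2 + 100 * 0.4 * 0.1^2)
  # median of per-SNP estimates: construct three SNPs whose estimates are
  # exactly (10, 12, 100) by inverting the identity with beta = 0
  n <- 10; s2 <- c(1, 1, 1)
  se <- sqrt(c(10, 12, 100) / (n^2 * s2))
  expect_equal(estimate_yty(c(0, 0, 0), se, s2, n), 12)

  d <- sim_score_data(n = 2000, seed = 21)
  sm <- marginal_ols(d$X, d$y)
  s2_hat <- apply(d$X, 2, var)
  yty_hat <- estimate_yty(sm[, "beta"], sm[, "se"], s2_hat, 2000)
  expect_lt(abs(yty_hat - sum(d$y^2)) / sum(d$y^2), 0.05)
})

test_that("q=1 unit-weight score reproduces the single-SNP statistics", {
  d <- sim_score_data(n = 5000, q = 1, maf = 0.3, beta = 0.08, seed = 31)
  ref <- withr_seed(32, matrix(rbinom(2000, 2, 0.3), ncol = 1))
  sm <- marginal_ols(d$X, d$y)
  sc <- make_score(ref, 1)
  sa <- score_association(
    data.frame(variant_id = "rs1", beta = sm[1, "beta"], se = sm[1, "se"]),
    sc, n = 5000)
  z_snp <- sm[1, "beta"] / sm[1, "se"]
  expect_lt(abs(sa$z_gs - z_snp) / abs(z_snp), 0.05)
})

test_that("summary-statistic score z agrees with direct regression", {
  d <- sim_score_data(n = 5000, seed = 41)
  ref <- withr_seed(42, sapply(c(0.2, 0.3, 0.4), function(m)
    rbinom(3000, 2, m)))
  w <- c(0.5, -0.2, 0.3)
  sm <- marginal_ols(d$X, d$y)
  sc <- make_score(ref, w)
  sa <- score_association(
    data.frame(variant_id = paste0("rs", 1:3),
               beta = sm[, "beta"], se = sm[, "se"]),
    sc, n = 5000)
  # direct regression of y on the realized score
  g <- drop(d$X %*% w); gc_ <- g - mean(g)
  b <- sum(gc_ * d$y) / sum(gc_^2)
  se <- sqrt(sum((d$y - b * gc_)^2) / (5000 - 2) / sum(gc_^2))
  z_direct <- b / se
  expect_lt(abs(sa$z_gs - z_direct) / abs(z_direct), 0.05)

  # weight rescaling leaves z unchanged exactly
  sa2 <- score_association(
    data.frame(variant_id = paste0("rs", 1:3),
               beta = sm[, "beta"], se = sm[, "se"]),
    make_score(ref, w * 7), n = 5000)
  expect_equal(sa2$z_gs, sa$z_gs, tolerance = 1e-12)
})

test_that("allele flips applied consistently leave z_gs invariant", {
  d <- sim_score_data(seed = 51)
  ref <- withr_seed(52, sapply(c(0.2, 0.3, 0.4), function(m)
    rbinom(1000, 2, m)))
  sm <- marginal_ols(d$X, d$y)
  sdf <- data.frame(variant_id = paste0("rs", 1:3),
                    beta = sm[, "beta"], se = sm[, "se"],
                    effect_allele = "A", other_allele = "G")
  sc <- make_score(ref, c(0.4, 0.1, -0.3))
  base <- score_association(sdf, sc, n = 5000)
  # flip SNP 2 in the summary stats (alleles swapped, beta negated upstream
  # by the reporting study) -> harmonization restores the original
  sdf2 <- sdf
  sdf2$beta[2] <- -sdf2$beta[2]
  sdf2$effect_allele[2] <- "G"; sdf2$other_allele[2] <- "A"
  flip <- score_association(sdf2, sc, n = 5000)
  expect_equal(flip$z_gs, base$z_gs, tolerance = 1e-12)

  sdf3 <- sdf; sdf3$effect_allele[3] <- "T"
  expect_error(score_association(sdf3, sc, n = 5000),
               class = "pleioscan_validation_error")
})

test_that("orthonormal-in-reference pair with weights (1, 0) recovers SNP 1", {
  d <- sim_score_data(n = 5000, q = 2, maf = c(0.3, 0.3),
                      beta = c(0.07, 0.02), seed = 61)
  ref <- withr_seed(62, cbind(rbinom(4000, 2, 0.3), rbinom(4000, 2, 0.3)))
  sm <- marginal_ols(d$X, d$y)
  sa <- score_association(
    data.frame(variant_id = c("rs1", "rs2"),
               beta = sm[, "beta"], se = sm[, "se"]),
    make_score(ref, c(1, 0)), n = 5000)
  z1 <- sm[1, "beta"] / sm[1, "se"]
  expect_lt(abs(sa$z_gs - z1) / abs(z1), 0.05)
})

test_that("degenerate inputs raise diagnostics, never complex SEs", {
  ref2 <- withr_seed(71, cbind(rbinom(1000, 2, 0.3), rbinom(1000, 2, 0.3)))
  sc2 <- make_score(ref2, c(0, 1), ids = c("rs1", "rs2"))
  # rs1's summary stats imply a small y'y while rs2's enormous beta makes
  # the fitted sum of squares exceed the median y'y estimate
  expect_error(score_association(
    data.frame(variant_id = c("rs1", "rs2"), beta = c(0, 50),
               se = c(0.1, 0.1)), sc2, n = 100),
    "residual variance", class = "pleioscan_validation_error")

  sc1 <- make_score(ref2[, 1, drop = FALSE], 1)
  expect_error(score_association(
    data.frame(variant_id = "rs1", beta = 0.1, se = 0.05), sc1, n = 1),
    class = "pleioscan_domain_error")
  expect_error(score_association(
    data.frame(variant_id = "rsX", beta = 0.1, se = 0.05), sc1, n = 100),
    "rs1", class = "pleioscan_lookup_error")
})

test_that("score_scan composes conversion, association, and the scan", {
  p <- 4
  withr_seed(81, {
    n <- 4000
    X <- sapply(c(0.2, 0.3, 0.4), function(m) rbinom(n, 2, m))
    Y <- matrix(rnorm(n * p), n, p)
    Y[, 1] <- Y[, 1] + drop(X %*% c(0.15, 0.1, 0.1))  # trait 1 associated
    ybin <- as.integer(Y[, 4] > median(Y[, 4]))
    meta <- list(trait_meta("T1", "continuous", n),
                 trait_meta("T2", "continuous", n),
                 trait_meta("T3", "continuous", n),
                 trait_meta("T4", "binary", n, sum(ybin), n - sum(ybin)))
    summaries <- lapply(1:p, function(j) {
      if (j == 4) {
        co <- summary(glm(ybin ~ X[, 1]))$coefficients
        co2 <- summary(glm(ybin ~ X[, 2]))$coefficients
        co3 <- summary(glm(ybin ~ X[, 3]))$coefficients
        data.frame(variant_id = paste0("rs", 1:3),
                   beta = c(co[2, 1], co2[2, 1], co3[2, 1]),
                   se = c(co[2, 2], co2[2, 2], co3[2, 2]))
      } else {
        sm <- marginal_ols(X, Y[, j])
        data.frame(variant_id = paste0("rs", 1:3),
                   beta = sm[, "beta"], se = sm[, "se"])
      }
    })
    ref <- sapply(c(0.2, 0.3, 0.4), function(m) rbinom(2000, 2, m))
    sc <- make_score(ref, c(0.4, 0.3, 0.3))
    R <- trait_cor(diag(p), paste0("T", 1:p))
    res <- score_scan(summaries, sc, meta, R, B = 500, seed = 4)
    expect_s3_class(res, "scan_result")
    expect_true(1 %in% res$S_combined)  # the associated trait is selected
    assoc <- attr(res, "associations")
    expect_length(assoc, p)
    expect_equal(assoc[[1]]$z_gs, assoc[[1]]$beta_gs / assoc[[1]]$se_gs)
  })
})
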