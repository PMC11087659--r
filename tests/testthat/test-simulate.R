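test_that("generator moments: centring, covariance, Binomial mean, seeding", {
  cfg <- sim_config(n = 10000, p = 4, maf = 0.5, Sigma = "exchangeable",
                    rho = 0.4, seed = 1)
  d <- generate_dataset(cfg, rep_seed = 5)
  expect_equal(colMeans(d$traits), rep(0, 4), tolerance = 1e-12)
  S_hat <- stats::cov(d$traits)
  S_true <- sigma_exchangeable(4, 0.4)
  # entrywise tolerance ~ 3 * sd of a covariance estimate at n = 10000
  expect_lt(max(abs(S_hat - S_true)), 3 * sqrt(2 / 10000) * 1.5)
  expect_equal(mean(d$genotype), 1, tolerance = 0.05)
  expect_identical(d$S0, integer(0))

  d2 <- generate_dataset(cfg, rep_seed = 5)
  expect_identical(d2, d)

  expect_error(sim_config(p = 2, Sigma = matrix(c(1, 2, 2, 1), 2),
                          beta = c(0, 0)),
               class = "pleioscan_validation_error")
})

test_that("binary traits are thresholded at the configured prevalence", {
  cfg <- sim_config(n = 2000, p = 2, trait_types = c("continuous", "binary"),
                    prevalence = 0.3, seed = 2)
  d <- generate_dataset(cfg, 9)
  expect_setequal(unique(d$traits[, 2]), c(0, 1))
  expect_equal(mean(d$traits[, 2]), 0.3, tolerance = 0.03)
})

test_that("summary statistics: exact fits, closed-form identity, null z law", {
  withr_seed(3, {
    n <- 500
    x <- rbinom(n, 2, 0.3)
    y <- 0.5 * x
    sm <- summarize_gwas(x, cbind(exact = y))
    expect_equal(sm$beta, 0.5, tolerance = 1e-10)
    expect_lt(sm$pval, 1e-200)

    Y <- cbind(a = rnorm(n), b = rnorm(n) + 0.2 * x)
    sm2 <- summarize_gwas(x, Y)
    xc <- x - mean(x)
    for (j in 1:2)  # OLS slope = cov(x, y) / var(x)
      expect_equal(sm2$beta[j], cov(x, Y[, j]) / var(x), tolerance = 1e-10)
  })
  # under beta = 0 the z statistics are standard normal
  zs <- withr_seed(4, vapply(1:2000, function(i) {
    x <- rbinom(200, 2, 0.3)
    summarize_gwas(x, cbind(rnorm(200)))$z
  }, numeric(1)))
  expect_gt(suppressWarnings(stats::ks.test(zs, "pnorm")$p.value), 0.001)
})

test_that("logistic path produces finite Wald statistics and flags separation", {
  withr_seed(5, {
    n <- 800
    x <- rbinom(n, 2, 0.4)
    latent <- 0.3 * x + rlogis(n)
    yb <- as.integer(latent > median(latent))
    sm <- summarize_gwas(x, cbind(bin = yb), trait_types = "binary")
    expect_false(sm$flagged)
    expect_true(is.finite(sm$z))
    # separation: outcome perfectly determined by genotype
    ysep <- as.integer(x > 0)
    sm2 <- summarize_gwas(x, cbind(sep = ysep), trait_types = "binary")
    expect_true(sm2$flagged)
  })
})

test_that("selection metrics: exact set arithmetic and identities", {
  ev <- evaluate_selection(c(2, 5), c(2, 5))
  expect_equal(unlist(ev), c(size = 2, precision = 1, recall = 1, jaccard = 1))

  ev2 <- evaluate_selection(1:3, 2:4)
  expect_equal(ev2$precision, 2 / 3)
  expect_equal(ev2$recall, 2 / 3)
  expect_equal(ev2$jaccard, 0.5)

  ev3 <- evaluate_selection(1:2, 3:4)
  expect_equal(c(ev3$precision, ev3$recall, ev3$jaccard), c(0, 0, 0))

  # empty truth: precision 0, recall undefined
  ev4 <- evaluate_selection(1:2, integer(0))
  expect_equal(ev4$precision, 0)
  expect_true(is.na(ev4$recall))

  # J = PR/(P + R - PR) and J <= min(P, R) over random sets
  withr_seed(6, {
    for (i in 1:50) {
      s <- sample(10, sample(1:10, 1)); t <- sample(10, sample(1:10, 1))
      ev <- evaluate_selection(s, t)
      expect_lte(ev$jaccard, min(ev$precision, ev$recall) + 1e-12)
      denom <- ev$precision + ev$recall - ev$precision * ev$recall
      if (denom > 0)
        expect_equal(ev$jaccard, ev$precision * ev$recall / denom,
                     tolerance = 1e-12)
    }
  })
})

test_that("run_scenario wires the pipeline and reports coherent metrics", {
  cfg <- sim_config(n = 1000, p = 8, maf = 0.3, Sigma = "exchangeable",
                    beta = c(0.15, 0.15, rep(0, 6)), n_reps = 30,
                    B_null = 500, seed = 10)
  rep <- run_scenario(cfg)
  expect_s3_class(rep, "metrics_report")
  expect_setequal(rep$method, c("traitscan_hc", "traitscan_tc",
                                "traitscan_combined", "phewas"))
  expect_true(all(rep$size >= 0 & rep$size <= 8))
  num <- c("precision", "recall", "jaccard", "power")
  for (cn in num) expect_true(all(rep[[cn]] >= 0 & rep[[cn]] <= 1))
  # strong sparse effects: scans should reject most of the time
  expect_gt(rep$power[rep$method == "traitscan_combined"], 0.5)
})

test_that("power estimates are stable in n_reps (binomial error bound)", {
  base <- sim_config(n = 800, p = 6, beta = c(0.12, rep(0, 5)),
                     n_reps = 60, B_null = 500, seed = 30)
  twice <- sim_config(n = 800, p = 6, beta = c(0.12, rep(0, 5)),
                      n_reps = 120, B_null = 500, seed = 30)
  p1 <- run_scenario(base)
  p2 <- run_scenario(twice)
  for (m in p1$method) {
    a <- p1$power[p1$method == m]; b <- p2$power[p2$method == m]
    se <- sqrt(max(a * (1 - a), 0.25 / 60) / 60)
    expect_lt(abs(a - b), 3 * se + 0.05)
  }
})

test_that("simulated null SNP panel recovers the z-correlation implied by Sigma", {
  # cross-module loop: many null variants scanned against correlated traits
  p <- 4
  Sig <- sigma_exchangeable(p, 0.5)
  cfg <- sim_config(n = 300, p = p, Sigma = Sig, seed = 40)
  K <- 400
  zmat <- t(vapply(seq_len(K), function(k) {
    d <- generate_dataset(cfg, 1000 + k)
    summarize_gwas(d$genotype, d$traits)$z
  }, numeric(p)))
  pan <- null_z_panel(paste0("s", 1:K), paste0("T", 1:p), zmat)
  R_hat <- estimate_z_correlation(pan)$R
  # K = 400 null SNPs: sampling error ~ 1/sqrt(K); generous 3x bound
  expect_lt(max(abs(R_hat - stats::cov2cor(Sig))), 3 / sqrt(K) * 1.5)
})

test_that("synthetic biobank covariance is a valid correlation matrix", {
  S <- synthetic_biobank_sigma(p = 100, seed = 3)
  expect_equal(unname(diag(S)), rep(1, 100))
  expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_identical(S, synthetic_biobank_sigma(p = 100, seed = 3))
})
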