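test_that("feature reduction keeps the minimal component count", {
  cfg <- voice_config()
  stim <- example_stimulus_table("NatS", n_vocal = 10, n_nonvocal = 20,
    seed = 6)
  # exactly rank-3 noiseless features -> k = 3
  af <- make_acoustic_features(stim, n_features = 15, n_latent = 3,
    noise_sd = 0, seed = 7)
  d3 <- reduce_features(af$features, stim$vocal, cfg)
  expect_equal(d3$k, 3)
  expect_equal(nrow(d3$components), 30)
  # minimality: k-1 components fall short of the target
  afn <- make_acoustic_features(stim, n_features = 15, n_latent = 5,
    noise_sd = 0.3, seed = 8)
  dn <- reduce_features(afn$features, stim$vocal, cfg)
  expect_gte(dn$explained[dn$k], cfg$pca_var_target)
  if (dn$k > 1) expect_lt(dn$explained[dn$k - 1], cfg$pca_var_target)
  # k equals the oracle from a direct eigen scan of the correlation matrix
  ev <- eigen(stats::cor(afn$features), symmetric = TRUE,
    only.values = TRUE)$values
  k_oracle <- which(cumsum(ev) / sum(ev) >= cfg$pca_var_target)[1]
  expect_equal(dn$k, k_oracle)
  # rescaling features does not change the design (standardization first)
  scaled <- sweep(afn$features, 2, c(rep(1000, 7), rep(0.001, 8)), "*")
  ds <- reduce_features(scaled, stim$vocal, cfg)
  expect_equal(ds$k, dn$k)
  expect_equal(abs(ds$components), abs(dn$components), tolerance = 1e-8)
  # exclusions and degenerate columns
  dx <- reduce_features(afn$features, stim$vocal, cfg,
    exclude_ids = stim$stimulus_id[1])
  expect_equal(nrow(dx$components), 29)
  bad <- afn$features
  bad[, 2] <- 7
  expect_error(reduce_features(bad, stim$vocal, cfg), "constant")
})

test_that("LOOCV R2 matches the explicit refit oracle", {
  set.seed(51)
  n <- 40
  X <- matrix(rnorm(n * 4), n, 4)
  y <- X %*% c(1, -2, 0.5, 0) + rnorm(n)
  r2 <- loocv_r2(X, y)
  # oracle: n refits, each leaving one observation out
  press <- 0
  for (i in seq_len(n)) {
    fit <- stats::lm(y[-i] ~ X[-i, , drop = FALSE])
    pred <- sum(c(1, X[i, ]) * stats::coef(fit))
    press <- press + (y[i] - pred)^2
  }
  expect_equal(r2, 1 - press / sum((y - mean(y))^2))
  # exact linear response: R2 ~ 1
  y0 <- X %*% c(1, 2, 3, 4)
  expect_gt(loocv_r2(X, y0), 0.999)
  # independent noise: penalized at or below 0 on average
  r2s <- vapply(1:50, function(i) {
    loocv_r2(matrix(rnorm(30 * 4), 30, 4), rnorm(30))
  }, numeric(1))
  expect_lt(mean(r2s), 0.02)
  expect_error(loocv_r2(X[1:5, ], y[1:5]), "n > p")
  expect_error(loocv_r2(cbind(X, X[, 1]), y), "rank-deficient")
})

test_that("the category LRT equals its closed-form and logLik oracles", {
  set.seed(52)
  stim <- example_stimulus_table("NatS", n_vocal = 15, n_nonvocal = 25,
    seed = 9)
  af <- make_acoustic_features(stim, n_features = 10, n_latent = 3,
    noise_sd = 0.2, seed = 10)
  design <- reduce_features(af$features, stim$vocal, voice_config())
  y <- af$latent %*% c(1, 0.5, -1) + 2 * stim$vocal + rnorm(40, sd = 0.5)
  out <- lrt_category(design, y)
  # closed form from two independent least-squares fits
  Xf <- cbind(design$components, vocal = as.numeric(design$vocal))
  rss_f <- sum(stats::lm(y ~ Xf)$residuals^2)
  rss_n <- sum(stats::lm(y ~ design$components)$residuals^2)
  expect_equal(out$chi2, 40 * log(rss_n / rss_f))
  # profile-likelihood identity via stats::logLik
  ll_f <- as.numeric(stats::logLik(stats::lm(y ~ Xf)))
  ll_n <- as.numeric(stats::logLik(stats::lm(y ~ design$components)))
  expect_equal(out$chi2, 2 * (ll_f - ll_n), tolerance = 1e-8)
  expect_gt(out$chi2, 4)
  expect_lt(out$p, 0.05)
  # identical full and nested predictions -> chi2 = 0: make the category
  # indicator collinear with the acoustic block so it adds nothing
  design_dup <- design
  design_dup$components <- cbind(design$components,
    dup = as.numeric(design$vocal))
  out0 <- lrt_category(design_dup, y)
  expect_equal(out0$chi2, 0)
})

test_that("R2 permutation significance hits the floor for strong fits", {
  set.seed(53)
  X <- matrix(rnorm(50 * 3), 50, 3)
  y <- drop(X %*% c(2, -1, 1)) + rnorm(50, sd = 0.1)
  res <- r2_significance(X, y, n_perm = 100, seed = 54, m_bonferroni = 30)
  expect_equal(res$p, 1 / 101)
  expect_equal(res$p_bonf, min(1, 30 / 101))
  resn <- r2_significance(X, rnorm(50), n_perm = 100, seed = 55,
    m_bonferroni = 30)
  expect_equal(resn$p_bonf, 1)
})

test_that("encoding fits separate category from acoustic encoders", {
  set.seed(56)
  stim <- example_stimulus_table("NatS", n_vocal = 16, n_nonvocal = 32,
    seed = 11)
  af <- make_acoustic_features(stim, n_features = 20, n_latent = 4,
    category_shift = 1, noise_sd = 0.1, seed = 12)
  design <- reduce_features(af$features, stim$vocal, voice_config())
  n <- nrow(stim)
  resp <- list(
    onset = cbind(
      cat1 = 1 + 2 * stim$vocal + rnorm(n, sd = 0.3),
      ac1 = 1 + drop(af$latent %*% c(1, 1, 0, 0)) + rnorm(n, sd = 0.3)
    ),
    sustained = cbind(
      cat1 = 3 * stim$vocal + rnorm(n, sd = 0.3),
      ac1 = 1 + drop(af$latent %*% c(1, 0.5, 0, 0)) + rnorm(n, sd = 0.3)
    )
  )
  fits <- fit_encoding_models(design, resp, n_perm = 200, seed = 57)
  expect_equal(nrow(fits), 4)
  sus <- fits[fits$window == "sustained", ]
  cat_row <- sus[sus$channel == "cat1", ]
  ac_row <- sus[sus$channel == "ac1", ]
  expect_gt(cat_row$lrt_chi2, 10 * max(1, ac_row$lrt_chi2))
  expect_gt(ac_row$r2_acoustic, 0.8)
  expect_lt(cat_row$r2_acoustic, 0.5)
  expect_gt(cat_row$r2_full, 0.8)

  # group contrasts over a planted cohort
  set.seed(58)
  mk <- function(kind, m) {
    sapply(seq_len(m), function(i) {
      if (kind == "cat") {
        2 * stim$vocal + rnorm(n, sd = 0.3)
      } else {
        drop(af$latent %*% rnorm(4)) + rnorm(n, sd = 0.3)
      }
    })
  }
  Y <- cbind(mk("cat", 6), mk("ac", 6))
  colnames(Y) <- sprintf("e%02d", 1:12)
  fits2 <- fit_encoding_models(design, list(onset = Y), n_perm = 100,
    seed = 59)
  roi <- setNames(rep(c("STG/STS", "STP"), each = 6), colnames(Y))
  contrasts <- classify_channels(fits2, roi)
  chi <- contrasts[contrasts$metric == "lrt_chi2", ]
  expect_lt(chi$p, 0.01)
  expect_equal(chi$direction, 1)
  # identical groups: p near 1
  roi_same <- setNames(rep(c("STG/STS", "STP"), 6), colnames(Y))
  # reorder so alternating channels of the same composition land in each ROI
  mixed <- classify_channels(fits2, roi_same)
  expect_gt(min(mixed$p[mixed$metric == "r2_full"]), 0.05)
})
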