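test_that("feature matrices follow the printed window grids", {
  cfg <- voice_config()
  # VL grid: 32 centers from -50 to 1500
  vl_stim <- example_stimulus_table("VL", n_vocal = 4, n_nonvocal = 4)
  vl_time <- seq(-900, 550 + 900, by = 10)
  vdat <- array(1, dim = c(8, 2, length(vl_time)))
  vresp <- fake_resp(vdat, vl_time, vl_stim, task = "VL", duration_ms = 550)
  fv <- build_features(vresp, vl_stim, cfg)
  expect_equal(length(fv$centers_ms), 32)
  expect_equal(range(fv$centers_ms), c(-50, 1500))
  # constant HGA -> all features 1
  expect_true(all(fv$X == 1))
  expect_equal(dim(fv$X), c(8, 2 * 32))

  # NatS grid: 51 centers from -50 to 2450
  ns_stim <- example_stimulus_table("NatS", n_vocal = 4, n_nonvocal = 4)
  ns_time <- nats_time_grid()
  ndat <- array(rnorm(8 * 2 * length(ns_time)), dim = c(8, 2, length(ns_time)))
  nresp <- fake_resp(ndat, ns_time, ns_stim)
  fn <- build_features(nresp, ns_stim, cfg)
  expect_equal(length(fn$centers_ms), 51)
  expect_equal(range(fn$centers_ms), c(-50, 2450))
  # column order is channel-major: window means of channel 2 start at col 52;
  # the 10th center is 400 ms, covering [350, 450)
  expect_equal(fn$centers_ms[10], 400)
  w10 <- which(ns_time >= 350 & ns_time < 450)
  expect_equal(fn$X[, 51 + 10], rowMeans(ndat[, 2, w10]))
  expect_error(build_features(nresp, ns_stim, cfg, channels = character(0)),
    "empty channel set")
  expect_error(build_features(nresp, ns_stim, cfg, windows = 33), "grid")
})

test_that("balanced accuracy equals the confusion-count oracle", {
  set.seed(31)
  for (i in 1:20) {
    truth <- sample(c(TRUE, FALSE), 50, replace = TRUE, prob = c(0.3, 0.7))
    pred <- sample(c(TRUE, FALSE), 50, replace = TRUE)
    tp <- sum(truth & pred)
    tn <- sum(!truth & !pred)
    oracle <- mean(c(tp / sum(truth), tn / sum(!truth)))
    expect_equal(balanced_accuracy(truth, pred), oracle)
    # duplicating all members of one class leaves it unchanged
    dup <- c(which(truth), which(truth), which(!truth))
    expect_equal(balanced_accuracy(truth[dup], pred[dup]),
      balanced_accuracy(truth, pred))
  }
})

test_that("decoding separates designed classes and stays at chance on null", {
  cfg <- voice_config()
  set.seed(32)
  n <- 60
  lab <- rep(c(TRUE, FALSE), each = n / 2)
  X <- matrix(rnorm(n * 10), n, 10)
  X[lab, 1:3] <- X[lab, 1:3] + 4
  fit <- fit_l1_logistic_cv(X, lab, cfg, seed = 33)
  expect_gte(fit$balanced_accuracy, 0.95)
  # uninformative features: near chance
  fit0 <- fit_l1_logistic_cv(matrix(rnorm(n * 10), n, 10), lab, cfg, seed = 34)
  expect_lt(abs(fit0$balanced_accuracy - 0.5), 0.2)
  expect_error(
    fit_l1_logistic_cv(X[1:8, ], c(rep(TRUE, 2), rep(FALSE, 6)), cfg),
    "stratification"
  )
})

test_that("cross-task models transfer and never see test labels", {
  cfg <- voice_config()
  set.seed(35)
  make_task <- function(n, task) {
    stim <- example_stimulus_table(task, n_vocal = n / 2, n_nonvocal = n / 2,
      seed = 1)
    dur <- if (task == "VL") 550 else 2000
    tm <- seq(-900, dur + 900, by = 10)
    dat <- array(rnorm(n * 3 * length(tm), sd = 0.5), dim = c(n, 3, length(tm)))
    resp_win <- tm >= 0 & tm < dur
    for (ch in 1:3) dat[stim$vocal, ch, resp_win] <-
      dat[stim$vocal, ch, resp_win] + 2
    build_features(fake_resp(dat, tm, stim, task = task, duration_ms = dur),
      stim, cfg)
  }
  fa <- make_task(40, "VL")
  fb <- make_task(40, "NatS")
  cross <- decode_cross_task(fa, fb, cfg, seed = 36)
  within <- fit_l1_logistic_cv(fa, cfg = cfg, seed = 37)
  expect_gt(cross$balanced_accuracy, 0.9)
  expect_lt(abs(cross$balanced_accuracy - within$balanced_accuracy), 0.1)

  # shuffling test labels leaves the fitted model and predictions unchanged
  fb_shuf <- fb
  set.seed(38)
  fb_shuf$labels <- sample(fb_shuf$labels)
  cross_shuf <- decode_cross_task(fa, fb_shuf, cfg, seed = 36)
  expect_identical(cross_shuf$predicted, cross$predicted)
  expect_identical(cross_shuf$lambda, cross$lambda)
  expect_lt(cross_shuf$balanced_accuracy, cross$balanced_accuracy)

  # mismatched grids (different channel counts) are a consistency error
  fc <- make_task(40, "NatS")
  fc$channel_ids <- fc$channel_ids[1:2]
  fc$X <- fc$X[, 1:(2 * length(fc$centers_ms))]
  expect_error(decode_cross_task(fa, fc, cfg), "mismatch")
})

test_that("full-model permutation p-values hit the floor for real effects", {
  cfg <- voice_config(n_lambda = 8, n_inner_folds = 5)
  set.seed(39)
  n <- 40
  lab <- rep(c(TRUE, FALSE), each = n / 2)
  X <- matrix(rnorm(n * 6), n, 6)
  X[lab, 1:2] <- X[lab, 1:2] + 5
  res <- permutation_significance_full(X, lab, cfg, n_perm = 100, seed = 40,
    m_bonferroni = 8)
  expect_equal(res$p, 1 / 101)
  expect_equal(res$p_bonf, 8 / 101)
  expect_equal(res$observed, 1)
  expect_error(permutation_significance_full(X, lab, cfg, n_perm = 10), "100")
})

test_that("sliding decoding localizes a planted window", {
  cfg <- voice_config(n_lambda = 5, n_inner_folds = 3, n_outer_folds = 4)
  set.seed(41)
  stim <- example_stimulus_table("NatS", n_vocal = 10, n_nonvocal = 10,
    seed = 5)
  tm <- nats_time_grid()
  dat <- array(rnorm(20 * 2 * length(tm), sd = 0.5),
    dim = c(20, 2, length(tm)))
  eff <- tm >= 300 & tm < 900
  for (ch in 1:2) dat[stim$vocal, ch, eff] <- dat[stim$vocal, ch, eff] + 3
  # coarse window subset keeps the permutation run desk-sized
  feats <- build_features(fake_resp(dat, tm, stim), stim, cfg,
    windows = seq(0, 1000, by = 100))
  sl <- decode_sliding(feats, cfg, n_perm = 100, seed = 42)
  sig <- sl$clusters$clusters[sl$clusters$clusters$p < 0.05, ]
  expect_gte(nrow(sig), 1)
  main <- sig[which.max(sig$mass), ]
  expect_lte(main$start_ms, 400)
  expect_gte(main$end_ms, 800)
  # no significant decoding before onset
  expect_true(all(sig$start_ms >= 0))
  # deterministic given the seed
  sl2 <- decode_sliding(feats, cfg, n_perm = 100, seed = 42)
  expect_identical(sl2$accuracy$values, sl$accuracy$values)
  expect_identical(sl2$clusters$clusters, sl$clusters$clusters)
})
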