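test_that("common average reference removes common-mode signal exactly", {
  set.seed(1)
  ch <- channel_info(sprintf("c%d", 1:4), "HG")
  v <- matrix(rnorm(4 * 1000), 4, 1000)
  rec <- recording(v, 1000, ch)
  out <- apply_car(rec)
  expect_true(all(abs(colMeans(out$voltage)) < 1e-10))
  # idempotent
  expect_equal(apply_car(out)$voltage, out$voltage)
  # common offset rejected
  rec2 <- recording(sweep(out$voltage, 2, rnorm(1000), "+"), 1000, ch)
  expect_equal(apply_car(rec2)$voltage, out$voltage)
  # antisymmetric 2-channel input is already zero-mean
  rec3 <- recording(rbind(v[1, ], -v[1, ]), 1000, channel_info(c("a", "b"), "HG"))
  expect_equal(apply_car(rec3)$voltage, rec3$voltage)
  expect_error(apply_car(recording(v[1, , drop = FALSE], 1000,
    channel_info("a", "HG"))), ">= 2 channels")
})

test_that("epoch extraction covers the task-specific bounds", {
  cfg <- voice_config()
  ch <- channel_info(c("a", "b"), "HG")
  set.seed(2)
  v <- matrix(rnorm(2 * 12000), 2, 12000)
  rec <- recording(v, 1000, ch)

  vl <- stimulus_table("s1", "VL", "clip", TRUE)
  ep <- epoch_voltage(rec, trial_table(1, "s1", 5000), vl, cfg)
  # VL: [-1000, 2000) ms around onset -> 0-based samples 4000..6999
  expect_equal(dim(ep$data), c(1, 2, 3000))
  expect_equal(ep$data[1, 1, ], v[1, 4001:7000])
  expect_equal(range(ep$time_ms), c(-1000, 1999))

  ns <- stimulus_table("s1", "NatS", "x", TRUE)
  ep2 <- epoch_voltage(rec, trial_table(1, "s1", 5000), ns, cfg)
  expect_equal(dim(ep2$data)[3], 4000)
  expect_equal(range(ep2$time_ms), c(-1000, 2999))

  expect_error(
    epoch_voltage(rec, trial_table(1, "s1", 100), ns, cfg),
    "trial id\\(s\\): 1"
  )
})

test_that("prestimulus normalization pools trials and is scale-invariant", {
  cfg <- voice_config()
  ch <- channel_info(c("a", "b"), "HG")
  set.seed(3)
  v <- matrix(rnorm(2 * 30000, sd = 5), 2, 30000)
  rec <- recording(v, 1000, ch)
  stim <- stimulus_table(c("s1", "s2", "s3"), "NatS", "x", TRUE)
  tr <- trial_table(1:3, stim$stimulus_id, c(4000, 12000, 20000))
  ep <- normalize_epochs(epoch_voltage(rec, tr, stim, cfg), cfg)
  pre <- which(ep$time_ms < 0)
  for (chn in 1:2) {
    base <- as.vector(ep$data[, chn, pre])
    expect_equal(mean(base), 0, tolerance = 1e-10)
    expect_equal(sd(base), 1, tolerance = 1e-10)
  }
  # scale invariance
  rec10 <- recording(10 * v, 1000, ch)
  ep10 <- normalize_epochs(epoch_voltage(rec10, tr, stim, cfg), cfg)
  expect_equal(ep10$data, ep$data)
  # constant channel is degenerate
  recc <- recording(rbind(v[1, ], 0 * v[2, ]), 1000, ch)
  expect_error(normalize_epochs(epoch_voltage(recc, tr, stim, cfg), cfg),
    "degenerate")
})

test_that("filter bank is a geometric progression over the stated edges", {
  bank <- make_filter_bank(voice_config())
  expect_equal(nrow(bank), 8)
  expect_equal(bank$center_hz[1], 70)
  expect_equal(bank$center_hz[8], 150)
  expect_equal(bank$bandwidth_hz[1], 16)
  expect_equal(bank$bandwidth_hz[8], 64)
  expect_equal(bank$center_hz[2], 70 * (150 / 70)^(1 / 7))
  expect_equal(bank$center_hz[2], 78.05, tolerance = 1e-4)
  # geometric: constant ratio
  expect_equal(diff(log(bank$center_hz)), rep(log(150 / 70) / 7, 7))
  expect_equal(bank$high_hz, bank$center_hz + bank$bandwidth_hz / 2)
  expect_error(make_filter_bank(voice_config(), sample_rate_hz = 300),
    "Nyquist")
})

test_that("HGA tracks in-band energy and rejects out-of-band energy", {
  cfg <- voice_config()
  set.seed(4)
  n <- 30000
  t_s <- seq_len(n) / 1000
  stim <- stimulus_table(c("s1", "s2", "s3"), "NatS", "x", TRUE)
  onsets <- c(4000, 12000, 20000)
  tr <- trial_table(1:3, stim$stimulus_id, onsets)
  tone_win <- rep(0, n)
  for (o in onsets) tone_win[(o + 1):(o + 2000)] <- 1

  for (freq in c(100, 30)) {
    v <- matrix(rnorm(2 * n, sd = 0.5), 2, n)
    v[1, ] <- v[1, ] + 3 * sin(2 * pi * freq * t_s) * tone_win
    rec <- recording(v, 1000, channel_info(c("a", "b"), "HG"))
    hga <- preprocess_recording(rec, tr, stim, cfg, car = FALSE)
    during <- rowMeans(hga$data[, 1, hga$time_ms >= 100 & hga$time_ms < 1900])
    before <- rowMeans(hga$data[, 1, hga$time_ms >= -800 & hga$time_ms < -100])
    if (freq == 100) {
      expect_gt(mean(during) - mean(before), 3)
    } else {
      expect_lt(abs(mean(during) - mean(before)), 1)
    }
  }
})

test_that("extracted HGA recovers a designed boxcar envelope", {
  cfg <- voice_config()
  stim <- example_stimulus_table("NatS", n_vocal = 2, n_nonvocal = 2, seed = 1)
  cors <- vapply(1:20, function(s) {
    tr <- make_trial_schedule(stim, n_presentations = 1, repeat_fraction = 0,
      seed = s)
    sim <- synthesize_recording(
      list(channel_spec("acoustic_encoder", 3, 3, 3, 3)),
      tr, stim, seed = s + 1000
    )
    hga <- preprocess_recording(sim$recording, tr, stim, cfg, car = FALSE)
    env <- ifelse(hga$time_ms >= 0 & hga$time_ms < 2000, 3, 0)
    mean(vapply(seq_len(nrow(tr)), function(i) cor(hga$data[i, 1, ], env),
      numeric(1)))
  }, numeric(1))
  expect_gt(mean(cors), 0.8)
})

test_that("stimulus responses equal the group-by mean of presentations", {
  stim <- example_stimulus_table("NatS", n_vocal = 3, n_nonvocal = 3, seed = 2)
  tr <- make_trial_schedule(stim, n_presentations = 2, repeat_fraction = 0.2,
    seed = 6)
  set.seed(7)
  nt <- nrow(tr)
  dat <- array(rnorm(nt * 2 * 50), dim = c(nt, 2, 50))
  hga <- fake_hga(dat, seq(-900, -910 + 50 * 10, by = 10), tr)
  resp <- average_stimulus_responses(hga, tr, stim)
  for (i in seq_len(nrow(stim))) {
    rows <- which(tr$stimulus_id == stim$stimulus_id[i])
    manual <- dat[rows[1], , ] * 0
    for (r in rows) manual <- manual + dat[r, , ]
    expect_equal(resp$data[i, , ], manual / length(rows))
  }
  expect_equal(resp$n_presentations,
    as.integer(table(factor(tr$stimulus_id, levels = stim$stimulus_id))))
  # two identical presentations average to themselves
  tr2 <- trial_table(1:2, rep(stim$stimulus_id[1], 2), c(0, 5000))
  one <- array(rep(dat[1, , ], each = 2), dim = c(2, 2, 50))
  hga2 <- fake_hga(one, seq(0, 490, 10), tr2)
  r2 <- average_stimulus_responses(hga2, tr2, stim[1, ])
  expect_equal(r2$data[1, , ], dat[1, , ])
  # a stimulus with no presentations is a consistency error
  expect_error(average_stimulus_responses(hga2, tr2, stim[1:2, ]),
    "zero presentations")
})
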