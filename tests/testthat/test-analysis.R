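test_that("blanking covers stimulation and actuator spans and nothing else", {
  r <- render_beat_train(3, noise_rms = 0, quantize = FALSE)
  rec <- r$record
  # no actuator events: only the 5 ms stimulus spans are masked
  expect_equal(sum(rec$blank_mask),
               3 * round(0.005 * rec$sample_rate))
  expect_true(all(rec$traces[rec$blank_mask, ] == 0))

  # a 200 ms ramp forces a 200 ms blank; a 3 ms ramp still blanks 10 ms
  stim <- (0:9) * 0.4
  act <- data.frame(beat_index = 1:10, electrode = "I",
                    t_AT_s = stim + 0.01)
  dea <- data.frame(onset_s = c(0.45, 1.25), span_s = c(0.2, 0.003),
                    polarity = c(1, -1))
  rec2 <- render_record(act, default_tpl, duration = 4, stim_times = stim,
                        dea_events = dea, noise_rms = 0, quantize = FALSE)
  rec2 <- blank_intervals(rec2)
  tt <- rec2$time_s
  expect_true(all(rec2$blank_mask[tt >= 0.45 & tt < 0.649]))
  expect_true(all(rec2$blank_mask[tt >= 1.25 & tt < 1.259]))
  expect_false(any(rec2$blank_mask[tt >= 1.261 & tt < 1.4]))
  expect_error(blank_intervals(rec2, dea_min_blank = 0.005), "10 ms")
})

test_that("the Gaussian downstroke fit is exact on clean derivatives", {
  fs <- 2e4
  tt <- seq(14.99, 15.01, by = 1 / fs)
  mu <- 15.000000; A <- 2.2; sig <- 163e-6
  d <- -A * exp(-(tt - mu)^2 / (2 * sig^2)) + 0.03
  f <- fit_downstroke(d, tt, fs)
  expect_equal(f$status, "accepted")
  expect_lt(abs(f$t_AT - mu), 1e-7)
  expect_equal(f$dvdt_max, -A, tolerance = 1e-6)
  expect_equal(f$sigma, sig, tolerance = 1e-6)
  expect_equal(f$b, 0.03, tolerance = 1e-6)
})

test_that("downstroke amplitude and width are recovered within 2%", {
  r <- render_beat_train(6, noise_rms = 0, quantize = FALSE)
  f <- extract_features(r$record)
  expect_equal(mean(f$dvdt_max_Vps), -2.2, tolerance = 0.02)
  expect_equal(mean(1e6 * f$t_DS_s), 940, tolerance = 0.02)
  expect_equal(mean(f$Vpp_uV), 900, tolerance = 0.06)
  # derivative fit is consistent with the raw voltage drop within 5%
  drop <- -mean(f$dvdt_max_Vps) * mean(f$sigma_s) * sqrt(2 * pi) * 1e6
  expect_equal(drop, 1e6 * default_tpl$neg_area, tolerance = 0.05)
})

test_that("activation-time extraction is unbiased under symmetric noise", {
  n <- 1000
  r <- render_beat_train(n, noise_rms = 10, quantize = TRUE, seed = 123)
  f <- extract_features(r$record)
  err <- f$t_AT_s - r$activation$t_AT_s
  expect_true(all(f$status == "accepted"))
  expect_lt(abs(mean(err)), 1e-6)
  expect_lt(sd(err), 10e-6)
  expect_true(all(is.finite(f$fit_se_tAT_s)))
})

test_that("silent channels are rejected with reasons, rows retained", {
  stim <- (0:4) * 0.4
  act <- data.frame(beat_index = 1:5, electrode = "II",
                    t_AT_s = stim + 0.01)
  rec <- render_record(act, apec_template(A = 0), duration = 2,
                       stim_times = stim, noise_rms = 10, seed = 5)
  f <- extract_features(blank_intervals(rec))
  expect_equal(nrow(f), 5)
  expect_true(all(f$status == "rejected"))
  expect_true(all(f$reason == "low_amplitude"))
  expect_true(all(is.na(f$t_AT_s)))
})

test_that("ATDs difference, add exactly, and vanish for identical electrodes", {
  stim <- (0:3) * 0.4
  geom <- default_geom
  rows <- do.call(rbind, lapply(seq_along(stim), function(i) {
    a <- kinematic_activation_times(geom, t_stim = stim[i])
    a$beat_index <- i
    a
  }))
  feats <- data.frame(beat_index = rows$beat_index,
                      electrode = rows$electrode, t_AT_s = rows$t_AT_s,
                      status = "accepted")
  atd <- compute_atd(feats, c("III", "IV"))
  expect_equal(atd$atd_s, rep(2.22 / 324, 4), tolerance = 1e-12)
  expect_equal(attr(atd, "n_dropped"), 0)
  expect_equal(compute_atd(feats, c("III", "III"))$atd_s, rep(0, 4))
  # additivity along the strand, beat by beat
  lhs <- compute_atd(feats, c("I", "VI"))$atd_s
  rhs <- compute_atd(feats, c("I", "III"))$atd_s +
    compute_atd(feats, c("III", "IV"))$atd_s +
    compute_atd(feats, c("IV", "VI"))$atd_s
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("velocity regression recovers uniform conduction exactly", {
  a <- kinematic_activation_times(default_geom)
  feats <- data.frame(beat_index = 1, electrode = a$electrode,
                      t_AT_s = a$t_AT_s, status = "accepted")
  pos <- strained_positions(default_geom)
  v <- fit_velocity(feats, pos)
  expect_equal(v$theta_mmps, 324, tolerance = 1e-9)
  expect_gt(v$r_squared, 1 - 1e-12)
  expect_false(v$discontinuous)
  expect_equal(v$direction, 1)

  # reversed propagation: same speed, negative direction
  rev <- feats
  rev$t_AT_s <- max(feats$t_AT_s) - feats$t_AT_s
  vr <- fit_velocity(rev, pos)
  expect_equal(vr$theta_mmps, 324, tolerance = 1e-9)
  expect_equal(vr$direction, -1)

  # non-monotone activation is flagged as discontinuous
  swap <- feats
  swap$t_AT_s[2:3] <- swap$t_AT_s[3:2]
  expect_true(fit_velocity(swap, pos)$discontinuous)
  expect_error(fit_velocity(feats[1:2, ], pos), "3 electrodes")
})
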