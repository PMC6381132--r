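test_that("the template has the prescribed downstroke and amplitude", {
  tpl <- default_tpl
  tt <- seq(-6e-3, 12e-3, by = 1e-6)
  w <- apec_waveform(tpl, tt)
  d <- diff(w) / 1e-6 * 1e-6                    # uV/us == V/s
  expect_equal(min(d), -2.2, tolerance = 0.01)
  expect_equal(tt[which.min(d)], 0, tolerance = 2e-6)
  # peak-to-peak equals the Gaussian-lobe drop A*sigma*sqrt(2*pi) ~ 0.9 mV
  expect_equal(max(w) - min(w), 1e6 * 2.2 * 163e-6 * sqrt(2 * pi),
               tolerance = 0.01)
  # waveform returns to baseline (zero net derivative area)
  expect_lt(abs(w[length(w)]), 1)
  flat <- apec_waveform(apec_template(A = 0), tt)
  expect_true(all(flat == 0))
  expect_error(make_template(tpl, 1e4), "3 samples")
  smp <- make_template(tpl, 2e4)
  expect_true(all(diff(smp$time_s) > 0) && nrow(smp) > 100)
})

test_that("AC coupling is a first-order high-pass and is linear", {
  fs <- 2e4
  # constant input decays to zero with time constant tau_c
  y <- ac_couple(rep(100, 4000), 0.008, fs)
  expect_equal(y[1], 100, tolerance = 1)
  expect_equal(y[round(0.008 * fs)], 100 * exp(-1), tolerance = 1.5)
  expect_lt(abs(y[4000]), 1e-6)

  atten <- function(f, tau) {
    tt <- seq(0, 30, by = 1 / fs)
    x <- sin(2 * pi * f * tt)
    y <- ac_couple(x, tau, fs)
    keep <- tt > 20                    # past the start-up transient
    sqrt(mean(y[keep]^2) / mean(x[keep]^2))
  }
  th <- function(f, tau) {
    w <- 2 * pi * f * tau
    w / sqrt(1 + w^2)
  }
  expect_equal(atten(1, 0.008), th(1, 0.008), tolerance = 2e-3)  # ~0.050
  expect_equal(atten(1, 1.6), th(1, 1.6), tolerance = 2e-3)      # ~0.995

  # linearity/superposition to 1e-9 relative
  set.seed(11)
  a <- rnorm(5000); b <- rnorm(5000)
  lhs <- ac_couple(2 * a + 3 * b, 0.008, fs)
  rhs <- 2 * ac_couple(a, 0.008, fs) + 3 * ac_couple(b, 0.008, fs)
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-9)
  expect_error(ac_couple(a, 5e-5, fs), "tau_c")
})

test_that("rendering is reproducible and quantisation is bounded", {
  r1 <- render_beat_train(4, noise_rms = 10, quantize = TRUE, seed = 9)
  r2 <- render_beat_train(4, noise_rms = 10, quantize = TRUE, seed = 9)
  expect_identical(r1$record$traces, r2$record$traces)
  r3 <- render_beat_train(4, noise_rms = 10, quantize = TRUE, seed = 10)
  expect_false(identical(r1$record$traces, r3$record$traces))

  rq <- render_beat_train(3, noise_rms = 5, quantize = TRUE, seed = 4)
  rc <- render_beat_train(3, noise_rms = 5, quantize = FALSE, seed = 4)
  expect_lte(max(abs(rq$record$traces - rc$record$traces)), 3)  # step/2
})

test_that("noiseless records round-trip activation times to < 0.1 us", {
  r <- render_beat_train(3, offset = 0.0123456, noise_rms = 0,
                         quantize = FALSE)
  f <- extract_features(r$record)
  expect_true(all(f$status == "accepted"))
  expect_lt(max(abs(f$t_AT_s - r$activation$t_AT_s)), 1e-7)
})

test_that("records survive a lossless file round trip", {
  dir <- withr::local_tempdir()
  r <- render_beat_train(3, noise_rms = 10, quantize = TRUE, seed = 2)
  rec <- r$record
  path <- file.path(dir, "rec.csv")
  write_record(rec, path)
  back <- read_record(path)
  expect_identical(back$traces, rec$traces)
  expect_equal(back$stim_times, rec$stim_times)
  expect_equal(back$sample_rate, rec$sample_rate)
  expect_equal(back$tau_c, rec$tau_c)
  expect_identical(back$quantized, rec$quantized)

  # unquantised traces are also bit-exact via 17-digit decimal
  r2 <- render_beat_train(2, noise_rms = 10, quantize = FALSE, seed = 2)
  path2 <- file.path(dir, "rec2.csv")
  write_record(r2$record, path2)
  expect_identical(read_record(path2)$traces, r2$record$traces)

  # empty record (0 channels)
  act0 <- data.frame(beat_index = integer(0), electrode = character(0),
                     t_AT_s = numeric(0))
  rec0 <- render_record(act0, duration = 0.01, noise_rms = 0)
  path0 <- file.path(dir, "rec0.csv")
  write_record(rec0, path0)
  expect_equal(ncol(read_record(path0)$traces), 0)

  # truncation and missing metadata are format errors
  lines <- readLines(path)
  writeLines(head(lines, 20), path)
  expect_error(read_record(path), "truncated")
  meta <- jsonlite::read_json(paste0(path2, ".json"))
  meta$sample_rate <- NULL
  jsonlite::write_json(meta, paste0(path2, ".json"), auto_unbox = TRUE)
  expect_error(read_record(path2), "sample_rate")
})

test_that("out-of-range traces are clipped with a warning flag", {
  big <- apec_template(A = 40)   # ~16 mV swing against a 4 mV range
  stim <- 0
  act <- data.frame(beat_index = 1, electrode = "I", t_AT_s = 0.02)
  expect_warning(rec <- render_record(act, big, duration = 0.1,
                                      stim_times = stim, noise_rms = 0),
                 "clipped")
  expect_true(rec$clipped)
  expect_lte(max(abs(rec$traces)), 4000)
})
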