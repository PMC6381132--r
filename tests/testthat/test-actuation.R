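test_that("the cubic voltage-strain law evaluates and inverts exactly", {
  cal <- calibration_curve()
  expect_equal(strain_from_voltage(3.6, cal), 0.10)
  expect_equal(strain_from_voltage(0, cal), 0)
  expect_equal(strain_from_voltage(1.8, cal), 0.0125)
  expect_error(strain_from_voltage(-1, cal), "negative")
  expect_error(strain_from_voltage(5.5, cal), "amplifier maximum")

  v <- seq(0, 5, length.out = 101)
  eps <- strain_from_voltage(v, cal)
  expect_true(all(diff(eps) > 0))                      # strictly monotone
  expect_equal(voltage_from_strain(eps, cal), v, tolerance = 1e-12)
})

test_that("cube-root drive composed with the cubic law is linear in time", {
  expect_equal(cube_root_voltage(0.2, 0.2, 3.6), 3.6)   # endpoint
  expect_equal(cube_root_voltage(0.2 / 8, 0.2, 3.6), 1.8)
  expect_equal(cube_root_voltage(0.5, 0.2, 3.6), 3.6)   # held after ramp

  cal <- calibration_curve()
  wf <- cube_root_ramp(0.1, 3.6, 1e4)
  eps <- strain_from_voltage(wf$V_kV, cal)
  lin <- 0.10 * wf$time_s / 0.1
  expect_lt(max(abs(eps - lin)), 1e-9 * 0.10)
  expect_equal(eps[nrow(wf)] , 0.10)
  expect_error(cube_root_ramp(0.0005, 3.6, 1e4), "10 samples")
})

test_that("nominal and realized strain rates match the protocol extremes", {
  expect_identical(nominal_strain_rate(0.10, 0.2), 0.5)
  expect_identical(nominal_strain_rate(0.10, 0.005), 20)
  expect_identical(realized_strain_rate(0.10, 0.005, 0.85), 17)
  expect_error(nominal_strain_rate(0.1, 0), "positive")
})

test_that("the slew low-pass has first-order step response", {
  fs <- 1e5
  expect_equal(lowpass_slew(rep(2.5, 100), 1000, fs), rep(2.5, 100))
  expect_equal(lowpass_slew(rep(0, 100), 1000, fs), rep(0, 100))
  step <- c(0, rep(1, 5000))
  y <- lowpass_slew(step, 1000, fs)
  t10 <- which(y >= 0.1)[1] / fs
  t90 <- which(y >= 0.9)[1] / fs
  expect_equal(t90 - t10, 2.2 / (2 * pi * 1000), tolerance = 0.05)
  # 63% within one time constant
  expect_gt(y[1 + round(fs / (2 * pi * 1000))], 0.63)
  expect_error(lowpass_slew(step, 6e4, fs), "Nyquist")
})

test_that("protocol construction enforces timing invariants", {
  p <- strain_protocol(0.10, 0.005)
  expect_equal(p$total_s, 68)
  expect_length(stimulus_times(p), 170)
  expect_equal(length(stimulus_times(p)), round(p$total_s * p$pacing_hz))
  sched <- ramp_schedule(p)
  # first stimulus after each ramp onset falls sync_offset_s later
  st <- stimulus_times(p)
  gaps <- vapply(sched$onset_s, function(on) min(st[st > on]) - on,
                 numeric(1))
  expect_equal(gaps, rep(0.3, 10))
  expect_error(strain_protocol(0.1, t_ramp = 2.4), "protocol error")
  expect_error(strain_protocol(0.1, t_ramp = 0.35), "sync_offset")
})

test_that("beat phases count 25 baseline, 6 strained and 12 per cycle", {
  ph <- beat_phases(strain_protocol(0.10, 0.005))
  expect_equal(sum(ph$phase == "baseline"), 25)
  expect_equal(sum(ph$phase == "strained" & ph$cycle == 3), 6)
  for (k in 1:9)
    expect_equal(sum(ph$cycle == k, na.rm = TRUE), 12)
  expect_equal(nrow(ph), 170)
})

test_that("realized strain traces ramp, creep, accumulate and saturate", {
  p <- strain_protocol(0.10, 0.005)
  tr <- realize_protocol(p)
  sched <- ramp_schedule(p)
  # end-of-ramp strain equals fast_fraction * amplitude on cycle 1
  expect_equal(strain_at(tr, sched$onset_s[1] + p$t_ramp), 0.085,
               tolerance = 1e-3)
  # cycle peaks non-decreasing and saturating
  peaks <- vapply(seq_len(10), function(k)
    max(tr$strain[tr$time_s >= sched$onset_s[k] &
                    tr$time_s < sched$offset_s[k]]), numeric(1))
  expect_true(all(diff(peaks) > -1e-9))
  expect_lt(peaks[10] - peaks[9], 0.01 * 0.10)
  expect_lt(max(tr$strain), 1.2 * 0.10)

  # compression zone mirrors at -k_c: ~-2% for 10% stretch
  trc <- realize_protocol(p, zone = "compress")
  expect_equal(min(trc$strain), -0.2 * max(tr$strain), tolerance = 1e-9)
  expect_lt(min(trc$strain), -0.018)
})

test_that("creep-free traces return exactly to zero between cycles", {
  p <- strain_protocol(0.08, 0.02)
  tr <- realize_protocol(p, creep = creep_params(fast_fraction = 1,
                                                 residual_fraction = 0))
  sched <- ramp_schedule(p)
  before_next <- strain_at(tr, sched$onset_s[-1] - 1e-3)
  expect_equal(before_next, rep(0, 9))
  # plateau holds the target exactly
  expect_equal(strain_at(tr, sched$offset_s[1] - 0.1), 0.08)
})

test_that("a zero-amplitude protocol yields a null trace and 170 stimuli", {
  tr <- realize_protocol(strain_protocol(0, 0.005))
  expect_true(all(tr$strain == 0))
  expect_length(tr$stim_times, 170)
  expect_equal(nrow(tr$dea_events), 20)  # one on- and one off-ramp per cycle
})
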