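# Dielectric-elastomer actuation: voltage-to-strain transduction, drive
# waveforms, and full strain protocols (baseline / strain cycles / tail)
# including viscoelastic creep and the coupled compression zones.

#' Voltage-strain calibration of the dielectric actuator
#'
#' The actuator strain follows a power law of the drive voltage,
#' \eqn{\varepsilon(V) = \varepsilon_{ref} (V/V_{ref})^p}, with a cubic
#' exponent (\eqn{p = 3}) for this device class: the Maxwell pressure scales
#' with \eqn{V^2} and the progressive thinning of the dielectric adds one
#' more power of \eqn{V}. Compression zones flanking the stretched region
#' move with opposite sign at a fixed fraction `k_c` of the stretch-zone
#' strain.
#'
#' @param V_ref reference voltage (kV) at which the strain equals `eps_ref`.
#' @param eps_ref dimensionless strain at `V_ref` (default 10\% at 3.6 kV).
#' @param exponent power-law exponent (default 3, cubic).
#' @param k_c compression coupling: ratio of compression-zone to
#'   stretch-zone strain magnitude (default 0.2, the ~-2\% / +10\% pair).
#' @param V_max amplifier maximum (kV); drive requests above it are a
#'   configuration error, never silently clipped.
#' @return an object of class `calibration_curve`.
#' @export
calibration_curve <- function(V_ref = 3.6, eps_ref = 0.10, exponent = 3,
                              k_c = 0.2, V_max = 5) {
  stopifnot(V_ref > 0, eps_ref > 0, exponent > 0, k_c >= 0, k_c <= 1,
            V_max >= V_ref)
  structure(list(V_ref = V_ref, eps_ref = eps_ref, exponent = exponent,
                 k_c = k_c, V_max = V_max),
            class = "calibration_curve")
}

#' Strain produced by a given actuator voltage
#'
#' @param V voltage (kV), non-negative, at most `cal$V_max`.
#' @param cal a [calibration_curve()].
#' @return dimensionless strain (vectorised over `V`).
#' @export
strain_from_voltage <- function(V, cal = calibration_curve()) {
  if (any(V < 0)) stop("strain_from_voltage: negative voltage (domain error)")
  if (any(V > cal$V_max))
    stop("strain_from_voltage: voltage exceeds the amplifier maximum of ",
         cal$V_max, " kV (configuration error)")
  cal$eps_ref * (V / cal$V_ref)^cal$exponent
}

#' Analytic inverse of [strain_from_voltage()]
#'
#' @param eps non-negative dimensionless strain.
#' @inheritParams strain_from_voltage
#' @return voltage (kV).
#' @export
voltage_from_strain <- function(eps, cal = calibration_curve()) {
  if (any(eps < 0)) stop("voltage_from_strain: negative strain (domain error)")
  cal$V_ref * (eps / cal$eps_ref)^(1 / cal$exponent)
}

#' Pointwise cube-root voltage ramp
#'
#' \eqn{V(t) = V_{max} (t/t_{ramp})^{1/p}} for \eqn{0 < t \le t_{ramp}},
#' held at `V_max` afterwards. Composed with the power-law
#' [strain_from_voltage()] of exponent `p` this yields a strain that is
#' linear in time, i.e. a constant-strain-rate ramp.
#'
#' @param t time (s), vectorised.
#' @param t_ramp ramp duration (s), positive.
#' @param V_max plateau voltage (kV).
#' @param exponent actuator power-law exponent (default 3).
#' @return voltage (kV) at each `t`.
#' @export
cube_root_voltage <- function(t, t_ramp, V_max, exponent = 3) {
  if (t_ramp <= 0) stop("cube_root_voltage: t_ramp must be positive")
  V_max * (pmin(pmax(t, 0), t_ramp) / t_ramp)^(1 / exponent)
}

#' Sampled cube-root drive waveform
#'
#' @inheritParams cube_root_voltage
#' @param sample_rate sampling rate (Hz); the ramp must carry at least
#'   10 samples.
#' @param hold_s extra hold time at `V_max` appended after the ramp (s).
#' @return a data frame with columns `time_s` and `V_kV`.
#' @export
cube_root_ramp <- function(t_ramp, V_max, sample_rate, exponent = 3,
                           hold_s = 0) {
  if (t_ramp <= 0) stop("cube_root_ramp: t_ramp must be positive")
  if (sample_rate * t_ramp < 10)
    stop("cube_root_ramp: fewer than 10 samples over the ramp ",
         "(configuration error)")
  tt <- seq(0, t_ramp + hold_s, by = 1 / sample_rate)
  data.frame(time_s = tt,
             V_kV = cube_root_voltage(tt, t_ramp, V_max, exponent))
}

#' Nominal and realized strain rates of a linear ramp
#'
#' The nominal rate is the ideal pre-filter slope `amplitude / t_ramp`. The
#' realized variant accounts for the fraction of the target strain actually
#' attained during the ramp (the remainder develops as creep), so the slope
#' set by the ramp is `fast_fraction * amplitude / t_ramp`.
#'
#' @param amplitude target strain (dimensionless).
#' @param t_ramp ramp duration (s), positive.
#' @param fast_fraction fraction of the amplitude attained within the ramp.
#' @return strain rate in s^-1.
#' @export
nominal_strain_rate <- function(amplitude, t_ramp) {
  if (any(t_ramp <= 0)) stop("nominal_strain_rate: t_ramp must be positive")
  amplitude / t_ramp
}

#' @rdname nominal_strain_rate
#' @export
realized_strain_rate <- function(amplitude, t_ramp, fast_fraction = 0.85) {
  fast_fraction * nominal_strain_rate(amplitude, t_ramp)
}

#' First-order low-pass filter (drive-chain slew limit)
#'
#' Discrete first-order low-pass with cutoff `cutoff` (Hz); a step input
#' reaches 63\% of its final value within one time constant
#' \eqn{1/(2\pi f_c)} and the 10-90\% rise time is \eqn{2.2/(2\pi f_c)}.
#'
#' @param x input waveform (numeric vector); the state is initialised at
#'   `x[1]` so a constant input passes unchanged.
#' @param cutoff cutoff frequency (Hz), below Nyquist.
#' @param sample_rate sampling rate (Hz).
#' @return filtered waveform.
#' @export
lowpass_slew <- function(x, cutoff, sample_rate) {
  if (cutoff >= sample_rate / 2)
    stop("lowpass_slew: cutoff at or above Nyquist (configuration error)")
  rc <- 1 / (2 * pi * cutoff)
  dt <- 1 / sample_rate
  a <- 1 - exp(-dt / rc)      # exact zero-order-hold discretisation
  if (length(x) == 0) return(x)
  y <- stats::filter(a * x, 1 - a, method = "recursive", init = x[1])
  as.numeric(y)
}

#' Strain protocol definition
#'
#' The standard measurement protocol: a baseline recording, `n_cycles`
#' square strain cycles of period `period_s` and duty cycle `duty`, and a
#' final relaxed tail. Pacing runs at `pacing_hz` throughout, phase-locked
#' to the strain cycles such that the first stimulus after each ramp falls
#' `sync_offset_s` after the ramp onset (ramp onsets are scheduled
#' `1/pacing_hz - sync_offset_s` after the preceding stimulus). With the
#' defaults the protocol lasts 10 + 48 + 10 = 68 s.
#'
#' @param amplitude target strain (dimensionless, >= 0).
#' @param t_ramp ramp duration (s); one of 0.005/0.02/0.05/0.1/0.2 in the
#'   standard protocol (any positive value below `duty * period_s` is
#'   accepted).
#' @param baseline_s,tail_s initial/final relaxed recording durations (s).
#' @param n_cycles number of strain cycles.
#' @param period_s cycle period (s).
#' @param duty fraction of the period spent strained.
#' @param pacing_hz stimulation rate (Hz).
#' @param sync_offset_s delay from ramp onset to the next stimulus (s).
#' @return an object of class `strain_protocol`.
#' @export
strain_protocol <- function(amplitude, t_ramp, baseline_s = 10,
                            n_cycles = 10, period_s = 4.8, duty = 0.5,
                            pacing_hz = 2.5, sync_offset_s = 0.3,
                            tail_s = 10) {
  stopifnot(amplitude >= 0, baseline_s >= 0, n_cycles >= 1, period_s > 0,
            duty > 0, duty < 1, pacing_hz > 0, tail_s >= 0)
  if (t_ramp <= 0 || t_ramp >= duty * period_s)
    stop("strain_protocol: t_ramp must lie in (0, duty * period_s) ",
         "(protocol error)")
  if (sync_offset_s < t_ramp)
    stop("strain_protocol: sync_offset_s must be >= t_ramp so ramps ",
         "complete before the next activation (protocol error)")
  if (sync_offset_s > 1 / pacing_hz)
    stop("strain_protocol: sync_offset_s exceeds the pacing interval")
  structure(list(amplitude = amplitude, t_ramp = t_ramp,
                 baseline_s = baseline_s, n_cycles = n_cycles,
                 period_s = period_s, duty = duty, pacing_hz = pacing_hz,
                 sync_offset_s = sync_offset_s, tail_s = tail_s,
                 total_s = baseline_s + n_cycles * period_s + tail_s),
            class = "strain_protocol")
}

#' Viscoelastic creep parameters of the actuator substrate
#'
#' During the ramp only `fast_fraction` of the target strain is attained;
#' the remainder creeps in exponentially with time constant `tau_on`.
#' Relaxation is slower (`tau_off`) and leaves a per-cycle residual that
#' accumulates geometrically (increment
#' `residual_fraction * amplitude * residual_decay^(k-1)` at cycle k) and
#' therefore saturates within the first ~5 cycles.
#'
#' @param fast_fraction fraction of target strain reached at end of ramp.
#' @param tau_on,tau_off creep time constants (s) for loading/unloading.
#' @param residual_fraction first-cycle residual as a fraction of amplitude.
#' @param residual_decay geometric decay of successive residual increments.
#' @return an object of class `creep_params`.
#' @export
creep_params <- function(fast_fraction = 0.85, tau_on = 2, tau_off = 4,
                         residual_fraction = 0.03, residual_decay = 0.5) {
  stopifnot(fast_fraction > 0, fast_fraction <= 1, tau_on > 0, tau_off > 0,
            residual_fraction >= 0, residual_decay >= 0, residual_decay < 1)
  structure(list(fast_fraction = fast_fraction, tau_on = tau_on,
                 tau_off = tau_off, residual_fraction = residual_fraction,
                 residual_decay = residual_decay),
            class = "creep_params")
}

#' Stimulus times of a protocol
#'
#' Pacing stimuli at fixed intervals from t = 0 for the whole protocol
#' duration; the count equals `round(total_s * pacing_hz)`.
#'
#' @param protocol a [strain_protocol()].
#' @return numeric vector of stimulus times (s).
#' @export
stimulus_times <- function(protocol) {
  seq(0, protocol$total_s - 1e-9, by = 1 / protocol$pacing_hz)
}

#' Ramp onset/offset schedule of a protocol
#'
#' @inheritParams stimulus_times
#' @return data frame with columns `cycle`, `onset_s` (loading ramp onset),
#'   `offset_s` (unloading ramp onset).
#' @export
ramp_schedule <- function(protocol) {
  lead <- 1 / protocol$pacing_hz - protocol$sync_offset_s
  on <- protocol$baseline_s + (seq_len(protocol$n_cycles) - 1) *
    protocol$period_s + lead
  data.frame(cycle = seq_len(protocol$n_cycles), onset_s = on,
             offset_s = on + protocol$duty * protocol$period_s)
}

#' Protocol phase of every stimulus
#'
#' Labels each pacing stimulus as `baseline` (before `baseline_s`),
#' `strained` or `relaxed` with its cycle index, or `tail`. The stimulus
#' falling between the end of the baseline window and the first ramp is
#' labelled `relaxed` with cycle 0: it is the reference beat immediately
#' preceding the first strain cycle.
#'
#' @inheritParams stimulus_times
#' @return data frame with columns `beat_index`, `t_stim_s`, `phase`,
#'   `cycle`.
#' @export
beat_phases <- function(protocol) {
  ts <- stimulus_times(protocol)
  sched <- ramp_schedule(protocol)
  phase <- rep("tail", length(ts))
  cycle <- rep(NA_integer_, length(ts))
  phase[ts < protocol$baseline_s] <- "baseline"
  pre <- ts >= protocol$baseline_s & ts < sched$onset_s[1]
  phase[pre] <- "relaxed"; cycle[pre] <- 0L
  for (k in seq_len(protocol$n_cycles)) {
    on <- sched$onset_s[k]; off <- sched$offset_s[k]
    nxt <- on + protocol$period_s
    i_str <- ts >= on & ts < off
    i_rel <- ts >= off & ts < nxt
    phase[i_str] <- "strained"; cycle[i_str] <- k
    phase[i_rel] <- "relaxed"; cycle[i_rel] <- k
  }
  data.frame(beat_index = seq_along(ts), t_stim_s = ts, phase = phase,
             cycle = cycle)
}

#' Realize a strain protocol as a sampled strain trace
#'
#' Generates the strain actually experienced by the substrate zone: a
#' linear ramp to `fast_fraction * amplitude` during `t_ramp`, exponential
#' creep toward the (residual-augmented) target with `tau_on`, a linear
#' unloading ramp and slower exponential relaxation with `tau_off` toward
#' the accumulated per-cycle residual. The compression-zone trace is
#' `-k_c` times the stretch-zone trace. Also carries the stimulus table
#' and the actuator (ramp) event table used downstream for blanking.
#'
#' @param protocol a [strain_protocol()].
#' @param cal a [calibration_curve()] (supplies the compression coupling
#'   and the voltage bound check for the requested amplitude).
#' @param creep a [creep_params()].
#' @param sample_rate strain-trace sampling rate (Hz), at least 1 kHz.
#' @param zone `"stretch"` or `"compress"`.
#' @return an object of class `strain_trace`: a list with `time_s`,
#'   `strain`, `zone`, `stim_times`, `phases`, `dea_events` (columns
#'   `onset_s`, `span_s`, `polarity`), `protocol`, `creep`, `cal`.
#' @export
realize_protocol <- function(protocol, cal = calibration_curve(),
                             creep = creep_params(), sample_rate = 1e4,
                             zone = c("stretch", "compress")) {
  zone <- match.arg(zone)
  if (sample_rate < 1000)
    stop("realize_protocol: sample_rate below 1 kHz (configuration error)")
  voltage_from_strain(protocol$amplitude, cal)  # errors above amplifier max
  A <- protocol$amplitude
  ff <- creep$fast_fraction
  tt <- seq(0, protocol$total_s, by = 1 / sample_rate)
  s <- numeric(length(tt))
  sched <- ramp_schedule(protocol)
  tr <- protocol$t_ramp
  dwell <- protocol$duty * protocol$period_s

  # accumulated residual after cycle k
  inc <- creep$residual_fraction * A *
    creep$residual_decay^(seq_len(protocol$n_cycles) - 1)
  resid <- cumsum(inc)

  seg_val <- function(t_rel, s0, se, target, tau) {
    # t_rel relative to ramp onset; ramp then exponential creep
    ifelse(t_rel < tr,
           s0 + (se - s0) * t_rel / tr,
           se + (target - se) * (1 - exp(-(t_rel - tr) / tau)))
  }

  s_prev <- 0
  for (k in seq_len(protocol$n_cycles)) {
    on <- sched$onset_s[k]; off <- sched$offset_s[k]
    end <- if (k < protocol$n_cycles) sched$onset_s[k + 1] else protocol$total_s
    target <- A + resid[k]
    se_up <- s_prev + ff * A
    i_on <- which(tt >= on & tt < off)
    s[i_on] <- seg_val(tt[i_on] - on, s_prev, se_up, target, creep$tau_on)
    s1 <- seg_val(dwell, s_prev, se_up, target, creep$tau_on)
    se_dn <- max(s1 - ff * A, resid[k])
    i_off <- which(tt >= off & tt < end)
    s[i_off] <- seg_val(tt[i_off] - off, s1, se_dn, resid[k], creep$tau_off)
    s_prev <- seg_val(end - off, s1, se_dn, resid[k], creep$tau_off)
  }
  if (length(tt) > 0 && tt[length(tt)] >= protocol$total_s)
    s[length(s)] <- s_prev

  if (A > 0 && max(s) > 1.2 * A)
    stop("realize_protocol: realized strain exceeds 1.2x the target ",
         "amplitude; creep parameters are inconsistent")

  dea_events <- data.frame(
    onset_s = c(rbind(sched$onset_s, sched$offset_s)),
    span_s = tr,
    polarity = rep(c(1, -1), protocol$n_cycles))
  dea_events <- dea_events[order(dea_events$onset_s), , drop = FALSE]
  rownames(dea_events) <- NULL

  if (zone == "compress") s <- -cal$k_c * s
  structure(list(time_s = tt, strain = s, zone = zone,
                 stim_times = stimulus_times(protocol),
                 phases = beat_phases(protocol),
                 dea_events = dea_events,
                 sample_rate = sample_rate,
                 protocol = protocol, creep = creep, cal = cal),
            class = "strain_trace")
}

#' Interpolate a strain trace at arbitrary times
#'
#' @param trace a `strain_trace`.
#' @param t times (s).
#' @return strain values at `t`.
#' @export
strain_at <- function(trace, t) {
  approx(trace$time_s, trace$strain, xout = t, rule = 2)$y
}

#' @export
print.strain_trace <- function(x, ...) {
  cat("<strain_trace>", x$zone, "zone;",
      sprintf("amplitude %.3g, t_ramp %g ms, %d cycles, %.3g s total\n",
              x$protocol$amplitude, 1e3 * x$protocol$t_ramp,
              x$protocol$n_cycles, x$protocol$total_s))
  cat(sprintf("  %d samples at %g kHz; %d stimuli; peak strain %.4g\n",
              length(x$time_s), x$sample_rate / 1e3, length(x$stim_times),
              max(abs(x$strain))))
  invisible(x)
}

#' @export
plot.strain_trace <- function(x, ...) {
  graphics::plot(x$time_s, 100 * x$strain, type = "l",
                 xlab = "time (s)", ylab = "strain (%)",
                 main = paste0(x$zone, " zone"), ...)
  graphics::abline(v = x$dea_events$onset_s, col = "grey85")
  invisible(x)
}

#' Write a strain trace to a two-column CSV
#'
#' @param trace a `strain_trace`.
#' @param path output file path.
#' @export
write_strain_csv <- function(trace, path) {
  data.table::fwrite(data.table::data.table(time_s = trace$time_s,
                                            strain = trace$strain), path)
  invisible(path)
}
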