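# Synthesis of multichannel extracellular recordings from activation
# times: biphasic field-potential templates, AC coupling, additive noise,
# stimulation / actuator artifacts, quantisation, and lossless record I/O
# (wide CSV + JSON metadata sidecar).

#' Biphasic extracellular action-potential template
#'
#' The template is defined through its first time-derivative: a Gaussian
#' negative lobe of amplitude `-A` and width `sigma` (the downstroke that
#' carries all timing information), preceded by a broader positive lobe
#' carrying `pos_fraction` of the downstroke area over twice its width,
#' and followed by a slow recovery lobe that returns the waveform to
#' baseline (zero net area). The peak-to-peak amplitude equals the
#' negative-phase drop \eqn{A \sigma \sqrt{2\pi}} (~0.9 mV for the
#' defaults). The positive lobe is placed `pos_delay` before the
#' downstroke so that the derivative within a +/-2 ms fitting window
#' around the downstroke is purely Gaussian.
#'
#' @param A downstroke amplitude (V/s, positive; the derivative minimum is
#'   `-A`).
#' @param sigma Gaussian width of the derivative's negative lobe (s).
#' @param pos_fraction positive-lobe area as a fraction of the
#'   negative-lobe area.
#' @param pos_width_factor positive-lobe width as a multiple of `sigma`.
#' @param pos_delay delay from positive-lobe centre to the downstroke (s).
#' @param rec_sigma,rec_delay width and delay (s) of the slow recovery
#'   lobe.
#' @return an object of class `apec_template`.
#' @export
apec_template <- function(A = 2.2, sigma = 163e-6, pos_fraction = 0.4,
                          pos_width_factor = 2, pos_delay = 3.2e-3,
                          rec_sigma = 2e-3, rec_delay = 6e-3) {
  stopifnot(A >= 0, sigma > 0, pos_fraction >= 0, pos_fraction < 1,
            pos_width_factor > 0, pos_delay > 0, rec_sigma > 0,
            rec_delay > 0)
  neg_area <- A * sigma * sqrt(2 * pi)          # volts
  structure(list(A = A, sigma = sigma, pos_fraction = pos_fraction,
                 pos_sigma = pos_width_factor * sigma,
                 pos_delay = pos_delay, rec_sigma = rec_sigma,
                 rec_delay = rec_delay,
                 neg_area = neg_area,
                 pos_area = pos_fraction * neg_area,
                 rec_area = (1 - pos_fraction) * neg_area,
                 Vpp_uV = neg_area * 1e6),
            class = "apec_template")
}

#' Evaluate the template waveform at arbitrary times
#'
#' Closed form (sums of Gaussian integrals), so beats can be placed with
#' sub-sample timing on any sampling grid.
#'
#' @param tpl an [apec_template()].
#' @param t_rel time relative to the activation time (s), vectorised. The
#'   activation time is the centre of the derivative's negative lobe.
#' @return waveform in microvolts.
#' @export
apec_waveform <- function(tpl, t_rel) {
  1e6 * (tpl$pos_area * stats::pnorm((t_rel + tpl$pos_delay) /
                                       tpl$pos_sigma) -
           tpl$neg_area * stats::pnorm(t_rel / tpl$sigma) +
           tpl$rec_area * stats::pnorm((t_rel - tpl$rec_delay) /
                                         tpl$rec_sigma))
}

# template support relative to the activation time
.tpl_support <- function(tpl) {
  c(-(tpl$pos_delay + 4 * tpl$pos_sigma),
    tpl$rec_delay + 4 * tpl$rec_sigma)
}

#' Sample a single-beat template waveform
#'
#' @param tpl an [apec_template()].
#' @param sample_rate sampling rate (Hz); `sigma` must span at least three
#'   samples.
#' @return data frame with columns `time_s` (relative to the activation
#'   time) and `uV`.
#' @export
make_template <- function(tpl, sample_rate) {
  if (tpl$sigma * sample_rate < 3)
    stop("make_template: sigma spans fewer than 3 samples ",
         "(configuration error)")
  sup <- .tpl_support(tpl)
  tt <- seq(sup[1], sup[2], by = 1 / sample_rate)
  data.frame(time_s = tt, uV = apec_waveform(tpl, tt))
}

#' First-order AC coupling (high-pass) filter
#'
#' Bilinear discretisation of a one-pole high-pass with coupling time
#' constant `tau_c`; DC decays to zero, and a sinusoid of frequency f is
#' attenuated by \eqn{2\pi f \tau_c / \sqrt{1 + (2\pi f \tau_c)^2}}. The
#' filter starts from zero state (a signal that has been constant since
#' before the record decays to zero with time constant `tau_c`).
#'
#' @param x input trace (numeric vector).
#' @param tau_c coupling time constant (s), > 2 sample intervals.
#' @param sample_rate sampling rate (Hz).
#' @return filtered trace.
#' @export
ac_couple <- function(x, tau_c, sample_rate) {
  if (tau_c <= 2 / sample_rate)
    stop("ac_couple: tau_c must exceed two sample intervals")
  if (length(x) == 0) return(x)
  a <- 2 * tau_c * sample_rate
  k <- a / (a + 1)
  p <- (a - 1) / (a + 1)
  d <- k * (x - c(0, x[-length(x)]))
  as.numeric(stats::filter(d, p, method = "recursive"))
}

#' Render a multichannel extracellular record
#'
#' Places one template per beat per channel with the derivative-Gaussian
#' centre at the activation time, adds stimulation-artifact leakage
#' (bi-polar rectangular pulse) at every stimulus, an exponentially
#' decaying oscillatory transient over every actuator ramp, and white
#' Gaussian noise; then applies AC coupling, clips to the dynamic range
#' (setting a warning flag) and quantises to the acquisition resolution.
#' Fully reproducible under a fixed `seed`.
#'
#' @param activation data frame with columns `beat_index`, `electrode`,
#'   `t_AT_s` (activation times sorted within each electrode).
#' @param tpl an [apec_template()].
#' @param sample_rate sampling rate (Hz), at least 10 kHz.
#' @param duration record duration (s); defaults to covering all events.
#' @param stim_times stimulus times (s).
#' @param dea_events `NULL` or data frame with columns `onset_s`,
#'   `span_s`, `polarity` (actuator ramp events).
#' @param tau_c AC-coupling time constant (s); 0.008 preserves the fast
#'   downstroke while suppressing repolarisation-scale components, 1.6
#'   passes them.
#' @param noise_rms white-noise RMS (µV).
#' @param stim_artifact_uV,stim_artifact_span amplitude (µV) and total
#'   span (s) of the bi-polar stimulation artifact (0 disables).
#' @param dea_artifact_uV amplitude (µV) of the actuator coupling
#'   transient (0 disables).
#' @param quantize quantise to `quantization_step` after filtering.
#' @param quantization_step acquisition resolution (µV).
#' @param dynamic_range_mV half range of the acquisition (mV).
#' @param seed integer seed for the noise generator (`NULL` leaves the
#'   RNG state alone).
#' @param ac apply AC coupling (disable only for diagnostics).
#' @return an object of class `electrogram_record`: list with `traces`
#'   (samples x channels matrix, µV), `time_s`, `electrodes`,
#'   `sample_rate`, `tau_c`, `stim_times`, `dea_events`, `noise_rms`,
#'   `quantized`, `quantization_step`, `dynamic_range_mV`, `clipped`,
#'   `seed`.
#' @export
render_record <- function(activation, tpl = apec_template(),
                          sample_rate = 2e4, duration = NULL,
                          stim_times = numeric(0), dea_events = NULL,
                          tau_c = 0.008, noise_rms = 10,
                          stim_artifact_uV = 1000,
                          stim_artifact_span = 0.002,
                          dea_artifact_uV = 500, quantize = TRUE,
                          quantization_step = 6, dynamic_range_mV = 4,
                          seed = NULL, ac = TRUE) {
  if (sample_rate < 1e4)
    stop("render_record: sample_rate below 10 kHz")
  channels <- unique(as.character(activation$electrode))
  channels <- channels[order(match(channels, .ELECTRODES))]
  if (is.null(duration))
    duration <- max(c(activation$t_AT_s, stim_times, 0)) + 0.1
  n <- floor(duration * sample_rate) + 1
  tt <- (seq_len(n) - 1) / sample_rate

  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }

  sup <- .tpl_support(tpl)
  artifact <- numeric(n)
  if (stim_artifact_uV > 0 && length(stim_times)) {
    half <- stim_artifact_span / 2
    for (ts in stim_times) {
      i1 <- .grid_span(ts, ts + half, sample_rate, n)
      i2 <- .grid_span(ts + half, ts + stim_artifact_span, sample_rate, n)
      artifact[i1] <- artifact[i1] + stim_artifact_uV
      artifact[i2] <- artifact[i2] - stim_artifact_uV
    }
  }
  if (dea_artifact_uV > 0 && !is.null(dea_events) && nrow(dea_events)) {
    for (j in seq_len(nrow(dea_events))) {
      on <- dea_events$onset_s[j]
      span <- max(dea_events$span_s[j], 0.002)
      idx <- .grid_span(on, on + span, sample_rate, n)
      if (!length(idx)) next
      tr <- tt[idx] - on
      artifact[idx] <- artifact[idx] + dea_events$polarity[j] *
        dea_artifact_uV * exp(-3 * tr / span) * sin(2 * pi * 2000 * tr)
    }
  }

  clipped <- FALSE
  rng <- dynamic_range_mV * 1e3
  traces <- matrix(0, nrow = n, ncol = length(channels),
                   dimnames = list(NULL, channels))
  for (ch in channels) {
    x <- numeric(n)
    beats <- activation[as.character(activation$electrode) == ch, ]
    for (b in seq_len(nrow(beats))) {
      ta <- beats$t_AT_s[b]
      i0 <- max(1L, floor((ta + sup[1]) * sample_rate) + 1L)
      i1 <- min(n, ceiling((ta + sup[2]) * sample_rate) + 1L)
      if (i0 > n || i1 < 1) next
      idx <- i0:i1
      x[idx] <- x[idx] + apec_waveform(tpl, tt[idx] - ta)
    }
    x <- x + artifact
    if (noise_rms > 0) x <- x + rnorm(n, 0, noise_rms)
    if (ac) x <- ac_couple(x, tau_c, sample_rate)
    if (any(abs(x) > rng)) {
      clipped <- TRUE
      x <- pmin(pmax(x, -rng), rng)
    }
    if (quantize) {
      x <- round(x / quantization_step) * quantization_step
      qmax <- floor(rng / quantization_step) * quantization_step
      x <- pmin(pmax(x, -qmax), qmax)
    }
    traces[, ch] <- x
  }
  if (clipped)
    warning("render_record: traces clipped at the dynamic range")

  structure(list(traces = traces, time_s = tt, electrodes = channels,
                 sample_rate = sample_rate, tau_c = tau_c,
                 stim_times = stim_times,
                 dea_events = dea_events, noise_rms = noise_rms,
                 quantized = quantize,
                 quantization_step = quantization_step,
                 dynamic_range_mV = dynamic_range_mV,
                 clipped = clipped,
                 seed = if (is.null(seed)) NA_integer_ else seed),
            class = "electrogram_record")
}

#' @export
print.electrogram_record <- function(x, ...) {
  cat(sprintf("<electrogram_record> %d channel(s) x %d samples at %g kHz\n",
              ncol(x$traces), nrow(x$traces), x$sample_rate / 1e3))
  cat(sprintf("  tau_c %g ms, %d stimuli, %s, noise %g uV RMS%s\n",
              1e3 * x$tau_c, length(x$stim_times),
              if (x$quantized) sprintf("quantized at %g uV",
                                       x$quantization_step)
              else "unquantized",
              x$noise_rms,
              if (isTRUE(x$clipped)) " [CLIPPED]" else ""))
  invisible(x)
}

#' @export
plot.electrogram_record <- function(x, channel = 1, xlim = NULL, ...) {
  i <- if (is.character(channel)) match(channel, x$electrodes) else channel
  graphics::plot(x$time_s, x$traces[, i], type = "l", xlim = xlim,
                 xlab = "time (s)", ylab = expression(V[EC] ~ (mu * V)),
                 main = paste("electrode", x$electrodes[i]), ...)
  invisible(x)
}

.REC_META_KEYS <- c("electrodes", "sample_rate", "tau_c", "stim_times",
                    "noise_rms", "quantized", "quantization_step",
                    "dynamic_range_mV", "clipped", "seed", "n_samples")

#' Write / read an electrogram record (CSV + JSON sidecar)
#'
#' The traces go to a wide CSV (`time_s`, one `<electrode>_uV` column per
#' channel) and all metadata to a JSON sidecar `<path>.json`. Quantised
#' traces are stored as integer step counts, unquantised traces with 17
#' significant digits, so the round trip is bit-exact in both cases.
#'
#' @param rec an `electrogram_record`.
#' @param path CSV file path (the sidecar gets `.json` appended).
#' @return `path`, invisibly (`write_record`); the reconstructed record
#'   (`read_record`).
#' @export
write_record <- function(rec, path) {
  dt <- data.table::data.table(time_s = sprintf("%.17g", rec$time_s))
  for (ch in rec$electrodes) {
    x <- rec$traces[, ch]
    col <- if (rec$quantized) {
      format(as.integer(round(x / rec$quantization_step)),
             scientific = FALSE, trim = TRUE)
    } else sprintf("%.17g", x)
    data.table::set(dt, j = paste0(ch, "_uV"), value = col)
  }
  data.table::fwrite(dt, path, quote = FALSE)
  meta <- list(electrodes = rec$electrodes,
               sample_rate = rec$sample_rate, tau_c = rec$tau_c,
               stim_times = rec$stim_times,
               dea_events = rec$dea_events, noise_rms = rec$noise_rms,
               quantized = rec$quantized,
               quantization_step = rec$quantization_step,
               dynamic_range_mV = rec$dynamic_range_mV,
               clipped = rec$clipped, seed = rec$seed,
               n_samples = nrow(rec$traces))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_record
#' @export
read_record <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(side))
    stop("read_record: missing record file or sidecar for ", path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  missing_keys <- setdiff(.REC_META_KEYS, names(meta))
  if (length(missing_keys))
    stop("read_record: format error, missing metadata key '",
         missing_keys[1], "'")
  dt <- data.table::fread(path, colClasses = "numeric")
  if (nrow(dt) != meta$n_samples)
    stop("read_record: format error, truncated trace file (expected ",
         meta$n_samples, " samples, found ", nrow(dt), ")")
  chans <- as.character(meta$electrodes)
  traces <- matrix(0, nrow = nrow(dt), ncol = length(chans),
                   dimnames = list(NULL, chans))
  for (ch in chans) {
    x <- dt[[paste0(ch, "_uV")]]
    if (is.null(x))
      stop("read_record: format error, missing trace column for ", ch)
    traces[, ch] <- if (isTRUE(meta$quantized))
      x * meta$quantization_step else x
  }
  dea <- meta$dea_events
  if (!is.null(dea) && length(dea)) dea <- as.data.frame(dea) else dea <- NULL
  structure(list(traces = traces, time_s = dt$time_s, electrodes = chans,
                 sample_rate = meta$sample_rate, tau_c = meta$tau_c,
                 stim_times = as.numeric(unlist(meta$stim_times)),
                 dea_events = dea, noise_rms = meta$noise_rms,
                 quantized = isTRUE(meta$quantized),
                 quantization_step = meta$quantization_step,
                 dynamic_range_mV = meta$dynamic_range_mV,
                 clipped = isTRUE(meta$clipped),
                 seed = meta$seed),
            class = "electrogram_record")
}
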