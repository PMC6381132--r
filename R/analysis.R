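# indices of grid times t in [t0, t1) for a uniform grid (k-1)/fs
.grid_span <- function(t0, t1, fs, n) {
  i0 <- max(1L, as.integer(ceiling(t0 * fs - 1e-9)) + 1L)
  i1 <- min(n, as.integer(ceiling(t1 * fs - 1e-9)))
  if (i0 > i1) integer(0) else i0:i1
}

# Electrogram analysis chain: artifact blanking, numerical
# differentiation, Gaussian fitting of the downstroke, per-beat feature
# extraction, activation-time differences, and conduction-velocity
# regression.

#' Blank artifact-contaminated intervals
#'
#' Marks samples within stimulation and actuator-ramp artifact spans,
#' sets them to background level (zero, the AC-coupled baseline) and
#' records a mask so downstream fits exclude them. Stimulation blanking
#' covers `stim_blank` after every stimulus; actuator blanking covers
#' each ramp event for at least `dea_min_blank` and never less than the
#' ramp time itself.
#'
#' @param rec an `electrogram_record`.
#' @param stim_blank stimulation blanking span (s).
#' @param dea_min_blank minimal actuator blanking span (s), >= 0.010.
#' @return the record with traces blanked and a logical `blank_mask`
#'   element added.
#' @export
blank_intervals <- function(rec, stim_blank = 0.005,
                            dea_min_blank = 0.010) {
  if (dea_min_blank < 0.010)
    stop("blank_intervals: actuator blanking must span at least 10 ms")
  n <- nrow(rec$traces)
  fs <- rec$sample_rate
  mask <- rep(FALSE, n)
  for (ts in rec$stim_times) {
    i <- .grid_span(ts, ts + stim_blank, fs, n)
    if (length(i)) mask[i] <- TRUE
  }
  if (!is.null(rec$dea_events) && nrow(rec$dea_events)) {
    for (j in seq_len(nrow(rec$dea_events))) {
      on <- rec$dea_events$onset_s[j]
      span <- max(dea_min_blank, rec$dea_events$span_s[j])
      i <- .grid_span(on, on + span, fs, n)
      if (length(i)) mask[i] <- TRUE
    }
  }
  rec$traces[mask, ] <- 0
  rec$blank_mask <- mask
  rec
}

#' Five-point central-difference derivative with AC-droop correction
#'
#' Fourth-order five-point stencil `(x[i-2] - 8 x[i-1] + 8 x[i+1] -
#' x[i+2]) / (12 dt)`; its amplitude response is flat to fourth order over
#' the downstroke bandwidth, so the fitted Gaussian amplitude is not
#' attenuated by the differentiation. When the AC-coupling constant of
#' the recording is supplied, the one-pole high-pass is inverted first
#' (baseline droop correction): the high-pass tilts the derivative lobe
#' asymmetrically by a few percent of the amplitude, which would bias the
#' fitted activation time by several microseconds.
#'
#' @param x trace (µV).
#' @param sample_rate sampling rate (Hz).
#' @param tau_c AC-coupling time constant (s) used during acquisition, or
#'   `NULL` for a DC-coupled trace.
#' @return derivative in V/s (`NA` at the two outermost samples each end).
#' @export
trace_derivative <- function(x, sample_rate, tau_c = NULL) {
  if (!is.null(tau_c) && length(x) > 1) {
    # exact inverse of the bilinear one-pole high-pass (the unobservable
    # DC offset is irrelevant to the derivative)
    a <- 2 * tau_c * sample_rate
    k <- a / (a + 1)
    p <- (a - 1) / (a + 1)
    u <- (x - p * c(0, x[-length(x)])) / k
    x <- cumsum(u)
  }
  w <- c(-1, 8, 0, -8, 1) / 12        # stats::filter pairs w[1] with x[i+2]
  d <- as.numeric(stats::filter(x, w, sides = 2))
  d * sample_rate * 1e-6
}

#' Gaussian fit to the electrogram downstroke
#'
#' Least-squares fit of \eqn{G(t) = -A \exp(-(t-\mu)^2 / 2\sigma^2) + b}
#' to the trace derivative within a window centred on the derivative's
#' global minimum. The fitted mean is the local activation time, the
#' amplitude the maximal downstroke velocity; the standard error of the
#' mean is reported as the fit error.
#'
#' @param deriv derivative trace segment (V/s) for one beat; may contain
#'   `NA` (blanked or edge samples are ignored).
#' @param time_s sample times of `deriv` (s).
#' @param sample_rate sampling rate (Hz).
#' @param window half-width of the fitting window (s).
#' @param noise_factor amplitude acceptance threshold in multiples of the
#'   derivative-noise RMS (estimated robustly away from the downstroke).
#' @return list with `t_AT`, `dvdt_max` (negative), `sigma`, `b`,
#'   `fit_rmse`, `fit_se_tAT`, `status` (`"accepted"`/`"rejected"`) and
#'   `reason`.
#' @export
fit_downstroke <- function(deriv, time_s, sample_rate, window = 0.002,
                           noise_factor = 5) {
  reject <- function(reason)
    list(t_AT = NA_real_, dvdt_max = NA_real_, sigma = NA_real_,
         b = NA_real_, fit_rmse = NA_real_, fit_se_tAT = NA_real_,
         status = "rejected", reason = reason)
  ok <- !is.na(deriv)
  if (sum(ok) < 10) return(reject("blanked"))
  i_min <- which.min(deriv)
  t0 <- time_s[i_min]
  # robust derivative-noise estimate away from the downstroke
  far <- ok & abs(time_s - t0) > 0.003
  noise <- if (sum(far) >= 20) mad(deriv[far], na.rm = TRUE) else 0
  a0 <- -deriv[i_min]
  if (a0 <= 0 || (noise > 0 && a0 < noise_factor * noise))
    return(reject("low_amplitude"))
  in_win <- ok & abs(time_s - t0) <= window
  if (sum(in_win) < 8) return(reject("blanked"))
  tt <- time_s[in_win] - t0                 # local coordinates
  yy <- deriv[in_win]
  dts <- 1 / sample_rate
  resid_fn <- function(p) {
    -p[1] * exp(-(tt - p[2])^2 / (2 * p[3]^2)) + p[4] - yy
  }
  jac_fn <- function(p) {
    z <- (tt - p[2]) / p[3]
    e <- exp(-z^2 / 2)
    cbind(-e, -p[1] * e * z / p[3], -p[1] * e * z^2 / p[3], 1)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(a0, 0, 2e-4, 0),
                       fn = resid_fn, jac = jac_fn,
                       lower = c(0, -window, 2 * dts, -Inf),
                       upper = c(Inf, window, 5e-3, Inf),
                       control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% c(1, 2, 3, 4, 6, 7))
    return(reject("no_convergence"))
  cf <- fit$par
  dof <- length(yy) - 4L
  s2 <- fit$deviance / max(dof, 1L)
  se <- tryCatch(sqrt(diag(solve(fit$hessian)) * s2)[2],
                 error = function(e) NA_real_)
  list(t_AT = t0 + cf[2], dvdt_max = -cf[1], sigma = cf[3],
       b = cf[4],
       fit_rmse = sqrt(fit$deviance / length(yy)),
       fit_se_tAT = se, status = "accepted", reason = "")
}

#' Per-beat, per-electrode feature extraction
#'
#' Segments the record into stimulus-to-stimulus windows (pacing is
#' stimulus-driven throughout) and extracts, for every beat and
#' electrode: the Gaussian-fit activation time, downstroke velocity and
#' width, the downstroke duration `t_DS = tds_factor * sigma`, the raw
#' peak-to-peak amplitude outside blanked spans, and fit diagnostics.
#' Rejected beats keep their row with `NA` features and a reason code.
#'
#' @param rec an `electrogram_record`, ideally after [blank_intervals()].
#' @param window Gaussian-fit half window (s).
#' @param tds_factor downstroke duration as a multiple of the fitted
#'   `sigma` (5.77 makes the default template report ~940 µs).
#' @param noise_factor see [fit_downstroke()].
#' @return data frame with columns `beat_index`, `electrode`, `t_AT_s`,
#'   `dvdt_max_Vps`, `sigma_s`, `t_DS_s`, `Vpp_uV`, `fit_se_tAT_s`,
#'   `status`, `reason`.
#' @export
extract_features <- function(rec, window = 0.002, tds_factor = 5.77,
                             noise_factor = 5) {
  stopifnot(length(rec$stim_times) > 0)
  tt <- rec$time_s
  fs <- rec$sample_rate
  mask <- if (!is.null(rec$blank_mask)) rec$blank_mask
          else rep(FALSE, length(tt))
  bounds <- c(rec$stim_times, tt[length(tt)] + 1 / fs)
  rows <- vector("list", (length(bounds) - 1) * length(rec$electrodes))
  r <- 0L
  # blanking leaves a background-level discontinuity at each span edge;
  # exclude derivative samples whose stencil reaches across it
  dmask <- mask
  if (any(mask)) {
    grow <- as.numeric(stats::filter(as.numeric(mask), rep(1, 9),
                                     sides = 2))
    dmask <- !is.na(grow) & grow > 0
  }
  for (ch in rec$electrodes) {
    d <- trace_derivative(rec$traces[, ch], fs, tau_c = rec$tau_c)
    d[dmask] <- NA
    raw <- rec$traces[, ch]
    for (b in seq_len(length(bounds) - 1)) {
      idx <- .grid_span(bounds[b], bounds[b + 1], fs, length(tt))
      f <- fit_downstroke(d[idx], tt[idx], fs, window = window,
                          noise_factor = noise_factor)
      seg <- raw[idx][!mask[idx]]
      vpp <- if (length(seg)) max(seg) - min(seg) else NA_real_
      r <- r + 1L
      rows[[r]] <- data.frame(
        beat_index = b, electrode = ch, t_AT_s = f$t_AT,
        dvdt_max_Vps = f$dvdt_max, sigma_s = f$sigma,
        t_DS_s = tds_factor * f$sigma, Vpp_uV = vpp,
        fit_se_tAT_s = f$fit_se_tAT, status = f$status,
        reason = f$reason)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Activation-time differences between an electrode pair
#'
#' Per-beat difference of the activation times at the downstream and
#' upstream electrode; beats with either fit rejected are dropped and
#' counted. If a phase table is supplied (see [beat_phases()]) it is
#' joined on the beat index.
#'
#' @param features output of [extract_features()].
#' @param pair character vector of two electrode names, upstream first.
#' @param phases optional beat-phase table.
#' @return an object of class `atd_series`: data frame with columns
#'   `beat_index`, `atd_s` and, when `phases` is given, `t_stim_s`,
#'   `phase`, `cycle`; the number of dropped beats is attached as
#'   attribute `n_dropped`.
#' @export
compute_atd <- function(features, pair = c("III", "IV"), phases = NULL) {
  up <- features[features$electrode == pair[1], ]
  dn <- features[features$electrode == pair[2], ]
  m <- merge(up[, c("beat_index", "t_AT_s", "status")],
             dn[, c("beat_index", "t_AT_s", "status")],
             by = "beat_index", suffixes = c("_up", "_dn"))
  ok <- m$status_up == "accepted" & m$status_dn == "accepted"
  out <- data.frame(beat_index = m$beat_index[ok],
                    atd_s = m$t_AT_s_dn[ok] - m$t_AT_s_up[ok])
  if (!is.null(phases))
    out <- merge(out, phases, by = "beat_index", sort = TRUE)
  out <- out[order(out$beat_index), ]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!ok)
  attr(out, "pair") <- pair
  class(out) <- c("atd_series", "data.frame")
  out
}

#' Conduction velocity from one beat's activation times
#'
#' Ordinary least squares of activation time versus electrode position in
#' strained (deformed) coordinates; the velocity is the inverse slope.
#' Reversed propagation yields a negative slope and is reported with
#' `direction = -1`; a non-monotone activation order is flagged as
#' discontinuous conduction.
#'
#' @param features features of one beat (or a larger table with
#'   `beat_index` to select via `beat`).
#' @param positions named vector of electrode positions (mm), e.g.
#'   [strained_positions()].
#' @param beat beat index to select when `features` spans several beats.
#' @return list with `theta_mmps` (positive), `direction` (+1/-1),
#'   `r_squared`, `residuals_s`, `n`, `discontinuous`.
#' @export
fit_velocity <- function(features, positions, beat = NULL) {
  f <- features[features$status == "accepted", ]
  if (!is.null(beat)) f <- f[f$beat_index == beat, ]
  if (nrow(f) < 3)
    stop("fit_velocity: fewer than 3 electrodes with accepted fits")
  x <- unname(positions[as.character(f$electrode)])
  y <- f$t_AT_s
  o <- order(x)
  mono_up <- !is.unsorted(y[o], strictly = TRUE)
  mono_dn <- !is.unsorted(rev(y[o]), strictly = TRUE)
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2])
  list(theta_mmps = 1 / abs(slope),
       direction = if (slope >= 0) 1 else -1,
       r_squared = suppressWarnings(summary(fit)$r.squared),
       residuals_s = unname(stats::residuals(fit)),
       n = nrow(f),
       discontinuous = !(mono_up || mono_dn))
}

#' Write a feature table to CSV (canonical column order)
#'
#' @param features output of [extract_features()].
#' @param path output file path.
#' @export
write_features_csv <- function(features, path) {
  cols <- c("beat_index", "electrode", "t_AT_s", "dvdt_max_Vps",
            "sigma_s", "t_DS_s", "Vpp_uV", "fit_se_tAT_s", "status",
            "reason")
  data.table::fwrite(data.table::as.data.table(features)[, cols,
                                                         with = FALSE],
                     path)
  invisible(path)
}
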