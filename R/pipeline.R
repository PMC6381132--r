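# Orchestration: experiment configuration, the end-to-end runner
# (strain protocol -> activation times -> electrogram -> features ->
# ATD modulation -> slope/partition estimates), inclusion QC, and
# config/report serialisation.

#' Experiment configuration
#'
#' Defines the full measurement campaign: the amplitude x ramp-time grid
#' (run in the experimental order: slowest ramp and smallest amplitude
#' first, amplitudes increasing at constant ramp time), the actuator
#' calibration and creep model, strand geometry and electrical
#' parameters, and the acquisition settings. The defaults are the
#' standard campaign: six amplitudes from 0.2\% to 10\% by five ramp
#' times from 5 to 200 ms, 68 s protocol per run, 2.5 Hz pacing.
#'
#' @param amplitudes target strain amplitudes (dimensionless).
#' @param ramp_times ramp durations (s).
#' @param cal a [calibration_curve()].
#' @param creep a [creep_params()].
#' @param geom a [strand_geometry()].
#' @param theta0 resting conduction velocity of the generator (mm/s).
#' @param f_cyto cytoplasmic resistance fraction of the generator.
#' @param latency stimulus-to-strand-edge latency (s).
#' @param tpl an [apec_template()].
#' @param noise_rms additive noise RMS (µV).
#' @param sample_rate electrogram sampling rate (Hz).
#' @param strain_sample_rate strain-trace sampling rate (Hz).
#' @param artifacts render stimulation/actuator artifacts.
#' @param protocol_args extra arguments passed to [strain_protocol()].
#' @param seed base seed; run k uses `seed + k`.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(amplitudes = c(0.002, 0.01, 0.03, 0.05,
                                             0.08, 0.10),
                              ramp_times = c(0.005, 0.02, 0.05, 0.1, 0.2),
                              cal = calibration_curve(),
                              creep = creep_params(),
                              geom = strand_geometry(),
                              theta0 = 324, f_cyto = 0.29,
                              latency = 0.0055,
                              tpl = apec_template(),
                              noise_rms = 10, sample_rate = 2e4,
                              strain_sample_rate = 1e4,
                              artifacts = TRUE,
                              protocol_args = list(), seed = 1) {
  stopifnot(length(amplitudes) >= 1, length(ramp_times) >= 1,
            all(amplitudes >= 0), all(ramp_times > 0),
            theta0 > 0, f_cyto >= 0, f_cyto <= 1, noise_rms >= 0)
  if (voltage_from_strain(max(amplitudes), cal) > cal$V_max)
    stop("experiment_config: the largest amplitude needs more than the ",
         "amplifier maximum of ", cal$V_max, " kV")
  grid <- expand.grid(amplitude = sort(amplitudes),
                      t_ramp = sort(ramp_times, decreasing = TRUE))
  grid <- grid[order(-grid$t_ramp, grid$amplitude), c("t_ramp", "amplitude")]
  rownames(grid) <- NULL
  structure(list(grid = grid, cal = cal, creep = creep, geom = geom,
                 theta0 = theta0, f_cyto = f_cyto, latency = latency,
                 tpl = tpl, noise_rms = noise_rms,
                 sample_rate = sample_rate,
                 strain_sample_rate = strain_sample_rate,
                 artifacts = artifacts, protocol_args = protocol_args,
                 seed = seed),
            class = "experiment_config")
}

# activation table for all beats of one protocol realisation
.protocol_activation <- function(config, trace_stretch) {
  ts <- trace_stretch$stim_times
  eps_p <- strain_at(trace_stretch, ts)
  eps_m <- -config$cal$k_c * eps_p
  rows <- vector("list", length(ts))
  for (i in seq_along(ts)) {
    a <- kinematic_activation_times(
      config$geom, theta0 = config$theta0, f = config$f_cyto,
      eps_zones = c(zm1 = eps_m[i], zp = eps_p[i], zm2 = eps_m[i]),
      t_stim = ts[i], latency = config$latency)
    a$beat_index <- i
    rows[[i]] <- a
  }
  do.call(rbind, rows)
}

#' Run one protocol of an experiment
#'
#' Realises the strain protocol, generates activation times with the
#' kinematic generator, renders and blanks the six-electrode record,
#' extracts features and computes the stretch-zone (III-IV) and
#' compression-zone (I-III) ATD series with per-cycle modulations.
#'
#' @param config an [experiment_config()].
#' @param amplitude,t_ramp the grid point to run.
#' @param seed seed for the record noise.
#' @param keep which heavy intermediates to keep: any of `"features"`,
#'   `"record"`.
#' @return list with `protocol`, per-zone modulation tables
#'   (`mod_stretch`, `mod_compress`), `atd_stretch`, `baseline_atd_s`,
#'   `theta0_mmps`, `counts`, and optionally `features` / `record`.
#' @export
run_protocol <- function(config, amplitude, t_ramp, seed = NULL,
                         keep = character(0)) {
  p <- do.call(strain_protocol,
               c(list(amplitude = amplitude, t_ramp = t_ramp),
                 config$protocol_args))
  tr_s <- realize_protocol(p, config$cal, config$creep,
                           config$strain_sample_rate, "stretch")
  tr_c <- realize_protocol(p, config$cal, config$creep,
                           config$strain_sample_rate, "compress")
  act <- .protocol_activation(config, tr_s)
  rec <- render_record(
    act, tpl = config$tpl, sample_rate = config$sample_rate,
    duration = p$total_s, stim_times = tr_s$stim_times,
    dea_events = if (config$artifacts) tr_s$dea_events else NULL,
    noise_rms = config$noise_rms,
    stim_artifact_uV = if (config$artifacts) 1000 else 0,
    dea_artifact_uV = if (config$artifacts) 500 else 0,
    seed = seed)
  rec <- blank_intervals(rec)
  feats <- extract_features(rec)
  atd_s <- compute_atd(feats, c("III", "IV"), phases = tr_s$phases)
  atd_c <- compute_atd(feats, c("I", "III"), phases = tr_s$phases)
  mod_s <- atd_modulation(atd_s, tr_s)
  mod_c <- atd_modulation(atd_c, tr_c)
  base <- atd_s[atd_s$phase == "baseline", ]

  # resting velocity from the first handful of baseline beats
  th <- vapply(head(unique(base$beat_index), 5), function(b) {
    v <- tryCatch(fit_velocity(feats, strained_positions(config$geom),
                               beat = b),
                  error = function(e) NULL)
    if (is.null(v)) NA_real_ else v$theta_mmps
  }, numeric(1))

  counts <- c(
    beats_per_electrode = sum(feats$electrode == "III"),
    baseline_atds = nrow(base),
    atds_cycle1 = sum(atd_s$cycle %in% 1, na.rm = TRUE))
  out <- list(protocol = p, mod_stretch = mod_s, mod_compress = mod_c,
              atd_stretch = atd_s,
              baseline_atd_s = mean(base$atd_s),
              theta0_mmps = mean(th, na.rm = TRUE),
              counts = counts,
              n_dropped = attr(atd_s, "n_dropped"))
  if ("features" %in% keep) out$features <- feats
  if ("record" %in% keep) out$record <- rec
  out
}

#' Run the full experiment campaign
#'
#' Executes every grid point of the configuration in the experimental
#' order and aggregates the mechano-electric fit: the per-ramp-time
#' slopes of ATD modulation versus effective strain, their pooled values
#' over positive strains and over all strains (compression included),
#' the inversion to the cytoplasmic resistance fraction, the
#' velocity-strain curve and the strain-rate-independence statistics.
#'
#' @param config an [experiment_config()].
#' @param seed overrides `config$seed`.
#' @param progress print one line per run.
#' @return an object of class `mec_experiment`: list with `report` (see
#'   [write_report()]), `runs` (per-run summaries), `qc`, `provenance`.
#' @export
run_experiment <- function(config, seed = NULL, progress = FALSE) {
  if (is.null(seed)) seed <- config$seed
  grid <- config$grid
  runs <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    if (progress)
      message(sprintf("run %d/%d: t_ramp %g ms, amplitude %.3g", i,
                      nrow(grid), 1e3 * grid$t_ramp[i],
                      grid$amplitude[i]))
    runs[[i]] <- run_protocol(config, grid$amplitude[i], grid$t_ramp[i],
                              seed = seed + i,
                              keep = if (i == 1) "features"
                                     else character(0))
  }

  pool <- do.call(rbind, lapply(seq_along(runs), function(i) {
    m <- runs[[i]]$mod_stretch
    if (is.null(m) || !nrow(m)) return(NULL)
    data.frame(t_ramp = grid$t_ramp[i], amplitude = grid$amplitude[i],
               zone = "stretch", cycle = m$cycle,
               modulation = m$modulation, eps_eff = m$eps_eff,
               atd_ref_s = m$atd_ref_s,
               atd_strained_s = m$atd_strained_s)
  }))
  pool_c <- do.call(rbind, lapply(seq_along(runs), function(i) {
    m <- runs[[i]]$mod_compress
    if (is.null(m) || !nrow(m)) return(NULL)
    data.frame(t_ramp = grid$t_ramp[i], amplitude = grid$amplitude[i],
               zone = "compress", cycle = m$cycle,
               modulation = m$modulation, eps_eff = m$eps_eff)
  }))

  safe_alpha <- function(m, e, subset) {
    tryCatch(fit_alpha(m, e, subset)$alpha, error = function(err) NA_real_)
  }
  ramp_levels <- sort(unique(grid$t_ramp), decreasing = TRUE)
  alpha_by_ramp <- vapply(ramp_levels, function(tr) {
    d <- pool[pool$t_ramp == tr, ]
    safe_alpha(d$modulation, d$eps_eff, "positive")
  }, numeric(1))
  names(alpha_by_ramp) <- sprintf("%g", 1e3 * ramp_levels)

  alpha_pos <- safe_alpha(pool$modulation, pool$eps_eff, "positive")
  all_mod <- c(pool$modulation, pool_c$modulation)
  all_eps <- c(pool$eps_eff, pool_c$eps_eff)
  alpha_all <- safe_alpha(all_mod, all_eps, "all")

  eps_max <- max(pool$eps_eff)
  f_est <- if (is.finite(alpha_pos))
    invert_alpha_to_f(alpha_pos, eps_max) else NA_real_
  rates <- realized_strain_rate(max(grid$amplitude), ramp_levels,
                                config$creep$fast_fraction)
  rate_reg <- if (length(ramp_levels) >= 3 && all(is.finite(alpha_by_ramp)))
    rate_independence_test(alpha_by_ramp, rates)
  else list(slope = NA_real_, ci = c(NA_real_, NA_real_),
            alpha_mean = mean(alpha_by_ramp, na.rm = TRUE),
            alpha_sd = sd(alpha_by_ramp), verdict = NA_character_)
  theta_curve <- velocity_strain_curve(pool$eps_eff,
                                       pool$atd_strained_s,
                                       pool$atd_ref_s,
                                       alpha = alpha_pos)
  theta0 <- mean(vapply(runs, `[[`, numeric(1), "theta0_mmps"),
                 na.rm = TRUE)

  qc <- preparation_qc(runs[[1]]$features, config)
  report <- list(alpha_pos = alpha_pos, alpha_all = alpha_all,
                 alpha_by_ramp = as.list(alpha_by_ramp),
                 alpha_mean = mean(alpha_by_ramp),
                 alpha_sd = sd(alpha_by_ramp),
                 f_cyto_est = f_est, eps_max = eps_max,
                 theta0_mmps = theta0,
                 theta_curve = theta_curve,
                 rate_regression = rate_reg[c("slope", "ci", "verdict")],
                 verdict = rate_reg$verdict)

  cfg_json <- tempfile(fileext = ".json")
  write_config(config, cfg_json)
  provenance <- list(config_md5 = unname(tools::md5sum(cfg_json)),
                     seed = seed,
                     package_version =
                       as.character(utils::packageVersion("mecstrand")),
                     r_version = R.version.string)
  unlink(cfg_json)

  structure(list(report = report, runs = runs, pool = pool,
                 pool_compress = pool_c, qc = qc,
                 provenance = provenance, config = config),
            class = "mec_experiment")
}

#' @export
print.mec_experiment <- function(x, ...) {
  r <- x$report
  cat("<mec_experiment>", nrow(x$config$grid), "runs\n")
  cat(sprintf("  alpha (eps > 0) %.3f | all strains %.3f | by ramp mean %.3f, sd %.4f\n",
              r$alpha_pos, r$alpha_all, r$alpha_mean, r$alpha_sd))
  cat(sprintf("  f_cyto %.3f, theta0 %.1f mm/s, rate verdict: %s\n",
              r$f_cyto_est, r$theta0_mmps, r$verdict))
  invisible(x)
}

#' Preparation inclusion QC
#'
#' The three inclusion criteria: (i) at least five recording electrodes
#' operational (>= 90\% of baseline beats with accepted fits), (ii) the
#' actuator can reach 10\% strain within the amplifier maximum, (iii)
#' uniform, continuous conduction at baseline (median activation times
#' strictly ordered along the strand).
#'
#' @param features a feature table that includes baseline beats.
#' @param config an [experiment_config()].
#' @param n_baseline number of initial beats treated as baseline.
#' @return list with per-criterion logicals and the overall `include`.
#' @export
preparation_qc <- function(features, config, n_baseline = 25) {
  base <- features[features$beat_index <= n_baseline, ]
  acc <- tapply(base$status == "accepted", as.character(base$electrode),
                mean)
  n_op <- sum(acc >= 0.9, na.rm = TRUE)
  c1 <- n_op >= 5
  c2 <- tryCatch(voltage_from_strain(0.10, config$cal) <= config$cal$V_max,
                 error = function(e) FALSE)
  med <- tapply(base$t_AT_s[base$status == "accepted"],
                as.character(base$electrode[base$status == "accepted"]),
                median)
  ordv <- med[order(config$geom$electrodes[names(med)])]
  c3 <- length(ordv) >= 3 &&
    (!is.unsorted(ordv, strictly = TRUE) ||
       !is.unsorted(rev(ordv), strictly = TRUE))
  list(electrodes_operational = c1, n_operational = n_op,
       actuator_reaches_10pct = c2, continuous_conduction = c3,
       include = c1 && c2 && c3)
}

#' Write / read an experiment configuration as JSON
#'
#' Keys mirror the constructor fields, in SI units (strains
#' dimensionless, times in seconds, rates in Hz, voltages in kV).
#'
#' @param config an [experiment_config()].
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  x <- list(amplitudes = sort(unique(config$grid$amplitude)),
            ramp_times = sort(unique(config$grid$t_ramp)),
            cal = unclass(config$cal), creep = unclass(config$creep),
            geom = unclass(config$geom)[c("length", "width",
                                          "cell_length", "zone_half",
                                          "electrode_width")],
            electrodes = as.list(config$geom$electrodes),
            theta0 = config$theta0, f_cyto = config$f_cyto,
            latency = config$latency,
            tpl = unclass(config$tpl)[c("A", "sigma", "pos_fraction",
                                        "pos_delay", "rec_sigma",
                                        "rec_delay")],
            noise_rms = config$noise_rms,
            sample_rate = config$sample_rate,
            strain_sample_rate = config$strain_sample_rate,
            artifacts = config$artifacts,
            protocol_args = config$protocol_args, seed = config$seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (key in c("amplitudes", "ramp_times", "theta0", "f_cyto",
                "noise_rms", "sample_rate"))
    if (is.null(x[[key]]))
      stop("read_config: missing configuration key '", key, "'")
  geom_args <- as.list(x$geom)
  if (!is.null(x$electrodes))
    geom_args$electrodes <- unlist(x$electrodes)
  experiment_config(
    amplitudes = x$amplitudes, ramp_times = x$ramp_times,
    cal = do.call(calibration_curve, as.list(x$cal)),
    creep = do.call(creep_params, as.list(x$creep)),
    geom = do.call(strand_geometry, geom_args),
    theta0 = x$theta0, f_cyto = x$f_cyto,
    latency = if (is.null(x$latency)) 0.0055 else x$latency,
    tpl = do.call(apec_template, as.list(x$tpl)),
    noise_rms = x$noise_rms, sample_rate = x$sample_rate,
    strain_sample_rate = if (is.null(x$strain_sample_rate)) 1e4
                         else x$strain_sample_rate,
    artifacts = isTRUE(x$artifacts),
    protocol_args = if (length(x$protocol_args)) as.list(x$protocol_args)
                    else list(),
    seed = if (is.null(x$seed)) 1 else x$seed)
}

#' Write the mechano-electric report as JSON
#'
#' @param experiment a `mec_experiment` (or its `report` element).
#' @param path JSON file path.
#' @export
write_report <- function(experiment, path) {
  rep <- if (inherits(experiment, "mec_experiment")) experiment$report
         else experiment
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
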