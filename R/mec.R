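# Mechano-electric analysis: ATD modulation per strain cycle, the linear
# slope alpha of modulation vs strain, its inversion to the cytoplasmic
# resistance fraction, velocity-strain curves, strain-rate-independence
# statistics, and strength-duration fitting.

#' Per-cycle fractional ATD modulation
#'
#' For each strain cycle the modulation is the fractional change of the
#' mean strained-phase ATD relative to a reference ATD taken as the last
#' ATD of the immediately preceding relaxed phase (this renews the
#' reference every cycle and thereby accommodates creep). For cycle 1 the
#' reference is the beat between baseline and first ramp when present,
#' otherwise the baseline mean. When the matching strain trace is given,
#' the effective strain of each cycle (mean realized strain over the
#' strained-phase beats minus the realized strain at the reference beat)
#' is reported alongside.
#'
#' @param series an [compute_atd()] result carrying phase labels.
#' @param trace optional `strain_trace` of the zone the electrode pair
#'   straddles.
#' @return data frame with one row per cycle: `cycle`, `modulation`,
#'   `atd_ref_s`, `atd_strained_s`, `n_beats` and, with `trace`,
#'   `eps_eff`. The within-cycle strained-phase ATD time series is
#'   attached as attribute `detail`.
#' @export
atd_modulation <- function(series, trace = NULL) {
  stopifnot(inherits(series, "atd_series"), !is.null(series$phase))
  cycles <- sort(unique(series$cycle[series$phase == "strained"]))
  base <- series[series$phase == "baseline", ]
  rows <- vector("list", length(cycles))
  for (i in seq_along(cycles)) {
    k <- cycles[i]
    str_k <- series[series$phase == "strained" & series$cycle == k, ]
    ref_k <- series[series$phase == "relaxed" & series$cycle == k - 1, ]
    if (nrow(ref_k)) {
      ref <- ref_k[which.max(ref_k$beat_index), ]
      ref_atd <- ref$atd_s
      ref_t <- ref$t_stim_s
    } else if (k == cycles[1] && nrow(base)) {
      ref_atd <- mean(base$atd_s)
      ref_t <- max(base$t_stim_s)
    } else {
      warning("atd_modulation: no reference beat for cycle ", k,
              "; cycle skipped")
      next
    }
    if (!nrow(str_k)) next
    row <- data.frame(cycle = k,
                      modulation = mean(str_k$atd_s) / ref_atd - 1,
                      atd_ref_s = ref_atd,
                      atd_strained_s = mean(str_k$atd_s),
                      n_beats = nrow(str_k))
    if (!is.null(trace))
      row$eps_eff <- mean(strain_at(trace, str_k$t_stim_s)) -
        strain_at(trace, ref_t)
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cycle = integer(0), modulation = numeric(0),
                      atd_ref_s = numeric(0), atd_strained_s = numeric(0),
                      n_beats = integer(0))
  rownames(out) <- NULL
  attr(out, "detail") <- series[series$phase == "strained", ]
  out
}

#' Linear slope of ATD modulation versus strain
#'
#' Least-squares slope through the origin (the scaling law passes through
#' (0, 0) exactly) of fractional modulation against strain; a
#' with-intercept variant is available for diagnostics.
#'
#' @param modulation fractional ATD modulations.
#' @param strain matching strain values (dimensionless).
#' @param subset `"positive"` restricts to strains > 0, `"all"` keeps
#'   compression points too.
#' @param intercept fit an intercept (diagnostic variant).
#' @return list with `alpha`, `n`, `se`, and `intercept` when requested.
#' @export
fit_alpha <- function(modulation, strain, subset = c("positive", "all"),
                      intercept = FALSE) {
  subset <- match.arg(subset)
  keep <- is.finite(modulation) & is.finite(strain)
  if (subset == "positive") keep <- keep & strain > 0
  m <- modulation[keep]; s <- strain[keep]
  if (length(unique(s)) < 3)
    stop("fit_alpha: fewer than 3 strain levels (estimation error)")
  if (intercept) {
    fit <- lm(m ~ s)
    list(alpha = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         se = suppressWarnings(summary(fit)$coefficients[2, 2]),
         n = length(m))
  } else {
    fit <- lm(m ~ s - 1)
    list(alpha = unname(coef(fit)[1]),
         se = suppressWarnings(summary(fit)$coefficients[1, 2]),
         n = length(m))
  }
}

#' Invert the ATD-strain slope to the cytoplasmic resistance fraction
#'
#' Matches the linear law `1 + alpha * eps` to the cable-theory scaling
#' `sqrt(f (1+eps)^2 + 1 - f)` at the maximal strain (secant match),
#' giving the closed form `f = alpha (2 + alpha eps) / (2 + eps)`.
#'
#' @param alpha linear modulation slope, in `[0, 1]`.
#' @param eps_max strain at which the secant is matched (> 0).
#' @return cytoplasmic fraction `f` in `[0, 1]`.
#' @export
invert_alpha_to_f <- function(alpha, eps_max) {
  stopifnot(eps_max > 0, alpha >= 0, alpha <= 1)
  f <- alpha * (2 + alpha * eps_max) / (2 + eps_max)
  if (f < 0 || f > 1)
    stop("invert_alpha_to_f: no solution in [0, 1] (estimation error)")
  f
}

#' Conduction-velocity/strain curve from measured ATDs
#'
#' The true velocity across the strained segment is its deformed length
#' over the traversal time, so
#' \eqn{\theta(\varepsilon)/\theta_0 = (1+\varepsilon)
#' \mathrm{ATD}_0 / \mathrm{ATD}(\varepsilon)}. The closed-form overlay
#' \eqn{(1+\varepsilon)/(1+\alpha\varepsilon)} is evaluated alongside
#' when `alpha` is supplied.
#'
#' @param eps per-cycle strain values.
#' @param atd matching strained-phase ATDs (s).
#' @param atd0 reference (unstrained) ATD (s).
#' @param alpha optional slope for the closed-form overlay.
#' @return data frame with `eps`, `theta_ratio` and optionally
#'   `theta_ratio_law`.
#' @export
velocity_strain_curve <- function(eps, atd, atd0, alpha = NULL) {
  out <- data.frame(eps = eps,
                    theta_ratio = (1 + eps) * atd0 / atd)
  if (!is.null(alpha))
    out$theta_ratio_law <- theoretical_velocity_ratio(eps, alpha, "alpha")
  out
}

#' Strain-rate independence of the modulation slope
#'
#' Regression of the per-ramp-time slope alpha on the maximal strain rate;
#' the verdict is `"independent"` when the confidence interval of the
#' regression slope covers zero.
#'
#' @param alpha_by_ramp named numeric vector of slopes, one per ramp time.
#' @param rates matching maximal strain rates (1/s).
#' @param level confidence level.
#' @return list with `slope`, `ci`, `alpha_mean`, `alpha_sd`, `verdict`.
#' @export
rate_independence_test <- function(alpha_by_ramp, rates, level = 0.95) {
  if (length(alpha_by_ramp) < 3)
    stop("rate_independence_test: need slopes for at least 3 ramp times")
  fit <- lm(alpha_by_ramp ~ rates)
  ci <- suppressWarnings(confint(fit, "rates", level = level))
  slope <- unname(coef(fit)[2])
  covers0 <- is.na(ci[1]) || (ci[1] <= 0 && ci[2] >= 0) || slope == 0
  list(slope = slope, ci = c(ci),
       alpha_mean = mean(alpha_by_ramp),
       alpha_sd = sd(alpha_by_ramp),
       verdict = if (covers0) "independent" else "dependent")
}

#' Lapicque strength-duration fit
#'
#' Least-squares fit of the hyperbola \eqn{I(t) = I_{rh} (1 + t_{ch}/t)}:
#' linear in the parameters after the substitution `u = 1/t`, so the fit
#' is an exact (weighted) linear least squares. Threshold-current scatter
#' is multiplicative, so relative least squares (weights
#' \eqn{1/I^2}) is used by default. By construction the fitted current
#' at the chronaxie equals twice the rheobase.
#'
#' @param duration_ms pulse durations (ms).
#' @param current_uA threshold currents (µA).
#' @param relative use relative (1/I^2-weighted) least squares.
#' @return an object of class `strength_duration_fit`: list with
#'   `rheobase_uA`, `chronaxie_ms`, `residuals_uA`, `fitted_uA`.
#' @export
fit_strength_duration <- function(duration_ms, current_uA,
                                  relative = TRUE) {
  if (length(duration_ms) < 3)
    stop("fit_strength_duration: need at least 3 points")
  w <- if (relative) 1 / current_uA^2 else rep(1, length(current_uA))
  fit <- lm(current_uA ~ I(1 / duration_ms), weights = w)
  irh <- unname(coef(fit)[1]); b <- unname(coef(fit)[2])
  if (irh <= 0 || b <= 0)
    stop("fit_strength_duration: non-hyperbolic data (estimation error)")
  structure(list(rheobase_uA = irh, chronaxie_ms = b / irh,
                 residuals_uA = unname(stats::residuals(fit)),
                 fitted_uA = unname(predict(fit))),
            class = "strength_duration_fit")
}

#' @export
print.strength_duration_fit <- function(x, ...) {
  cat(sprintf(paste0("<strength_duration_fit> rheobase %.3g uA, ",
                     "chronaxie %.3g ms (current at chronaxie %.3g uA)\n"),
              x$rheobase_uA, x$chronaxie_ms, 2 * x$rheobase_uA))
  invisible(x)
}

#' Immobilized-substrate control comparison
#'
#' Compares per-cycle ATD modulations between a run with the substrate
#' free to deform and a run with the substrate immobilized (actuator
#' driven, strain forced to zero): actuator activation without strain
#' must leave ATDs unchanged, while the free run must modulate the
#' stretch and compression zones in opposite directions. Two-sided Welch
#' tests on the per-cycle modulations.
#'
#' @param mod_free,mod_immobilized per-cycle modulation vectors (one
#'   zone).
#' @return list with `p_immobilized` (against zero), `p_between`
#'   (free vs immobilized), means and a verdict for the immobilized arm.
#' @export
dea_control_comparison <- function(mod_free, mod_immobilized) {
  p_imm <- if (sd(mod_immobilized) == 0) {
    if (all(mod_immobilized == 0)) 1 else 0
  } else t.test(mod_immobilized, mu = 0)$p.value
  p_bet <- if (sd(mod_free) == 0 && sd(mod_immobilized) == 0) {
    if (isTRUE(all.equal(mean(mod_free), mean(mod_immobilized)))) 1 else 0
  } else t.test(mod_free, mod_immobilized)$p.value
  list(p_immobilized = p_imm, p_between = p_bet,
       mean_free = mean(mod_free),
       mean_immobilized = mean(mod_immobilized),
       immobilized_effect = p_imm < 0.05)
}
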