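# Discrete-cable model of the patterned cardiomyocyte strand. Axial
# resistance per cell splits into a cytoplasmic part that scales with local
# strain as (1+eps)^2 (constant-volume cytoplasm: length x(1+eps),
# cross-section x 1/(1+eps)) and a strain-independent gap-junctional part.
# Membrane (capacitance) per cell is conserved under strain.

#' Geometry of the strand, strain zones and recording electrodes
#'
#' The strand is a bar of cardiomyocytes spanning one central stretch zone
#' (`Z+`, tensile strain) flanked by two compression zones (`Z1-`, `Z2-`).
#' Material coordinates are in mm relative to the strand centre; electrodes
#' are material points (cells stay attached to them under strain).
#' Electrodes III and IV straddle the stretch-zone boundaries: their
#' centres sit half an electrode width outside the 2.2 mm zone, giving a
#' III-IV centre separation of 2.22 mm.
#'
#' @param length strand length (mm).
#' @param width strand width (mm).
#' @param cell_length resting cell length (mm).
#' @param zone_half half-length of the stretch zone (mm).
#' @param electrode_width recording-electrode width (mm).
#' @param electrodes named vector of electrode centre positions (mm).
#' @return an object of class `strand_geometry`.
#' @export
strand_geometry <- function(length = 9.7, width = 1.6, cell_length = 0.030,
                            zone_half = 1.1, electrode_width = 0.2,
                            electrodes = NULL) {
  if (is.null(electrodes)) {
    # III/IV centres 10 um outside the zone boundaries, so each 200 um
    # electrode straddles its boundary; III-IV separation 2.22 mm
    inner <- zone_half + 0.01
    electrodes <- c(-(inner + 3), -(inner + 1.5), -inner,
                    inner, inner + 1.5, inner + 3)
    names(electrodes) <- .ELECTRODES
  }
  stopifnot(length > 0, width > 0, cell_length > 0,
            zone_half > 0, 2 * zone_half < length,
            !is.unsorted(electrodes),
            all(abs(electrodes) <= length / 2))
  structure(list(length = length, width = width, cell_length = cell_length,
                 zone_half = zone_half, electrode_width = electrode_width,
                 electrodes = electrodes,
                 n_cells = round(length / cell_length)),
            class = "strand_geometry")
}

#' Strain zone of a material position
#'
#' @param x material position (mm, strand centre at 0), vectorised.
#' @param geom a [strand_geometry()].
#' @return character vector among `"zm1"`, `"zp"`, `"zm2"`.
#' @export
zone_of <- function(x, geom) {
  ifelse(x < -geom$zone_half, "zm1",
         ifelse(x <= geom$zone_half, "zp", "zm2"))
}

#' Electrical parameters of the cell chain
#'
#' `f_cyto` is the cytoplasmic share of total axial resistance at rest; the
#' remainder `1 - f_cyto` is gap-junctional and assumed strain-independent.
#' `r_axial` and `c_m` are axial resistance and membrane capacitance per
#' unit resting length (model units: time in ms, space in mm, normalised
#' membrane voltage 0 at rest, ~1 at peak). The membrane model is a
#' two-variable excitable kinetic (cubic fast activation `k v(v-a)(v-1)`
#' plus slow linear recovery) -- only upstroke timing matters for the
#' quantities analysed downstream. The default `r_axial` is calibrated so
#' the resting conduction velocity matches `theta0_target`; rerun
#' [calibrate_strand()] after changing membrane parameters.
#'
#' @param f_cyto cytoplasmic fraction of total axial resistance, in `[0,1]`.
#' @param r_axial axial resistance per resting mm (model units).
#' @param c_m membrane capacitance per resting mm (model units).
#' @param theta0_target resting conduction velocity (mm/s).
#' @param a,k threshold and gain of the cubic activation term (a
#'   dimensionless threshold ~0.15 corresponds to roughly -20 mV on the
#'   physiological scale).
#' @param b,cw rate and gain of the linear recovery variable (1/ms, -).
#' @param v_thresh normalised voltage whose ascending crossing defines the
#'   local activation time.
#' @param stim_amp,stim_dur_ms stimulation drive (dv/dt units) and duration
#'   applied to the first two cells.
#' @return an object of class `cell_chain_params`.
#' @export
cell_chain_params <- function(f_cyto = 0.29, r_axial = 8.575, c_m = 1,
                              theta0_target = 324, a = 0.15, k = 4,
                              b = 0.02, cw = 1.5, v_thresh = 0.5,
                              stim_amp = 50, stim_dur_ms = 1) {
  stopifnot(f_cyto >= 0, f_cyto <= 1, r_axial > 0, c_m > 0,
            theta0_target > 0, a > 0, a < 0.5, k > 0, b > 0, cw > 0,
            v_thresh > a, v_thresh < 1)
  structure(list(f_cyto = f_cyto, r_axial = r_axial, c_m = c_m,
                 theta0_target = theta0_target, a = a, k = k, b = b,
                 cw = cw, v_thresh = v_thresh, stim_amp = stim_amp,
                 stim_dur_ms = stim_dur_ms),
            class = "cell_chain_params")
}

#' Strain scaling of the per-junction axial resistances
#'
#' Cytoplasmic resistance scales as \eqn{(1+\varepsilon)^2} (constant
#' cytoplasm volume); gap-junctional resistance is strain-independent.
#'
#' @param params a [cell_chain_params()].
#' @param eps local strain (> -1), vectorised.
#' @param cell_length resting cell length (mm) defining the per-cell
#'   resistance `R_total0 = r_axial * cell_length`.
#' @return a list with components `R_myo`, `R_gj` and `R_total0`.
#' @export
strain_scaled_resistances <- function(params, eps, cell_length = 0.030) {
  if (any(eps <= -1))
    stop("strain_scaled_resistances: strain must exceed -1 (domain error)")
  R0 <- params$r_axial * cell_length
  list(R_myo = params$f_cyto * R0 * (1 + eps)^2,
       R_gj = rep((1 - params$f_cyto) * R0, length(eps)),
       R_total0 = R0)
}

#' Cable-theory ratio of activation-time differences under strain
#'
#' Across a uniformly strained segment the traversal time scales as
#' \eqn{\sqrt{f (1+\varepsilon)^2 + 1 - f}}: per cell, the conduction time
#' goes as the square root of total axial resistance (membrane per cell is
#' conserved), of which the fraction `f` grows as \eqn{(1+\varepsilon)^2}.
#'
#' @param eps strain (> -1).
#' @param f cytoplasmic fraction of axial resistance, in `[0,1]`.
#' @return dimensionless ratio ATD(eps)/ATD(0), vectorised.
#' @export
theoretical_atd_ratio <- function(eps, f) {
  if (any(eps <= -1)) stop("theoretical_atd_ratio: strain must exceed -1")
  if (any(f < 0 | f > 1)) stop("theoretical_atd_ratio: f must be in [0,1]")
  sqrt(f * (1 + eps)^2 + 1 - f)
}

#' Conduction-velocity ratio under strain
#'
#' Velocity is strained segment length over traversal time, so
#' \eqn{\theta/\theta_0 = (1+\varepsilon)/\sqrt{f(1+\varepsilon)^2+1-f}}
#' in terms of the resistance partition `f`, or, with the linear
#' activation-time-difference slope `alpha`,
#' \eqn{\theta/\theta_0 = (1+\varepsilon)/(1+\alpha\varepsilon)}. The two
#' forms agree when `alpha` is the secant slope of
#' [theoretical_atd_ratio()] over `[0, eps]`.
#'
#' @param eps strain (> -1).
#' @param x the slope `alpha` (mode `"alpha"`) or the fraction `f`
#'   (mode `"f"`).
#' @param mode which parameterisation `x` uses.
#' @return dimensionless ratio theta(eps)/theta0, vectorised over `eps`.
#' @export
theoretical_velocity_ratio <- function(eps, x, mode = c("alpha", "f")) {
  mode <- match.arg(mode)
  if (any(eps <= -1)) stop("theoretical_velocity_ratio: strain must exceed -1")
  if (mode == "alpha") (1 + eps) / (1 + x * eps)
  else (1 + eps) / theoretical_atd_ratio(eps, x)
}

#' Deformed (strained) position of material points
#'
#' Piecewise-linear deformation map with the strand centre as fixed point:
#' each zone stretches uniformly by its own strain factor.
#'
#' @param geom a [strand_geometry()].
#' @param eps_zones named strain vector `c(zm1=, zp=, zm2=)`.
#' @param x material positions (mm); defaults to the electrode centres.
#' @return deformed positions (mm).
#' @export
strained_positions <- function(geom, eps_zones = c(zm1 = 0, zp = 0, zm2 = 0),
                               x = geom$electrodes) {
  h <- geom$zone_half
  ep <- eps_zones[["zp"]]; e1 <- eps_zones[["zm1"]]; e2 <- eps_zones[["zm2"]]
  ifelse(x < -h, -h * (1 + ep) + (x + h) * (1 + e1),
         ifelse(x <= h, x * (1 + ep),
                h * (1 + ep) + (x - h) * (1 + e2)))
}

# overlap length of material interval [a,b] with each zone
.zone_overlaps <- function(geom, a, b) {
  h <- geom$zone_half; L <- geom$length / 2
  ov <- function(lo, hi) max(0, min(b, hi) - max(a, lo))
  c(zm1 = ov(-L, -h), zp = ov(-h, h), zm2 = ov(h, L))
}

#' Closed-form (kinematic) activation times at the electrodes
#'
#' Fast generator bypassing the cable integration: the conduction time
#' along each zone segment is its material length times
#' [theoretical_atd_ratio()] for the zone strain, divided by the resting
#' velocity `theta0`. Propagation starts at the left strand edge after a
#' fixed stimulus-to-edge latency (the latency models conduction through
#' the unrecorded tissue around the stimulation site and cancels in every
#' activation-time difference).
#'
#' @param geom a [strand_geometry()].
#' @param theta0 resting conduction velocity (mm/s).
#' @param f cytoplasmic fraction of axial resistance.
#' @param eps_zones named strain vector `c(zm1=, zp=, zm2=)`.
#' @param t_stim stimulus time (s).
#' @param latency stimulus-to-strand-edge latency (s).
#' @return data frame with columns `electrode`, `x_mm` (material position)
#'   and `t_AT_s`.
#' @export
kinematic_activation_times <- function(geom, theta0 = 324, f = 0.29,
                                       eps_zones = c(zm1 = 0, zp = 0,
                                                     zm2 = 0),
                                       t_stim = 0, latency = 0.0055) {
  ratios <- theoretical_atd_ratio(eps_zones[c("zm1", "zp", "zm2")], f)
  L <- geom$length / 2
  t_at <- vapply(geom$electrodes, function(xe) {
    ov <- .zone_overlaps(geom, -L, xe)
    t_stim + latency + sum(ov * ratios) / theta0
  }, numeric(1))
  data.frame(electrode = names(geom$electrodes), x_mm = geom$electrodes,
             t_AT_s = t_at, row.names = NULL)
}

# per-junction conductances (1/R) for the current strain field
.junction_conductance <- function(geom, params, eps_cells) {
  eps_j <- (eps_cells[-1] + eps_cells[-length(eps_cells)]) / 2
  rr <- strain_scaled_resistances(params, eps_j, geom$cell_length)
  1 / (rr$R_myo + rr$R_gj)
}

#' Simulate impulse propagation along the discrete cable
#'
#' Integrates, with explicit Euler steps, the resistor-chain cable equation
#' \deqn{C_i dv_i/dt = (v_{i-1}-v_i)/R_{i-1,i} + (v_{i+1}-v_i)/R_{i,i+1}
#'   - C_i I_{ion}(v_i, w_i)}
#' with a cubic-activation / linear-recovery membrane. Strain is treated
#' as quasi-static over a conduction sweep (ramps complete well before the
#' next activation): each stimulus is integrated from rest with the strain
#' field in force at that stimulus.
#'
#' @param geom a [strand_geometry()].
#' @param params a [cell_chain_params()].
#' @param eps_zones named strain vector `c(zm1=, zp=, zm2=)`, or a matrix
#'   with one row per stimulus and those three columns.
#' @param stim_times stimulus times (s).
#' @param dt integration step (s), at most 5e-6.
#' @param t_max maximal integrated sweep duration per stimulus (s).
#' @param record_v if `TRUE`, also return the transmembrane field of the
#'   first sweep (cells x time, every `v_stride`-th step).
#' @param v_stride stride for the recorded voltage field.
#' @return list with `activation` (data frame: `beat_index`, `cell`,
#'   `x_mm`, `x_strained_mm`, `t_AT_s`; `NA` activation time where a cell
#'   never fired) and optionally `v_field`, `v_time_s`.
#' @export
simulate_propagation <- function(geom, params, eps_zones = c(zm1 = 0,
                                                             zp = 0,
                                                             zm2 = 0),
                                 stim_times = 0, dt = 2e-6, t_max = 0.06,
                                 record_v = FALSE, v_stride = 50) {
  if (dt > 5e-6) stop("simulate_propagation: dt must be <= 5e-6 s")
  n <- geom$n_cells
  x_cells <- -geom$length / 2 + (seq_len(n) - 0.5) * geom$cell_length
  if (length(stim_times) == 0) {
    return(list(activation = data.frame(beat_index = integer(0),
                                        cell = integer(0),
                                        x_mm = numeric(0),
                                        x_strained_mm = numeric(0),
                                        t_AT_s = numeric(0))))
  }
  if (is.null(dim(eps_zones)))
    eps_zones <- matrix(rep(eps_zones[c("zm1", "zp", "zm2")],
                            each = length(stim_times)),
                        nrow = length(stim_times),
                        dimnames = list(NULL, c("zm1", "zp", "zm2")))
  dt_ms <- dt * 1e3
  n_steps <- ceiling(t_max * 1e3 / dt_ms)
  stim_steps <- ceiling(params$stim_dur_ms / dt_ms)
  out <- vector("list", length(stim_times))
  v_field <- NULL; v_time <- NULL

  for (s_i in seq_along(stim_times)) {
    eps_cells <- unname(eps_zones[s_i, ][zone_of(x_cells, geom)])
    g <- .junction_conductance(geom, params, eps_cells)
    Ci <- params$c_m * geom$cell_length
    v <- numeric(n); w <- numeric(n)
    t_act <- rep(NA_real_, n)
    keep_v <- record_v && s_i == 1L
    if (keep_v) {
      v_field <- matrix(NA_real_, nrow = n,
                        ncol = floor(n_steps / v_stride) + 1)
      v_time <- numeric(ncol(v_field)); col <- 1L
      v_field[, 1] <- v
    }
    for (step in seq_len(n_steps)) {
      gd <- g * diff(v)
      i_ax <- c(gd, 0) - c(0, gd)
      dv <- i_ax / Ci - (params$k * v * (v - params$a) * (v - 1) + w)
      if (step <= stim_steps) dv[1:2] <- dv[1:2] + params$stim_amp
      dw <- params$b * (params$cw * v - w)
      v_new <- v + dt_ms * dv
      w <- w + dt_ms * dw
      crossed <- which(is.na(t_act) & v_new >= params$v_thresh &
                         v < params$v_thresh)
      if (length(crossed)) {
        frac <- (params$v_thresh - v[crossed]) /
          (v_new[crossed] - v[crossed])
        t_act[crossed] <- (step - 1 + frac) * dt
      }
      v <- v_new
      if (max(abs(v)) > 5)
        stop("simulate_propagation: integration unstable at dt = ", dt,
             " s; reduce dt")
      if (keep_v && step %% v_stride == 0) {
        col <- col + 1L
        v_field[, col] <- v
        v_time[col] <- step * dt
      }
      if (!anyNA(t_act) && step * dt > max(t_act, na.rm = TRUE) + 0.002)
        break
    }
    xs <- strained_positions(geom, eps_zones[s_i, ], x_cells)
    out[[s_i]] <- data.frame(beat_index = s_i, cell = seq_len(n),
                             x_mm = x_cells, x_strained_mm = xs,
                             t_AT_s = stim_times[s_i] + t_act)
  }
  res <- list(activation = do.call(rbind, out))
  if (record_v) {
    res$v_field <- v_field
    res$v_time_s <- v_time
  }
  res
}

#' Activation times at the electrodes from a simulated sweep
#'
#' Linear interpolation of the per-cell activation times at the electrode
#' material positions.
#'
#' @param geom a [strand_geometry()].
#' @param activation the `activation` data frame of
#'   [simulate_propagation()] for one beat.
#' @return data frame with columns `electrode`, `x_mm`, `t_AT_s`.
#' @export
electrode_activation <- function(geom, activation) {
  ok <- !is.na(activation$t_AT_s)
  t_at <- approx(activation$x_mm[ok], activation$t_AT_s[ok],
                 xout = geom$electrodes)$y
  data.frame(electrode = names(geom$electrodes), x_mm = geom$electrodes,
             t_AT_s = t_at, row.names = NULL)
}

#' Measure the conduction velocity of a simulated resting sweep
#'
#' Ordinary least squares of activation time on strained position over the
#' interior of the strand (the outer 15\% at each end is excluded to avoid
#' stimulation and sealed-end boundary effects).
#'
#' @param activation one beat of [simulate_propagation()] output.
#' @param trim fraction of cells excluded at each end.
#' @return list with `theta_mmps` and `r_squared`.
#' @export
measure_velocity <- function(activation, trim = 0.15) {
  n <- nrow(activation)
  keep <- seq(ceiling(n * trim), floor(n * (1 - trim)))
  a <- activation[keep, ]
  fit <- lm(t_AT_s ~ x_strained_mm, data = a)
  list(theta_mmps = 1 / unname(coef(fit)[2]),
       r_squared = suppressWarnings(summary(fit)$r.squared))
}

#' Calibrate the axial resistance to a target resting velocity
#'
#' Conduction velocity scales as the inverse square root of axial
#' resistance, so each iteration rescales `r_axial` by the squared ratio
#' of measured to target velocity.
#'
#' @param geom a [strand_geometry()].
#' @param params a [cell_chain_params()].
#' @param dt integration step (s).
#' @param iterations number of rescaling passes.
#' @return `params` with calibrated `r_axial`; the achieved velocity is
#'   attached as attribute `theta_mmps`.
#' @export
calibrate_strand <- function(geom, params, dt = 2e-6, iterations = 2) {
  for (i in seq_len(iterations)) {
    sim <- simulate_propagation(geom, params, stim_times = 0, dt = dt)
    th <- measure_velocity(sim$activation)$theta_mmps
    params$r_axial <- params$r_axial * (th / params$theta0_target)^2
  }
  sim <- simulate_propagation(geom, params, stim_times = 0, dt = dt)
  attr(params, "theta_mmps") <- measure_velocity(sim$activation)$theta_mmps
  params
}
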