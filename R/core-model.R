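#' Model parameters for the two-state condensate swimming model
#'
#' Bundles every rate, momentum and timing parameter of the binary
#' liquid/dissociated mass-transport model. During UV-to-Vis intervals a
#' time-growing fraction `A(t')` of the liquid mass disassembles into the
#' dissociated state, of which a fraction `lambda(t')` disengages from the
#' cycle by free diffusion. During Vis-to-UV intervals a constant fraction `B`
#' of the dissociated mass returns to the liquid, losing a constant fraction
#' `kappa` on the way. Both growing ratios saturate on the characteristic
#' diffusion time scale `tau_star`.
#'
#' The momentum bookkeeping adds four auxiliary constants: `v_eject`, the
#' speed (relative to the liquid domain) at which UV-discharged mass is shed
#' backward, producing a rocket-type recoil; `v_reverse`, the bias speed of
#' the Vis-generated reversing flow directed toward the irradiated region;
#' `gamma`, the viscous drag rate acting on the liquid velocity; and `beta`,
#' the rate at which the bulk momentum of the dissociated domain randomizes
#' away by diffusion. `exchange_enabled = FALSE` switches off the
#' dissociated-to-liquid momentum transfer in Vis-to-UV intervals (the
#' ablation used to show that this transfer is what makes the migration
#' direction frequency dependent).
#'
#' All quantities are dimensionless model units (time, mass, length).
#'
#' @param A_max Maximum disassembly ratio in UV-to-Vis intervals (1/time).
#' @param lambda_max Maximum disengagement ratio in UV-to-Vis intervals,
#'   in `[0, 1]`.
#' @param B Constant disassembly ratio in Vis-to-UV intervals (1/time).
#' @param kappa Constant disengagement ratio in Vis-to-UV intervals, in
#'   `[0, 1]`.
#' @param tau_star Characteristic diffusion time on which `A` and `lambda`
#'   saturate (time units).
#' @param dt Euler time step. Must satisfy `A_max * dt < 1` and `B * dt < 1`.
#' @param v_eject Ejection speed of the UV-discharged flow relative to the
#'   liquid domain (length/time, >= 0).
#' @param v_reverse Speed of the Vis-generated reversing flow toward the
#'   irradiated region (length/time, >= 0).
#' @param gamma Viscous drag rate on the liquid velocity (1/time, >= 0).
#' @param beta Diffusive momentum-decay rate of the dissociated domain
#'   (1/time, >= 0).
#' @param exchange_enabled Logical; apply the Vis-to-UV momentum exchange?
#' @return An object of class `"condensate_params"` (a validated list).
#' @seealso [default_model_params()] for the shipped calibration,
#'   [simulate_condensate()] to run the model.
#' @export
#' @examples
#' p <- model_params(A_max = 0.3, lambda_max = 0.7, B = 0.3, kappa = 0.05,
#'                   tau_star = 8, dt = 0.01)
#' disassembly_ratio(8, p) / p$A_max  # 1 - exp(-1)
model_params <- function(A_max, lambda_max, B, kappa, tau_star, dt,
                         v_eject = 0, v_reverse = 0, gamma = 0, beta = 0,
                         exchange_enabled = TRUE) {
  p <- list(A_max = as.numeric(A_max), lambda_max = as.numeric(lambda_max),
            B = as.numeric(B), kappa = as.numeric(kappa),
            tau_star = as.numeric(tau_star), dt = as.numeric(dt),
            v_eject = as.numeric(v_eject), v_reverse = as.numeric(v_reverse),
            gamma = as.numeric(gamma), beta = as.numeric(beta),
            exchange_enabled = isTRUE(exchange_enabled))
  num <- vapply(p[names(p) != "exchange_enabled"], function(v)
    length(v) == 1L && is.finite(v), logical(1))
  if (!all(num))
    stop("all model parameters must be finite scalars")
  if (p$dt <= 0) stop("dt must be > 0")
  if (p$tau_star <= 0) stop("tau_star must be > 0")
  if (p$A_max < 0 || p$B < 0) stop("A_max and B must be >= 0")
  if (p$A_max * p$dt >= 1 || p$B * p$dt >= 1)
    stop("explicit-Euler stability requires A_max*dt < 1 and B*dt < 1")
  if (p$lambda_max < 0 || p$lambda_max > 1)
    stop("lambda_max must lie in [0, 1]")
  if (p$kappa < 0 || p$kappa > 1) stop("kappa must lie in [0, 1]")
  if (p$v_eject < 0 || p$v_reverse < 0 || p$gamma < 0 || p$beta < 0)
    stop("v_eject, v_reverse, gamma and beta must be >= 0")
  class(p) <- "condensate_params"
  p
}

#' @export
print.condensate_params <- function(x, ...) {
  cat("Two-state condensate model parameters\n")
  cat(sprintf("  mass transfer: A_max = %g, lambda_max = %g, B = %g, kappa = %g\n",
              x$A_max, x$lambda_max, x$B, x$kappa))
  cat(sprintf("  time scales:   tau_star = %g, dt = %g\n", x$tau_star, x$dt))
  cat(sprintf("  momentum:      v_eject = %g, v_reverse = %g, gamma = %g, beta = %g\n",
              x$v_eject, x$v_reverse, x$gamma, x$beta))
  cat(sprintf("  momentum exchange (Vis-to-UV): %s\n",
              if (x$exchange_enabled) "enabled" else "ablated"))
  invisible(x)
}

#' Default (shipped) model parameters
#'
#' Reads the versioned default parameter profile shipped with the package
#' (`inst/extdata/defaults.yaml`). The profile fixes `dt = 0.01` and
#' `tau_star = 800 * dt`, starts runs from a liquid mass of 100 with no
#' dissociated mass, and carries a one-time calibration of the momentum
#' constants chosen so that the default three-frequency sweep displays the
#' three swimming regimes (see the methods vignette): net positive ("push")
#' displacement at the low frequency, a larger net negative ("pull")
#' displacement at the intermediate frequency, and a minimal displacement at
#' the high frequency, with the condensate lifetime nondecreasing in
#' frequency.
#'
#' @param file Optional path to an alternative YAML profile with the same
#'   keys.
#' @return A list with elements `params` (a [model_params()] object),
#'   `m_L0` (initial liquid mass), `frequencies` (default sweep, 1/time) and
#'   `horizon` (default simulated time span).
#' @export
default_model_params <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "defaults.yaml", package = "photoswim",
                        mustWork = TRUE)
  y <- yaml::read_yaml(file)
  par_names <- c("A_max", "lambda_max", "B", "kappa", "tau_star", "dt",
                 "v_eject", "v_reverse", "gamma", "beta", "exchange_enabled")
  params <- do.call(model_params, y[par_names])
  list(params = params,
       m_L0 = as.numeric(y$m_L0),
       frequencies = as.numeric(unlist(y$frequencies)),
       horizon = as.numeric(y$horizon))
}

#' Switching schedule of alternating UV/Vis intervals
#'
#' Photoswitching is treated as instantaneous: each half-cycle (a UV-to-Vis
#' or a Vis-to-UV interval) lasts exactly `interval_length` time units and
#' the lap clock `t'` resets to zero at every switch. One full cycle takes
#' two intervals, so the switching frequency is `f = 1 / (2 * interval_length)`.
#'
#' @param interval_length Length `T` of one interval (model time units, > 0).
#' @param n_intervals Number of intervals to run (>= 1).
#' @param start_phase Phase of the first interval, `"UV_to_Vis"` (default)
#'   or `"Vis_to_UV"`.
#' @return An object of class `"switching_schedule"` with the derived
#'   `switching_frequency`.
#' @export
switching_schedule <- function(interval_length, n_intervals,
                               start_phase = c("UV_to_Vis", "Vis_to_UV")) {
  start_phase <- match.arg(start_phase)
  if (!is.finite(interval_length) || interval_length <= 0)
    stop("interval_length must be > 0")
  n_intervals <- as.integer(n_intervals)
  if (is.na(n_intervals) || n_intervals < 1L)
    stop("n_intervals must be >= 1")
  structure(list(interval_length = as.numeric(interval_length),
                 n_intervals = n_intervals,
                 start_phase = start_phase,
                 switching_frequency = 1 / (2 * interval_length)),
            class = "switching_schedule")
}

#' Schedule for a given switching frequency
#'
#' Convenience constructor: `f = 1/(2T)` so `T = 1/(2f)`; enough intervals
#' are allocated to cover `horizon` time units.
#'
#' @param f Switching frequency (full UV+Vis cycles per unit time, > 0).
#' @param horizon Total time span to cover (> 0).
#' @inheritParams switching_schedule
#' @return A [switching_schedule()] object.
#' @export
schedule_for_frequency <- function(f, horizon,
                                   start_phase = c("UV_to_Vis", "Vis_to_UV")) {
  if (!is.finite(f) || f <= 0) stop("switching frequency must be > 0")
  T_int <- 1 / (2 * f)
  switching_schedule(T_int, ceiling(horizon / T_int - 1e-9),
                     start_phase = match.arg(start_phase))
}

#' Disassembly ratio A(t') in UV-to-Vis intervals
#'
#' The fraction of liquid-state motifs transferred to the dissociated state
#' per unit time, a diffusion-limited quantity that grows non-linearly with
#' the lap time and saturates at `A_max`:
#' `A(t') = A_max * (1 - exp(-(t'/tau_star)^2))`. The quadratic onset encodes
#' the diffusion-limited build-up of the discharged flow; the saturating form
#' keeps the ratio bounded by its maximum.
#'
#' @param t_lap Lap time `t'` since the last switching event (>= 0).
#' @param params A [model_params()] object.
#' @return The rate `A(t')` (1/time).
#' @export
disassembly_ratio <- function(t_lap, params) {
  if (any(t_lap < 0)) stop("t_lap must be >= 0")
  params$A_max * (1 - exp(-(t_lap / params$tau_star)^2))
}

#' Disengagement ratio lambda(t') in UV-to-Vis intervals
#'
#' The fraction of disassembling motifs lost from the cyclic reaction by free
#' diffusion, sharing the diffusion-limited growth of [disassembly_ratio()]:
#' `lambda(t') = lambda_max * (1 - exp(-(t'/tau_star)^2))`.
#'
#' @inheritParams disassembly_ratio
#' @return The dimensionless fraction `lambda(t')` in `[0, lambda_max]`.
#' @export
disengagement_ratio <- function(t_lap, params) {
  if (any(t_lap < 0)) stop("t_lap must be >= 0")
  params$lambda_max * (1 - exp(-(t_lap / params$tau_star)^2))
}

#' Initial state of the simulated condensate
#'
#' @param m_L0 Initial liquid mass (> 0).
#' @param phase Phase of the first interval.
#' @return An object of class `"condensate_state"`: elapsed time `t`, lap
#'   time `t_lap`, `phase`, masses `m_L`, `m_D`, cumulative disengaged mass
#'   `m_lost`, liquid velocity `u`, dissociated bulk velocity `u_D`, and
#'   liquid position `x`.
#' @export
condensate_state <- function(m_L0 = 100, phase = c("UV_to_Vis", "Vis_to_UV")) {
  if (!is.finite(m_L0) || m_L0 <= 0) stop("m_L0 must be > 0")
  structure(list(t = 0, t_lap = 0, phase = match.arg(phase),
                 m_L = as.numeric(m_L0), m_D = 0, m_lost = 0,
                 u = 0, u_D = 0, x = 0),
            class = "condensate_state")
}

# Core Euler update on bare scalars; shared by euler_step() and the
# simulation loop. Returns c(m_L, m_D, m_lost, u, u_D, x).
# Mass transfers are written so that (m_L + m_D + m_lost) is conserved
# exactly: every unit leaving one ledger entry is added to another.
.step_uv <- function(m_L, m_D, m_lost, u, u_D, x, t_lap, p) {
  g <- 1 - exp(-(t_lap / p$tau_star)^2)
  A <- p$A_max * g
  lam <- p$lambda_max * g
  dm <- A * m_L * p$dt
  gain <- (1 - lam) * dm
  # ejected mass is shed backward at v_eject relative to the liquid: the
  # dissociated domain absorbs its momentum, the liquid recoils forward
  pD <- m_D * u_D + gain * (u - p$v_eject)
  m_L <- m_L - dm
  m_D <- m_D + gain
  m_lost <- m_lost + lam * dm
  u_D <- if (m_D > 1e-12) pD / m_D else 0
  u <- u + A * p$v_eject * p$dt - p$gamma * u * p$dt
  u_D <- u_D * (1 - p$beta * p$dt)
  c(m_L, m_D, m_lost, u, u_D, x + u * p$dt)
}

.step_vis <- function(m_L, m_D, m_lost, u, u_D, x, t_lap, p) {
  dm <- p$B * m_D * p$dt
  m_D0 <- m_D
  m_D <- m_D - dm
  m_L <- m_L + (1 - p$kappa) * dm
  m_lost <- m_lost + p$kappa * dm
  if (p$exchange_enabled) {
    # returning mass mixes into the liquid, carrying the reversing-flow bias
    # (-v_reverse toward the irradiated region) plus whatever negative
    # momentum the dissociated domain conserved from the previous UV interval
    u <- u + (1 - p$kappa) * p$B * (m_D0 / max(m_L, 1e-12)) *
      ((u_D - p$v_reverse) - u) * p$dt
  }
  u <- u - p$gamma * u * p$dt
  u_D <- u_D * (1 - p$beta * p$dt)
  c(m_L, m_D, m_lost, u, u_D, x + u * p$dt)
}

#' Advance the model state by one Euler step
#'
#' Applies the forward-Euler update of the mass-transfer equations for the
#' current phase, the momentum-exchange and viscous-dissipation velocity
#' updates, and the position and clock updates. Phase switching itself is
#' handled by [simulate_condensate()]; `euler_step()` never changes `phase`.
#'
#' @param state A [condensate_state()] object.
#' @param params A [model_params()] object.
#' @return The updated `condensate_state`.
#' @export
euler_step <- function(state, params) {
  if (!inherits(state, "condensate_state")) stop("state must be a condensate_state")
  s <- if (state$phase == "UV_to_Vis") {
    .step_uv(state$m_L, state$m_D, state$m_lost, state$u, state$u_D, state$x,
             state$t_lap, params)
  } else {
    .step_vis(state$m_L, state$m_D, state$m_lost, state$u, state$u_D, state$x,
              state$t_lap, params)
  }
  if (s[1] < 0 || s[2] < 0)
    stop("mass went negative: Euler step rejected (reduce dt)")
  state$m_L <- s[1]; state$m_D <- s[2]; state$m_lost <- s[3]
  state$u <- s[4]; state$u_D <- s[5]; state$x <- s[6]
  state$t <- state$t + params$dt
  state$t_lap <- state$t_lap + params$dt
  state
}

#' Simulate the photoswitched condensate model
#'
#' Integrates the two-state mass-transport and 1D momentum equations with
#' the forward Euler method over an alternating UV/Vis switching schedule.
#' The interval length must be an integer multiple of `dt` so that phase
#' changes fall exactly on the Euler grid; the lap clock resets to zero at
#' every switch. The model is fully deterministic.
#'
#' @param params A [model_params()] object.
#' @param schedule A [switching_schedule()] object.
#' @param m_L0 Initial liquid mass (default 100); the dissociated mass and
#'   all velocities start at zero.
#' @param horizon Optional cap (time units) on the simulated span; by default
#'   the whole schedule (`n_intervals * interval_length`) is run.
#' @return An object of class `"condensate_series"`: a data frame with one
#'   row per Euler step (including the initial state) and columns `t`,
#'   `phase`, `m_L`, `m_D`, `m_lost`, `u`, `u_D`, `x`, carrying `params` and
#'   `schedule` as attributes.
#' @export
#' @examples
#' d <- default_model_params()
#' s <- simulate_condensate(d$params, schedule_for_frequency(0.125, 40),
#'                          m_L0 = d$m_L0)
#' summary(s)
simulate_condensate <- function(params, schedule, m_L0 = 100, horizon = NULL) {
  if (!inherits(params, "condensate_params")) stop("params must come from model_params()")
  if (!inherits(schedule, "switching_schedule")) stop("schedule must come from switching_schedule()")
  if (!is.finite(m_L0) || m_L0 <= 0) stop("m_L0 must be > 0")
  dt <- params$dt
  spi <- round(schedule$interval_length / dt)
  if (spi < 1L || abs(spi * dt - schedule$interval_length) > 1e-9 * schedule$interval_length)
    stop("interval_length must be a positive integer multiple of dt")
  n_total <- spi * schedule$n_intervals
  if (!is.null(horizon)) {
    if (!is.finite(horizon) || horizon <= 0) stop("horizon must be > 0")
    n_total <- min(n_total, round(horizon / dt))
  }

  m_L <- m_L0; m_D <- 0; m_lost <- 0; u <- 0; u_D <- 0; x <- 0
  uv <- schedule$start_phase == "UV_to_Vis"
  out <- matrix(NA_real_, nrow = n_total + 1L, ncol = 6L)
  phase_uv <- logical(n_total + 1L)
  out[1L, ] <- c(m_L, m_D, m_lost, u, u_D, x)
  phase_uv[1L] <- uv
  k <- 0L  # step index within current interval
  for (i in seq_len(n_total)) {
    t_lap <- k * dt
    s <- if (uv) .step_uv(m_L, m_D, m_lost, u, u_D, x, t_lap, params)
         else    .step_vis(m_L, m_D, m_lost, u, u_D, x, t_lap, params)
    if (s[1] < 0 || s[2] < 0)
      stop("mass went negative: Euler step rejected (reduce dt)")
    m_L <- s[1]; m_D <- s[2]; m_lost <- s[3]; u <- s[4]; u_D <- s[5]; x <- s[6]
    k <- k + 1L
    if (k == spi && i < n_total) { k <- 0L; uv <- !uv }
    out[i + 1L, ] <- s
    phase_uv[i + 1L] <- uv
  }
  res <- data.frame(t = seq(0, by = dt, length.out = n_total + 1L),
                    phase = ifelse(phase_uv, "UV_to_Vis", "Vis_to_UV"),
                    m_L = out[, 1], m_D = out[, 2], m_lost = out[, 3],
                    u = out[, 4], u_D = out[, 5], x = out[, 6])
  attr(res, "params") <- params
  attr(res, "schedule") <- schedule
  attr(res, "m_L0") <- m_L0
  class(res) <- c("condensate_series", "data.frame")
  res
}

#' @export
print.condensate_series <- function(x, ...) {
  sc <- attr(x, "schedule")
  cat(sprintf("Condensate simulation: %d steps over t = [0, %g], f = %g (T = %g)\n",
              nrow(x) - 1L, x$t[nrow(x)], sc$switching_frequency,
              sc$interval_length))
  cat(sprintf("  final m_L = %.4g, m_D = %.4g, m_lost = %.4g, x = %.4g\n",
              x$m_L[nrow(x)], x$m_D[nrow(x)], x$m_lost[nrow(x)], x$x[nrow(x)]))
  invisible(x)
}

#' @export
summary.condensate_series <- function(object, lifetime_threshold = 0.10, ...) {
  summarize_run(object, lifetime_threshold = lifetime_threshold)
}

#' @export
plot.condensate_series <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$t, x$m_L, type = "l", xlab = "t", ylab = "mass",
                 ylim = range(0, x$m_L, x$m_D), ...)
  graphics::lines(x$t, x$m_D, lty = 2)
  graphics::legend("topright", c("m_L", "m_D"), lty = 1:2, bty = "n")
  graphics::plot(x$t, x$x, type = "l", xlab = "t", ylab = "x")
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}

#' Summarize a simulated run into regime metrics
#'
#' Reduces a simulated time series to the quantities used to compare
#' switching-frequency regimes: the condensate lifetime (first time the
#' liquid mass falls below a threshold fraction of its initial value, `Inf`
#' if it never does), the net displacement at the horizon, the peak speed,
#' and the fraction of steps with positive velocity.
#'
#' @param series A `"condensate_series"` from [simulate_condensate()].
#' @param lifetime_threshold Fraction of the initial liquid mass defining the
#'   lifetime first-passage (default 0.10).
#' @return A one-row data frame of class `"regime_summary"` with columns
#'   `f`, `lifetime`, `net_displacement`, `peak_speed`, `positive_fraction`.
#' @export
summarize_run <- function(series, lifetime_threshold = 0.10) {
  if (!inherits(series, "condensate_series") || nrow(series) == 0L)
    stop("series must be a non-empty condensate_series")
  m_L0 <- attr(series, "m_L0")
  below <- which(series$m_L < lifetime_threshold * m_L0)
  lifetime <- if (length(below)) series$t[below[1L]] else Inf
  out <- data.frame(
    f = attr(series, "schedule")$switching_frequency,
    lifetime = lifetime,
    net_displacement = series$x[nrow(series)],
    peak_speed = max(abs(series$u)),
    positive_fraction = mean(series$u > 0))
  class(out) <- c("regime_summary", "data.frame")
  out
}

#' Frequency sweep of the swimming model
#'
#' Runs the deterministic model at each switching frequency over a common
#' horizon and summarizes each run with [summarize_run()].
#'
#' @param params A [model_params()] object.
#' @param frequencies Numeric vector of at least two distinct positive
#'   switching frequencies.
#' @param horizon Common simulated time span (> 0).
#' @param m_L0 Initial liquid mass.
#' @param lifetime_threshold Passed to [summarize_run()].
#' @return A data frame with one `regime_summary` row per frequency.
#' @export
frequency_sweep <- function(params, frequencies, horizon, m_L0 = 100,
                            lifetime_threshold = 0.10) {
  if (length(frequencies) < 2L || length(unique(frequencies)) < 2L)
    stop("need at least two distinct frequencies")
  if (any(!is.finite(frequencies) | frequencies <= 0))
    stop("frequencies must be positive")
  rows <- lapply(frequencies, function(f) {
    sc <- schedule_for_frequency(f, horizon)
    summarize_run(simulate_condensate(params, sc, m_L0 = m_L0, horizon = horizon),
                  lifetime_threshold = lifetime_threshold)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Momentum-exchange ablation comparison
#'
#' Runs the same frequency sweep with the Vis-to-UV momentum exchange
#' enabled and disabled. Without the exchange the only propulsion source is
#' the UV recoil, so the net displacement stays non-negative at every
#' frequency and the frequency dependence of the migration direction
#' disappears.
#'
#' @inheritParams frequency_sweep
#' @return A data frame of paired summaries with an `exchange` column.
#' @export
ablation_compare <- function(params, frequencies, horizon, m_L0 = 100,
                             lifetime_threshold = 0.10) {
  p_off <- params
  p_off$exchange_enabled <- FALSE
  on <- frequency_sweep(params, frequencies, horizon, m_L0, lifetime_threshold)
  off <- frequency_sweep(p_off, frequencies, horizon, m_L0, lifetime_threshold)
  on$exchange <- TRUE
  off$exchange <- FALSE
  rbind(on, off)
}
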