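#' Stepwise displacement series of a swimming condensate
#'
#' Book-keeps the interface positions of a swimming condensate recorded at
#' successive switching moments: per-switch displacement vectors
#' `dr_i = p_i - p_{i-1}`, their cumulative sum `(dx, dy)`, the net
#' displacement `L(t) = |sum_i dr_i|` after each step, and its maximum
#' `L_max` over the series.
#'
#' @param positions Two-column numeric matrix of interface positions (um) at
#'   the switching moments, in time order (>= 2 rows).
#' @param switch_times Numeric vector of switching times (s), strictly
#'   increasing, same length as `positions` rows.
#' @return An object of class `"displacement_series"`: a data frame with one
#'   row per step (`time`, `dx`, `dy`, `cum_x`, `cum_y`, `L`,
#'   `normalized_time`) and attributes `L_max` and `start_time`.
#' @export
#' @examples
#' d <- displacement_series(rbind(c(0, 0), c(3, 4)), c(0, 10))
#' attr(d, "L_max")  # 5
displacement_series <- function(positions, switch_times) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 2L) stop("positions must have two columns")
  n <- nrow(positions)
  if (n < 2L) stop("need at least 2 interface positions")
  if (length(switch_times) != n) stop("one switch time per position required")
  if (any(diff(switch_times) <= 0)) stop("switch_times must be increasing")
  dr <- diff(positions)
  cum <- apply(dr, 2L, cumsum)
  cum <- matrix(cum, ncol = 2L)
  L <- sqrt(rowSums(cum^2))
  total <- switch_times[n] - switch_times[1L]
  out <- data.frame(time = switch_times[-1L],
                    dx = dr[, 1L], dy = dr[, 2L],
                    cum_x = cum[, 1L], cum_y = cum[, 2L],
                    L = L,
                    normalized_time = (switch_times[-1L] - switch_times[1L]) / total)
  attr(out, "L_max") <- max(L)
  attr(out, "start_time") <- switch_times[1L]
  class(out) <- c("displacement_series", "data.frame")
  out
}

#' @export
print.displacement_series <- function(x, ...) {
  cat(sprintf("Displacement series: %d steps, L_max = %.3g um, final L = %.3g um\n",
              nrow(x), attr(x, "L_max"), x$L[nrow(x)]))
  invisible(x)
}

#' Characteristic cycle time and threshold switching frequency
#'
#' For a condensate of size `a`, the UV-discharged microflow spreads a
#' distance `a` with effective diffusion coefficient `D_S`, and on switching
#' to Vis the reversed flow travels the same distance back with coefficient
#' `D_R`. With the 2D mean-square-displacement relation
#' `<r^2(tau)> ~ 2 d D tau` (d = 2), each traversal takes `a^2/(4 D)`, so the
#' characteristic cycle time is
#' `tau_c = tau_UV + tau_Vis = a^2/(4 D_S) + a^2/(4 D_R)` and the threshold
#' switching frequency separating the two swimming regimes is
#' `f_c = 1/tau_c`.
#'
#' @param a Condensate size (um, > 0).
#' @param D_S Effective diffusion coefficient of the UV-induced spreading
#'   flow (um^2/s, > 0).
#' @param D_R Effective diffusion coefficient of the Vis-reversed flow
#'   (um^2/s, > 0).
#' @return An object of class `"cycle_estimate"` with fields `a`, `D_S`,
#'   `D_R`, `tau_UV`, `tau_Vis`, `tau_c` (s) and `f_c` (1/s).
#' @export
#' @examples
#' cycle_estimate(a = 20, D_S = 20, D_R = 10)  # tau_c = 15 s, f_c ~ 0.07/s
cycle_estimate <- function(a, D_S, D_R) {
  vals <- c(a = a, D_S = D_S, D_R = D_R)
  if (any(!is.finite(vals) | vals <= 0))
    stop("a, D_S and D_R must be positive")
  tau_UV <- a^2 / (4 * D_S)
  tau_Vis <- a^2 / (4 * D_R)
  structure(list(a = a, D_S = D_S, D_R = D_R,
                 tau_UV = tau_UV, tau_Vis = tau_Vis,
                 tau_c = tau_UV + tau_Vis,
                 f_c = 1 / (tau_UV + tau_Vis)),
            class = "cycle_estimate")
}

#' @export
print.cycle_estimate <- function(x, ...) {
  cat(sprintf("Characteristic cycle time for a = %g um (D_S = %g, D_R = %g um^2/s)\n",
              x$a, x$D_S, x$D_R))
  cat(sprintf("  tau_UV = %g s, tau_Vis = %g s, tau_c = %g s\n",
              x$tau_UV, x$tau_Vis, x$tau_c))
  cat(sprintf("  threshold switching frequency f_c = %.2f /s (%g full precision)\n",
              x$f_c, x$f_c))
  invisible(x)
}

#' Swimming regime for a switching frequency
#'
#' Below the threshold frequency the long intervals let viscous dissipation
#' dominate and the condensate push-swims away from the irradiated region;
#' above it the conserved momentum exchange dominates and the condensate
#' pull-swims toward it. The boundary `f = f_c` is assigned to the pull
#' regime and flagged.
#'
#' @param f Switching frequency (1/s, > 0).
#' @param estimate A [cycle_estimate()] object.
#' @return A character scalar, `"dissipation_dominant_push"` or
#'   `"exchange_dominant_pull"`, with logical attribute `"boundary"`.
#' @export
swim_regime <- function(f, estimate) {
  if (!inherits(estimate, "cycle_estimate")) stop("estimate must be a cycle_estimate")
  if (!is.finite(f) || f <= 0) stop("f must be positive")
  regime <- if (f < estimate$f_c) "dissipation_dominant_push"
            else "exchange_dominant_pull"
  structure(regime, boundary = (f == estimate$f_c))
}

#' Maximum net displacement per series
#'
#' Collects `L_max` of each displacement series together with its switching
#' frequency, one row per series (the scatter of maximum net displacement
#' against switching frequency).
#'
#' @param series_set List of `"displacement_series"` objects.
#' @param f Numeric vector of switching frequencies (1/s), one per series.
#' @return A data frame with columns `f`, `L_max`, `n_steps` and `duration`.
#' @export
max_net_displacement <- function(series_set, f) {
  if (length(series_set) < 1L) stop("need at least one series")
  if (length(f) != length(series_set))
    stop("one frequency per series required")
  data.frame(
    f = as.numeric(f),
    L_max = vapply(series_set, function(s) attr(s, "L_max"), numeric(1)),
    n_steps = vapply(series_set, nrow, integer(1)),
    duration = vapply(series_set, function(s)
      s$time[nrow(s)] - attr(s, "start_time"), numeric(1)))
}
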