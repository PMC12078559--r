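#' 2D particle trajectory
#'
#' A single tracked path: strictly increasing sample times and one 2D
#' position per time. The FFT-based MSD requires uniform sampling, which is
#' checked to a relative tolerance of 1e-6 against the nominal frame
#' interval.
#'
#' @param track_id Identifier (coerced to character).
#' @param times Sample times in seconds, strictly increasing.
#' @param positions Two-column numeric matrix of coordinates in micrometres
#'   (one row per time).
#' @param frame_interval Nominal sampling period in seconds; defaults to the
#'   median time difference.
#' @return An object of class `"trajectory"`.
#' @export
trajectory <- function(track_id, times, positions, frame_interval = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 2L) stop("positions must have two columns (x, y)")
  if (length(times) != nrow(positions))
    stop("times and positions must have the same length")
  if (length(times) < 2L) stop("a trajectory needs at least 2 samples")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (is.null(frame_interval)) frame_interval <- stats::median(diff(times))
  structure(list(track_id = as.character(track_id)[1L],
                 times = as.numeric(times),
                 positions = unname(positions),
                 frame_interval = as.numeric(frame_interval)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory '%s': %d samples, frame interval %g s\n",
              x$track_id, length(x$times), x$frame_interval))
  invisible(x)
}

.is_uniform <- function(traj, tol = 1e-6) {
  dt <- diff(traj$times)
  all(abs(dt - traj$frame_interval) <= tol * traj$frame_interval)
}

# sum_t x[t] * x[t+k] for k = 0..N-1, via zero-padded FFT
.autocorr_sum_fft <- function(x) {
  N <- length(x)
  n <- stats::nextn(2L * N, 2L)
  f <- stats::fft(c(x, numeric(n - N)))
  Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(N)] / n
}

#' Time-averaged MSD via FFT (Wiener-Khinchin)
#'
#' Computes the time-averaged mean-square displacement of a uniformly
#' sampled 2D trajectory for every lag `tau_k = k * frame_interval`,
#' `k = 0..N-1`, averaging over all start points. The O(N log N) algorithm
#' splits the MSD into a squared-norm running sum and a positional
#' autocorrelation, the latter evaluated with the FFT via the
#' Wiener-Khinchin theorem. The result is identical (to floating-point
#' accuracy) to the naive O(N^2) definition in [compute_msd_naive()].
#'
#' @param traj A [trajectory()] object with uniform sampling.
#' @return An object of class `"msd_curve"`: list with `lags` (s), `values`
#'   (um^2), `n_pairs` (displacement pairs averaged per lag), dimension
#'   `d = 2` and the `track_id`.
#' @export
compute_msd_fft <- function(traj) {
  if (!inherits(traj, "trajectory")) stop("traj must be a trajectory")
  if (!.is_uniform(traj))
    stop("non-uniform sampling: use compute_msd_naive() instead")
  r <- traj$positions
  N <- nrow(r)
  D <- rowSums(r^2)
  S2 <- .autocorr_sum_fft(r[, 1L]) + .autocorr_sum_fft(r[, 2L])
  Dpad <- c(D, 0)
  Q <- 2 * sum(D)
  S1 <- numeric(N)
  for (m in seq_len(N)) {
    # running sum excludes the m-1 leading and trailing squared norms
    Q <- Q - Dpad[if (m == 1L) N + 1L else m - 1L] - Dpad[N - m + 2L]
    S1[m] <- Q / (N - m + 1L)
  }
  n_pairs <- N - seq_len(N) + 1L
  values <- S1 - 2 * S2 / n_pairs
  values[1L] <- 0  # lag zero, exact
  .msd_curve(traj, values, n_pairs)
}

#' Time-averaged MSD by direct summation
#'
#' The O(N^2) reference definition:
#' `MSD(tau_k) = mean_i |r(t_i + tau_k) - r(t_i)|^2`. Serves as the
#' independent oracle for [compute_msd_fft()] and as the fallback for
#' non-uniformly sampled paths (lags are indexed by sample offset).
#'
#' @inheritParams compute_msd_fft
#' @return An `"msd_curve"` object.
#' @export
compute_msd_naive <- function(traj) {
  if (!inherits(traj, "trajectory")) stop("traj must be a trajectory")
  r <- traj$positions
  N <- nrow(r)
  values <- numeric(N)
  for (k in seq_len(N - 1L)) {
    d <- r[(1L + k):N, , drop = FALSE] - r[seq_len(N - k), , drop = FALSE]
    values[k + 1L] <- mean(rowSums(d^2))
  }
  .msd_curve(traj, values, N - seq_len(N) + 1L)
}

.msd_curve <- function(traj, values, n_pairs) {
  structure(list(lags = (seq_along(values) - 1L) * traj$frame_interval,
                 values = pmax(values, 0),
                 n_pairs = as.integer(n_pairs),
                 d = 2L,
                 track_id = traj$track_id),
            class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("MSD curve for track '%s': %d lags up to %g s\n",
              x$track_id, length(x$lags), max(x$lags)))
  invisible(x)
}

#' @export
plot.msd_curve <- function(x, ...) {
  graphics::plot(x$lags, x$values, type = "l",
                 xlab = expression(tau ~ "(s)"),
                 ylab = expression("MSD (" * mu * m^2 * ")"), ...)
  invisible(x)
}

#' Fit an unsigned diffusion coefficient from an MSD curve
#'
#' Applies the truncation/fit-window protocol: the curve is reduced to the
#' first `truncate_fraction` of its positive lags, an ordinary least-squares
#' line is fitted to the largest `fit_fraction` of the retained lags, and
#' the unsigned diffusion coefficient is read off the slope, `D' = slope/4`
#' (2D: slope = 2*d*D with d = 2). Lags averaged over fewer than two
#' displacement pairs are dropped before fitting. A negative fitted slope is
#' clipped to `D' = 0` with a warning.
#'
#' @param curve An `"msd_curve"` object.
#' @param truncate_fraction Fraction of positive lags retained from the
#'   start of the curve (default 0.20).
#' @param fit_fraction Fraction of the retained lags, taken from the largest
#'   lags, used in the linear fit (default 0.20).
#' @return An object of class `"diffusion_estimate"`: `D_prime` (um^2/s),
#'   `direction` (`"unclassified"` until signed), `D_star` (= `D_prime`
#'   until signed), the `fit_window` (s), `r_squared`, and `track_id`.
#' @seealso [signed_estimates()] to attach the flow direction and sign.
#' @export
fit_diffusion <- function(curve, truncate_fraction = 0.20,
                          fit_fraction = 0.20) {
  if (!inherits(curve, "msd_curve")) stop("curve must be an msd_curve")
  pos <- which(curve$lags > 0 & curve$n_pairs >= 2L)
  n_keep <- floor(truncate_fraction * length(pos))
  if (n_keep < 5L)
    stop("fewer than 5 usable lags after truncation")
  keep <- pos[seq_len(n_keep)]
  n_fit <- max(2L, ceiling(fit_fraction * n_keep))
  win <- keep[(n_keep - n_fit + 1L):n_keep]
  tau <- curve$lags[win]
  msd <- curve$values[win]
  fit <- stats::lm.fit(cbind(1, tau), msd)
  slope <- fit$coefficients[2L]
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((msd - mean(msd))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  if (slope < 0) {
    warning("negative fitted MSD slope; clipping D' to 0")
    slope <- 0
  }
  structure(list(D_prime = unname(slope) / 4,
                 direction = "unclassified",
                 D_star = unname(slope) / 4,
                 fit_window = range(tau),
                 r_squared = unname(r2),
                 track_id = curve$track_id),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("Track '%s': D' = %.4g um^2/s, D* = %.4g (%s), fit tau in [%g, %g] s, R^2 = %.3f\n",
              x$track_id, x$D_prime, x$D_star, x$direction,
              x$fit_window[1L], x$fit_window[2L], x$r_squared))
  invisible(x)
}

#' @export
coef.diffusion_estimate <- function(object, ...) {
  c(D_prime = object$D_prime, D_star = object$D_star)
}

#' Classify ensemble flow direction per trajectory
#'
#' Automates the inward/outward call from the net radial displacement of
#' each track with respect to a reference point (the irradiated region's
#' centre): inward if the final radius is smaller than the initial radius,
#' outward if larger, and unclassified when the net radial change is within
#' the localization noise floor.
#'
#' @param trajectories A list of [trajectory()] objects.
#' @param roi_center Numeric length-2 reference point (um). Defaults to the
#'   centroid of the tracks' initial positions.
#' @param noise_floor Minimum |net radial displacement| (um) for a call
#'   (default 0.5).
#' @return A character vector (`"inward"`, `"outward"`, `"unclassified"`),
#'   one per trajectory, named by track id.
#' @export
classify_direction <- function(trajectories, roi_center = NULL,
                               noise_floor = 0.5) {
  if (length(trajectories) == 0L) stop("empty trajectory set")
  if (is.null(roi_center)) {
    starts <- t(vapply(trajectories, function(tr) tr$positions[1L, ],
                       numeric(2)))
    roi_center <- colMeans(starts)
  }
  out <- vapply(trajectories, function(tr) {
    r0 <- sqrt(sum((tr$positions[1L, ] - roi_center)^2))
    r1 <- sqrt(sum((tr$positions[nrow(tr$positions), ] - roi_center)^2))
    dr <- r1 - r0
    if (abs(dr) < noise_floor) "unclassified"
    else if (dr < 0) "inward" else "outward"
  }, character(1))
  names(out) <- vapply(trajectories, `[[`, character(1), "track_id")
  out
}

#' Attach flow direction and sign to diffusion estimates
#'
#' Applies the signed-coefficient rule: `D* = -D'` for inward-directed flow
#' and `D* = +D'` otherwise.
#'
#' @param estimates List of `"diffusion_estimate"` objects.
#' @param directions Character vector (one per estimate) with values
#'   `"inward"`, `"outward"` or `"unclassified"`.
#' @return The list of estimates with `direction` and `D_star` filled in.
#' @export
signed_estimates <- function(estimates, directions) {
  if (length(estimates) != length(directions))
    stop("estimates and directions must have the same length")
  if (!all(directions %in% c("inward", "outward", "unclassified")))
    stop("directions must be 'inward', 'outward' or 'unclassified'")
  Map(function(e, d) {
    e$direction <- d
    e$D_star <- if (d == "inward") -e$D_prime else e$D_prime
    e
  }, estimates, directions)
}

#' Select the largest-mobility estimates
#'
#' Returns up to `k` estimates with the largest unsigned `D_prime`, in
#' decreasing order; ties are broken by track id so the selection is stable.
#'
#' @param estimates List of `"diffusion_estimate"` objects.
#' @param k Maximum number to return (default 20).
#' @return A list of `min(k, length(estimates))` estimates.
#' @export
select_top <- function(estimates, k = 20L) {
  if (k < 1L) stop("k must be >= 1")
  dp <- vapply(estimates, `[[`, numeric(1), "D_prime")
  id <- vapply(estimates, `[[`, character(1), "track_id")
  ord <- order(-dp, id)
  estimates[ord[seq_len(min(k, length(estimates)))]]
}

#' Tabulate diffusion estimates
#'
#' @param estimates List of `"diffusion_estimate"` objects.
#' @return A data frame with one row per estimate (`track_id`, `D_prime`,
#'   `direction`, `D_star`, `r_squared`).
#' @export
estimates_table <- function(estimates) {
  data.frame(
    track_id = vapply(estimates, `[[`, character(1), "track_id"),
    D_prime = vapply(estimates, `[[`, numeric(1), "D_prime"),
    direction = vapply(estimates, `[[`, character(1), "direction"),
    D_star = vapply(estimates, `[[`, numeric(1), "D_star"),
    r_squared = vapply(estimates, `[[`, numeric(1), "r_squared"))
}
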