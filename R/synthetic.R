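#' Specification for a synthetic data generator
#'
#' Describes a ground-truth generating process emulating the statistical
#' structure the analysis chain assumes: Brownian trajectories with known
#' diffusion coefficient, ballistic drift trajectories, radially
#' spreading/collapsing ensembles around an irradiated region, and stepwise
#' interface-displacement walks for push/pull swimming. All generators are
#' deterministic under a fixed seed, and isotropic Gaussian localization
#' noise (default 0.05 um, the standard tracking-error model) can be added
#' post hoc.
#'
#' @param kind One of `"brownian"`, `"ballistic"`, `"radial_spread"`,
#'   `"radial_collapse"`, `"push_walk"`, `"pull_walk"`.
#' @param n_particles Number of tracks (ignored by the walk generators).
#' @param n_steps Number of recorded steps per track (>= 2).
#' @param frame_interval Sampling period in seconds (default 0.2).
#' @param D_true Diffusion coefficient (um^2/s) for diffusive kinds.
#' @param v_true Drift speed (um/s) for ballistic/radial kinds.
#' @param noise_sigma Localization noise s.d. (um).
#' @param roi_center Length-2 centre of the irradiated region (um).
#' @param step_mean Mean per-switch step length (um) for the walk kinds;
#'   defaults to 3 for `push_walk` and 1 for `pull_walk`.
#' @param angle_sigma Angular jitter (radians) of the walk heading.
#' @param plateau_onset Step index after which walk step lengths decay
#'   (plateau onset); defaults to `n_steps` for `push_walk` (no plateau
#'   before crumbling) and `n_steps %/% 2` for `pull_walk`.
#' @param switch_interval Time between switching moments (s) for the walk
#'   kinds; defaults to 25 for `push_walk` and 5 for `pull_walk`.
#' @param seed Integer RNG seed, recorded in the generated output.
#' @return An object of class `"generator_spec"`.
#' @export
generator_spec <- function(kind = c("brownian", "ballistic", "radial_spread",
                                    "radial_collapse", "push_walk",
                                    "pull_walk"),
                           n_particles = 50L, n_steps = 100L,
                           frame_interval = 0.2, D_true = 0.5, v_true = 1,
                           noise_sigma = 0.05, roi_center = c(0, 0),
                           step_mean = NULL, angle_sigma = 0.3,
                           plateau_onset = NULL, switch_interval = NULL,
                           seed = 1L) {
  kind <- match.arg(kind)
  n_steps <- as.integer(n_steps)
  if (n_steps < 2L) stop("n_steps must be >= 2")
  if (D_true < 0 || noise_sigma < 0) stop("D_true and noise_sigma must be >= 0")
  if (length(roi_center) != 2L) stop("roi_center must have length 2")
  if (is.null(step_mean))
    step_mean <- if (kind == "push_walk") 3 else 1
  if (is.null(plateau_onset))
    plateau_onset <- if (kind == "push_walk") n_steps else n_steps %/% 2L
  if (is.null(switch_interval))
    switch_interval <- if (kind == "push_walk") 25 else 5
  structure(list(kind = kind, n_particles = as.integer(n_particles),
                 n_steps = n_steps, frame_interval = frame_interval,
                 D_true = D_true, v_true = v_true,
                 noise_sigma = noise_sigma, roi_center = as.numeric(roi_center),
                 step_mean = step_mean, angle_sigma = angle_sigma,
                 plateau_onset = as.integer(plateau_onset),
                 switch_interval = switch_interval,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

.traj_set <- function(pos_list, spec) {
  times <- (seq_len(spec$n_steps) - 1L) * spec$frame_interval
  out <- lapply(seq_along(pos_list), function(i)
    trajectory(sprintf("%s_%03d", spec$kind, i), times, pos_list[[i]],
               frame_interval = spec$frame_interval))
  attr(out, "spec") <- spec
  out
}

.add_noise <- function(pos, sigma) {
  if (sigma > 0) pos + matrix(stats::rnorm(length(pos), sd = sigma), ncol = 2L)
  else pos
}

#' Generate Brownian trajectories with known diffusion coefficient
#'
#' Independent Gaussian increments per axis with variance
#' `2 * D_true * frame_interval`, so the ensemble MSD slope recovers
#' `4 * D_true` in 2D.
#'
#' @param spec A [generator_spec()] with `kind = "brownian"`.
#' @return A list of [trajectory()] objects with the spec attached as an
#'   attribute.
#' @export
gen_brownian <- function(spec) {
  if (!inherits(spec, "generator_spec") || spec$kind != "brownian")
    stop("spec must be a generator_spec of kind 'brownian'")
  sd_step <- sqrt(2 * spec$D_true * spec$frame_interval)
  .with_seed(spec$seed, {
    pos <- lapply(seq_len(spec$n_particles), function(i) {
      steps <- matrix(stats::rnorm(2L * (spec$n_steps - 1L), sd = sd_step),
                      ncol = 2L)
      .add_noise(rbind(c(0, 0), apply(steps, 2L, cumsum)), spec$noise_sigma)
    })
    .traj_set(pos, spec)
  })
}

#' Generate ballistic drift trajectories
#'
#' `r(t) = r0 + v_true * t * u_hat + noise`, with a random unit heading per
#' particle. Noise-free drift has the exactly quadratic MSD
#' `(v_true * tau)^2`, the ballistic reference against which upward MSD
#' curvature is judged.
#'
#' @param spec A [generator_spec()] with `kind = "ballistic"`.
#' @inherit gen_brownian return
#' @export
gen_ballistic <- function(spec) {
  if (!inherits(spec, "generator_spec") || spec$kind != "ballistic")
    stop("spec must be a generator_spec of kind 'ballistic'")
  times <- (seq_len(spec$n_steps) - 1L) * spec$frame_interval
  .with_seed(spec$seed, {
    pos <- lapply(seq_len(spec$n_particles), function(i) {
      th <- stats::runif(1L, 0, 2 * pi)
      .add_noise(cbind(spec$v_true * times * cos(th),
                       spec$v_true * times * sin(th)),
                 spec$noise_sigma)
    })
    .traj_set(pos, spec)
  })
}

#' Generate radially spreading or collapsing ensembles
#'
#' Particles start on an annulus around `roi_center` and drift radially away
#' from it (`radial_spread`) or toward it (`radial_collapse`) at `v_true`,
#' on top of Brownian motion with `D_true`; collapsing particles stop at the
#' centre. Each trajectory carries its ground-truth direction label
#' (attribute `"direction_truth"`), making the set a truth standard for
#' [classify_direction()] and the signed-coefficient pipeline.
#'
#' @param spec A [generator_spec()] with `kind` `"radial_spread"` or
#'   `"radial_collapse"`.
#' @inherit gen_brownian return
#' @export
gen_radial <- function(spec) {
  if (!inherits(spec, "generator_spec") ||
      !spec$kind %in% c("radial_spread", "radial_collapse"))
    stop("spec must be a generator_spec of kind 'radial_spread' or 'radial_collapse'")
  inward <- spec$kind == "radial_collapse"
  sd_step <- sqrt(2 * spec$D_true * spec$frame_interval)
  .with_seed(spec$seed, {
    pos <- lapply(seq_len(spec$n_particles), function(i) {
      th <- stats::runif(1L, 0, 2 * pi)
      r0 <- stats::runif(1L, 20, 50)
      p <- matrix(NA_real_, nrow = spec$n_steps, ncol = 2L)
      p[1L, ] <- spec$roi_center + r0 * c(cos(th), sin(th))
      for (k in 2L:spec$n_steps) {
        rel <- p[k - 1L, ] - spec$roi_center
        r <- sqrt(sum(rel^2))
        drift <- if (r > 1e-9) {
          step <- spec$v_true * spec$frame_interval * (if (inward) -1 else 1)
          if (inward) step <- max(step, -r)  # stop at the centre
          rel / r * step
        } else c(0, 0)
        p[k, ] <- p[k - 1L, ] + drift + stats::rnorm(2L, sd = sd_step)
      }
      .add_noise(p, spec$noise_sigma)
    })
    out <- .traj_set(pos, spec)
    attr(out, "direction_truth") <-
      rep(if (inward) "inward" else "outward", spec$n_particles)
    out
  })
}

#' Generate a stepwise interface walk for push/pull swimming
#'
#' Produces interface positions at successive switching moments with a
#' persistent heading: per-step displacements of mean length `step_mean`
#' with angular jitter, decaying exponentially after `plateau_onset` (the
#' displacement plateau seen in long-lived pull-swimming). The push defaults
#' take large steps over few switching intervals; the pull defaults take
#' smaller steps over more intervals before the plateau.
#'
#' @param spec A [generator_spec()] with `kind` `"push_walk"` or
#'   `"pull_walk"`.
#' @return A list with `positions` (matrix, one row per switching moment),
#'   `switch_times` (s) and the `spec`.
#' @export
gen_interface_walk <- function(spec) {
  if (!inherits(spec, "generator_spec") ||
      !spec$kind %in% c("push_walk", "pull_walk"))
    stop("spec must be a generator_spec of kind 'push_walk' or 'pull_walk'")
  n <- spec$n_steps
  .with_seed(spec$seed, {
    heading <- stats::runif(1L, 0, 2 * pi)
    lens <- spec$step_mean *
      exp(-pmax(seq_len(n) - spec$plateau_onset, 0) / 3) *
      stats::rlnorm(n, 0, 0.2)
    angles <- heading + stats::rnorm(n, sd = spec$angle_sigma)
    steps <- cbind(lens * cos(angles), lens * sin(angles))
    positions <- rbind(c(0, 0), apply(steps, 2L, cumsum))
    list(positions = positions,
         switch_times = (0:n) * spec$switch_interval,
         spec = spec)
  })
}
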