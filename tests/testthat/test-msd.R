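test_that("two-point and constant trajectories give the expected MSD", {
  tr <- trajectory("a", c(0, 1), rbind(c(0, 0), c(3, 4)), frame_interval = 1)
  for (f in list(compute_msd_fft, compute_msd_naive)) {
    m <- f(tr)
    expect_equal(m$values, c(0, 25))
    expect_equal(m$lags, c(0, 1))
  }
  still <- trajectory("b", 0:9, matrix(5, nrow = 10, ncol = 2))
  expect_lt(max(abs(compute_msd_fft(still)$values)), 1e-9)
  expect_true(all(compute_msd_naive(still)$values == 0))
})

test_that("pure drift has the exact ballistic MSD (v*tau)^2", {
  tr <- drift_traj(v = 2, n = 100, dt = 1)
  k <- 0:99
  for (f in list(compute_msd_fft, compute_msd_naive)) {
    m <- f(tr)
    expect_equal(m$values, (2 * k)^2, tolerance = 1e-12)
    expect_equal(m$n_pairs, 100L - k)
  }
})

test_that("FFT and naive MSD agree on random walks to 1e-9 relative", {
  set.seed(99)
  lens <- c(2, 3, 5, sample(4:512, 17))
  for (n in lens) {
    tr <- random_walk_traj(n, seed = n)
    expect_lt(max_rel_diff(compute_msd_fft(tr)$values,
                           compute_msd_naive(tr)$values), 1e-9)
  }
})

test_that("MSD requires uniform sampling on the FFT path", {
  tr <- trajectory("nu", c(0, 1, 3), matrix(0, 3, 2), frame_interval = 1)
  expect_error(compute_msd_fft(tr), "naive")
  expect_silent(compute_msd_naive(tr))
})

test_that("fit_diffusion reads D' = slope/4 off exact linear curves", {
  est <- fit_diffusion(exact_curve(slope = 4 * 1.0, n_lags = 100))
  expect_equal(est$D_prime, 1.0, tolerance = 1e-12)
  # static offset does not affect the slope
  est2 <- fit_diffusion(exact_curve(slope = 4 * 0.5, intercept = 7,
                                    n_lags = 100))
  expect_equal(est2$D_prime, 0.5, tolerance = 1e-12)
  expect_equal(est2$r_squared, 1, tolerance = 1e-9)
  # the window sits in the largest lags of the first 20%
  expect_true(all(est$fit_window <= 0.2 * 100 + 1))
  expect_gt(est$fit_window[1], 0.2 * 0.2 * 100 * 0.5)
})

test_that("negative slopes are clipped to zero with a warning", {
  expect_warning(est <- fit_diffusion(exact_curve(slope = -2, intercept = 300,
                                                  n_lags = 100)),
                 "clipping")
  expect_identical(est$D_prime, 0)
})

test_that("fit_diffusion refuses curves with too few usable lags", {
  expect_error(fit_diffusion(exact_curve(slope = 1, n_lags = 10)),
               "fewer than 5")
})

test_that("direction is called from net radial displacement", {
  mk <- function(id, r0, r1) {
    trajectory(id, 0:1, rbind(c(r0, 0), c(r1, 0)), frame_interval = 1)
  }
  trs <- list(mk("in", 50, 10), mk("out", 10, 50), mk("flat", 20, 20.1))
  dir <- classify_direction(trs, roi_center = c(0, 0))
  expect_equal(unname(dir), c("inward", "outward", "unclassified"))
  expect_error(classify_direction(list()), "empty")
})

test_that("sign rule: D* = -D' iff inward, and flipping directions flips signs", {
  ests <- lapply(1:6, function(i) {
    e <- fit_diffusion(exact_curve(slope = 4 * i, n_lags = 100,
                                   id = sprintf("t%02d", i)))
    e
  })
  dirs <- c("inward", "outward", "unclassified", "inward", "outward", "inward")
  signed <- signed_estimates(ests, dirs)
  for (i in seq_along(signed)) {
    expect_equal(abs(signed[[i]]$D_star), signed[[i]]$D_prime)
    expect_equal(signed[[i]]$D_star < 0, dirs[i] == "inward")
  }
  flipped <- signed_estimates(ests, ifelse(dirs == "inward", "outward", "inward"))
  ds1 <- sapply(signed, `[[`, "D_star")
  ds2 <- sapply(flipped, `[[`, "D_star")
  expect_equal(ds2, -ds1)
  expect_error(signed_estimates(ests, dirs[1:2]), "same length")
  expect_error(signed_estimates(ests, rep("sideways", 6)), "inward")
})

test_that("select_top returns min(k, n) largest-D' estimates, ties by id", {
  ests <- lapply(1:35, function(i)
    fit_diffusion(exact_curve(slope = 4 * ((i - 1) %% 7 + 1), n_lags = 100,
                              id = sprintf("t%02d", i))))
  top <- select_top(ests, k = 20)
  expect_length(top, 20)
  dp <- sapply(top, `[[`, "D_prime")
  expect_false(is.unsorted(rev(dp)))
  # ties broken by track id: equal D' blocks come in id order
  ids <- sapply(top, `[[`, "track_id")
  for (v in unique(dp)) expect_false(is.unsorted(ids[dp == v]))
  expect_length(select_top(ests[1:12], k = 20), 12)
})

test_that("drift-dominated ensembles show upward MSD curvature", {
  spec <- generator_spec("ballistic", n_particles = 10, n_steps = 200,
                         v_true = 1, noise_sigma = 0.1, seed = 5)
  trs <- gen_ballistic(spec)
  curv <- sapply(trs, function(tr) {
    m <- compute_msd_fft(tr)
    i <- seq(2, 40)
    early <- coef(lm(m$values[i] ~ m$lags[i]))[2]
    j <- seq(120, 160)
    late <- coef(lm(m$values[j] ~ m$lags[j]))[2]
    late / early
  })
  expect_true(all(curv > 1))
})
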