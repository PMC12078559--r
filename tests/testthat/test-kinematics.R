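test_that("displacement bookkeeping on the 3-4-5 example", {
  d <- displacement_series(rbind(c(0, 0), c(3, 4)), c(0, 10))
  expect_equal(d$dx, 3)
  expect_equal(d$dy, 4)
  expect_equal(d$L, 5)
  expect_equal(attr(d, "L_max"), 5)
  expect_equal(d$normalized_time, 1)
  expect_error(displacement_series(rbind(c(0, 0)), 0), "at least 2")
  expect_error(displacement_series(rbind(c(0, 0), c(1, 1)), c(1, 0)),
               "increasing")
})

test_that("a closed loop returns to L = 0 while path length stays positive", {
  pos <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2), c(0, 0))
  d <- displacement_series(pos, 0:4)
  expect_equal(d$L[nrow(d)], 0)
  expect_gt(sum(sqrt(d$dx^2 + d$dy^2)), 0)
  expect_gt(attr(d, "L_max"), 0)
})

test_that("L_max equals the brute-force maximum over prefix-sum norms", {
  w <- gen_interface_walk(generator_spec("pull_walk", n_steps = 30, seed = 21))
  d <- displacement_series(w$positions, w$switch_times)
  dr <- diff(w$positions)
  brute <- max(sqrt(cumsum(dr[, 1])^2 + cumsum(dr[, 2])^2))
  expect_equal(attr(d, "L_max"), brute)
})

test_that("net displacement is invariant under global rotation", {
  set.seed(31)
  for (rep in 1:5) {
    pos <- matrix(rnorm(20), ncol = 2)
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    d1 <- displacement_series(pos, 1:10)
    d2 <- displacement_series(pos %*% t(R), 1:10)
    expect_equal(d2$L, d1$L, tolerance = 1e-12)
    # triangle inequality
    expect_lte(attr(d1, "L_max"), sum(sqrt(d1$dx^2 + d1$dy^2)) + 1e-12)
  }
})

test_that("cycle time estimate reproduces the worked example", {
  est <- cycle_estimate(a = 20, D_S = 20, D_R = 10)
  expect_equal(est$tau_UV, 5)
  expect_equal(est$tau_Vis, 10)
  expect_equal(est$tau_c, 15)
  expect_equal(round(est$f_c, 2), 0.07)
  expect_equal(est$f_c * est$tau_c, 1)
})

test_that("cycle time scales and degenerates as the closed form dictates", {
  # symmetric coefficients: tau_c = a^2 / (2 D)
  expect_equal(cycle_estimate(20, 20, 20)$tau_c, 10)
  # doubling the size quadruples the cycle time
  expect_equal(cycle_estimate(40, 20, 10)$tau_c, 60)
  expect_error(cycle_estimate(-1, 20, 10), "positive")
  expect_error(cycle_estimate(20, 0, 10), "positive")
})

test_that("regime rule splits push and pull at the threshold frequency", {
  est <- cycle_estimate(20, 20, 10)
  expect_equal(as.character(swim_regime(0.02, est)),
               "dissipation_dominant_push")
  expect_equal(as.character(swim_regime(0.12, est)),
               "exchange_dominant_pull")
  at <- swim_regime(est$f_c, est)
  expect_equal(as.character(at), "exchange_dominant_pull")
  expect_true(attr(at, "boundary"))
  expect_false(attr(swim_regime(0.12, est), "boundary"))
  expect_error(swim_regime(0, est), "positive")
})

test_that("maximum net displacement table has one row per tagged series", {
  d1 <- displacement_series(rbind(c(0, 0), c(3, 4)), c(0, 10))
  tab <- max_net_displacement(list(d1), f = 0.02)
  expect_equal(tab$L_max, 5)
  tab2 <- max_net_displacement(list(d1, d1), f = c(0.02, 0.02))
  expect_equal(tab2$L_max[1], tab2$L_max[2])
  expect_error(max_net_displacement(list(d1), f = c(1, 2)), "per series")
})

test_that("push walks take larger steps than pull walks", {
  push <- gen_interface_walk(generator_spec("push_walk", n_steps = 11, seed = 8))
  pull <- gen_interface_walk(generator_spec("pull_walk", n_steps = 30, seed = 8))
  mean_step <- function(w) mean(sqrt(rowSums(diff(w$positions)^2)))
  expect_gt(mean_step(push), mean_step(pull))
  # pull series last longer before the plateau
  expect_gt(max(pull$switch_times), 0)
  tab <- max_net_displacement(
    list(displacement_series(push$positions, push$switch_times),
         displacement_series(pull$positions, pull$switch_times)),
    f = c(0.02, 0.1))
  expect_equal(nrow(tab), 2)
  expect_gt(tab$duration[2] / tab$n_steps[2], 0)
})
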