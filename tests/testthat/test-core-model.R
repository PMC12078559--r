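test_that("disassembly and disengagement ratios follow the saturating form", {
  p <- basic_params(A_max = 0.4, lambda_max = 0.8, tau_star = 8)
  expect_identical(disassembly_ratio(0, p), 0)
  expect_identical(disengagement_ratio(0, p), 0)
  expect_equal(disassembly_ratio(8, p), 0.4 * (1 - exp(-1)))
  expect_equal(disengagement_ratio(8, p), 0.8 * (1 - exp(-1)))
  expect_equal(disassembly_ratio(1e6, p), 0.4)
  # monotone nondecreasing and bounded
  tl <- seq(0, 50, by = 0.5)
  a <- disassembly_ratio(tl, p)
  expect_true(all(diff(a) >= 0))
  expect_true(all(a <= 0.4 + 1e-15))
  p0 <- basic_params(lambda_max = 0)
  expect_identical(disengagement_ratio(123, p0), 0)
  expect_error(disassembly_ratio(-1, p), "t_lap")
  expect_error(disengagement_ratio(-0.5, p), "t_lap")
})

test_that("parameter validation enforces Euler stability and ranges", {
  expect_error(basic_params(dt = 0), "dt")
  expect_error(basic_params(A_max = 200, dt = 0.01), "stability")
  expect_error(basic_params(B = 150, dt = 0.01), "stability")
  expect_error(basic_params(lambda_max = 1.2), "lambda_max")
  expect_error(basic_params(kappa = -0.1), "kappa")
  expect_error(basic_params(tau_star = 0), "tau_star")
  expect_error(basic_params(gamma = -1), ">= 0")
})

test_that("a single Euler step reproduces the hand-evaluated update", {
  # constant-A limit: tiny tau_star saturates A and lambda immediately
  p <- basic_params(A_max = 0.3, lambda_max = 0, tau_star = 1e-9,
                    v_eject = 0, v_reverse = 0, gamma = 0, beta = 0)
  st <- condensate_state(m_L0 = 100)
  st$t_lap <- 1  # past saturation
  st2 <- euler_step(st, p)
  expect_equal(st2$m_L, 100 * (1 - 0.3 * 0.01))
  expect_equal(st2$m_D, 100 * 0.3 * 0.01)
  expect_equal(st2$m_lost, 0)
  expect_equal(st2$t, st$t + p$dt)
  expect_equal(st2$t_lap, st$t_lap + p$dt)
})

test_that("no dynamics means only the clocks advance", {
  p <- basic_params(A_max = 0, B = 0, v_eject = 0, v_reverse = 0)
  st <- condensate_state(100)
  st2 <- euler_step(st, p)
  expect_equal(st2[c("m_L", "m_D", "m_lost", "u", "u_D", "x")],
               st[c("m_L", "m_D", "m_lost", "u", "u_D", "x")])
  expect_gt(st2$t, st$t)
})

test_that("full disengagement sends no mass to the dissociated state", {
  p <- basic_params(lambda_max = 1, tau_star = 1e-9)
  st <- condensate_state(100)
  st$t_lap <- 5
  st2 <- euler_step(st, p)
  expect_lt(st2$m_L, 100)
  expect_equal(st2$m_D, 0)
  expect_equal(st2$m_lost, 100 - st2$m_L)
})

test_that("constant-A single-interval decay is the Euler geometric series", {
  p <- basic_params(A_max = 0.2, lambda_max = 0, tau_star = 1e-12,
                    v_eject = 0, v_reverse = 0, gamma = 0, beta = 0)
  sc <- switching_schedule(interval_length = 1, n_intervals = 1)
  s <- simulate_condensate(p, sc, m_L0 = 100)
  # A(0) = 0 by construction, so decay starts from the second step
  expect_equal(s$m_L[2], 100)
  expect_equal(s$m_L[3:101], 100 * (1 - 0.2 * 0.01)^(1:99),
               tolerance = 1e-10)
})

test_that("initial snapshot matches the reference starting conditions", {
  d <- default_model_params()
  expect_equal(d$params$dt, 0.01)
  expect_equal(d$params$tau_star, 800 * d$params$dt)
  s <- simulate_condensate(d$params, schedule_for_frequency(0.125, 8),
                           m_L0 = d$m_L0)
  expect_equal(s$m_L[1], 100)
  expect_equal(s$m_D[1], 0)
  expect_equal(s$x[1], 0)
})

test_that("mass ledger and positivity hold across random valid parameters", {
  set.seed(11)
  for (rep in 1:10) {
    p <- model_params(A_max = runif(1, 0, 5), lambda_max = runif(1),
                      B = runif(1, 0, 5), kappa = runif(1),
                      tau_star = runif(1, 0.5, 20), dt = 0.01,
                      v_eject = runif(1, 0, 2), v_reverse = runif(1, 0, 2),
                      gamma = runif(1, 0, 0.5), beta = runif(1, 0, 0.2))
    sc <- switching_schedule(runif(1, 0.5, 10) %/% 0.01 * 0.01, 4)
    s <- simulate_condensate(p, sc, m_L0 = 100)
    expect_true(all(s$m_L >= 0))
    expect_true(all(s$m_D >= 0))
    expect_true(all(s$m_lost >= 0))
    expect_lt(max(abs(s$m_L + s$m_D + s$m_lost - 100)) / 100, 1e-9)
  }
})

test_that("no momentum source means no motion", {
  p <- basic_params(v_eject = 0, v_reverse = 0)
  s <- simulate_condensate(p, switching_schedule(4, 6), m_L0 = 100)
  expect_true(all(s$u == 0))
  expect_true(all(s$x == 0))
})

test_that("the model is deterministic: identical runs are bit-identical", {
  p <- basic_params()
  sc <- switching_schedule(4, 4)
  s1 <- simulate_condensate(p, sc, m_L0 = 100)
  s2 <- simulate_condensate(p, sc, m_L0 = 100)
  expect_identical(s1, s2)
})

test_that("phase alternates exactly at interval boundaries", {
  p <- basic_params()
  s <- simulate_condensate(p, switching_schedule(2, 3), m_L0 = 100)
  switches <- which(s$phase[-1] != s$phase[-nrow(s)])
  expect_equal(s$t[switches + 1], c(2, 4))
})

test_that("summarize_run computes lifetime, displacement and sign metrics", {
  p <- basic_params(A_max = 0, B = 0, v_eject = 0, v_reverse = 0)
  s <- simulate_condensate(p, switching_schedule(1, 2), m_L0 = 100)
  r <- summarize_run(s)
  expect_identical(r$lifetime, Inf)
  expect_equal(r$net_displacement, 0)
  expect_equal(r$positive_fraction, 0)
  expect_equal(r$peak_speed, 0)
})

test_that("lifetime grows with switching frequency under shipped defaults", {
  d <- default_model_params()
  sw <- frequency_sweep(d$params, d$frequencies, d$horizon, m_L0 = d$m_L0)
  expect_false(is.unsorted(sw$lifetime))
  expect_lt(sw$lifetime[1], sw$lifetime[2])
})

test_that("default sweep shows push, pull and minimal-displacement regimes", {
  d <- default_model_params()
  sw <- frequency_sweep(d$params, d$frequencies, d$horizon, m_L0 = d$m_L0)
  expect_gt(sw$net_displacement[1], 0)           # low f: push
  expect_gt(sw$positive_fraction[1], 0.5)        # predominantly positive u
  expect_lt(sw$net_displacement[2], 0)           # intermediate f: pull
  expect_lt(sw$peak_speed[2], sw$peak_speed[1])  # lower peak heights
  expect_gt(abs(sw$net_displacement[2]), abs(sw$net_displacement[1]))
  expect_lt(abs(sw$net_displacement[3]),
            min(abs(sw$net_displacement[1:2])))  # high f: minimal
})

test_that("removing the momentum exchange removes pull-swimming", {
  d <- default_model_params()
  ab <- ablation_compare(d$params, d$frequencies, d$horizon, m_L0 = d$m_L0)
  off <- ab[!ab$exchange, ]
  on <- ab[ab$exchange, ]
  expect_true(all(off$net_displacement >= 0))
  # at low f both configurations push in the same direction
  expect_equal(sign(on$net_displacement[1]), sign(off$net_displacement[1]))
  # with exchange on, the sign inverts between low and intermediate f
  expect_lt(on$net_displacement[2] * on$net_displacement[1], 0)
  # ablated runs with no ejection speed do not move at all
  p0 <- basic_params(v_eject = 0, exchange_enabled = FALSE)
  s <- simulate_condensate(p0, switching_schedule(4, 4), m_L0 = 100)
  expect_equal(summarize_run(s)$net_displacement, 0)
})

test_that("frequency sweep input validation", {
  d <- default_model_params()
  expect_error(frequency_sweep(d$params, 0.1, 10), "two distinct")
  expect_error(frequency_sweep(d$params, c(0.1, -0.2), 10), "positive")
  expect_error(summarize_run(data.frame()), "condensate_series")
})
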