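# small builders shared across tests

basic_params <- function(...) {
  defaults <- list(A_max = 0.3, lambda_max = 0.7, B = 0.3, kappa = 0.05,
                   tau_star = 8, dt = 0.01, v_eject = 0.5, v_reverse = 2,
                   gamma = 0.2, beta = 0.02)
  do.call(model_params, utils::modifyList(defaults, list(...)))
}

drift_traj <- function(v = 2, n = 100, dt = 1, id = "drift") {
  t <- (seq_len(n) - 1) * dt
  trajectory(id, t, cbind(v * t, 0), frame_interval = dt)
}

random_walk_traj <- function(n, seed, id = paste0("rw", seed), dt = 0.2) {
  set.seed(seed)
  steps <- matrix(rnorm(2 * (n - 1)), ncol = 2)
  pos <- rbind(c(0, 0), apply(steps, 2, cumsum))
  trajectory(id, (seq_len(n) - 1) * dt, pos, frame_interval = dt)
}

# exact linear MSD curve msd = slope * tau + intercept over n_lags lags
exact_curve <- function(slope, intercept = 0, n_lags = 100, dt = 1,
                        id = "exact") {
  tau <- (0:n_lags) * dt
  structure(list(lags = tau, values = pmax(slope * tau + intercept, 0),
                 n_pairs = as.integer(n_lags + 1 - (0:n_lags)),
                 d = 2L, track_id = id),
            class = "msd_curve")
}

max_rel_diff <- function(a, b) {
  max(abs(a - b) / pmax(abs(b), 1))
}
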