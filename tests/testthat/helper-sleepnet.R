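# Shared fixtures for the suite: short, coarse configurations so unit tests
# stay fast; the full-resolution study conditions are exercised in
# test-acceptance.R.

quick_params <- function(duration = 600, dt = 0.05, ...) {
  sleep_params(duration = duration, dt = dt, ...)
}

# Random admissible state inside (or on the boundary of) the state box.
random_state <- function(params, boundary = FALSE) {
  u <- runif(7)
  if (boundary) u <- round(u)  # corners
  network_state(u[1] * params$W_max, u[2] * params$N_max, u[3] * params$R_max,
                u[4], u[5], u[6], u[7] * params$H_max, params)
}

# Random hypnogram with geometric-ish episode lengths; used for the
# oracle-equivalence sweeps.
random_hypnogram <- function(n_samples = 120, dt = 1) {
  labels <- character(n_samples)
  state <- sample(c("WAKE", "NREM", "REM"), 1)
  i <- 1
  while (i <= n_samples) {
    len <- min(1 + rgeom(1, 0.2), n_samples - i + 1)
    labels[i:(i + len - 1)] <- state
    i <- i + len
    state <- sample(setdiff(c("WAKE", "NREM", "REM"), state), 1)
  }
  hypnogram(labels, dt)
}

# Self-consistent wake fixed point of the noise-free system, by fixed-point
# iteration on (F, C) with H pinned at H_max.
wake_fixed_point <- function(params, iters = 400) {
  s <- initial_state(params)
  s[["H"]] <- params$H_max
  for (i in seq_len(iters)) {
    I_W <- synaptic_input("W", s[["C_W"]], s[["C_N"]], s[["C_R"]], params$weights)
    I_N <- synaptic_input("N", s[["C_W"]], s[["C_N"]], s[["C_R"]], params$weights)
    I_R <- synaptic_input("R", s[["C_W"]], s[["C_N"]], s[["C_R"]], params$weights)
    s[["F_W"]] <- steady_state_rate("W", I_W, params = params)
    s[["F_N"]] <- steady_state_rate("N", I_N, H = s[["H"]], params = params)
    s[["F_R"]] <- steady_state_rate("R", I_R, params = params)
    s[["C_W"]] <- transmitter_steady_state(s[["F_W"]], params$gamma_C_W)
    s[["C_N"]] <- transmitter_steady_state(s[["F_N"]], params$gamma_C_N)
    s[["C_R"]] <- transmitter_steady_state(s[["F_R"]], params$gamma_C_R)
  }
  s
}

# Empirical convergence order of the RK4 stepper on scalar relaxation
# dF/dt = (F_inf - F)/tau against the closed-form solution.
rk4_relaxation_order <- function(F0 = 0, F_inf = 1, tau = 0.5, t_end = 2) {
  err_at <- function(dt) {
    n <- round(t_end / dt)
    y <- F0
    rhs <- function(f) (F_inf - f) / tau
    for (i in seq_len(n)) y <- rk4_step(y, dt, rhs)
    abs(y - (F_inf + (F0 - F_inf) * exp(-t_end / tau)))
  }
  dts <- t_end / c(20, 40, 80, 160)
  errs <- vapply(dts, err_at, numeric(1))
  fit <- stats::lm(log(errs) ~ log(dts))
  unname(coef(fit)[2])
}
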