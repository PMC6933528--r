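test_that("heaviside follows the z >= 0 convention and rejects non-finite input", {
  expect_identical(heaviside(-1.0), 0)
  expect_identical(heaviside(0.0), 1)
  expect_identical(heaviside(2.5), 1)
  expect_identical(heaviside(c(-0.1, 0, 0.1)), c(0, 1, 1))
  expect_error(heaviside(NaN), "finite")
  expect_error(heaviside(Inf), "finite")
})

test_that("steady-state rates match the closed-form activation function", {
  p <- sleep_params()
  # input at threshold gives half-maximum for any H
  expect_equal(steady_state_rate("W", p$beta_W, params = p), p$W_max / 2)
  expect_equal(steady_state_rate("R", p$beta_R, params = p), p$R_max / 2)
  expect_equal(steady_state_rate("N", p$k_N * 0.37, H = 0.37, params = p),
               p$N_max / 2)
  # explicit evaluation of the printed form
  q <- sleep_params(W_max = 4, alpha_W = 1, beta_W = 0)
  expect_equal(steady_state_rate("W", 1, params = q),
               4 * 0.5 * (1 + tanh(1)))
  expect_equal(steady_state_rate("W", 1, params = q), 3.523188, tolerance = 1e-6)
  # saturation
  expect_equal(steady_state_rate("R", 1e6, params = p), p$R_max)
  expect_error(steady_state_rate("Q", 0, params = p))
})

test_that("steady-state rate is bounded and monotone in the input", {
  p <- sleep_params()
  set.seed(42)
  for (pop in c("W", "N", "R")) {
    I <- sort(runif(50, -20, 20))
    f <- vapply(I, function(x) steady_state_rate(pop, x, H = 0.5, params = p),
                numeric(1))
    expect_true(all(f >= 0))
    expect_true(all(f <= c(W = p$W_max, N = p$N_max, R = p$R_max)[[pop]]))
    expect_true(all(diff(f) >= 0))
  }
})

test_that("synaptic inputs are the printed weighted sums", {
  expect_equal(synaptic_input("W", 0, 0, 0), 0)
  w <- pathway_weights(NWi = -2.0, RWe = 1.0)
  expect_equal(synaptic_input("W", C_W = 0, C_N = 0.5, C_R = 0.25,
                              weights = w, noise_draw = 0.01), -0.74)
  w2 <- pathway_weights(WRi = -4.0, NRi = -1.3)
  expect_equal(synaptic_input("R", C_W = 1, C_N = 1, C_R = 0, weights = w2), -5.3)
  # only the Wake population projects to NREM
  expect_equal(synaptic_input("N", C_W = 0.3, C_N = 1, C_R = 1,
                              weights = pathway_weights()),
               pathway_weights()[["WNi"]] * 0.3)
  expect_error(synaptic_input("W", 0, 1.5, 0), "\\[0, 1\\]")
})

test_that("transmitter release saturates in [0, 1)", {
  expect_equal(transmitter_steady_state(0, 2), 0)
  expect_equal(transmitter_steady_state(3, 3), tanh(1))
  expect_equal(transmitter_steady_state(3, 3), 0.7615942, tolerance = 1e-6)
  expect_lt(transmitter_steady_state(20, 2), 1)
  expect_lte(transmitter_steady_state(1e9, 2), 1)
  f <- transmitter_steady_state(seq(0, 30, by = 0.5), 2)
  expect_true(all(diff(f) > 0))
  expect_error(transmitter_steady_state(-1, 2), ">= 0")
})

test_that("homeostatic drive has the stated fixed points and decay rate", {
  p <- sleep_params()
  expect_equal(homeostatic_rhs(p$H_max, p$theta_W + 1, p), 0)
  expect_equal(homeostatic_rhs(0, p$theta_W - 1, p), 0)
  # at F_W exactly at threshold both indicator terms fire (Heaviside(0) = 1)
  expect_equal(homeostatic_rhs(0.5, p$theta_W, p),
               (p$H_max - 0.5) / p$tau_hw - 0.5 / p$tau_hs)
  q <- sleep_params(tau_hs = 2, H_max = 2)
  expect_equal(homeostatic_rhs(1, q$theta_W - 0.5, q), -0.5)
  # signs away from the fixed points
  expect_gt(homeostatic_rhs(0.5 * p$H_max, p$theta_W + 1, p), 0)
  expect_lt(homeostatic_rhs(0.5 * p$H_max, p$theta_W - 1, p), 0)
})

test_that("network_rhs is the composition of its component operations", {
  p <- quick_params()
  set.seed(7)
  for (i in 1:20) {
    s <- random_state(p)
    xi <- rnorm(3, 0.01, 0.005)
    d <- network_rhs(s, p, xi)
    I_W <- synaptic_input("W", s[["C_W"]], s[["C_N"]], s[["C_R"]], p$weights, xi[1])
    I_N <- synaptic_input("N", s[["C_W"]], s[["C_N"]], s[["C_R"]], p$weights, xi[2])
    I_R <- synaptic_input("R", s[["C_W"]], s[["C_N"]], s[["C_R"]], p$weights, xi[3])
    expect_equal(d[["F_W"]], (steady_state_rate("W", I_W, params = p) - s[["F_W"]]) / p$tau_W)
    expect_equal(d[["F_N"]], (steady_state_rate("N", I_N, H = s[["H"]], params = p) - s[["F_N"]]) / p$tau_N)
    expect_equal(d[["F_R"]], (steady_state_rate("R", I_R, params = p) - s[["F_R"]]) / p$tau_R)
    expect_equal(d[["C_W"]], (transmitter_steady_state(s[["F_W"]], p$gamma_C_W) - s[["C_W"]]) / p$tau_C_W)
    expect_equal(d[["H"]], homeostatic_rhs(s[["H"]], s[["F_W"]], p))
  }
})

test_that("relaxed rest state with zero drive has the stated derivative", {
  p <- sleep_params()
  s <- network_state(0, 0, 0, 0, 0, 0, 0, p)
  d <- network_rhs(s, p)
  expect_equal(d[["F_W"]], steady_state_rate("W", 0, params = p) / p$tau_W)
  expect_equal(d[["F_N"]], steady_state_rate("N", 0, H = 0, params = p) / p$tau_N)
  expect_equal(d[["F_R"]], steady_state_rate("R", 0, params = p) / p$tau_R)
  expect_equal(d[["C_W"]], 0)
  expect_equal(d[["H"]], 0)
})

test_that("self-consistent wake state is a fixed point of the noise-free system", {
  # under doubled Wake->NREM inhibition wakefulness is stable even at
  # maximal sleep pressure, so a true wake fixed point exists
  p <- sleep_params(weights = pathway_weights(WNi = -8))
  s <- wake_fixed_point(p)
  expect_gte(s[["F_W"]], p$theta_W)  # the iteration must land in wake
  d <- network_rhs(s, p)
  expect_equal(unname(d), rep(0, 7), tolerance = 1e-10)
})

test_that("the derivative field points inward on the state-box boundary", {
  p <- sleep_params()
  set.seed(11)
  hi <- c(p$W_max, p$N_max, p$R_max, 1, 1, 1, p$H_max)
  for (i in 1:200) {
    s <- random_state(p)
    comp <- sample(7, 1)
    at_top <- runif(1) > 0.5
    s[comp] <- if (at_top) hi[comp] else 0
    d <- network_rhs(s, p)
    if (at_top) expect_lte(d[[comp]], 0) else expect_gte(d[[comp]], 0)
  }
})

test_that("the noise-free right-hand side is deterministic", {
  p <- sleep_params()
  s <- random_state(p)
  expect_identical(network_rhs(s, p), network_rhs(s, p))
})

test_that("state and parameter constructors enforce their invariants", {
  p <- sleep_params()
  expect_error(network_state(-1, 0, 0, 0, 0, 0, 0, p), "outside")
  expect_error(network_state(0, 0, 0, 1.2, 0, 0, 0, p), "outside")
  expect_error(network_state(0, 0, 0, 0, 0, 0, p$H_max + 1, p), "outside")
  expect_error(sleep_params(tau_W = -1), "tau_W")
  expect_error(sleep_params(noise_sd = -0.1), "noise_sd")
  expect_error(pathway_weights(WNi = 1), "inhibitory")
  expect_error(pathway_weights(RRe = -0.5), "excitatory")
})
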