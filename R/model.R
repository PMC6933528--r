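#' Heaviside step function
#'
#' Returns 0 for negative arguments and 1 otherwise (the convention used by
#' the homeostatic drive: the value at zero is 1).
#'
#' @param z numeric vector; must be finite.
#' @return 0/1 numeric vector of the same length.
#' @examples
#' heaviside(c(-1, 0, 2.5))
#' @export
heaviside <- function(z) {
  if (!is.numeric(z) || any(!is.finite(z)))
    stop("heaviside() requires finite numeric input", call. = FALSE)
  as.numeric(z >= 0)
}

#' Network state vector
#'
#' Assembles and validates the 7-dimensional dynamical state: three
#' population firing rates (Hz), three transmitter concentrations (a.u., in
#' [0, 1]; one per source population, shared by all of its targets), and the
#' homeostatic sleep drive H.
#'
#' @param F_W,F_N,F_R firing rates (Hz), each within `[0, X_max]`.
#' @param C_W,C_N,C_R transmitter concentrations in `[0, 1]`.
#' @param H homeostatic drive in `[0, H_max]`.
#' @param params a [sleep_params()] object supplying the box bounds.
#' @return Named numeric vector `c(F_W, F_N, F_R, C_W, C_N, C_R, H)`.
#' @export
network_state <- function(F_W, F_N, F_R, C_W, C_N, C_R, H,
                          params = sleep_params()) {
  s <- c(F_W = F_W, F_N = F_N, F_R = F_R,
         C_W = C_W, C_N = C_N, C_R = C_R, H = H)
  if (any(!is.finite(s))) stop("state components must be finite", call. = FALSE)
  hi <- c(params$W_max, params$N_max, params$R_max, 1, 1, 1, params$H_max)
  for (i in seq_along(s)) {
    if (s[[i]] < 0 || s[[i]] > hi[[i]])
      stop("state component ", names(s)[i], " = ", s[[i]],
           " outside [0, ", hi[[i]], "]", call. = FALSE)
  }
  s
}

#' Default initial state: wakefulness
#'
#' The network starts awake: the Wake population at its maximum rate, the
#' sleep-promoting populations silent, transmitter concentrations at the
#' steady state implied by those rates, and no accumulated sleep pressure.
#'
#' @param params a [sleep_params()] object.
#' @return A [network_state()] vector.
#' @export
initial_state <- function(params = sleep_params()) {
  network_state(F_W = params$W_max, F_N = 0, F_R = 0,
                C_W = transmitter_steady_state(params$W_max, params$gamma_C_W),
                C_N = 0, C_R = 0, H = 0, params = params)
}

#' Steady-state firing rate of a population
#'
#' The saturating activation `X_max * 0.5 * (1 + tanh((I - beta) / alpha))`.
#' For the NREM population the threshold is not a constant but `k_N * H`,
#' which couples NREM excitability to the homeostatic sleep drive.
#'
#' @param population one of `"W"`, `"N"`, `"R"`.
#' @param input_I summed synaptic input (a.u.).
#' @param H homeostatic drive; used only when `population == "N"`.
#' @param params a [sleep_params()] object.
#' @return Firing rate in `[0, X_max]` (Hz).
#' @examples
#' p <- sleep_params()
#' steady_state_rate("W", input_I = p$beta_W, params = p)  # half-maximum
#' @export
steady_state_rate <- function(population, input_I, H = 0,
                              params = sleep_params()) {
  switch(match.arg(population, c("W", "N", "R")),
    W = params$W_max * 0.5 * (1 + tanh((input_I - params$beta_W) / params$alpha_W)),
    N = params$N_max * 0.5 * (1 + tanh((input_I - params$k_N * H) / params$alpha_N)),
    R = params$R_max * 0.5 * (1 + tanh((input_I - params$beta_R) / params$alpha_R)))
}

#' Synaptic input to a population
#'
#' The weighted sum of pre-synaptic transmitter concentrations plus the
#' additive noise term:
#' `I_W = g_NWi C_N + g_RWe C_R + xi`,
#' `I_N = g_WNi C_W + xi`,
#' `I_R = g_WRi C_W + g_NRi C_N + g_RRe C_R + xi`.
#'
#' @param population one of `"W"`, `"N"`, `"R"`.
#' @param C_W,C_N,C_R transmitter concentrations in `[0, 1]`.
#' @param weights a [pathway_weights()] vector.
#' @param noise_draw the noise realisation xi for this population (Hz).
#' @return Synaptic input (a.u.).
#' @export
synaptic_input <- function(population, C_W, C_N, C_R,
                           weights = pathway_weights(), noise_draw = 0) {
  conc <- c(C_W, C_N, C_R)
  if (any(conc < 0 | conc > 1))
    stop("concentrations must lie in [0, 1]", call. = FALSE)
  w <- weights
  switch(match.arg(population, c("W", "N", "R")),
    W = w[["NWi"]] * C_N + w[["RWe"]] * C_R + noise_draw,
    N = w[["WNi"]] * C_W + noise_draw,
    R = w[["WRi"]] * C_W + w[["NRi"]] * C_N + w[["RRe"]] * C_R + noise_draw)
}

#' Steady-state transmitter concentration
#'
#' Saturating release function `tanh(F_Y / gamma)`: zero at rest, approaching
#' (never exceeding) 1 at high firing rates.
#'
#' @param F_Y source-population firing rate (Hz), non-negative.
#' @param gamma release half-saturation scale (Hz), positive.
#' @return Concentration in `[0, 1)`.
#' @export
transmitter_steady_state <- function(F_Y, gamma) {
  if (any(F_Y < 0)) stop("firing rate must be >= 0", call. = FALSE)
  if (any(gamma <= 0)) stop("gamma must be > 0", call. = FALSE)
  tanh(F_Y / gamma)
}

#' Time derivative of the homeostatic sleep drive
#'
#' `dH/dt = (H_max - H)/tau_hw * Heav(F_W - theta_W) - H/tau_hs *
#' Heav(theta_W - F_W)`: the drive relaxes upward toward `H_max` while the
#' Wake population fires above `theta_W`, and decays toward zero otherwise.
#'
#' @param H current drive, in `[0, H_max]`.
#' @param F_W Wake-population firing rate (Hz).
#' @param params a [sleep_params()] object.
#' @return dH/dt (a.u. per second).
#' @export
homeostatic_rhs <- function(H, F_W, params = sleep_params()) {
  (params$H_max - H) / params$tau_hw * heaviside(F_W - params$theta_W) -
    H / params$tau_hs * heaviside(params$theta_W - F_W)
}

#' Right-hand side of the full network ODE system
#'
#' Assembles the 7-component derivative from the component operations:
#' firing-rate relaxation toward [steady_state_rate()] of the
#' [synaptic_input()], transmitter relaxation toward
#' [transmitter_steady_state()], and [homeostatic_rhs()]. Noise enters only
#' through the synaptic inputs.
#'
#' This is the reference implementation used for testing and small problems;
#' the simulator integrates an equivalent compiled version.
#'
#' @param state a [network_state()] vector.
#' @param params a [sleep_params()] object.
#' @param noise_draws length-3 numeric, the noise realisations for the W, N
#'   and R inputs (Hz).
#' @return Named derivative vector with the same layout as the state.
#' @export
network_rhs <- function(state, params = sleep_params(),
                        noise_draws = c(0, 0, 0)) {
  stopifnot(length(state) == 7L, length(noise_draws) == 3L)
  F_W <- state[[1]]; F_N <- state[[2]]; F_R <- state[[3]]
  C_W <- state[[4]]; C_N <- state[[5]]; C_R <- state[[6]]
  H <- state[[7]]
  I_W <- synaptic_input("W", C_W, C_N, C_R, params$weights, noise_draws[[1]])
  I_N <- synaptic_input("N", C_W, C_N, C_R, params$weights, noise_draws[[2]])
  I_R <- synaptic_input("R", C_W, C_N, C_R, params$weights, noise_draws[[3]])
  c(F_W = (steady_state_rate("W", I_W, params = params) - F_W) / params$tau_W,
    F_N = (steady_state_rate("N", I_N, H = H, params = params) - F_N) / params$tau_N,
    F_R = (steady_state_rate("R", I_R, params = params) - F_R) / params$tau_R,
    C_W = (transmitter_steady_state(F_W, params$gamma_C_W) - C_W) / params$tau_C_W,
    C_N = (transmitter_steady_state(F_N, params$gamma_C_N) - C_N) / params$tau_C_N,
    C_R = (transmitter_steady_state(F_R, params$gamma_C_R) - C_R) / params$tau_C_R,
    H = homeostatic_rhs(H, F_W, params))
}
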