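#' One classical fourth-order Runge-Kutta step
#'
#' Advances a state vector by one fixed step of the classical RK4 scheme
#' (stage weights 1/6, 2/6, 2/6, 1/6) for an autonomous derivative function.
#' Stochastic forcing is handled by freezing the noise realisation inside
#' `rhs` for the duration of the step, which preserves the classical RK4
#' update semantics.
#'
#' @param state numeric state vector.
#' @param dt step size (s), positive.
#' @param rhs function of the state returning its derivative (noise, if any,
#'   already fixed inside it).
#' @return The state after one step, same names as the input.
#' @examples
#' # scalar relaxation toward a constant target
#' step <- rk4_step(0, dt = 0.1, rhs = function(y) (1 - y) / 0.5)
#' @export
rk4_step <- function(state, dt, rhs) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  k1 <- rhs(state)
  k2 <- rhs(state + dt / 2 * k1)
  k3 <- rhs(state + dt / 2 * k2)
  k4 <- rhs(state + dt * k3)
  out <- state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  if (any(!is.finite(out)))
    stop("integration failure: non-finite RK4 stage value", call. = FALSE)
  out
}

#' Per-step Gaussian noise draws
#'
#' Draws the additive synaptic noise consumed by the simulator: one value per
#' population per time step, independent across populations and steps, in the
#' fixed order W, N, R within each step. With the same RNG state this
#' reproduces exactly the sequence the compiled integrator consumes.
#'
#' @param n_steps number of time steps.
#' @param params a [sleep_params()] object (supplies `noise_mean`,
#'   `noise_sd`).
#' @return An `n_steps x 3` matrix with columns `W`, `N`, `R` (Hz).
#' @examples
#' set.seed(1)
#' head(sample_noise(5, sleep_params()))
#' @export
sample_noise <- function(n_steps, params = sleep_params()) {
  m <- matrix(rnorm(3 * n_steps, params$noise_mean, params$noise_sd),
              ncol = 3, byrow = TRUE)
  colnames(m) <- c("W", "N", "R")
  m
}
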