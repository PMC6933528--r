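#' Synaptic pathway weights
#'
#' The six directed pathways of the network, named source-population letter,
#' target-population letter, and "e" (excitatory) or "i" (inhibitory).
#' Excitatory weights must be non-negative, inhibitory weights non-positive.
#' The defaults are the control condition of the perturbation experiments;
#' every scaled condition is an exact multiple of them (see
#' [sweep_table()]).
#'
#' @param RRe recurrent excitation within the REM-promoting population (a.u.).
#' @param RWe excitation from the REM- onto the Wake-promoting population.
#' @param WNi inhibition from the Wake- onto the NREM-promoting population.
#' @param WRi inhibition from the Wake- onto the REM-promoting population.
#' @param NRi inhibition from the NREM- onto the REM-promoting population.
#' @param NWi inhibition from the NREM- onto the Wake-promoting population.
#' @return A named numeric vector of class `"pathway_weights"`.
#' @examples
#' pathway_weights()
#' pathway_weights(WNi = -4)  # the "double" condition for WNi
#' @export
pathway_weights <- function(RRe = 1.6, RWe = 1.0, WNi = -2.0, WRi = -4.0,
                            NRi = -1.3, NWi = -1.68) {
  w <- c(RRe = RRe, RWe = RWe, WNi = WNi, WRi = WRi, NRi = NRi, NWi = NWi)
  validate_weights(w)
  structure(w, class = "pathway_weights")
}

validate_weights <- function(w) {
  if (!is.numeric(w) || length(w) != 6L || !all(PATHWAYS %in% names(w)))
    stop("weights must be a named numeric vector over pathways ",
         paste(PATHWAYS, collapse = ", "), call. = FALSE)
  if (any(!is.finite(w))) stop("pathway weights must be finite", call. = FALSE)
  for (p in c("RRe", "RWe"))
    if (w[[p]] < 0)
      stop("excitatory weight ", p, " must be >= 0 (got ", w[[p]], ")",
           call. = FALSE)
  for (p in c("WNi", "WRi", "NRi", "NWi"))
    if (w[[p]] > 0)
      stop("inhibitory weight ", p, " must be <= 0 (got ", w[[p]], ")",
           call. = FALSE)
  invisible(w)
}

#' Model parameters for the sleep-wake network
#'
#' Collects every constant of the coupled ODE system: maximum firing rates,
#' activation slopes and thresholds, membrane and transmitter time constants,
#' homeostatic-drive constants, the six pathway weights, the additive noise
#' specification and the integration grid. Any subset can be overridden; the
#' result is validated against the model's sign and positivity constraints.
#'
#' Defaults are the package's calibrated reference configuration: with them
#' the noise-free model starts in wakefulness and cycles through all three
#' vigilance states over 24 h, with homeostatic build-up during wakefulness
#' and decay during sleep (see the package vignette for the calibration
#' rationale). Note `k_N` is negative: the NREM activation threshold is
#' `k_N * H(t)`, so a negative coefficient makes rising homeostatic pressure
#' promote NREM activation.
#'
#' @param W_max,N_max,R_max maximum firing rate of each population (Hz).
#' @param alpha_W,alpha_N,alpha_R activation slope of the tanh nonlinearity
#'   (a.u.).
#' @param beta_W,beta_R activation threshold for the Wake and REM populations
#'   (a.u.). The NREM threshold is dynamic: `k_N * H(t)`.
#' @param k_N homeostatic coupling coefficient for the NREM threshold
#'   (a.u. per unit H); negative by default, see Details.
#' @param tau_W,tau_N,tau_R population time constants (s).
#' @param H_max maximum homeostatic sleep drive (a.u.).
#' @param theta_W wake-detection threshold of the homeostat (Hz).
#' @param tau_hw,tau_hs homeostat build-up (wake) and decay (sleep) time
#'   constants (s).
#' @param tau_C_W,tau_C_N,tau_C_R transmitter concentration decay time
#'   constants per source population (s).
#' @param gamma_C_W,gamma_C_N,gamma_C_R transmitter release half-saturation
#'   scales (Hz); the release steady state is `tanh(F_Y / gamma_C_Y)`. They
#'   default to the same numeric values as the corresponding `tau_C_*`.
#' @param weights a [pathway_weights()] vector.
#' @param noise_mean,noise_sd mean and standard deviation of the per-step
#'   Gaussian noise added to each population's synaptic input (Hz).
#' @param dt integration step (s).
#' @param duration simulation length (s).
#' @return A validated list of class `"sleep_params"`.
#' @examples
#' p <- sleep_params(duration = 6 * 3600)
#' p$weights
#' @export
sleep_params <- function(W_max = 5, N_max = 5, R_max = 5,
                         alpha_W = 0.25, alpha_N = 0.25, alpha_R = 0.25,
                         beta_W = -1.1, beta_R = -1.2, k_N = -2.5,
                         tau_W = 30, tau_N = 30, tau_R = 30,
                         H_max = 1, theta_W = 2,
                         tau_hw = 10800, tau_hs = 5400,
                         tau_C_W = 4, tau_C_N = 2, tau_C_R = 5,
                         gamma_C_W = tau_C_W, gamma_C_N = tau_C_N,
                         gamma_C_R = tau_C_R,
                         weights = pathway_weights(),
                         noise_mean = 0.01, noise_sd = 0.005,
                         dt = 0.001, duration = 86400) {
  p <- list(W_max = W_max, N_max = N_max, R_max = R_max,
            alpha_W = alpha_W, alpha_N = alpha_N, alpha_R = alpha_R,
            beta_W = beta_W, beta_R = beta_R, k_N = k_N,
            tau_W = tau_W, tau_N = tau_N, tau_R = tau_R,
            H_max = H_max, theta_W = theta_W,
            tau_hw = tau_hw, tau_hs = tau_hs,
            tau_C_W = tau_C_W, tau_C_N = tau_C_N, tau_C_R = tau_C_R,
            gamma_C_W = gamma_C_W, gamma_C_N = gamma_C_N,
            gamma_C_R = gamma_C_R,
            weights = weights,
            noise_mean = noise_mean, noise_sd = noise_sd,
            dt = dt, duration = duration)
  class(p) <- "sleep_params"
  validate_params(p)
}

#' Validate a parameter set
#'
#' Checks the sign and positivity invariants of [sleep_params()]; the error
#' message names the offending field.
#'
#' @param p a `"sleep_params"` object (or plain list with the same fields).
#' @return `p`, invisibly classed as `"sleep_params"`, if valid.
#' @export
validate_params <- function(p) {
  need_pos <- c("W_max", "N_max", "R_max", "alpha_W", "alpha_N", "alpha_R",
                "tau_W", "tau_N", "tau_R", "H_max", "theta_W",
                "tau_hw", "tau_hs", "tau_C_W", "tau_C_N", "tau_C_R",
                "gamma_C_W", "gamma_C_N", "gamma_C_R", "dt", "duration")
  scalar_fields <- setdiff(param_field_names(), "weights")
  for (f in scalar_fields) {
    v <- p[[f]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", f, "' must be a single finite number", call. = FALSE)
  }
  for (f in need_pos)
    if (p[[f]] <= 0)
      stop("parameter '", f, "' must be strictly positive (got ", p[[f]], ")",
           call. = FALSE)
  if (p$noise_sd < 0)
    stop("parameter 'noise_sd' must be >= 0 (got ", p$noise_sd, ")",
         call. = FALSE)
  validate_weights(p$weights)
  class(p) <- "sleep_params"
  invisible(p)
}

param_field_names <- function() {
  c("W_max", "N_max", "R_max", "alpha_W", "alpha_N", "alpha_R",
    "beta_W", "beta_R", "k_N", "tau_W", "tau_N", "tau_R",
    "H_max", "theta_W", "tau_hw", "tau_hs",
    "tau_C_W", "tau_C_N", "tau_C_R",
    "gamma_C_W", "gamma_C_N", "gamma_C_R", "weights",
    "noise_mean", "noise_sd", "dt", "duration")
}

# Flat named vector of the packed constants consumed by the compiled core.
# The order is an internal contract with src/sim.cpp.
.pack_params <- function(p) {
  w <- p$weights
  c(p$W_max, p$N_max, p$R_max, p$alpha_W, p$alpha_N, p$alpha_R,
    p$beta_W, p$beta_R, p$k_N, p$tau_W, p$tau_N, p$tau_R,
    p$H_max, p$theta_W, p$tau_hw, p$tau_hs,
    p$tau_C_W, p$tau_C_N, p$tau_C_R,
    p$gamma_C_W, p$gamma_C_N, p$gamma_C_R,
    w[["RRe"]], w[["RWe"]], w[["WNi"]], w[["WRi"]], w[["NRi"]], w[["NWi"]])
}

# Canonical flat key = value representation (weights as g_<pathway>).
params_to_flat <- function(p) {
  scalar_fields <- setdiff(param_field_names(), "weights")
  vals <- lapply(scalar_fields, function(f) p[[f]])
  names(vals) <- scalar_fields
  for (pw in PATHWAYS) vals[[paste0("g_", pw)]] <- unname(p$weights[[pw]])
  vals
}

#' Deterministic digest of a resolved configuration
#'
#' A 32-bit FNV-1a hash of the canonical `key=value` rendering of a parameter
#' set, used to tag trajectories and manifests so results can be traced back
#' to the exact configuration that produced them.
#'
#' @param p a `"sleep_params"` object.
#' @return An 8-character hexadecimal string.
#' @export
config_digest <- function(p) {
  flat <- params_to_flat(p)
  txt <- paste(names(flat), vapply(flat, function(v) sprintf("%.17g", v), ""),
               sep = "=", collapse = ";")
  fnv1a32(txt)
}

# FNV-1a over the bytes of a string, in double arithmetic (products kept
# below 2^53 by splitting the multiplication).
fnv1a32 <- function(txt) {
  bytes <- as.integer(charToRaw(txt))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- ((hi * prime) %% 65536) * 65536 + lo * prime
    h <- h %% 4294967296
  }
  lo <- h %% 65536
  hi <- (h - lo) / 65536
  sprintf("%04x%04x", as.integer(hi), as.integer(lo))
}

bitwXor_dbl <- function(a, b) {
  # a < 2^32, b < 2^8: xor via 16-bit halves to stay in integer range
  alo <- a %% 65536
  ahi <- (a - alo) / 65536
  ahi * 65536 + bitwXor(as.integer(alo), as.integer(b))
}

#' @export
print.sleep_params <- function(x, ...) {
  cat("Sleep-wake network parameters\n")
  cat(sprintf("  populations : max %g/%g/%g Hz (W/N/R), tau %g/%g/%g s\n",
              x$W_max, x$N_max, x$R_max, x$tau_W, x$tau_N, x$tau_R))
  cat(sprintf("  activation  : alpha %g/%g/%g, beta_W %g, beta_R %g, k_N %g\n",
              x$alpha_W, x$alpha_N, x$alpha_R, x$beta_W, x$beta_R, x$k_N))
  cat(sprintf("  homeostat   : H_max %g, theta_W %g Hz, tau_hw %g s, tau_hs %g s\n",
              x$H_max, x$theta_W, x$tau_hw, x$tau_hs))
  cat(sprintf("  transmitters: tau_C %g/%g/%g s, gamma_C %g/%g/%g Hz\n",
              x$tau_C_W, x$tau_C_N, x$tau_C_R,
              x$gamma_C_W, x$gamma_C_N, x$gamma_C_R))
  cat("  weights     : ",
      paste(sprintf("%s=%g", PATHWAYS, x$weights[PATHWAYS]), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  noise       : mean %g Hz, sd %g Hz\n", x$noise_mean, x$noise_sd))
  cat(sprintf("  integration : dt %g s, duration %g s (%.3g h)\n",
              x$dt, x$duration, x$duration / 3600))
  cat(sprintf("  digest      : %s\n", config_digest(x)))
  invisible(x)
}
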