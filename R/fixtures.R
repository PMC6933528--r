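# Synthetic fixtures: hypnograms with known episode structure and
# piecewise-constant rate trajectories, so scoring and statistics can be
# exercised independently of the ODE core. The brute-force metrics oracle
# lives here too; it is used only as an independent cross-check in tests.

#' Synthetic hypnogram with known structure
#'
#' Two modes. Explicit: `episodes` is a data.frame of `(state, duration_s)`
#' rows realised exactly. Markov: a first-order chain over the three states
#' with transition probabilities `transitions` (zero diagonal, rows summing
#' to 1) and geometric dwell times at `dt` resolution with the given mean
#' episode durations; this is a test device, not a biological model.
#'
#' @param episodes data.frame with columns `state`, `duration_s` (explicit
#'   mode); durations must be positive multiples of `dt`.
#' @param transitions 3x3 matrix of state-transition probabilities with rows
#'   and columns named `WAKE`, `NREM`, `REM` (Markov mode).
#' @param mean_duration_s named numeric, mean episode duration per state
#'   (Markov mode).
#' @param duration total record length (s, Markov mode; generation stops at
#'   the first episode boundary at or beyond it, then truncates).
#' @param dt sample spacing (s).
#' @param seed integer seed (Markov mode).
#' @param start_state initial state of the chain (Markov mode).
#' @return A [hypnogram()].
#' @examples
#' make_synthetic_hypnogram(
#'   episodes = data.frame(state = c("WAKE", "NREM", "REM"),
#'                         duration_s = c(3, 4, 2)), dt = 1)
#' @export
make_synthetic_hypnogram <- function(episodes = NULL, transitions = NULL,
                                     mean_duration_s = NULL, duration = NULL,
                                     dt = 1, seed = NULL,
                                     start_state = "WAKE") {
  if (!is.null(episodes)) {
    if (any(episodes$duration_s <= 0))
      stop("episode durations must be positive", call. = FALSE)
    n <- round(episodes$duration_s / dt)
    if (any(n < 1) || any(abs(n * dt - episodes$duration_s) > 1e-9))
      stop("durations must be positive multiples of dt", call. = FALSE)
    return(hypnogram(rep(as.character(episodes$state), n), dt))
  }
  stopifnot(!is.null(transitions), !is.null(mean_duration_s),
            !is.null(duration))
  if (!all(rownames(transitions) == STATE_LEVELS) ||
      !all(colnames(transitions) == STATE_LEVELS))
    stop("transitions must have rows/columns WAKE, NREM, REM", call. = FALSE)
  if (any(abs(rowSums(transitions) - 1) > 1e-9))
    stop("transition rows must sum to 1", call. = FALSE)
  if (any(diag(transitions) != 0))
    stop("self-transitions are not allowed (episodes must alternate)",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  state <- match.arg(start_state, STATE_LEVELS)
  n_total <- round(duration / dt)
  labels <- character(0)
  while (length(labels) < n_total) {
    mean_n <- mean_duration_s[[state]] / dt
    dwell <- 1L + stats::rgeom(1, prob = min(1, 1 / mean_n))
    labels <- c(labels, rep(state, dwell))
    state <- sample(STATE_LEVELS, 1, prob = transitions[state, ])
  }
  hypnogram(labels[seq_len(n_total)], dt)
}

#' Brute-force metrics oracle
#'
#' Recomputes every sleep-architecture metric by a per-sample linear scan of
#' the label sequence, without run-length encoding: totals by counting
#' samples, episodes and transitions by comparing consecutive samples,
#' latencies by scanning forward. Deliberately naive and independent of
#' [compute_metrics()]; used to cross-check it in tests.
#'
#' @param h a [hypnogram()].
#' @return A one-row data.frame with the same columns as
#'   [compute_metrics()].
#' @export
brute_force_metrics_oracle <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  lab <- as.character(h$labels)
  n <- length(lab)
  out <- list()
  for (s in STATE_LEVELS) out[[paste0("total_s_", s)]] <- sum(lab == s) * h$dt
  for (s in STATE_LEVELS) out[[paste0("pct_", s)]] <- 100 * sum(lab == s) / n
  for (s in STATE_LEVELS) {
    cnt <- 0
    for (i in seq_len(n))
      if (lab[i] == s && (i == 1 || lab[i - 1] != s)) cnt <- cnt + 1
    out[[paste0("episodes_", s)]] <- cnt
  }
  for (a in STATE_LEVELS) for (b in STATE_LEVELS) {
    if (a == b) next
    cnt <- 0
    for (i in seq_len(n - 1))
      if (lab[i] == a && lab[i + 1] == b) cnt <- cnt + 1
    out[[paste0("trans_", a, "_", b)]] <- cnt
  }
  first_n <- NA_real_; first_r <- NA_real_
  for (i in seq_len(n)) {
    if (is.na(first_n) && lab[i] == "NREM") first_n <- (i - 1) * h$dt
    if (!is.na(first_n) && is.na(first_r) && lab[i] == "REM")
      first_r <- (i - 1) * h$dt - first_n
  }
  out$latency_nrem_s <- first_n
  out$latency_rem_s <- first_r
  as.data.frame(out)
}

#' Piecewise-constant synthetic trajectory
#'
#' Builds a `"sleep_sim"`-compatible trajectory whose firing rates are
#' exactly the requested piecewise-constant segments (transmitter
#' concentrations and homeostatic drive are filled with admissible
#' constants), so the scoring layer can be exercised with known answers.
#'
#' @param segments data.frame with columns `duration_s`, `F_W`, `F_N`,
#'   `F_R`; segments must tile the record without gaps (durations are
#'   positive multiples of `dt`).
#' @param dt sample spacing (s).
#' @param C_W,C_N,C_R,H constants used to fill the remaining state
#'   components.
#' @param params box-defining [sleep_params()].
#' @return An object of class `"sleep_sim"` flagged as synthetic.
#' @export
make_test_timeseries <- function(segments, dt = 1,
                                 C_W = 0.5, C_N = 0.5, C_R = 0.5, H = 0.5,
                                 params = sleep_params()) {
  stopifnot(all(c("duration_s", "F_W", "F_N", "F_R") %in% names(segments)))
  if (any(segments$duration_s <= 0))
    stop("segment durations must be positive (no gaps or overlaps)",
         call. = FALSE)
  n <- round(segments$duration_s / dt)
  if (any(n < 1) || any(abs(n * dt - segments$duration_s) > 1e-9))
    stop("segment durations must be positive multiples of dt", call. = FALSE)
  FW <- rep(segments$F_W, n); FN <- rep(segments$F_N, n)
  FR <- rep(segments$F_R, n)
  n_tot <- length(FW)
  states <- cbind(F_W = FW, F_N = FN, F_R = FR,
                  C_W = rep(C_W, n_tot), C_N = rep(C_N, n_tot),
                  C_R = rep(C_R, n_tot), H = rep(H, n_tot))
  # validate against the state box
  network_state(FW[1], FN[1], FR[1], C_W, C_N, C_R, H, params)
  structure(list(
    time = (seq_len(n_tot) - 1) * dt, states = states,
    state_min = apply(states, 2, min), state_max = apply(states, 2, max),
    dt = dt, store_every = 1L, duration = n_tot * dt, n_steps = n_tot - 1,
    seed = NA_integer_, noisy = FALSE, params = params,
    meta = list(params_digest = config_digest(params), rng = "synthetic",
                synthetic = TRUE)
  ), class = "sleep_sim")
}
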