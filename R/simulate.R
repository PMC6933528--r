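#' Construct a sleep-wake network model
#'
#' The central model object: three neural populations (Wake-, NREM- and
#' REM-promoting) coupled by six weighted pathways, with a homeostatic sleep
#' drive gating NREM excitability. Simulate trajectories from it with
#' [simulate()][simulate.sleep_model]; inspect the control pathway weights
#' with [coef()].
#'
#' @param params a [sleep_params()] object.
#' @return An object of class `"sleep_model"`.
#' @examples
#' m <- sleep_model(sleep_params(duration = 3600))
#' coef(m)
#' @export
sleep_model <- function(params = sleep_params()) {
  params <- validate_params(params)
  structure(list(params = params), class = "sleep_model")
}

#' @export
print.sleep_model <- function(x, ...) {
  cat("Three-population sleep-wake network model\n")
  cat("  populations: Wake, NREM, REM; homeostatic drive on NREM threshold\n")
  cat("  pathways   : ",
      paste(sprintf("%s=%g", PATHWAYS, x$params$weights[PATHWAYS]),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  integration: RK4, dt = %g s, duration = %g h\n",
              x$params$dt, x$params$duration / 3600))
  invisible(x)
}

#' @export
summary.sleep_model <- function(object, ...) {
  print(object)
  print(object$params)
  invisible(object)
}

#' @export
coef.sleep_model <- function(object, ...) object$params$weights

#' Simulate trajectories from a sleep-wake network model
#'
#' Runs `nsim` seeded replicate simulations of the model. Replicates differ
#' only in their noise seed (`seed`, `seed + 1`, ...). With `noise = FALSE` a
#' single deterministic trajectory is produced.
#'
#' @param object a [sleep_model()].
#' @param nsim number of replicate trajectories.
#' @param seed base integer seed (required when `noise = TRUE`).
#' @param noise logical; `FALSE` sets the noise term to exactly zero.
#' @param ... passed on to [run_simulation()] (e.g. `store_every`,
#'   `duration`, `dt`).
#' @return A single `"sleep_sim"` object if `nsim == 1`, otherwise a list of
#'   them.
#' @export
simulate.sleep_model <- function(object, nsim = 1, seed = NULL,
                                 noise = !is.null(seed), ...) {
  if (noise && is.null(seed))
    stop("a seed is required for noisy simulations", call. = FALSE)
  sims <- lapply(seq_len(nsim) - 1L, function(k) {
    run_simulation(object$params,
                   seed = if (noise) as.integer(seed) + k else NULL, ...)
  })
  if (nsim == 1) sims[[1]] else sims
}

#' Run one simulation of the network
#'
#' Integrates the 7-dimensional stochastic ODE system with the compiled
#' fixed-step RK4 core. Noise is one Gaussian draw per population per step
#' (order W, N, R), frozen across the four RK4 stages of that step. `seed =
#' NULL` runs the deterministic (noise-free) system. Every stored sample is
#' guaranteed to lie in the admissible state box; excursions beyond
#' `clip_tol` abort with a diagnostic naming the step and component.
#'
#' @param params a [sleep_params()] object.
#' @param seed integer seed for the noise stream, or `NULL` for a noise-free
#'   run.
#' @param duration,dt simulation length and step (s); default from `params`.
#' @param store_every storage stride: every `store_every`-th sample is kept
#'   (the integration always runs at `dt`). The default 100 stores a 0.1-s
#'   grid at the standard 1-ms step.
#' @param init initial [network_state()]; default [initial_state()]
#'   (wakefulness).
#' @param clip_tol tolerance for clipping numerical overshoot back onto the
#'   state-box boundary.
#' @return An object of class `"sleep_sim"`: list with elements `time`
#'   (seconds), `states` (samples x 7 matrix), `state_min`/`state_max`
#'   (full-resolution extrema over every integration step), `dt`,
#'   `store_every`, `duration`, `n_steps`, `seed`, `noisy`, `params`, and
#'   `meta` (parameter digest, RNG description, package version).
#' @examples
#' p <- sleep_params(duration = 1800, dt = 0.01)
#' ts <- run_simulation(p, seed = 1, store_every = 10)
#' ts
#' @export
run_simulation <- function(params = sleep_params(), seed = NULL,
                           duration = params$duration, dt = params$dt,
                           store_every = 100L, init = NULL,
                           clip_tol = 1e-6) {
  params <- validate_params(params)
  if (is.null(init)) init <- initial_state(params)
  n_steps <- round(duration / dt)
  noisy <- !is.null(seed)
  if (noisy) {
    seed <- as.integer(seed)
    set.seed(seed)
  }
  res <- .sim_core(unname(init), .pack_params(params), dt, n_steps,
                   as.integer(store_every), noisy,
                   params$noise_mean, params$noise_sd, clip_tol)
  names(res$state_min) <- names(res$state_max) <- colnames(res$states)
  structure(list(
    time = res$time, states = res$states,
    state_min = res$state_min, state_max = res$state_max,
    dt = dt, store_every = as.integer(store_every),
    duration = n_steps * dt, n_steps = res$n_steps,
    seed = if (noisy) seed else NA_integer_, noisy = noisy,
    params = params,
    meta = list(params_digest = config_digest(params),
                rng = paste(RNGkind(), collapse = "/"),
                package_version = as.character(utils::packageVersion("sleepnet")),
                grid_note = if (store_every > 1L)
                  sprintf("stored every %d-th %g-s step; scoring runs on the stored grid",
                          as.integer(store_every), dt) else "full-resolution storage")
  ), class = "sleep_sim")
}

#' @export
print.sleep_sim <- function(x, ...) {
  cat(sprintf("Sleep-wake trajectory: %.3g h at dt = %g s (stored every %d steps, %d samples)\n",
              x$duration / 3600, x$dt, x$store_every, length(x$time)))
  cat(sprintf("  %s run%s; params digest %s\n",
              if (x$noisy) "noisy" else "noise-free",
              if (x$noisy) sprintf(", seed %d", x$seed) else "",
              x$meta$params_digest))
  rng <- apply(x$states, 2, range)
  cat("  stored ranges:\n")
  for (v in colnames(x$states))
    cat(sprintf("    %-3s in [%.4g, %.4g]\n", v, rng[1, v], rng[2, v]))
  invisible(x)
}

#' @export
summary.sleep_sim <- function(object, ...) {
  print(object)
  h <- build_hypnogram(object)
  m <- compute_metrics(h)
  cat("\nSleep architecture:\n")
  print(m)
  invisible(m)
}

#' @export
as.data.frame.sleep_sim <- function(x, ...) {
  data.frame(time_s = x$time, x$states, check.names = FALSE)
}

#' Plot a simulated trajectory
#'
#' Three stacked panels in the style of the model's reference figure:
#' population firing rates, transmitter concentrations with the homeostatic
#' drive, and the scored hypnogram.
#'
#' @param x a `"sleep_sim"` object.
#' @param hours show time in hours (default) or seconds.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.sleep_sim <- function(x, hours = TRUE, ...) {
  tt <- if (hours) x$time / 3600 else x$time
  xlab <- if (hours) "time (h)" else "time (s)"
  op <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1.5, 1), mgp = c(2, 0.7, 0))
  on.exit(graphics::par(op))
  cols <- c(F_W = "darkorange3", F_N = "forestgreen", F_R = "royalblue3")
  graphics::matplot(tt, x$states[, c("F_W", "F_N", "F_R")], type = "l",
                    lty = 1, col = cols, ylab = "firing rate (Hz)", xlab = "")
  graphics::legend("topright", legend = c("Wake", "NREM", "REM"),
                   col = cols, lty = 1, bty = "n", cex = 0.8)
  graphics::matplot(tt, cbind(x$states[, c("C_W", "C_N", "C_R")], x$states[, "H"]),
                    type = "l", lty = c(1, 1, 1, 2),
                    col = c(cols, "gray30"), ylab = "C, H (a.u.)", xlab = "")
  graphics::legend("topright", legend = c("C_W", "C_N", "C_R", "H"),
                   col = c(cols, "gray30"), lty = c(1, 1, 1, 2), bty = "n", cex = 0.8)
  h <- build_hypnogram(x)
  graphics::plot(tt, as.integer(h$labels), type = "s", yaxt = "n",
                 ylab = "state", xlab = xlab, col = "gray20")
  graphics::axis(2, at = 1:3, labels = STATE_LEVELS, las = 1, cex.axis = 0.8)
  invisible(x)
}

#' Write / read a trajectory as tab-separated text
#'
#' Columns `time_s, F_W, F_N, F_R, C_W, C_N, C_R, H`, preceded by `#`-prefixed
#' metadata lines. Values are written with 17 significant digits so the
#' reader round-trips doubles bit-exactly.
#'
#' @param ts a `"sleep_sim"` object.
#' @param path output file.
#' @return `write_timeseries()` returns `path` invisibly;
#'   `read_timeseries()` returns a `"sleep_sim"`-like object (without the
#'   full parameter set, which is summarised by its digest).
#' @export
write_timeseries <- function(ts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(dt = ts$dt, store_every = ts$store_every, duration = ts$duration,
            seed = if (ts$noisy) ts$seed else NA)
  writeLines(sprintf("# %s: %s", names(meta), as.character(meta)), con)
  writeLines(sprintf("# params_digest: %s", ts$meta$params_digest), con)
  writeLines(sprintf("# rng: %s", ts$meta$rng), con)
  tab <- cbind(time_s = ts$time, ts$states)
  writeLines(paste(colnames(tab), collapse = "\t"), con)
  body <- apply(tab, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_timeseries
#' @param path input file for `read_timeseries()`.
#' @export
read_timeseries <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta_kv <- sub("^# *", "", lines[is_meta])
  kv <- strsplit(meta_kv, ": ", fixed = TRUE)
  meta <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  body <- lines[!is_meta]
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  vals <- matrix(as.numeric(unlist(strsplit(body[-1], "\t", fixed = TRUE))),
                 ncol = length(header), byrow = TRUE,
                 dimnames = list(NULL, header))
  seed <- suppressWarnings(as.integer(meta$seed))
  structure(list(
    time = unname(vals[, "time_s"]), states = vals[, -1, drop = FALSE],
    state_min = NULL, state_max = NULL,
    dt = as.numeric(meta$dt), store_every = as.integer(meta$store_every),
    duration = as.numeric(meta$duration),
    n_steps = round(as.numeric(meta$duration) / as.numeric(meta$dt)),
    seed = seed, noisy = !is.na(seed), params = NULL,
    meta = list(params_digest = meta$params_digest, rng = meta$rng)
  ), class = "sleep_sim")
}
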