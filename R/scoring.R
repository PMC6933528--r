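#' Classify vigilance state from firing rates
#'
#' The scoring rule, applied with strict precedence: Wake if the
#' Wake-promoting population fires above `wake_threshold`; otherwise REM if
#' the REM-promoting population fires above `rem_threshold`; otherwise NREM.
#' Comparisons are strict (`>`), so rates exactly at threshold fall through
#' to the next rule.
#'
#' @param F_W,F_R firing rates (Hz); vectors of equal length, non-negative.
#' @param wake_threshold,rem_threshold classification thresholds (Hz),
#'   default 2.
#' @return Factor over levels `WAKE`, `NREM`, `REM`.
#' @examples
#' classify_sample(c(3, 1, 1, 2), c(5, 3, 1, 2))  # WAKE REM NREM NREM
#' @export
classify_sample <- function(F_W, F_R, wake_threshold = 2, rem_threshold = 2) {
  if (any(F_W < 0) || any(F_R < 0))
    stop("firing rates must be >= 0", call. = FALSE)
  lab <- ifelse(F_W > wake_threshold, 1L, ifelse(F_R > rem_threshold, 3L, 2L))
  factor(STATE_LEVELS[lab], levels = STATE_LEVELS)
}

#' Construct a hypnogram from per-sample labels
#'
#' Stores the label sequence together with its exact run-length episode
#' encoding (state, onset time, duration). Adjacent episodes always differ in
#' state and episode durations sum to the record length.
#'
#' @param labels factor (or character) of per-sample states over
#'   `WAKE`/`NREM`/`REM`.
#' @param dt sample spacing (s).
#' @return An object of class `"hypnogram"`: list with `labels`, `dt` and
#'   `episodes` (data.frame `state`, `onset_s`, `duration_s`).
#' @export
hypnogram <- function(labels, dt) {
  if (length(labels) == 0) stop("empty label sequence", call. = FALSE)
  labels <- factor(as.character(labels), levels = STATE_LEVELS)
  if (anyNA(labels)) stop("labels must be WAKE, NREM or REM", call. = FALSE)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  r <- rle(as.integer(labels))
  onsets <- dt * cumsum(c(0, head(r$lengths, -1)))
  episodes <- data.frame(state = factor(STATE_LEVELS[r$values],
                                        levels = STATE_LEVELS),
                         onset_s = onsets,
                         duration_s = dt * r$lengths)
  structure(list(labels = labels, dt = dt, episodes = episodes),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("Hypnogram: %d samples at dt = %g s (%.4g h), %d episodes\n",
              length(x$labels), x$dt, length(x$labels) * x$dt / 3600,
              nrow(x$episodes)))
  tot <- tapply(x$episodes$duration_s, x$episodes$state, sum, default = 0)
  cat("  time per state (s): ",
      paste(sprintf("%s=%g", names(tot), tot), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Score a trajectory into a hypnogram
#'
#' Applies [classify_sample()] to every stored sample of a simulated
#' trajectory. If the trajectory was stored with a stride, classification
#' runs on the stored grid (recorded in the trajectory metadata).
#'
#' @param ts a `"sleep_sim"` object.
#' @param wake_threshold,rem_threshold thresholds (Hz) passed to
#'   [classify_sample()].
#' @param min_duration_s optional minimum episode duration (s): shorter
#'   episodes are merged into the preceding episode. Off (`0`) by default;
#'   the scoring convention applies no smoothing.
#' @return A [hypnogram()].
#' @export
build_hypnogram <- function(ts, wake_threshold = 2, rem_threshold = 2,
                            min_duration_s = 0) {
  if (is.null(ts$states) || nrow(ts$states) == 0)
    stop("empty trajectory", call. = FALSE)
  lab <- classify_sample(ts$states[, "F_W"], ts$states[, "F_R"],
                         wake_threshold, rem_threshold)
  h <- hypnogram(lab, dt = ts$dt * ts$store_every)
  if (min_duration_s > 0) h <- filter_min_duration(h, min_duration_s)
  h
}

# Merge episodes shorter than min_s into their predecessor (the first
# episode is never merged forward), then re-encode.
filter_min_duration <- function(h, min_s) {
  ep <- h$episodes
  keep_state <- as.character(ep$state)
  n_samp <- round(ep$duration_s / h$dt)
  for (i in seq_along(keep_state)[-1]) {
    if (ep$duration_s[i] < min_s) keep_state[i] <- keep_state[i - 1]
  }
  hypnogram(rep(keep_state, n_samp), h$dt)
}

#' Sleep-architecture metrics of a hypnogram
#'
#' Computes the run summary reported for every simulation: total duration
#' and percentage of time per state, episode counts per state, transition
#' counts per ordered state pair, and the NREM and REM latencies.
#'
#' @param h a [hypnogram()].
#' @return A one-row data.frame of class `"sleep_metrics"` with columns
#'   `total_s_*`, `pct_*`, `episodes_*` for each state, `trans_<from>_<to>`
#'   for the six ordered pairs, and `latency_nrem_s` / `latency_rem_s`
#'   (`NA` when the state never occurs).
#' @examples
#' h <- hypnogram(c("WAKE", "WAKE", "NREM", "NREM", "REM", "NREM", "WAKE"), dt = 1)
#' compute_metrics(h)
#' @export
compute_metrics <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  ep <- h$episodes
  tot <- tapply(ep$duration_s, ep$state, sum, default = 0)
  nep <- tapply(rep(1, nrow(ep)), ep$state, sum, default = 0)
  dur <- sum(ep$duration_s)
  out <- as.list(stats::setNames(as.numeric(tot),
                                 paste0("total_s_", STATE_LEVELS)))
  out <- c(out, stats::setNames(as.list(100 * as.numeric(tot) / dur),
                                paste0("pct_", STATE_LEVELS)))
  out <- c(out, stats::setNames(as.list(as.numeric(nep)),
                                paste0("episodes_", STATE_LEVELS)))
  from <- as.character(ep$state[-nrow(ep)])
  to <- as.character(ep$state[-1])
  for (a in STATE_LEVELS) for (b in STATE_LEVELS) {
    if (a == b) next
    out[[paste0("trans_", a, "_", b)]] <- sum(from == a & to == b)
  }
  lat <- latencies(h)
  out$latency_nrem_s <- lat[["nrem"]]
  out$latency_rem_s <- lat[["rem"]]
  structure(as.data.frame(out), class = c("sleep_metrics", "data.frame"))
}

#' NREM and REM sleep latencies
#'
#' NREM latency is the onset time of the first NREM episode measured from
#' the start of the record (0 if the record begins in NREM). REM latency is
#' the time from that first NREM onset to the first REM onset at or after
#' it; REM occurring before any NREM does not count. A latency is `NA`
#' ("no occurrence") when the required state never appears.
#'
#' @param h a [hypnogram()].
#' @return Named numeric `c(nrem = , rem = )` in seconds, `NA` when
#'   undefined.
#' @export
latencies <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  ep <- h$episodes
  iN <- which(ep$state == "NREM")[1]
  if (is.na(iN)) return(c(nrem = NA_real_, rem = NA_real_))
  n_on <- ep$onset_s[iN]
  iR <- which(ep$state == "REM" & ep$onset_s >= n_on)[1]
  c(nrem = n_on, rem = if (is.na(iR)) NA_real_ else ep$onset_s[iR] - n_on)
}

#' Export a rate trajectory with periodic time markers
#'
#' Returns the three-population firing-rate trajectory with a logical marker
#' column flagging every `marker_interval` seconds (e.g. 30-min marks on a
#' 24-h run), for external 3-D trajectory plotting.
#'
#' @param ts a `"sleep_sim"` object.
#' @param marker_interval marker spacing (s); must be a multiple of the
#'   stored sample spacing.
#' @return data.frame `time_s, F_W, F_N, F_R, marker`.
#' @export
export_trajectory <- function(ts, marker_interval = 1800) {
  dt_grid <- ts$dt * ts$store_every
  ratio <- marker_interval / dt_grid
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("marker_interval must be a multiple of the stored sample spacing",
         call. = FALSE)
  idx <- seq_along(ts$time) - 1L
  data.frame(time_s = ts$time,
             F_W = ts$states[, "F_W"],
             F_N = ts$states[, "F_N"],
             F_R = ts$states[, "F_R"],
             marker = idx %% round(ratio) == 0)
}

#' Write / read a hypnogram as run-length encoded CSV
#'
#' Columns `state, onset_s, duration_s`; the sample spacing is kept in a
#' leading `# dt:` comment so the label sequence can be reconstructed
#' exactly.
#'
#' @param h a [hypnogram()].
#' @param path file path.
#' @return `write_hypnogram()` returns `path` invisibly; `read_hypnogram()`
#'   the reconstructed [hypnogram()].
#' @export
write_hypnogram <- function(h, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt: %.17g", h$dt), con)
  ep <- h$episodes
  ep$onset_s <- sprintf("%.17g", ep$onset_s)
  ep$duration_s <- sprintf("%.17g", ep$duration_s)
  write.csv(ep, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path) {
  first <- readLines(path, n = 1)
  dt <- as.numeric(sub("^# dt: ", "", first))
  ep <- read.csv(path, comment.char = "#")
  labels <- rep(ep$state, round(ep$duration_s / dt))
  hypnogram(labels, dt)
}

#' Write metrics rows to CSV
#'
#' One row per run with named columns; round-trips through
#' [read_metrics()].
#'
#' @param m a `"sleep_metrics"` row or a data.frame of stacked rows.
#' @param path file path.
#' @export
write_metrics <- function(m, path) {
  write.csv(m, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) read.csv(path)
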