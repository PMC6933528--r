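test_that("classification applies Wake-then-REM precedence with strict thresholds", {
  expect_identical(as.character(classify_sample(3, 5)), "WAKE")
  expect_identical(as.character(classify_sample(1, 3)), "REM")
  expect_identical(as.character(classify_sample(1, 1)), "NREM")
  expect_identical(as.character(classify_sample(2.0, 2.0)), "NREM")
  expect_error(classify_sample(-1, 0), ">= 0")
})

test_that("every rate pair maps to exactly one state", {
  set.seed(21)
  F_W <- runif(500, 0, 5); F_R <- runif(500, 0, 5)
  lab <- classify_sample(F_W, F_R)
  expect_false(anyNA(lab))
  expect_identical(levels(lab), c("WAKE", "NREM", "REM"))
})

test_that("hypnograms are exact run-length encodings", {
  ts <- make_test_timeseries(data.frame(
    duration_s = c(2, 3, 1), F_W = c(5, 0, 0), F_N = c(0, 5, 0),
    F_R = c(0, 0, 5)), dt = 1)
  h <- build_hypnogram(ts)
  expect_identical(as.character(h$episodes$state), c("WAKE", "NREM", "REM"))
  expect_equal(h$episodes$onset_s, c(0, 2, 5))
  expect_equal(h$episodes$duration_s, c(2, 3, 1))
  # re-expanding the episode list reproduces the label sequence
  expanded <- rep(as.character(h$episodes$state),
                  round(h$episodes$duration_s / h$dt))
  expect_identical(expanded, as.character(h$labels))
  # adjacent episodes always differ; durations conserve record length
  expect_true(all(diff(as.integer(h$episodes$state)) != 0))
  expect_equal(sum(h$episodes$duration_s), length(h$labels) * h$dt)

  const <- make_test_timeseries(data.frame(duration_s = 10, F_W = 5,
                                           F_N = 0, F_R = 0), dt = 1)
  hc <- build_hypnogram(const)
  expect_equal(nrow(hc$episodes), 1)
  expect_error(hypnogram(character(0), 1), "empty")
})

test_that("metrics match the hand-counted toy hypnogram", {
  h <- hypnogram(c("WAKE", "WAKE", "NREM", "NREM", "REM", "NREM", "WAKE"), dt = 1)
  m <- compute_metrics(h)
  expect_equal(m$total_s_WAKE, 3)
  expect_equal(m$total_s_NREM, 3)
  expect_equal(m$total_s_REM, 1)
  expect_equal(m$episodes_WAKE, 2)
  expect_equal(m$episodes_NREM, 2)
  expect_equal(m$episodes_REM, 1)
  expect_equal(m$trans_WAKE_NREM, 1)
  expect_equal(m$trans_NREM_REM, 1)
  expect_equal(m$trans_REM_NREM, 1)
  expect_equal(m$trans_NREM_WAKE, 1)
  expect_equal(m$trans_WAKE_REM, 0)
  expect_equal(m$trans_REM_WAKE, 0)
  expect_equal(m$latency_nrem_s, 2)
  expect_equal(m$latency_rem_s, 2)
})

test_that("single-state hypnogram gives 100%, one episode, no transitions", {
  h <- hypnogram(rep("NREM", 50), dt = 2)
  m <- compute_metrics(h)
  expect_equal(m$pct_NREM, 100)
  expect_equal(m$episodes_NREM, 1)
  trans <- unlist(m[grep("^trans_", names(m))])
  expect_true(all(trans == 0))
  expect_equal(m$latency_nrem_s, 0)
  expect_true(is.na(m$latency_rem_s))
})

test_that("percentages, durations and transition counts obey the conservation identities", {
  set.seed(31)
  for (i in 1:50) {
    h <- random_hypnogram(n_samples = sample(20:300, 1), dt = 0.5)
    m <- compute_metrics(h)
    expect_equal(m$pct_WAKE + m$pct_NREM + m$pct_REM, 100)
    expect_equal(m$total_s_WAKE + m$total_s_NREM + m$total_s_REM,
                 length(h$labels) * h$dt)
    n_trans <- sum(unlist(m[grep("^trans_", names(m))]))
    n_ep <- m$episodes_WAKE + m$episodes_NREM + m$episodes_REM
    expect_equal(n_trans, n_ep - 1)
  }
})

test_that("latency conventions handle edge cases", {
  # direct reading: 600 s of wake, then NREM
  h <- make_synthetic_hypnogram(
    episodes = data.frame(state = c("WAKE", "NREM"), duration_s = c(600, 100)),
    dt = 1)
  expect_equal(latencies(h), c(nrem = 600, rem = NA_real_))
  # W(10) N(20) W(5) R(5): REM latency from the first NREM onset
  h2 <- make_synthetic_hypnogram(
    episodes = data.frame(state = c("WAKE", "NREM", "WAKE", "REM"),
                          duration_s = c(10, 20, 5, 5)), dt = 1)
  expect_equal(latencies(h2), c(nrem = 10, rem = 25))
  # REM before any NREM is ignored for the latency
  h3 <- make_synthetic_hypnogram(
    episodes = data.frame(state = c("REM", "WAKE", "NREM", "REM"),
                          duration_s = c(5, 5, 10, 5)), dt = 1)
  expect_equal(latencies(h3), c(nrem = 10, rem = 10))
  # record starting in NREM has zero NREM latency
  h4 <- hypnogram(c("NREM", "WAKE"), dt = 1)
  expect_equal(latencies(h4)[["nrem"]], 0)
  # no NREM at all: both undefined
  h5 <- hypnogram(rep("WAKE", 5), dt = 1)
  expect_equal(latencies(h5), c(nrem = NA_real_, rem = NA_real_))
})

test_that("trajectory export marks the requested grid points", {
  # 24 h of samples on a closed grid (both endpoints stored)
  ts <- make_test_timeseries(data.frame(duration_s = 86460, F_W = 5,
                                        F_N = 0, F_R = 0), dt = 60)
  tab <- export_trajectory(ts, marker_interval = 1800)
  expect_equal(sum(tab$marker), 49)  # 24 h / 30 min + 1
  expect_true(all(tab$time_s[tab$marker] %% 1800 == 0))
  tab2 <- export_trajectory(ts, marker_interval = 86400)
  expect_equal(sum(tab2$marker), 2)  # start and end
  expect_error(export_trajectory(ts, marker_interval = 90), "multiple")
})

test_that("hypnogram and metrics files round-trip", {
  set.seed(5)
  h <- random_hypnogram(200, dt = 0.5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_hypnogram(h, f)
  back <- read_hypnogram(f)
  expect_identical(as.character(back$labels), as.character(h$labels))
  expect_equal(back$dt, h$dt)
  expect_equal(back$episodes, h$episodes)

  m <- compute_metrics(h)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_metrics(m, f2)
  m2 <- read_metrics(f2)
  expect_equal(unlist(m2), unlist(as.data.frame(m)), tolerance = 1e-12)
})

test_that("optional minimum-duration filter merges short episodes and defaults off", {
  labels <- c("WAKE", "WAKE", "NREM", "WAKE", "WAKE")
  ts <- make_test_timeseries(data.frame(duration_s = c(2, 1, 2),
                                        F_W = c(5, 0, 5), F_N = c(0, 1, 0),
                                        F_R = 0), dt = 1)
  h0 <- build_hypnogram(ts)
  expect_identical(as.character(h0$labels), labels)
  h1 <- build_hypnogram(ts, min_duration_s = 2)
  expect_identical(as.character(h1$labels), rep("WAKE", 5))
})
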