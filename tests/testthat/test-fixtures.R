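test_that("explicit synthetic hypnograms realise the requested episodes exactly", {
  h <- make_synthetic_hypnogram(
    episodes = data.frame(state = c("WAKE", "NREM", "REM"),
                          duration_s = c(3, 4, 2)), dt = 1)
  expect_length(h$labels, 9)
  expect_equal(h$episodes$duration_s, c(3, 4, 2))
  expect_equal(h$episodes$onset_s, c(0, 3, 7))
  expect_error(make_synthetic_hypnogram(
    episodes = data.frame(state = "WAKE", duration_s = 0), dt = 1), "positive")
})

test_that("Markov-mode hypnograms are seeded and validate their spec", {
  P <- matrix(c(0, 0.8, 0.2,
                0.5, 0, 0.5,
                0.9, 0.1, 0), 3, 3, byrow = TRUE,
              dimnames = list(c("WAKE", "NREM", "REM"),
                              c("WAKE", "NREM", "REM")))
  means <- c(WAKE = 20, NREM = 15, REM = 5)
  h1 <- make_synthetic_hypnogram(transitions = P, mean_duration_s = means,
                                 duration = 500, dt = 1, seed = 42)
  h2 <- make_synthetic_hypnogram(transitions = P, mean_duration_s = means,
                                 duration = 500, dt = 1, seed = 42)
  expect_identical(h1$labels, h2$labels)
  expect_length(h1$labels, 500)

  bad <- P; bad[1, ] <- c(0, 0.5, 0.4)
  expect_error(make_synthetic_hypnogram(transitions = bad,
                                        mean_duration_s = means,
                                        duration = 100, dt = 1, seed = 1),
               "sum to 1")
})

test_that("Markov-mode transition frequencies match the spec within sampling error", {
  P <- matrix(c(0, 0.7, 0.3,
                0.4, 0, 0.6,
                0.5, 0.5, 0), 3, 3, byrow = TRUE,
              dimnames = list(c("WAKE", "NREM", "REM"),
                              c("WAKE", "NREM", "REM")))
  means <- c(WAKE = 4, NREM = 4, REM = 4)
  h <- make_synthetic_hypnogram(transitions = P, mean_duration_s = means,
                                duration = 4e4, dt = 1, seed = 7)
  ep <- as.character(h$episodes$state)
  n_ep <- length(ep)
  expect_gt(n_ep, 5000)
  for (a in c("WAKE", "NREM", "REM")) {
    from_a <- which(ep[-n_ep] == a)
    for (b in setdiff(c("WAKE", "NREM", "REM"), a)) {
      phat <- mean(ep[from_a + 1] == b)
      se <- sqrt(P[a, b] * (1 - P[a, b]) / length(from_a))
      expect_lt(abs(phat - P[a, b]), 3.5 * se + 1e-12)
    }
  }
})

test_that("piecewise timeseries fixtures carry exactly the requested rates", {
  seg <- data.frame(duration_s = c(5, 5), F_W = c(5, 1), F_N = c(0, 1),
                    F_R = c(0, 3))
  ts <- make_test_timeseries(seg, dt = 1)
  expect_equal(unname(ts$states[1, "F_W"]), 5)
  expect_equal(unname(ts$states[10, "F_R"]), 3)
  h <- build_hypnogram(ts)
  expect_identical(as.character(h$episodes$state), c("WAKE", "REM"))
  # threshold probe: rates exactly at 2 Hz fall through to NREM
  probe <- make_test_timeseries(data.frame(duration_s = 2, F_W = 2, F_N = 0,
                                           F_R = 2), dt = 1)
  expect_true(all(build_hypnogram(probe)$labels == "NREM"))
  expect_error(make_test_timeseries(data.frame(duration_s = -1, F_W = 0,
                                               F_N = 0, F_R = 0), dt = 1),
               "positive")
})

test_that("fixture outputs satisfy the target type invariants", {
  set.seed(13)
  for (i in 1:20) {
    h <- random_hypnogram(100, dt = 1)
    expect_true(all(diff(as.integer(h$episodes$state)) != 0))
    expect_equal(sum(h$episodes$duration_s), 100)
  }
  ts <- make_test_timeseries(data.frame(duration_s = 3, F_W = 4, F_N = 0,
                                        F_R = 0), dt = 1)
  expect_true(all(ts$states[, c("C_W", "C_N", "C_R")] >= 0 &
                    ts$states[, c("C_W", "C_N", "C_R")] <= 1))
})

test_that("brute-force oracle agrees with compute_metrics on toy and random input", {
  h <- hypnogram(c("WAKE", "WAKE", "NREM", "NREM", "REM", "NREM", "WAKE"), dt = 1)
  expect_equal(brute_force_metrics_oracle(h),
               as.data.frame(compute_metrics(h)))
  h1 <- hypnogram(rep("REM", 9), dt = 2)
  o <- brute_force_metrics_oracle(h1)
  expect_equal(o$episodes_REM, 1)
  expect_equal(sum(unlist(o[grep("^trans_", names(o))])), 0)
  set.seed(17)
  for (i in 1:25) {
    h <- random_hypnogram(sample(10:200, 1), dt = 1)
    expect_equal(brute_force_metrics_oracle(h),
                 as.data.frame(compute_metrics(h)))
  }
})
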