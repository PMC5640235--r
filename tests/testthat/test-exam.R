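test_that("every location finishes against a noiseless observer", {
  cfg <- small_config()
  obs <- observer_uniform(cfg$grid, 30)
  s <- run_exam(cfg, obs, seed = 1)
  expect_true(all(vapply(s$staircases, function(st) st$finished, logical(1))))
  expect_equal(nrow(s$thresholds), nrow(cfg$grid$locations))
})

test_that("identical seed and config reproduce the presentation log", {
  cfg <- small_config()
  obs <- observer_uniform(cfg$grid, 30, guess_rate = 0.1, lapse_rate = 0.05,
                          fixation_loss_prob = 0.1)
  s1 <- run_exam(cfg, obs, seed = 123)
  s2 <- run_exam(cfg, obs, seed = 123)
  expect_identical(s1$presentations, s2$presentations)
  expect_identical(s1$counters, s2$counters)
  s3 <- run_exam(cfg, obs, seed = 124)
  expect_false(identical(s1$presentations, s3$presentations))
})

test_that("check frequency [1,1] inserts one check per ordinary stimulus", {
  cfg <- small_config(check_frequency = c(1L, 1L))
  obs <- observer_uniform(cfg$grid, 30)
  s <- run_exam(cfg, obs, seed = 6)
  n_stim <- sum(s$presentations$kind == "stimulus")
  n_check <- sum(s$presentations$kind != "stimulus")
  expect_equal(n_check, n_stim)
})

test_that("check counts stay within the [floor(n/b), ceiling(n/a)] bound", {
  for (seed in 1:10) {
    cfg <- small_config(check_frequency = c(3L, 6L))
    obs <- observer_uniform(cfg$grid, 30)
    s <- run_exam(cfg, obs, seed = seed)
    n <- sum(s$presentations$kind == "stimulus")
    k <- sum(s$presentations$kind != "stimulus")
    expect_gte(k, floor(n / 6))
    expect_lte(k, ceiling(n / 3))
  }
})

test_that("inter-stimulus intervals stay inside the configured bounds", {
  cfg <- small_config(isi_min_ms = 1000, isi_max_ms = 1500)
  obs <- observer_uniform(cfg$grid, 30)
  s <- run_exam(cfg, obs, seed = 3)
  gaps <- diff(s$presentations$time_ms)
  expect_true(all(gaps >= 1000 + cfg$display_time_ms - 1e-9))
  expect_true(all(gaps <= 1500 + cfg$display_time_ms + 1e-9))
  expect_gte(s$duration_ms, sum(gaps))
})

test_that("the virtual duration counter only ever increases", {
  cfg <- small_config()
  obs <- observer_uniform(cfg$grid, 30)
  s <- run_exam(cfg, obs, seed = 4)
  expect_true(all(diff(s$presentations$time_ms) > 0))
  expect_gt(s$duration_ms, max(s$presentations$time_ms))
})

test_that("the false-positive response rate follows F/(F+P)", {
  expect_equal(false_positive_rate(list(false_positives = 0L,
                                        positives = 50L)), 0)
  expect_equal(false_positive_rate(list(false_positives = 1L,
                                        positives = 99L)), 1)
  expect_equal(false_positive_rate(list(false_positives = 10L,
                                        positives = 90L)), 10)
  expect_true(is.na(false_positive_rate(list(false_positives = 0L,
                                             positives = 0L))))
})

test_that("fixation accuracy reproduces the printed 70/78 summary cell", {
  expect_equal(round(fixation_accuracy(70, 78)), 90)
  expect_equal(fixation_accuracy(0, 10), 0)
  expect_equal(fixation_accuracy(10, 10), 100)
  expect_true(is.na(fixation_accuracy(0, 0)))
})

test_that("parameter recovery: noiseless thresholds on vector values are
           recovered exactly, off-vector within one step", {
  sc <- exact_scale()
  vec <- make_brightness_vector(0, 100, 9)
  grid <- small_grid()
  lums <- brightness_to_luminance(sc, round(vec$values))
  # truth exactly on vector luminances
  truth_idx <- c(2L, 5L, 9L, 3L, 7L, 1L, 4L, 8L)
  obs <- make_observer(lums[truth_idx])
  cfg <- small_config(grid = grid, scale = sc, vector = vec)
  s <- run_exam(cfg, obs, seed = 10)
  expect_equal(s$thresholds$luminance_cd_m2, lums[truth_idx])
  # truth strictly between vector values: estimate is the smallest vector
  # luminance at or above it (quantisation within one step)
  truth <- (lums[truth_idx] + lums[pmin(truth_idx + 1L, 9L)]) / 2
  truth[truth_idx == 9L] <- lums[9L]
  obs2 <- make_observer(truth)
  s2 <- run_exam(cfg, obs2, seed = 11)
  est <- s2$thresholds$luminance_cd_m2
  expected_idx <- vapply(truth, function(t) min(which(lums >= t)), integer(1))
  expect_equal(est, lums[expected_idx])
})

test_that("blind locations finish with no response", {
  cfg <- small_config()
  obs <- observer_hemianopia(cfg$grid, 30, blind_side = "right")
  s <- run_exam(cfg, obs, seed = 12)
  blind <- cfg$grid$locations$x_deg > 0
  expect_true(all(is.na(s$thresholds$luminance_cd_m2[blind])))
  expect_true(all(!is.na(s$thresholds$luminance_cd_m2[!blind])))
})

test_that("empirical FPRR of a gamma = 0.05 observer sits in the exact
           binomial 99% interval over 200 seeded exams", {
  cfg <- small_config(grid = generate_grid(c(20, 20), 10, 10))
  # very sensitive observer: every presented stimulus is detected, so
  # in-window guesses never fire and F is driven by the blank intervals
  f_tot <- 0L; p_tot <- 0L
  for (seed in 1:200) {
    obs <- observer_uniform(cfg$grid, 0.4, guess_rate = 0.05)
    s <- run_exam(cfg, obs, seed = seed)
    f_tot <- f_tot + s$counters$false_positives
    p_tot <- p_tot + s$counters$positives
  }
  n <- f_tot + p_tot
  # spurious responses arise once per interval at rate gamma, giving an
  # expected false fraction gamma/(1+gamma) of all responses
  p_expect <- 0.05 / 1.05
  ci <- qbinom(c(0.005, 0.995), n, p_expect)
  expect_gte(f_tot, ci[1])
  expect_lte(f_tot, ci[2])
  # and the reported rate is within a point of the nominal 5%
  expect_lt(abs(f_tot / n * 100 - 5), 1)
})

test_that("the presentation log exports with the documented columns", {
  cfg <- small_config()
  obs <- observer_uniform(cfg$grid, 30)
  s <- run_exam(cfg, obs, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_session_csv(s, path)
  d <- read.csv(path)
  expect_named(d, c("seq", "time_ms", "kind", "loc_index", "brightness_pct",
                    "luminance_cd_m2", "response", "latency_ms"))
  expect_equal(nrow(d), nrow(s$presentations))
})

test_that("config validation rejects inconsistent timing and mismatched
           observers", {
  g <- small_grid()
  sc <- exact_scale()
  vec <- make_brightness_vector(0, 100, 9)
  expect_error(exam_config(g, sc, vec, display_time_ms = 0), "positive")
  expect_error(exam_config(g, sc, vec, isi_min_ms = 100, isi_max_ms = 50),
               "isi_min_ms")
  cfg <- small_config(grid = g)
  obs_bad <- make_observer(rep(10, 3))
  expect_error(run_exam(cfg, obs_bad), "truth map")
})
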