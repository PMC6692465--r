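test_that("sample counts follow rate x duration and time is uniform", {
  p <- fitts_sim_params(block_duration = 600, sample_rate = 60, seed = 3)
  s <- simulate_fitts_session(p, 1)
  expect_equal(nrow(s), 2 * 36000)
  expect_equal(sum(s$half == 1), 36000)
  expect_equal(diff(s$time_s[1:100]), rep(1 / 60, 99), tolerance = 1e-12)
  tc <- attr(s, "true_contacts")
  expect_true(all(tc$target[tc$half == 1][-1] !=
                  head(tc$target[tc$half == 1], -1)))
})

test_that("sessions are bit-reproducible under a fixed seed", {
  p <- fitts_sim_params(block_duration = 30, seed = 77)
  a <- simulate_fitts_session(p, 2, 1, 1)
  b <- simulate_fitts_session(p, 2, 1, 1)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("a noiseless session has zero aiming variability end to end", {
  p <- fitts_sim_params(block_duration = 120, contact_noise_sd = 0,
                        cycle_period_cv = 0, hand_tremor_sd = 0, seed = 5)
  s <- simulate_fitts_session(p, 1)
  g <- attr(s, "geometry")
  for (h in 1:2) {
    lat <- project_lateral(s[s$half == h, c("hand_x", "hand_y", "hand_z")], g)
    ct <- detect_contacts(lat, 6.35, 15)
    ep <- segment_epochs(ct, 20, length(lat))
    # interior extrema: the boundary contact at t = 0 is not a turning point
    expect_equal(nrow(ct), 2 * 120 - 1)
    expect_equal(nrow(ep), (nrow(ct) %/% 2) %/% 20)
    for (e in seq_len(nrow(ep))) {
      idx <- ep$first_contact[e]:ep$last_contact[e]
      expect_equal(compute_sd_aim(ct$position[idx], ct$target[idx])$sd_aim, 0)
    }
  }
})

test_that("study assignment is a balanced 2 x 2", {
  p <- fitts_sim_params(block_duration = 16, seed = 10)
  st <- simulate_fitts_study(p)
  expect_length(st, 12)
  cond <- t(vapply(st, function(s)
    c(s$expectation[1], s$closed_eyes[nrow(s)]), numeric(2)))
  expect_equal(unname(table(cond[, 1], cond[, 2])), matrix(3, 2, 2))
  # closed eyes only ever in half 2
  for (s in st) expect_true(all(s$closed_eyes[s$half == 1] == 0))
})

test_that("session CSV round-trips through write and read", {
  p <- fitts_sim_params(block_duration = 16, seed = 11)
  s <- simulate_fitts_session(p, 3, 1, 0)
  path <- file.path(tempdir(), "session-test.csv")
  write_session_csv(s, path)
  expect_true(file.exists(sub("csv$", "json", path)))
  r <- read_session_csv(path)
  expect_s3_class(r, "fitts_session")
  expect_equal(r$hand_x, s$hand_x, tolerance = 1e-6)
  expect_equal(r$participant[1], 3)
  unlink(c(path, sub("csv$", "json", path)))
})

test_that("parameter validation rejects impossible task settings", {
  expect_error(fitts_sim_params(block_duration = -5), "block_duration")
  expect_error(fitts_sim_params(sample_rate = 0), "sample_rate")
  expect_error(fitts_sim_params(contact_noise_sd = -1), "contact_noise_sd")
  expect_error(fitts_sim_params(cascade_weight = 0.7), "cascade_weight")
})

test_that("cascade coupling raises hand nonlinearity relative to the linear null", {
  # ensemble comparison across seeded sessions: mean epoch t_MF(hand) must
  # be larger under coupling c = 2 than under c = 0
  arm <- function(cc, n = 25) {
    vapply(seq_len(n), function(i) {
      p <- fitts_sim_params(block_duration = 45, sample_rate = 30,
                            nonlinearity_coupling = cc, seed = 5000 + i)
      s <- simulate_fitts_session(p, i)
      r <- analyze_session(s, epoch_sizes = 20, n_surrogates = 8,
                           max_iter = 40, q = seq(-5, 5, 0.5),
                           seed = 6000 + i)
      mean(r$tmf_hand, na.rm = TRUE)
    }, numeric(1))
  }
  t0 <- arm(0)
  t2 <- arm(2)
  expect_gt(mean(t2), mean(t0))
})
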