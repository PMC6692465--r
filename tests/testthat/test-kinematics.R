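geom <- task_geometry(target_a = c(-12.7, 0, 0), target_b = c(12.7, 0, 0))

test_that("lateral projection is the signed displacement along the target axis", {
  expect_equal(project_lateral(matrix(c(0, 0, 0), 1), geom), 0)
  expect_equal(project_lateral(matrix(c(12.7, 0, 0), 1), geom), 12.7)
  expect_equal(project_lateral(matrix(c(-12.7, 0, 0), 1), geom), -12.7)
  # orthogonal displacement projects to zero
  expect_equal(project_lateral(matrix(c(0, 3, -2), 1), geom), 0)
  # invariant under a rotated geometry
  g2 <- task_geometry(target_a = c(0, -12.7, 1), target_b = c(0, 12.7, 1))
  expect_equal(project_lateral(matrix(c(5, 12.7, 1), 1), g2), 12.7)
  expect_error(task_geometry(c(1, 1, 1), c(1, 1, 1)), "distinct")
})

test_that("head interpoint distances match a brute-force norm computation", {
  expect_equal(head_interpoint_distances(matrix(0, 5, 3)), rep(0, 4))
  steps <- matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0), 3, 3, byrow = TRUE)
  expect_equal(head_interpoint_distances(steps), c(1, 1))
  set.seed(14)
  walk <- apply(matrix(rnorm(3000), ncol = 3), 2, cumsum)
  d <- head_interpoint_distances(walk)
  ref <- vapply(seq_len(999), function(i)
    sqrt(sum((walk[i + 1, ] - walk[i, ])^2)), numeric(1))
  expect_identical(length(d), 999L)
  expect_equal(d, ref)
  expect_error(head_interpoint_distances(walk[1, , drop = FALSE]), "2 samples")
})

test_that("contacts on a pure sinusoid are its alternating extrema", {
  tt <- seq(0, 10 - 1e-9, by = 1 / 60)           # 10 full periods
  x <- 12.7 * sin(2 * pi * tt)
  ct <- detect_contacts(x, min_prominence = 6, min_separation = 10)
  expect_equal(nrow(ct), 20)
  expect_true(all(ct$target[-1] != ct$target[-20]))
  expect_equal(max(ct$cycle), 10)
  expect_equal(detect_contacts(seq(0, 1, length.out = 100)),
               detect_contacts(seq(0, 1, length.out = 100)))  # idempotent
  expect_equal(nrow(detect_contacts(seq(0, 1, length.out = 100))), 0)
})

test_that("detected contacts track simulator ground truth", {
  # tremor-free so extremum timing is governed by the waveform alone
  p <- fitts_sim_params(block_duration = 120, hand_tremor_sd = 0, seed = 42)
  s <- simulate_fitts_session(p, 1, expectation = 1, closed_eyes_block2 = 1)
  g <- attr(s, "geometry")
  truth <- attr(s, "true_contacts")
  hits <- total <- 0
  for (h in 1:2) {
    lat <- project_lateral(s[s$half == h, c("hand_x", "hand_y", "hand_z")], g)
    ct <- detect_contacts(lat, min_prominence = 0.25 * 25.4,
                          min_separation = 15)
    th <- truth[truth$half == h, ]
    near <- vapply(ct$index, function(i) min(abs(th$index - i)), numeric(1))
    hits <- hits + sum(near <= 2)
    total <- total + nrow(ct)
  }
  expect_gte(hits / total, 0.99)
})

test_that("epoch segmentation follows floor-division arithmetic", {
  mk <- function(n_contacts) data.frame(
    index = seq(10, by = 30, length.out = n_contacts),
    position = rep(c(-12, 12), length.out = n_contacts),
    target = rep(c("A", "B"), length.out = n_contacts),
    cycle = (seq_len(n_contacts) - 1) %/% 2 + 1)
  expect_equal(nrow(segment_epochs(mk(200), 40)), 2)    # 100 cycles
  expect_equal(nrow(segment_epochs(mk(38), 20)), 0)     # 19 cycles
  ct <- mk(320)                                          # 160 cycles
  counts <- vapply(c(20, 40, 80), function(sz)
    nrow(segment_epochs(ct, sz)), numeric(1))
  expect_equal(counts, c(8, 4, 2))
  ep <- segment_epochs(ct, 20, n_samples = 12000)
  expect_true(all(diff(ep$start) > 0))
  expect_equal(ep$end[-nrow(ep)], ep$start[-1])          # contiguous, half-open
  expect_equal(ep$last_contact - ep$first_contact + 1, rep(40, 8))
  expect_warning(segment_epochs(mk(100), 25), "standard")
})

test_that("SD(Aim) pools per-target deviations with n - 1 denominator", {
  r <- compute_sd_aim(c(12.6, 12.8, -12.7, -12.7), c("A", "A", "B", "B"))
  expect_equal(r$sd_aim, sqrt((0.1^2 + 0.1^2 + 0 + 0) / 3))
  expect_false(r$flagged)
  # all contacts exactly at per-target means
  r0 <- compute_sd_aim(c(5, 5, -5, -5), c("A", "A", "B", "B"))
  expect_equal(r0$sd_aim, 0)
  # translation invariance
  pos <- c(12.4, 12.9, -12.5, -13.0, 12.6, -12.8)
  tg <- c("B", "B", "A", "A", "B", "A")
  expect_equal(compute_sd_aim(pos, tg)$sd_aim,
               compute_sd_aim(pos + 3.3, tg)$sd_aim)
  # scale equivariance of the noise component
  expect_equal(compute_sd_aim(2 * pos, tg)$sd_aim,
               2 * compute_sd_aim(pos, tg)$sd_aim)
  # fewer than 2 contacts on one target: flagged, undefined
  expect_true(compute_sd_aim(c(1, -1, 1.2), c("B", "A", "B"))$flagged)
})

test_that("short NA runs are interpolated, long runs abort", {
  x <- sin(seq(0, 20, by = 0.05))
  x[100:102] <- NA
  expect_silent(ct <- detect_contacts(x, 0.5, 5))
  expect_gt(nrow(ct), 0)
  x[200:204] <- NA
  expect_error(detect_contacts(x, 0.5, 5), "NA run")
})
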