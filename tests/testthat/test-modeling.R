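test_that("design expansion produces every reported predictor", {
  rec <- make_records(8, 2, seed = 3)
  des <- build_design(rec)
  want <- c(
    "Number(Epoch) × t_MF(Hand)",
    "Number(Epoch) × Size(Epoch) × t_MF(Hand)",
    "Closedeyes × t_MF(Head)",
    "Closedeyes × Number(Epoch) × t_MF(Head)",
    "Closedeyes × Size(Epoch) × t_MF(Head)",
    "Number(Epoch) × Size(Epoch) × t_MF(Hand) × t_MF(Head)",
    "Expectation × Number(Epoch) × Size(Epoch) × t_MF(Hand) × t_MF(Head)",
    "Expectation × Number(Epoch) × W_MF(Hand) × W_MF(Head)",
    "Number(Epoch) × Half")
  for (w in want) expect_true(w %in% des$labels, label = w)
  # main effects and control descriptives present
  for (w in c("Expectation", "Closedeyes", "t_MF(Hand)", "t_MF(Head)",
              "Mean(Head)", "SD(Head)", "Half"))
    expect_true(w %in% des$labels, label = w)
  # term columns are the products of their component columns
  i <- match("expectation:number:size:tmf_hand:tmf_head", des$terms)
  r <- des$records
  expect_equal(unname(des$x[, i]),
               r$expectation * r$number * r$size * r$tmf_hand * r$tmf_head)
})

test_that("degenerate factors are dropped with a rank warning", {
  rec <- make_records(8, 2, seed = 4)
  rec$expectation <- 0
  expect_warning(des <- build_design(rec), "aliased")
  expect_false("Expectation" %in% des$labels)
})

test_that("a noiseless linear outcome is recovered exactly", {
  rec <- make_records(8, 3, effects = list(tmf_hand = 0.5, number = -0.02),
                      participant_sd = 0.3, noise_sd = 1e-9, seed = 4)
  fit <- suppressWarnings(fit_aim_model(rec))
  co <- fit$coefficients
  expect_equal(co$estimate[co$term == "tmf_hand"], 0.5, tolerance = 1e-6)
  expect_equal(co$estimate[co$term == "number"], -0.02, tolerance = 1e-6)
  expect_equal(fit$fit_r, 1, tolerance = 1e-9)
})

test_that("model predictions are invariant to record order", {
  rec <- make_records(6, 2, effects = list(tmf_head = 0.3),
                      noise_sd = 0.05, seed = 6)
  f1 <- suppressWarnings(fit_aim_model(rec))
  set.seed(8)
  perm <- sample(nrow(rec))
  f2 <- suppressWarnings(fit_aim_model(rec[perm, ]))
  expect_equal(f2$predictions[order(perm)], f1$predictions, tolerance = 1e-8)
  expect_equal(f1$fit_r, f2$fit_r, tolerance = 1e-8)
})

test_that("record-level planted 5-way effect is recovered in sign", {
  hits <- 0
  for (r in 1:10) {
    rec <- make_records(12, 3, sizes = c(20, 40, 80),
                        effects = list("expectation:number:size:tmf_hand:tmf_head" = -1e-3),
                        noise_sd = 0.08, seed = 40 + r)
    fit <- suppressWarnings(fit_aim_model(rec))
    co <- fit$coefficients
    est <- co$estimate[co$term == "expectation:number:size:tmf_hand:tmf_head"]
    hits <- hits + (est < 0)
  }
  expect_gte(hits / 10, 0.8)
})

test_that("effect-range summary reproduces its defining arithmetic", {
  er <- summarize_effect_range(c(-0.0025, 0.0035),
                               observed_quartiles = c(0.0131, 0.0194))
  expect_equal(er$predicted_range, 0.0060, tolerance = 1e-12)
  expect_equal(er$observed_iqr, 0.0063, tolerance = 1e-12)
  expect_equal(er$coverage_pct, 100 * 0.0060 / 0.0063, tolerance = 1e-9)
  # degenerate spread is flagged
  flat <- summarize_effect_range(c(0, 1), observed_quartiles = c(0.5, 0.5))
  expect_true(flat$flagged)
  # quartiles computed from raw observations when not supplied
  set.seed(2)
  obs <- rlnorm(400, -4, 0.3)
  er2 <- summarize_effect_range(c(-0.001, 0.002), observed = obs)
  expect_equal(er2$observed_iqr,
               unname(diff(stats::quantile(obs, c(0.25, 0.75)))))
})

test_that("nonlinearity contributions span a finite range at t_MF quartiles", {
  rec <- make_records(8, 3, effects = list("number:tmf_hand" = 1e-3),
                      noise_sd = 0.05, seed = 9)
  fit <- fit_aim_model(rec)
  nc <- nonlinearity_contributions(fit)
  expect_true(is.finite(nc$range) && nc$range > 0)
  expect_length(nc$contributions, 2 * fit$n_records)
  er <- summarize_effect_range(nc$contributions, observed = rec$sd_aim)
  expect_true(is.finite(er$coverage_pct))
})

test_that("bootstrap power tables are seeded-reproducible", {
  rec <- make_records(8, 2, effects = list(closedeyes = 0.5),
                      noise_sd = 0.1, seed = 12)
  p1 <- bootstrap_power(rec, n_boot = 8, seed = 31)
  p2 <- bootstrap_power(rec, n_boot = 8, seed = 31)
  expect_identical(p1, p2)
  expect_true(all(p1$power >= 0 & p1$power <= 1, na.rm = TRUE))
})
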