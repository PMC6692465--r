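# Synthetic epoch-record tables for modeling tests: covariates drawn
# directly (no time-series pipeline), outcome assembled from a chosen set
# of planted term effects plus participant intercepts and Gaussian noise.
make_records <- function(n_participants = 12, epochs_per_size = 4,
                         sizes = c(20, 40, 80), effects = list(),
                         participant_sd = 0.2, noise_sd = 0.1, seed = 1) {
  set.seed(seed)
  cells <- expand.grid(expectation = 0:1, closed = 0:1)
  rows <- list()
  for (p in seq_len(n_participants)) {
    cond <- cells[(p - 1L) %% 4L + 1L, ]
    for (h in 1:2) for (sz in sizes) for (e in seq_len(epochs_per_size)) {
      rows[[length(rows) + 1L]] <- data.frame(
        participant = p, half = h, size = sz, number = e,
        expectation = cond$expectation,
        closedeyes = as.integer(h == 2 && cond$closed == 1),
        tmf_hand = rnorm(1), tmf_head = rnorm(1),
        w_hand = abs(rnorm(1, 1, 0.2)), w_head = abs(rnorm(1, 0.5, 0.1)),
        mean_head = abs(rnorm(1, 0.1, 0.02)), sd_head = abs(rnorm(1, 0.05, 0.01)),
        flagged = FALSE)
    }
  }
  rec <- do.call(rbind, rows)
  offs <- rnorm(n_participants, 0, participant_sd)
  y <- offs[rec$participant] + rnorm(nrow(rec), 0, noise_sd)
  for (nm in names(effects)) {
    vars <- strsplit(nm, ":", fixed = TRUE)[[1]]
    y <- y + effects[[nm]] * Reduce(`*`, lapply(vars, function(v) rec[[v]]))
  }
  rec$sd_aim <- y
  rec
}
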