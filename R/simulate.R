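#' Parameters for the simulated two-target tapping task
#'
#' Bundles every knob of the synthetic session generator. Defaults emulate
#' the reference task: 12 participants, two 10-minute blocks sampled at
#' 60 Hz, targets 25.4 cm apart, roughly one movement cycle per second
#' with mild timing jitter, and centimetre-scale contact scatter.
#'
#' The nonlinearity machinery works as follows. Each participant gets two
#' modulation depths, one for the hand and one for the head, drawn
#' independently from a log-normal distribution (\code{depth_sd} on the
#' log scale). With coupling \code{c = nonlinearity_coupling}, each depth
#' \code{d} maps to an effective cascade depth
#' \code{lambda = c d / (1 + c d)} in [0, 1). Sample-resolution binomial
#' multiplicative cascades (weight \code{cascade_weight}), normalized to
#' mean 1 and blended as \code{(1 - lambda) + lambda m}, scale the
#' innovation SD of the head sway and of a fine-scale hand tremor
#' (\code{hand_tremor_sd}), planting cross-scale multiplicative structure
#' through the whole scaling range the spectrum estimator sees. Contact
#' positional noise itself is homoscedastic, so the aiming outcome stays
#' conditionally Gaussian. At \code{c = 0} every series is linear
#' Gaussian; at \code{c > 0} hand and head fluctuations carry nonlinear
#' structure detectable as t_MF shifts.
#'
#' Condition effects are planted with signs matching the reference
#' direction. Closing the eyes inflates contact noise by
#' \code{eyes_closed_noise_factor}. Under Expectation = 1 the generator
#' measures, with the package's own spectrum/surrogate machinery, the
#' joint multifractal nonlinearity of the half it just synthesized
#' (t_MF of hand and head over consecutive 20-cycle windows, 6 internal
#' surrogates each, standardized within the half) and rescales the
#' contact aiming deviations by
#' \code{exp(-expectation_shrink * u * z(t_MF hand) * z(t_MF head))},
#' with \code{u} the fraction of the half elapsed. This is a pure
#' within-participant interaction plant: neither channel's nonlinearity
#' shifts aiming variability on its own, but windows of jointly elevated
#' hand and head nonlinearity progressively stabilize aiming under the
#' threat of losing vision — placing the planted signal specifically on
#' the Expectation x time x t_MF(Hand) x t_MF(Head) product, with no
#' t_MF main effects, matching the interaction-only structure of the
#' reference findings. Coupling the plant to the measured statistic
#' (rather than to a latent generator parameter) makes the planted
#' quantity the same quantity the recovery analysis later re-estimates
#' from the data, up to independent surrogate draws.
#'
#' @param n_participants Number of participants (default 12).
#' @param block_duration Block length in seconds (default 600).
#' @param sample_rate Sampling rate in Hz (default 60).
#' @param target_separation Distance between target centers, cm (default 25.4).
#' @param cycle_period_mean Mean movement-cycle period, seconds.
#' @param cycle_period_cv Coefficient of variation of cycle periods.
#' @param contact_noise_sd Baseline SD of contact position noise, cm.
#' @param nonlinearity_coupling Coupling c >= 0 between cascade modulation
#'   and movement variability.
#' @param hand_tremor_sd Stationary SD of the fine-scale hand tremor, cm.
#' @param head_sway_scale Stationary SD of head sway per axis, cm.
#' @param head_sway_rho AR(1) coefficient of head sway.
#' @param eyes_closed_noise_factor Multiplier on contact noise when eyes
#'   are closed (> 1 destabilizes aiming).
#' @param expectation_shrink Strength of the planted Expectation x time x
#'   nonlinearity reduction in contact noise.
#' @param depth_sd Log-scale SD of the participant modulation depth.
#' @param cascade_weight Weight of the modulation cascade, in (0, 0.5].
#' @param seed Study-level RNG seed.
#' @return A list of class \code{"fitts_sim_params"}.
#' @export
fitts_sim_params <- function(n_participants = 12,
                             block_duration = 600,
                             sample_rate = 60,
                             target_separation = 25.4,
                             cycle_period_mean = 1.0,
                             cycle_period_cv = 0.08,
                             contact_noise_sd = 1.5,
                             nonlinearity_coupling = 1,
                             hand_tremor_sd = 0.4,
                             head_sway_scale = 0.25,
                             head_sway_rho = 0.98,
                             eyes_closed_noise_factor = 1.4,
                             expectation_shrink = 0.5,
                             depth_sd = 0.75,
                             cascade_weight = 0.3,
                             seed = NULL) {
  stopifnot_scalar(block_duration, "block_duration", 0, strict_lower = TRUE)
  stopifnot_scalar(sample_rate, "sample_rate", 0, strict_lower = TRUE)
  stopifnot_scalar(target_separation, "target_separation", 0, strict_lower = TRUE)
  stopifnot_scalar(cycle_period_mean, "cycle_period_mean", 0, strict_lower = TRUE)
  stopifnot_scalar(cycle_period_cv, "cycle_period_cv", 0)
  stopifnot_scalar(contact_noise_sd, "contact_noise_sd", 0)
  stopifnot_scalar(nonlinearity_coupling, "nonlinearity_coupling", 0)
  stopifnot_scalar(hand_tremor_sd, "hand_tremor_sd", 0)
  stopifnot_scalar(head_sway_scale, "head_sway_scale", 0)
  stopifnot_scalar(head_sway_rho, "head_sway_rho", -1, 1,
                   strict_lower = TRUE, strict_upper = TRUE)
  stopifnot_scalar(cascade_weight, "cascade_weight", 0, 0.5,
                   strict_lower = TRUE)
  structure(as.list(environment()), class = "fitts_sim_params")
}

# mean-1 cascade modulation series covering at least n cycles
modulation_series <- function(n, weight, seed) {
  levels <- max(2L, ceiling(log2(n)))
  m <- binomial_cascade(levels, weight, orientation = "random", seed = seed)
  m <- m[seq_len(n)]
  m / mean(m)
}

#' Simulate one participant's tapping session
#'
#' Generates a full two-block session of the two-target tapping task:
#' the lateral hand coordinate oscillates between the targets along a
#' raised-cosine half-cycle waveform with jittered periods and noisy
#' contact positions, and the head follows a 3-D AR(1) sway process. See
#' \code{\link{fitts_sim_params}} for the planted nonlinearity and
#' condition effects.
#'
#' @param params A \code{\link{fitts_sim_params}} object.
#' @param participant_id Integer participant label.
#' @param expectation 0/1: told they might have to close their eyes.
#' @param closed_eyes_block2 0/1: actually closes eyes in the second half.
#' @return A data frame of class \code{"fitts_session"} with columns
#'   \code{time_s}, \code{hand_x}, \code{hand_y}, \code{hand_z},
#'   \code{head_x}, \code{head_y}, \code{head_z}, \code{half},
#'   \code{participant}, \code{expectation}, \code{closed_eyes}.
#'   Attributes: \code{true_contacts} (data frame: half, index, time_s,
#'   position, target, cycle), \code{geometry}, \code{params}.
#' @export
simulate_fitts_session <- function(params, participant_id = 1L,
                                   expectation = 0L, closed_eyes_block2 = 0L) {
  stopifnot(inherits(params, "fitts_sim_params"))
  p <- params
  n_samp <- round(p$block_duration * p$sample_rate)
  dt <- 1 / p$sample_rate
  pseed <- child_seed(p$seed, "participant", participant_id)
  # participant-level modulation depths -> effective cascade depths
  d_p <- with_seed(child_seed(pseed, "depth"),
                   stats::rlnorm(2, 0, p$depth_sd))
  cc <- p$nonlinearity_coupling
  lambda_hand <- cc * d_p[1] / (1 + cc * d_p[1])
  lambda_head <- cc * d_p[2] / (1 + cc * d_p[2])

  halves <- lapply(1:2, function(h) {
    closed <- as.integer(h == 2L && closed_eyes_block2 == 1L)
    hseed <- child_seed(pseed, "half", h)
    n_cyc_max <- ceiling(p$block_duration / p$cycle_period_mean * 1.5) + 4L
    blend_hand <- (1 - lambda_hand) + lambda_hand *
      modulation_series(n_samp, p$cascade_weight,
                        child_seed(hseed, "cascade-hand"))
    blend_head <- (1 - lambda_head) + lambda_head *
      modulation_series(n_samp, p$cascade_weight,
                        child_seed(hseed, "cascade-head"))
    with_seed(child_seed(hseed, "kinematics"), {
      # cycle periods with mild timing jitter
      z <- stats::rnorm(n_cyc_max)
      periods <- p$cycle_period_mean * pmax(0.3, 1 + p$cycle_period_cv * z)
      # contacts: two per cycle, alternating A (negative) and B (positive)
      n_contact <- 2L * n_cyc_max
      cyc_of_contact <- rep(seq_len(n_cyc_max), each = 2L)
      sigma <- rep(p$contact_noise_sd *
        (if (closed) p$eyes_closed_noise_factor else 1), n_contact)
      amp <- p$target_separation / 2
      sgn <- rep_len(c(-1, 1), n_contact + 1L)       # start at target A
      cpos <- sgn * amp + stats::rnorm(n_contact + 1L) * c(sigma[1], sigma)
      ctime <- c(0, cumsum(rep(periods / 2, each = 2L)))
      # sample the raised-cosine half-cycle waveform on the uniform grid
      tt <- (seq_len(n_samp) - 1L) * dt
      seg <- findInterval(tt, ctime, rightmost.closed = FALSE)
      seg[seg < 1L] <- 1L
      tau <- (tt - ctime[seg]) / (ctime[seg + 1L] - ctime[seg])
      wave <- function(cp)
        cp[seg] + (cp[seg + 1L] - cp[seg]) * (1 - cos(pi * tau)) / 2
      # fine-scale tremor with cascade-modulated variance rides on the
      # deterministic waveform
      tremor <- if (p$hand_tremor_sd > 0)
        as.numeric(stats::filter(
          stats::rnorm(n_samp) * p$hand_tremor_sd * sqrt(1 - 0.3^2) *
            blend_hand, 0.3, method = "recursive")) else 0
      hand_x <- wave(cpos) + tremor
      # small transverse wobble, task-irrelevant
      hand_y <- as.numeric(stats::filter(stats::rnorm(n_samp, sd = 0.05), 0.95,
                                         method = "recursive"))
      hand_z <- as.numeric(stats::filter(stats::rnorm(n_samp, sd = 0.05), 0.95,
                                         method = "recursive"))
      # head: 3-D AR(1) sway with cascade-modulated innovation variance
      innov_sd <- p$head_sway_scale * sqrt(1 - p$head_sway_rho^2) *
        blend_head
      head_xyz <- vapply(1:3, function(axis)
        as.numeric(stats::filter(stats::rnorm(n_samp) * innov_sd,
                                 p$head_sway_rho, method = "recursive")),
        numeric(n_samp))
      # Planted expectation effect: measure each window's joint hand/head
      # nonlinearity with the package's own t_MF machinery, then rescale
      # the contact aiming deviations by
      # exp(-shrink * u * z(t_MF hand) * z(t_MF head)).
      if (expectation == 1L && p$expectation_shrink > 0 &&
          p$nonlinearity_coupling > 0) {
        win <- 20L                        # cycles per measurement window
        headd <- sqrt(rowSums(diff(head_xyz)^2))
        n_cyc_in <- (sum(ctime <= p$block_duration) - 1L) %/% 2L
        n_win <- n_cyc_in %/% win
        if (n_win >= 3L) {
          t_win <- function(xs, policy, tag) {
            vapply(seq_len(n_win), function(wd) {
              c0 <- 2L * win * (wd - 1L) + 1L
              c1 <- min(2L * win * wd + 1L, length(ctime))
              spn <- (round(ctime[c0] / dt) + 1L):min(round(ctime[c1] / dt),
                                                      length(xs))
              tryCatch({
                x <- xs[spn]
                w_ <- cj_spectrum(x, q = seq(-5, 5, 0.5),
                                  shift_policy = policy)$width
                tmf_stat(w_, surrogate_ensemble(
                  x, 6, q = seq(-5, 5, 0.5), shift_policy = policy,
                  max_iter = 30,
                  seed = child_seed(hseed, "plant", tag, wd)), "sd")$t_mf
              }, error = function(e) NA_real_)
            }, numeric(1))
          }
          zst <- function(v) {
            s <- stats::sd(v, na.rm = TRUE)
            if (!is.finite(s) || s == 0) return(rep(0, length(v)))
            zz <- (v - mean(v, na.rm = TRUE)) / s
            zz[!is.finite(zz)] <- 0
            zz
          }
          z_joint <- zst(t_win(hand_x, "abs-increments", "hand")) *
                     zst(t_win(headd, "none", "head"))
          cyc_all <- c(1L, cyc_of_contact)            # contact 1 sits at t = 0
          win_of <- pmin(pmax(ceiling(cyc_all / win), 1L), n_win)
          u_all <- pmin((cyc_all - 0.5) /
                          (p$block_duration / p$cycle_period_mean), 1)
          # bounded so the adjusted kinematics stay realistic and the
          # covariates remain measurable on the adjusted series
          expo <- pmin(pmax(-p$expectation_shrink * u_all *
                              z_joint[win_of], -0.6), 0.6)
          f <- exp(expo)
          cpos <- sgn * amp + (cpos - sgn * amp) * f
          hand_x <- wave(cpos) + tremor
        }
      }
      # ground truth: contacts landing inside this half
      keep <- which(ctime <= tt[n_samp] + dt / 2)
      truth <- data.frame(
        half = h,
        index = pmin(round(ctime[keep] / dt) + 1L, n_samp),
        time_s = ctime[keep] + (h - 1L) * p$block_duration,
        position = cpos[keep],
        target = ifelse(sgn[keep] < 0, "A", "B"),
        cycle = (keep - 1L) %/% 2L + 1L)
      list(df = data.frame(
             time_s = tt + (h - 1L) * p$block_duration,
             hand_x = hand_x, hand_y = hand_y, hand_z = hand_z,
             head_x = head_xyz[, 1], head_y = head_xyz[, 2],
             head_z = head_xyz[, 3],
             half = h, participant = participant_id,
             expectation = as.integer(expectation),
             closed_eyes = closed),
           truth = truth)
    })
  })
  out <- rbind(halves[[1]]$df, halves[[2]]$df)
  attr(out, "true_contacts") <- rbind(halves[[1]]$truth, halves[[2]]$truth)
  attr(out, "geometry") <- task_geometry(
    target_a = c(-p$target_separation / 2, 0, 0),
    target_b = c(p$target_separation / 2, 0, 0))
  attr(out, "params") <- p
  attr(out, "lambda") <- c(hand = lambda_hand, head = lambda_head)
  class(out) <- c("fitts_session", "data.frame")
  out
}

#' Simulate a full study
#'
#' Simulates \code{n_participants} sessions with a balanced 2 x 2
#' between-participant assignment of Expectation and Eyes-Closed-in-
#' Block-2 (3 participants per cell at the default n = 12).
#'
#' @param params A \code{\link{fitts_sim_params}} object.
#' @return List of \code{\link{simulate_fitts_session}} results.
#' @export
simulate_fitts_study <- function(params) {
  stopifnot(inherits(params, "fitts_sim_params"))
  n <- params$n_participants
  cells <- expand.grid(expectation = 0:1, closed = 0:1)
  assign <- cells[rep_len(seq_len(4L), n), ]
  lapply(seq_len(n), function(i)
    simulate_fitts_session(params, participant_id = i,
                           expectation = assign$expectation[i],
                           closed_eyes_block2 = assign$closed[i]))
}

#' Write / read a simulated session as CSV
#'
#' The CSV holds the per-sample columns of the session; a JSON sidecar
#' (same path with extension \code{.json}) records the generator
#' parameters and seed so a run can be reproduced.
#'
#' @param session A \code{"fitts_session"}.
#' @param path CSV file path.
#' @return \code{write_session_csv}: \code{path}, invisibly.
#' @export
write_session_csv <- function(session, path) {
  utils::write.csv(as.data.frame(session), path, row.names = FALSE)
  prm <- attr(session, "params")
  if (!is.null(prm)) {
    side <- sub("\\.csv$", ".json", path)
    if (identical(side, path)) side <- paste0(path, ".json")
    jsonlite::write_json(unclass(prm), side, auto_unbox = TRUE, null = "null",
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_session_csv
#' @param geometry Task geometry to attach; defaults to targets 25.4 cm
#'   apart on the x axis.
#' @return \code{read_session_csv}: a \code{"fitts_session"} data frame
#'   (without ground-truth contacts).
#' @export
read_session_csv <- function(path, geometry = task_geometry()) {
  df <- utils::read.csv(path)
  need <- c("time_s", "hand_x", "hand_y", "hand_z",
            "head_x", "head_y", "head_z", "half", "participant",
            "expectation", "closed_eyes")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("session CSV is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  attr(df, "geometry") <- geometry
  class(df) <- c("fitts_session", "data.frame")
  df
}
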