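#' Per-epoch multifractal and aiming-variability records
#'
#' Runs the full per-epoch analysis on one recorded (or simulated)
#' session: projects the hand onto the inter-target axis, reduces the head
#' to its interpoint-distance series, detects contacts, cuts each half
#' into non-overlapping epochs of each requested cycle count, and for
#' every epoch computes SD(Aim), the multifractal spectrum width of the
#' hand and head series, their IAAFT surrogate ensembles and t_MF
#' statistics, and the head-sway descriptives. Epochs with undefined
#' spectra, flagged ensembles or too few contacts are kept in the table
#' with \code{flagged = TRUE} and NA covariates; modeling uses complete
#' cases.
#'
#' Epoch numbering restarts at 1 within each half (the model crosses
#' epoch number with Half); set \code{continuous_numbering = TRUE} to
#' number epochs across the whole session instead.
#'
#' @param session A \code{"fitts_session"} data frame (simulated or read
#'   from CSV) with a \code{geometry} attribute.
#' @param epoch_sizes Cycle counts per epoch (default \code{c(20, 40, 80)}).
#' @param q,r_min Spectrum configuration, see \code{\link{cj_spectrum}}.
#' @param n_surrogates Surrogates per epoch and channel (default 30).
#' @param max_iter Surrogate iteration cap, see \code{\link{iaaft_surrogate}}.
#' @param hand_policy Measure transformation for the signed lateral hand
#'   series (see \code{\link{cj_measure}}). The default
#'   \code{"abs-increments"} analyzes the magnitude of lateral velocity,
#'   which is far less dominated by the deterministic target-to-target
#'   oscillation than the min-shifted position profile;
#'   \code{"min-shift"} analyzes the raw positional profile. Head
#'   distances are already non-negative and always pass through
#'   unchanged.
#' @param se_mode Passed to \code{\link{tmf_stat}}.
#' @param min_prominence Contact-detection prominence (cm); default one
#'   quarter of the target separation.
#' @param min_separation Minimum contact spacing in samples; default one
#'   quarter of the cycle period estimated from the lateral series' mean
#'   zero-crossing interval.
#' @param continuous_numbering Number epochs across halves instead of
#'   within each half.
#' @param seed Parent seed for the surrogate generation.
#' @return Data frame with one row per (half, size, epoch): participant,
#'   half, size, number, expectation, closedeyes, sd_aim, n_contacts,
#'   w_hand, w_head, tmf_hand, tmf_head, mean_head, sd_head, flagged.
#' @export
analyze_session <- function(session, epoch_sizes = c(20, 40, 80),
                            q = seq(-5, 5, by = 0.25), r_min = 0.995,
                            n_surrogates = 30, max_iter = 100,
                            hand_policy = c("abs-increments", "min-shift"),
                            se_mode = c("sem", "sd"),
                            min_prominence = NULL, min_separation = NULL,
                            continuous_numbering = FALSE, seed = NULL) {
  se_mode <- match.arg(se_mode)
  hand_policy <- match.arg(hand_policy)
  geometry <- attr(session, "geometry")
  if (is.null(geometry)) geometry <- task_geometry()
  if (is.null(min_prominence)) min_prominence <- 0.25 * geometry$separation
  participant <- session$participant[1]
  rows <- list()
  for (h in sort(unique(session$half))) {
    sub <- session[session$half == h, , drop = FALSE]
    lateral <- project_lateral(sub[, c("hand_x", "hand_y", "hand_z")], geometry)
    headd <- head_interpoint_distances(sub[, c("head_x", "head_y", "head_z")])
    msep <- min_separation
    if (is.null(msep)) {
      cr <- sum(abs(diff(sign(lateral - mean(lateral)))) > 0)
      msep <- if (cr > 2) max(1L, floor(0.25 * 2 * length(lateral) / cr)) else 1L
    }
    contacts <- detect_contacts(lateral, min_prominence = min_prominence,
                                min_separation = msep)
    for (sz in epoch_sizes) {
      eps <- suppressWarnings(segment_epochs(contacts, sz, length(lateral)))
      for (e in seq_len(nrow(eps))) {
        idx <- eps$first_contact[e]:eps$last_contact[e]
        aim <- compute_sd_aim(contacts$position[idx], contacts$target[idx])
        span <- eps$start[e]:(eps$end[e] - 1L)
        hspan <- span[span <= length(headd)]
        hand_series <- lateral[span]
        head_series <- headd[hspan]
        eseed <- child_seed(seed, participant, h, sz, e)
        chan <- function(x, policy, tag) {
          w <- tryCatch(cj_spectrum(x, q = q, r_min = r_min,
                                    shift_policy = policy)$width,
                        error = function(err) NA_real_)
          if (!is.finite(w))
            return(list(w = NA_real_, t = NA_real_, flag = TRUE))
          ens <- surrogate_ensemble(x, n_surrogates = n_surrogates, q = q,
                                    r_min = r_min, shift_policy = policy,
                                    max_iter = max_iter,
                                    seed = child_seed(eseed, tag))
          tm <- tmf_stat(w, ens, se_mode = se_mode)
          list(w = w, t = tm$t_mf, flag = tm$flagged)
        }
        hand <- chan(hand_series, hand_policy, "hand")
        head <- chan(head_series, "none", "head")
        rows[[length(rows) + 1L]] <- data.frame(
          participant = participant, half = h, size = sz, number = e,
          expectation = sub$expectation[1], closedeyes = sub$closed_eyes[1],
          sd_aim = aim$sd_aim, n_contacts = aim$n_contacts,
          w_hand = hand$w, w_head = head$w,
          tmf_hand = hand$t, tmf_head = head$t,
          mean_head = mean(head_series), sd_head = stats::sd(head_series),
          flagged = aim$flagged || hand$flag || head$flag)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (continuous_numbering && !is.null(out)) {
    # renumber across halves within each epoch size
    for (sz in unique(out$size)) {
      sel <- out$size == sz
      ord <- order(out$half[sel], out$number[sel])
      out$number[sel][ord] <- seq_len(sum(sel))
    }
  }
  if (is.null(out))
    out <- data.frame(participant = integer(0), half = integer(0),
                      size = integer(0), number = integer(0),
                      expectation = integer(0), closedeyes = integer(0),
                      sd_aim = numeric(0), n_contacts = integer(0),
                      w_hand = numeric(0), w_head = numeric(0),
                      tmf_hand = numeric(0), tmf_head = numeric(0),
                      mean_head = numeric(0), sd_head = numeric(0),
                      flagged = logical(0))
  rownames(out) <- NULL
  out
}

#' Analyze a list of sessions into one record table
#'
#' @param sessions List of sessions (e.g. from
#'   \code{\link{simulate_fitts_study}}).
#' @param ... Passed to \code{\link{analyze_session}}.
#' @param seed Parent seed, fanned out per participant.
#' @return Row-bound record table.
#' @export
analyze_study <- function(sessions, ..., seed = NULL) {
  do.call(rbind, lapply(sessions, function(s)
    analyze_session(s, ..., seed = child_seed(seed, s$participant[1]))))
}
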