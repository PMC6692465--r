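#' Task geometry for the two-target tapping task
#'
#' @param target_a,target_b 3-D centers of the two targets (cm).
#' @param target_width Target side length (cm); default 3.81 (1.5 in).
#' @return Object of class \code{"task_geometry"} with the two centers,
#'   the midpoint, the unit axis vector (A towards B) and the separation.
#' @export
task_geometry <- function(target_a = c(-12.7, 0, 0), target_b = c(12.7, 0, 0),
                          target_width = 3.81) {
  target_a <- as.numeric(target_a); target_b <- as.numeric(target_b)
  if (length(target_a) != 3L || length(target_b) != 3L)
    stop("target centers must be 3-D", call. = FALSE)
  axis <- target_b - target_a
  sep <- sqrt(sum(axis^2))
  if (sep == 0) stop("targets must be distinct", call. = FALSE)
  structure(list(target_a = target_a, target_b = target_b,
                 midpoint = (target_a + target_b) / 2,
                 axis = axis / sep, separation = sep,
                 target_width = target_width),
            class = "task_geometry")
}

#' Lateral hand position along the inter-target axis
#'
#' Projects 3-D hand positions onto the line connecting the two targets,
#' measured from the midpoint between them: positive values lie toward
#' target B, negative toward target A. This signed one-dimensional series
#' is the hand channel for all downstream analysis.
#'
#' @param hand Numeric matrix (n x 3) or data frame of hand positions (cm).
#' @param geometry A \code{\link{task_geometry}}.
#' @return Numeric vector of signed lateral displacements (cm).
#' @export
project_lateral <- function(hand, geometry) {
  if (!inherits(geometry, "task_geometry"))
    stop("`geometry` must be a task_geometry object", call. = FALSE)
  hand <- as.matrix(hand)
  if (ncol(hand) != 3L) stop("`hand` must have 3 columns", call. = FALSE)
  drop(sweep(hand, 2L, geometry$midpoint) %*% geometry$axis)
}

#' Head interpoint Euclidean-distance series
#'
#' Reduces a 3-D head position series to the Euclidean distance between
#' each pair of consecutive positions, a non-negative one-dimensional
#' series capturing the magnitude of head sway.
#'
#' @param head Numeric matrix (n x 3) or data frame of head positions (cm).
#' @return Numeric vector of length \code{n - 1}, all values >= 0.
#' @export
head_interpoint_distances <- function(head) {
  head <- as.matrix(head)
  if (ncol(head) != 3L) stop("`head` must have 3 columns", call. = FALSE)
  if (nrow(head) < 2L)
    stop("need at least 2 samples to form distances", call. = FALSE)
  d <- diff(head)
  sqrt(rowSums(d^2))
}

# Linearly interpolate runs of <= max_run NAs; abort on longer runs.
fill_short_gaps <- function(x, max_run = 3L) {
  if (!anyNA(x)) return(x)
  r <- rle(is.na(x))
  if (any(r$values & r$lengths > max_run))
    stop(sprintf("NA run longer than %d samples; half unusable", max_run),
         call. = FALSE)
  if (is.na(x[1]) || is.na(x[length(x)]))
    stop("series begins or ends with NA; cannot interpolate", call. = FALSE)
  idx <- which(!is.na(x))
  stats::approx(idx, x[idx], xout = seq_along(x))$y
}

#' Detect alternating target contacts from the lateral series
#'
#' Contacts are operationalized as alternating extrema of the lateral
#' position series: maxima are contacts with target B, minima with target
#' A. Candidate extrema must alternate in type; between consecutive
#' candidates of the same type only the more extreme one is kept. An
#' extremum qualifies only when its excursion from the previously accepted
#' opposite extremum is at least \code{min_prominence} and it is at least
#' \code{min_separation} samples later. The cycle index increments every
#' second contact.
#'
#' @param lateral Signed lateral position series (cm). Runs of up to 3 NA
#'   samples are linearly interpolated; longer runs raise an error.
#' @param min_prominence Minimum excursion between consecutive contacts
#'   (cm); default one quarter of the peak-to-peak range.
#' @param min_separation Minimum sample spacing between contacts.
#' @return Data frame with columns \code{index} (1-based sample),
#'   \code{position} (cm), \code{target} ("A"/"B") and \code{cycle};
#'   zero rows when no extrema qualify.
#' @export
detect_contacts <- function(lateral, min_prominence = NULL, min_separation = 1L) {
  lateral <- fill_short_gaps(as.numeric(lateral))
  n <- length(lateral)
  empty <- data.frame(index = integer(0), position = numeric(0),
                      target = character(0), cycle = integer(0))
  if (n < 3 || diff(range(lateral)) == 0) return(empty)
  if (is.null(min_prominence)) min_prominence <- 0.25 * diff(range(lateral))
  d <- diff(lateral)
  # collapse plateaus so strict sign changes mark extrema
  nz <- which(d != 0)
  if (length(nz) < 2) return(empty)
  sgn <- sign(d[nz])
  turn <- which(diff(sgn) != 0)
  cand_idx <- nz[turn] + 1L          # sample at the extremum
  cand_type <- ifelse(sgn[turn] > 0, 1L, -1L)  # 1 = maximum, -1 = minimum
  keep_idx <- integer(0)
  keep_type <- integer(0)
  for (k in seq_along(cand_idx)) {
    i <- cand_idx[k]; ty <- cand_type[k]; v <- lateral[i]
    if (length(keep_idx) == 0L) {
      if (abs(v - if (ty > 0) min(lateral[1:i]) else max(lateral[1:i])) >=
          min_prominence) {
        keep_idx <- i; keep_type <- ty
      }
      next
    }
    last <- length(keep_idx)
    if (ty == keep_type[last]) {
      # same type: keep the more extreme of the two
      if ((ty > 0 && v > lateral[keep_idx[last]]) ||
          (ty < 0 && v < lateral[keep_idx[last]]))
        keep_idx[last] <- i
      next
    }
    exc <- abs(v - lateral[keep_idx[last]])
    sep_ok <- (i - keep_idx[last]) >= min_separation
    if (exc >= min_prominence && sep_ok) {
      keep_idx <- c(keep_idx, i)
      keep_type <- c(keep_type, ty)
    } else {
      # not a qualifying reversal: it may still extend the previous extremum
      prev <- if (last > 1L) keep_idx[last - 1L] else NULL
      if (!is.null(prev)) {
        pty <- keep_type[last - 1L]
        if (ty == pty &&
            ((ty > 0 && v > lateral[prev]) || (ty < 0 && v < lateral[prev])))
          keep_idx[last - 1L] <- i
      }
    }
  }
  if (length(keep_idx) == 0L) return(empty)
  data.frame(index = keep_idx,
             position = lateral[keep_idx],
             target = ifelse(keep_type > 0, "B", "A"),
             cycle = (seq_along(keep_idx) - 1L) %/% 2L + 1L)
}

#' Segment contacts into fixed-cycle epochs
#'
#' Splits a contact table into non-overlapping, contiguous epochs of
#' \code{epoch_size} movement cycles (two contacts per cycle). Trailing
#' incomplete cycles are discarded, so a half with \code{m} complete
#' cycles yields \code{floor(m / epoch_size)} epochs. Sample ranges are
#' half-open: an epoch runs from its first contact's sample up to (not
#' including) the next epoch's first contact sample; the last epoch ends
#' at \code{n_samples + 1}.
#'
#' @param contacts Contact table from \code{\link{detect_contacts}}.
#' @param epoch_size Number of cycles per epoch (20, 40 or 80 in the
#'   standard analysis; other positive values are accepted with a warning).
#' @param n_samples Total samples in the series (for the last epoch's end).
#' @return Data frame with one row per epoch: \code{number},
#'   \code{size}, \code{start}, \code{end} (half-open sample range),
#'   \code{first_contact}, \code{last_contact} (row indices into
#'   \code{contacts}).
#' @export
segment_epochs <- function(contacts, epoch_size, n_samples = NULL) {
  if (!epoch_size %in% c(20L, 40L, 80L))
    warning("epoch_size outside the standard {20, 40, 80} grid")
  if (epoch_size < 1 || epoch_size != floor(epoch_size))
    stop("`epoch_size` must be a positive integer", call. = FALSE)
  n_contacts <- nrow(contacts)
  n_cycles <- n_contacts %/% 2L
  n_epochs <- n_cycles %/% epoch_size
  if (n_epochs == 0L)
    return(data.frame(number = integer(0), size = integer(0),
                      start = integer(0), end = integer(0),
                      first_contact = integer(0), last_contact = integer(0)))
  first <- (seq_len(n_epochs) - 1L) * 2L * epoch_size + 1L
  last <- first + 2L * epoch_size - 1L
  start <- contacts$index[first]
  end <- c(start[-1L], if (is.null(n_samples)) contacts$index[last[n_epochs]] + 1L
           else n_samples + 1L)
  data.frame(number = seq_len(n_epochs), size = as.integer(epoch_size),
             start = start, end = end,
             first_contact = first, last_contact = last)
}

#' Per-epoch aiming variability SD(Aim)
#'
#' The pooled standard deviation of contact lateral positions around each
#' target's own epoch mean: deviations from the per-target means are
#' pooled over both targets and divided by \code{n - 1}, with \code{n} the
#' total number of contacts in the epoch. Per-target standard deviations
#' are returned as diagnostics.
#'
#' @param positions Contact lateral positions within one epoch (cm).
#' @param targets Parallel character vector of target labels ("A"/"B").
#' @return List with \code{sd_aim}, \code{sd_a}, \code{sd_b},
#'   \code{n_contacts}, \code{flagged} (TRUE when either target has fewer
#'   than 2 contacts, in which case \code{sd_aim} is \code{NA}).
#' @export
compute_sd_aim <- function(positions, targets) {
  stopifnot(length(positions) == length(targets))
  a <- positions[targets == "A"]
  b <- positions[targets == "B"]
  n <- length(positions)
  if (length(a) < 2L || length(b) < 2L)
    return(list(sd_aim = NA_real_, sd_a = NA_real_, sd_b = NA_real_,
                n_contacts = n, flagged = TRUE))
  dev <- c(a - mean(a), b - mean(b))
  list(sd_aim = sqrt(sum(dev^2) / (n - 1L)),
       sd_a = stats::sd(a), sd_b = stats::sd(b),
       n_contacts = n, flagged = FALSE)
}
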