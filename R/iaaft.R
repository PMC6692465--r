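#' IAAFT surrogate series
#'
#' Iterative amplitude-adjusted Fourier-transform surrogate: a reordering
#' of the original series' values that preserves the value distribution
#' exactly and the Fourier amplitude spectrum (hence the linear
#' autocorrelation) approximately, while destroying any nonlinear
#' sequential structure. Starting from a random permutation, each
#' iteration (a) imposes the original amplitude spectrum on the current
#' phases, then (b) rank-remaps the result onto the original's sorted
#' values. Iteration stops when the rank ordering no longer changes or
#' after \code{max_iter} iterations; the final step is always the rank
#' remap, so the value multiset is exact.
#'
#' @param x Numeric series of length >= 16, finite.
#' @param max_iter Maximum number of iterations (default 100).
#' @param spectrum_tol Early-stopping tolerance: iteration also stops once
#'   the surrogate's relative RMS amplitude-spectrum discrepancy from the
#'   original falls below this value (default 1e-3).
#' @param seed Optional RNG seed for the initial permutation.
#' @return Numeric vector, same length as \code{x}, with attributes
#'   \code{iterations} (iterations used) and \code{converged}.
#' @examples
#' s <- iaaft_surrogate(ar1_series(256, 0.8, seed = 1), seed = 2)
#' identical(sort(s), sort(ar1_series(256, 0.8, seed = 1)))
#' @export
iaaft_surrogate <- function(x, max_iter = 100, spectrum_tol = 1e-3,
                            seed = NULL) {
  if (!is.numeric(x) || length(x) < 16)
    stop("series must be numeric with length >= 16", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop("series must be finite and free of NAs", call. = FALSE)
  n <- length(x)
  if (diff(range(x)) == 0) {
    warning("constant series has no phase content; returning it unchanged")
    out <- x
    attr(out, "iterations") <- 0L
    attr(out, "converged") <- TRUE
    return(out)
  }
  amp <- Mod(stats::fft(x))
  sx <- sort(x)
  y <- with_seed(seed, sample(x))
  prev_rank <- integer(0)
  iter <- 0L
  converged <- FALSE
  amp_rms <- sqrt(mean(amp^2))
  while (iter < max_iter) {
    iter <- iter + 1L
    ph <- stats::fft(y)
    if (iter > 1L &&
        sqrt(mean((Mod(ph) - amp)^2)) / amp_rms < spectrum_tol) {
      converged <- TRUE
      break
    }
    ph <- ph / Mod(ph)
    ph[!is.finite(ph)] <- 1 + 0i          # zero-amplitude bins: arbitrary phase
    z <- Re(stats::fft(amp * ph, inverse = TRUE)) / n
    rk <- rank(z, ties.method = "first")
    y <- sx[rk]
    if (identical(rk, prev_rank)) {
      converged <- TRUE
      break
    }
    prev_rank <- rk
  }
  attr(y, "iterations") <- iter
  attr(y, "converged") <- converged
  y
}

# Batched IAAFT: k surrogates of x iterated together via column-wise FFTs
# (mvfft). Each column follows the same amplitude-impose / rank-remap
# iteration as iaaft_surrogate and freezes once its rank ordering repeats
# or its spectrum discrepancy drops below spectrum_tol.
iaaft_batch <- function(x, k, max_iter = 100, spectrum_tol = 1e-3,
                        seed = NULL) {
  n <- length(x)
  amp <- Mod(stats::fft(x))
  amp_rms <- sqrt(mean(amp^2))
  sx <- sort(x)
  Y <- with_seed(seed, vapply(seq_len(k), function(j) sample(x),
                              numeric(n)))
  prev <- matrix(0L, n, k)
  active <- rep(TRUE, k)
  iters <- rep(max_iter, k)
  converged <- rep(FALSE, k)
  for (iter in seq_len(max_iter)) {
    cols <- which(active)
    if (!length(cols)) break
    F <- stats::mvfft(Y[, cols, drop = FALSE])
    A <- Mod(F)
    if (iter > 1L) {
      disc <- sqrt(colMeans((A - amp)^2)) / amp_rms
      done <- disc < spectrum_tol
      if (any(done)) {
        converged[cols[done]] <- TRUE
        iters[cols[done]] <- iter
        active[cols[done]] <- FALSE
        keep <- !done
        cols <- cols[keep]
        if (!length(cols)) break
        F <- F[, keep, drop = FALSE]
        A <- A[, keep, drop = FALSE]
      }
    }
    P <- F / A
    P[!is.finite(P)] <- 1 + 0i
    Z <- Re(stats::mvfft(amp * P, inverse = TRUE)) / n
    for (j in seq_along(cols)) {
      rk <- rank(Z[, j], ties.method = "first")
      Y[, cols[j]] <- sx[rk]
      if (identical(rk, prev[, cols[j]])) {
        converged[cols[j]] <- TRUE
        iters[cols[j]] <- iter
        active[cols[j]] <- FALSE
      } else {
        prev[, cols[j]] <- rk
      }
    }
  }
  list(series = Y, iterations = iters, converged = converged)
}

#' Surrogate ensemble of multifractal spectrum widths
#'
#' Generates \code{n_surrogates} independent IAAFT surrogates of a series
#' and computes each one's multifractal spectrum width with exactly the
#' same estimator configuration as used for the original. Surrogates whose
#' width is undefined (too few retained moment orders) are dropped and
#' counted; the ensemble is flagged when more than 20\% drop.
#'
#' @param x Numeric series.
#' @param n_surrogates Number of surrogates, >= 2 (default 30).
#' @param q,r_min,shift_policy Spectrum configuration passed to
#'   \code{\link{cj_spectrum}}; must match the original's.
#' @param max_iter,spectrum_tol Passed to \code{\link{iaaft_surrogate}}.
#' @param seed Parent seed; each surrogate gets an independent derived seed.
#' @param keep_series Keep the surrogate series themselves (default FALSE).
#' @return Object of class \code{"surrogate_ensemble"}: list with
#'   \code{widths} (defined widths), \code{n_surrogates}, \code{n_dropped},
#'   \code{flagged}, \code{mean}, \code{sd}, \code{se} (\code{sd/sqrt(n)}),
#'   \code{iterations}, and optionally \code{series}.
#' @export
surrogate_ensemble <- function(x, n_surrogates = 30,
                               q = seq(-5, 5, by = 0.25), r_min = 0.995,
                               shift_policy = "min-shift",
                               max_iter = 100, spectrum_tol = 1e-3,
                               seed = NULL, keep_series = FALSE) {
  if (!is.numeric(n_surrogates) || n_surrogates < 2)
    stop("`n_surrogates` must be >= 2", call. = FALSE)
  n_surrogates <- as.integer(n_surrogates)
  if (anyNA(x) || any(!is.finite(x)))
    stop("series must be finite and free of NAs", call. = FALSE)
  batch <- iaaft_batch(x, n_surrogates, max_iter = max_iter,
                       spectrum_tol = spectrum_tol,
                       seed = child_seed(seed, "surrogates"))
  widths <- vapply(seq_len(n_surrogates), function(k)
    cj_spectrum(batch$series[, k], q = q, r_min = r_min,
                shift_policy = shift_policy)$width, numeric(1))
  iters <- batch$iterations
  series <- if (keep_series)
    lapply(seq_len(n_surrogates), function(k) batch$series[, k]) else NULL
  defined <- widths[is.finite(widths)]
  n_drop <- n_surrogates - length(defined)
  structure(list(
    widths = defined,
    n_surrogates = n_surrogates,
    n_dropped = n_drop,
    flagged = n_drop > 0.2 * n_surrogates || length(defined) < 2,
    mean = if (length(defined)) mean(defined) else NA_real_,
    sd = if (length(defined) > 1) stats::sd(defined) else NA_real_,
    se = if (length(defined) > 1) stats::sd(defined) / sqrt(length(defined))
         else NA_real_,
    iterations = iters,
    series = series
  ), class = "surrogate_ensemble")
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf(
    "IAAFT surrogate ensemble: %d surrogates (%d dropped%s)\n  width mean = %.4g, sd = %.4g\n",
    x$n_surrogates, x$n_dropped, if (x$flagged) ", FLAGGED" else "",
    x$mean, x$sd))
  invisible(x)
}
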