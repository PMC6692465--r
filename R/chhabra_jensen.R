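#' Dyadic bin lengths for direct spectrum estimation
#'
#' Bin (scale) lengths used by the direct multifractal estimator: powers of
#' two from 4 samples up to the largest power of two not exceeding a
#' quarter of the series length. At each scale the series is cut into
#' \code{floor(n / L)} full bins and the remaining tail samples are
#' discarded, so bin proportions are comparable across scales.
#'
#' @param n Series length, >= 16.
#' @return Integer vector of bin lengths.
#' @examples
#' cj_scales(1024)  # 4 8 16 32 64 128 256
#' @export
cj_scales <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 16 || n != floor(n))
    stop("series too short for multifractal analysis (need n >= 16)",
         call. = FALSE)
  as.integer(2^(2:floor(log2(n / 4))))
}

#' Convert a series to a normalized non-negative measure
#'
#' The direct estimator bins a non-negative measure, but movement series
#' are signed. \code{"min-shift"} (default) maps the series affinely to
#' non-negative values, \code{x - min(x) + eps} with
#' \code{eps = 1e-6 * diff(range(x))}, preserving the profile's spatial
#' heterogeneity; \code{"abs-increments"} uses \code{|diff(x)|};
#' \code{"none"} requires an already non-negative series (e.g. a head
#' interpoint-distance series). All policies end by normalizing to unit
#' sum.
#'
#' @param x Numeric series, finite, non-constant after transformation.
#' @param shift_policy One of \code{"min-shift"}, \code{"abs-increments"},
#'   \code{"none"}.
#' @return Non-negative numeric vector summing to 1.
#' @export
cj_measure <- function(x, shift_policy = c("min-shift", "abs-increments", "none")) {
  shift_policy <- match.arg(shift_policy)
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("series must be finite and free of NAs", call. = FALSE)
  m <- switch(shift_policy,
    "min-shift" = {
      rng <- diff(range(x))
      x - min(x) + 1e-6 * rng
    },
    "abs-increments" = abs(diff(x)),
    "none" = {
      if (any(x < 0))
        stop("shift_policy = \"none\" requires a non-negative series",
             call. = FALSE)
      x
    }
  )
  tot <- sum(m)
  if (tot <= 0 || diff(range(m)) == 0 && all(m == 0))
    stop("degenerate measure: series has no mass after transformation",
         call. = FALSE)
  m / tot
}

#' Direct (Chhabra-Jensen) multifractal spectrum
#'
#' Estimates the multifractal spectrum of a series by direct mass-weighted
#' binning. The series is converted to a unit-mass measure
#' (\code{\link{cj_measure}}) and partitioned at dyadic scales
#' (\code{\link{cj_scales}}). At each scale \code{L} the bin proportions
#' \eqn{P_i(L)} are raised to the moment order \code{q} and normalized
#' into mass weights \eqn{\mu_i(q,L) = P_i(L)^q / \sum_j P_j(L)^q}. The
#' singularity strength \eqn{\alpha(q)} is the ordinary least-squares
#' slope of \eqn{\sum_i \mu_i \ln P_i} against \eqn{\ln L}, and the
#' singularity dimension \eqn{f(q)} the slope of
#' \eqn{\sum_i \mu_i \ln \mu_i} against \eqn{\ln L}. A moment order is
#' retained only when both log-log fits correlate at \code{|r| >= r_min}
#' and all summands are finite; the spectrum width \code{width} is the
#' range of \eqn{\alpha(q)} over retained orders.
#'
#' @param x Numeric series (>= 16 samples).
#' @param q Moment-order grid; default \code{seq(-5, 5, by = 0.25)}.
#' @param r_min Minimum absolute Pearson correlation for both log-log fits;
#'   default 0.995.
#' @param shift_policy Measure transformation, see \code{\link{cj_measure}}.
#' @return An object of class \code{"cj_spectrum"}: a list with elements
#'   \code{q}, \code{alpha}, \code{f}, \code{r_alpha}, \code{r_f},
#'   \code{retained} (logical mask), \code{width} (\code{NA} and
#'   \code{flagged = TRUE} when fewer than 2 orders are retained),
#'   \code{scales}, \code{n}.
#' @examples
#' w <- cj_spectrum(binomial_cascade(12, 0.3))$width
#' @export
cj_spectrum <- function(x, q = seq(-5, 5, by = 0.25), r_min = 0.995,
                        shift_policy = c("min-shift", "abs-increments", "none")) {
  mu0 <- cj_measure(x, match.arg(shift_policy))
  n <- length(mu0)
  scales <- cj_scales(n)
  if (length(scales) < 3)
    warning("fewer than 3 scales available; spectrum fits are unreliable")
  nq <- length(q)
  # per-scale accumulators of the two mass-weighted log sums
  num_alpha <- matrix(NA_real_, length(scales), nq)  # sum mu * ln P
  num_f     <- matrix(NA_real_, length(scales), nq)  # sum mu * ln mu
  for (s in seq_along(scales)) {
    L <- scales[s]
    nbin <- n %/% L
    P <- .colSums(mu0[seq_len(nbin * L)], L, nbin)
    P <- P / sum(P)                      # renormalize after tail truncation
    pos <- P > 0
    lnP <- log(P[pos])
    # mass weights mu_i(q, L) for the whole q grid at once:
    # exp(q * lnP) column-normalized, computed via shifted logs for stability
    M <- outer(lnP, q)                   # nbin_pos x nq
    shift <- ifelse(q >= 0, max(lnP), min(lnP)) * q   # per-column max of M
    M <- sweep(M, 2L, shift)
    W <- exp(M)
    W <- sweep(W, 2L, colSums(W), "/")
    num_alpha[s, ] <- colSums(W * lnP)
    lw <- W * log(W)
    lw[W == 0] <- 0
    num_f[s, ] <- colSums(lw)
  }
  lnL <- log(scales)
  lc <- lnL - mean(lnL)
  ssl <- sum(lc^2)
  # vectorized OLS slope and Pearson r of each column against lnL
  fit_cols <- function(Y) {
    yc <- sweep(Y, 2L, colMeans(Y))
    sl <- colSums(yc * lc) / ssl
    r <- colSums(yc * lc) / sqrt(ssl * colSums(yc^2))
    rbind(sl, r)
  }
  fa <- fit_cols(num_alpha)
  ff <- fit_cols(num_f)
  alpha <- fa[1L, ]; r_alpha <- fa[2L, ]
  f <- ff[1L, ];     r_f <- ff[2L, ]
  finite_ok <- colSums(!is.finite(num_alpha)) == 0L &
               colSums(!is.finite(num_f)) == 0L
  retained <- finite_ok & is.finite(r_alpha) & is.finite(r_f) &
              abs(r_alpha) >= r_min & abs(r_f) >= r_min
  width <- if (sum(retained) >= 2) {
    max(alpha[retained]) - min(alpha[retained])
  } else NA_real_
  structure(list(q = q, alpha = alpha, f = f,
                 r_alpha = r_alpha, r_f = r_f,
                 retained = retained, width = width,
                 flagged = !is.finite(width) || sum(retained) < 2,
                 scales = scales, n = n),
            class = "cj_spectrum")
}

#' @export
print.cj_spectrum <- function(x, ...) {
  cat(sprintf(
    "Direct multifractal spectrum: n = %d, %d scales (%d..%d), %d/%d q retained\n",
    x$n, length(x$scales), min(x$scales), max(x$scales),
    sum(x$retained), length(x$q)))
  cat(sprintf("  width = %s%s\n",
              format(x$width, digits = 4),
              if (x$flagged) " [flagged: undefined]" else ""))
  invisible(x)
}

#' Export a spectrum to a data frame
#'
#' One row per moment order with the fitted exponents, fit correlations
#' and retention mask; suitable for CSV export.
#'
#' @param x A \code{"cj_spectrum"} object.
#' @param row.names,optional,... Passed through (ignored).
#' @export
as.data.frame.cj_spectrum <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(q = x$q, alpha = x$alpha, f = x$f,
             r_alpha = x$r_alpha, r_f = x$r_f, retained = x$retained)
}
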