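#' Binomial multiplicative cascade
#'
#' Generates the canonical multifractal calibration series: unit mass is
#' split recursively, each interval passing proportion \code{weight_p} of
#' its mass to one half and \code{1 - weight_p} to the other, for
#' \code{levels} refinements. The result is a non-negative series of length
#' \code{2^levels} that sums to 1 and has a closed-form singularity
#' spectrum (see \code{\link{cascade_alpha}}), making it the standard
#' oracle for multifractal estimators.
#'
#' @param levels Integer >= 2; the series length is \code{2^levels}.
#' @param weight_p Proportion in (0, 1) assigned to the left half of each
#'   interval (or to a randomly chosen half, see \code{orientation}).
#' @param orientation \code{"left"} (default) always gives \code{weight_p}
#'   to the left half, so the series is fully deterministic;
#'   \code{"random"} flips a fair coin at every split, which randomises
#'   the series ordering without changing its multifractal spectrum.
#' @param seed RNG seed used only when \code{orientation = "random"}.
#' @return Numeric vector of length \code{2^levels}, non-negative,
#'   summing to 1.
#' @examples
#' x <- binomial_cascade(10, 0.3)
#' sum(x)  # 1
#' @export
binomial_cascade <- function(levels, weight_p, orientation = c("left", "random"),
                             seed = NULL) {
  orientation <- match.arg(orientation)
  if (!is.numeric(levels) || length(levels) != 1L || levels < 2 ||
      levels != floor(levels))
    stop("`levels` must be an integer >= 2", call. = FALSE)
  stopifnot_scalar(weight_p, "weight_p", 0, 1,
                   strict_lower = TRUE, strict_upper = TRUE)
  levels <- as.integer(levels)
  build <- function() {
    x <- 1
    for (l in seq_len(levels)) {
      n <- length(x)
      p_left <- if (orientation == "left") rep(weight_p, n)
                else ifelse(stats::runif(n) < 0.5, weight_p, 1 - weight_p)
      left <- x * p_left
      right <- x - left
      # interleave left/right children
      x <- as.vector(rbind(left, right))
    }
    x
  }
  if (orientation == "random") with_seed(seed, build()) else build()
}

#' Closed-form singularity strength of the binomial cascade
#'
#' For a binomial cascade with weight \code{p}, the Legendre-transform
#' singularity strength at moment order \code{q} is
#' \deqn{\alpha(q) = -\frac{p^q \ln p + (1-p)^q \ln(1-p)}
#'                        {(p^q + (1-p)^q)\,\ln 2}.}
#' The analytic spectrum width over a grid \code{q} is
#' \code{max(alpha) - min(alpha)}; since \eqn{\alpha(q)} is non-increasing
#' this equals \code{cascade_alpha(min(q), p) - cascade_alpha(max(q), p)}.
#'
#' @param q Numeric vector of moment orders.
#' @param p Cascade weight in (0, 1).
#' @return \code{cascade_alpha}: the vector \eqn{\alpha(q)}.
#' @export
cascade_alpha <- function(q, p) {
  stopifnot_scalar(p, "p", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  -(p^q * log(p) + (1 - p)^q * log(1 - p)) / ((p^q + (1 - p)^q) * log(2))
}

#' @rdname cascade_alpha
#' @return \code{cascade_width_analytic}: the analytic spectrum width over
#'   the grid \code{q}.
#' @export
cascade_width_analytic <- function(p, q = seq(-5, 5, by = 0.25)) {
  a <- cascade_alpha(q, p)
  max(a) - min(a)
}

#' Stationary AR(1) Gaussian series
#'
#' Linear-Gaussian null series for surrogate-test calibration: an order-1
#' autoregressive process \eqn{x_t = \phi x_{t-1} + \epsilon_t} with
#' standard-normal innovations, initialised from its stationary
#' distribution.
#'
#' @param n Series length, >= 16.
#' @param phi AR(1) coefficient, |phi| < 1.
#' @param innov_sd Innovation standard deviation.
#' @param seed Optional RNG seed for reproducibility.
#' @return Numeric vector of length \code{n}.
#' @export
ar1_series <- function(n, phi = 0, innov_sd = 1, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 16 || n != floor(n))
    stop("`n` must be an integer >= 16", call. = FALSE)
  stopifnot_scalar(phi, "phi", -1, 1, strict_lower = TRUE, strict_upper = TRUE)
  stopifnot_scalar(innov_sd, "innov_sd", 0)
  with_seed(seed, {
    e <- stats::rnorm(n, sd = innov_sd)
    x <- numeric(n)
    x[1] <- e[1] / sqrt(1 - phi^2)
    if (phi == 0) x <- e
    else for (t in 2:n) x[t] <- phi * x[t - 1] + e[t]
    x
  })
}
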