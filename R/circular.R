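#' Circular mean of a set of phases
#'
#' The argument of the resultant of the unit phasors: `arg(sum(exp(1i * x)))`.
#' When the phasors cancel (resultant length below `tol`) the circular mean is
#' undefined; the function then throws an error, which callers that work
#' window-by-window translate into an invalid window.
#'
#' @param phases numeric vector of phases in radians.
#' @param tol resultant-length threshold below which the mean is declared
#'   undefined. Default `1e-9`.
#' @return a single phase in `(-pi, pi]`.
#' @examples
#' circular_mean(c(0, pi / 2)) # pi / 4
#' @export
circular_mean <- function(phases, tol = 1e-9) {
  stopifnot(is.numeric(phases), length(phases) > 0L)
  z <- sum(exp(1i * phases))
  if (Mod(z) / length(phases) < tol) {
    stop("circular mean undefined: phasors cancel (resultant length ~ 0)",
         call. = FALSE)
  }
  Arg(z)
}

#' Circular correlation between two phase series
#'
#' The Jammalamadaka-SenGupta circular correlation coefficient
#' \deqn{\rho = \frac{\sum_k \sin(\theta_k - \bar\theta)\sin(\phi_k - \bar\phi)}
#'   {\sqrt{\sum_k \sin^2(\theta_k - \bar\theta)\,\sum_k \sin^2(\phi_k - \bar\phi)}}}
#' with \eqn{\bar\theta,\bar\phi} the circular means. This is the standard
#' correlation coefficient for angular data: it is 1 for identical series, -1
#' for a series and its reflection, symmetric in its arguments, bounded in
#' \eqn{[-1, 1]}, and invariant to adding a constant offset to either series.
#'
#' Pairs where either phase is `NA` are dropped. If either series is
#' phase-constant (degenerate denominator) or a circular mean is undefined the
#' coefficient is undefined and `NA` is returned (never 0).
#'
#' @param theta,phi numeric vectors of phases in radians, equal length.
#' @param min_n minimum number of valid pairs required (default 10).
#' @return a scalar in `[-1, 1]`, or `NA` if undefined.
#' @examples
#' th <- runif(100, -pi, pi)
#' circular_correlation(th, th) # 1
#' @export
circular_correlation <- function(theta, phi, min_n = 10L) {
  stopifnot(length(theta) == length(phi))
  ok <- !is.na(theta) & !is.na(phi)
  theta <- theta[ok]
  phi <- phi[ok]
  if (length(theta) < min_n) return(NA_real_)
  tbar <- tryCatch(circular_mean(theta), error = function(e) NA_real_)
  pbar <- tryCatch(circular_mean(phi), error = function(e) NA_real_)
  if (is.na(tbar) || is.na(pbar)) return(NA_real_)
  st <- sin(theta - tbar)
  sp <- sin(phi - pbar)
  den <- sqrt(sum(st^2) * sum(sp^2))
  if (den < 1e-12) return(NA_real_)
  sum(st * sp) / den
}

#' Wrap phases into (-pi, pi]
#' @param x numeric vector of angles in radians.
#' @return wrapped angles.
#' @keywords internal
wrap_phase <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}
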