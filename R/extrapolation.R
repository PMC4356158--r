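#' Extrapolate cumulative fitness gain from the adaptability slope
#'
#' If excess gains scale log-log-linearly with the fitness deficit with
#' slope magnitude \eqn{\beta}, then each successive fitting interval's
#' log-fitness gain shrinks geometrically by a factor \eqn{(1-\beta)},
#' giving the closed-form trajectory
#' \deqn{\ln(w_t/w_0) = \ln(w_1/w_0) \, (1 - (1-\beta)^t) / \beta}
#' where \eqn{\ln(w_1/w_0)} is the gain over the first interval.  For
#' \eqn{\beta \in (0,1)} the cumulative gain increases monotonically to
#' the plateau \eqn{\ln(w_1/w_0)/\beta}; for \eqn{\beta \in (1,2)} it
#' oscillates toward the same plateau.  Outside \eqn{(0,2)} the
#' geometric series diverges and the extrapolation is undefined.
#'
#' The time unit of \eqn{t} is the interval over which the first gain
#' was measured (abstract "fitting intervals", not necessarily single
#' generations).
#'
#' @param beta slope magnitude, in (0, 2).
#' @param first_gain log-fitness gain \eqn{\ln(w_1/w_0)} over the first
#'   interval.
#' @param t non-negative integer time (vectorized).
#' @return \code{forecast_gain}: cumulative log-gain \eqn{\ln(w_t/w_0)}
#'   at each \code{t}; \code{plateau_gain}: the \eqn{t \to \infty}
#'   limit \eqn{first\_gain/\beta}.
#' @export
#' @examples
#' forecast_gain(0.5, 0.1, 0:3)   # 0, 0.1, 0.15, 0.175
#' plateau_gain(0.5, 0.1)         # 0.2
forecast_gain <- function(beta, first_gain, t) {
  check_beta(beta)
  if (!is.numeric(first_gain) || length(first_gain) != 1 ||
      !is.finite(first_gain))
    stop("first_gain must be a single finite number")
  if (any(t < 0) || any(t != floor(t)))
    stop("t must be non-negative integer(s)")
  # (1 - (1-beta)^t) / beta; the expm1 form is used below 1 for
  # stability as beta -> 0, the direct form above 1 where (1-beta) < 0
  # (t is integer, so the sign is well defined)
  out <- if (beta < 1) first_gain * -expm1(t * log1p(-beta)) / beta
         else first_gain * (1 - (1 - beta)^t) / beta
  out[t == 0] <- 0
  out
}

#' @rdname forecast_gain
#' @export
plateau_gain <- function(beta, first_gain) {
  check_beta(beta)
  first_gain / beta
}

check_beta <- function(beta) {
  if (!is.numeric(beta) || length(beta) != 1 || !is.finite(beta) ||
      beta <= 0 || beta >= 2)
    stop("beta must lie in the open interval (0, 2); ",
         "outside it the per-interval gains do not converge")
  invisible(beta)
}

#' Tabulate a forecast trajectory
#'
#' Convenience wrapper producing the (t, cumulative gain) table plus the
#' plateau, ready to write as TSV.
#'
#' @inheritParams forecast_gain
#' @param horizon last time step to tabulate.
#' @return A data frame with columns \code{t} and
#'   \code{cumulative_gain}; the plateau is attached as attribute
#'   \code{"plateau"}.
#' @export
forecast_table <- function(beta, first_gain, horizon) {
  t <- 0:horizon
  out <- data.frame(t = t,
                    cumulative_gain = forecast_gain(beta, first_gain, t))
  attr(out, "plateau") <- plateau_gain(beta, first_gain)
  out
}
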