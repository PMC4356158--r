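#' Fit the log-log-linear adaptability model
#'
#' Ordinary least squares of \eqn{\ln y} on \eqn{\ln(-x)} over the
#' standardized points: excess per-generation log-gain \eqn{y} against
#' initial per-generation log-deficit magnitude \eqn{|x|}, both in
#' natural-log units.  The fitted slope is the adaptability exponent;
#' its absolute value is reported as \eqn{\beta}, the quantity that
#' drives the trajectory extrapolation ([forecast_gain()]).
#'
#' Points that cannot enter the double-log transform are excluded and
#' logged, never dropped silently: the reference point (\eqn{x = 0}) and
#' any point with \eqn{y \le 0} (a genotype that gained no more than the
#' reference).
#'
#' @param points a \code{standardized_points} data frame (columns
#'   \code{genotype_id}, \code{x}, \code{y}).
#' @return A \code{regression_result} list: \code{model_form},
#'   \code{slope}, \code{intercept}, \code{beta} (\eqn{|slope|}),
#'   \code{r}, \code{r_squared}, \code{f_pvalue}, \code{n_used},
#'   \code{excluded} (data frame of \code{genotype_id}, \code{reason}),
#'   and the underlying \code{lm} fit.
#' @export
#' @examples
#' pts <- data.frame(genotype_id = letters[1:5],
#'                   x = -c(0.001, 0.002, 0.003, 0.004, 0.005))
#' pts$y <- exp(0.5) * (-pts$x)^0.87
#' pts$reference_flag <- FALSE
#' fit_loglog(pts)$beta   # 0.87
fit_loglog <- function(points) {
  check_points(points)
  excl <- exclusion_log(points, drop_x_zero = TRUE)
  use <- !(points$genotype_id %in% excl$genotype_id)
  n_used <- sum(use)
  if (n_used < 3)
    stop("insufficient data: ", n_used,
         " eligible points (need >= 3 with x < 0 and y > 0)")
  fit <- stats::lm(log(y) ~ log(-x), data = points[use, ])
  regression_result("loglog", fit, n_used, excl)
}

#' Fit the exponential adaptability model
#'
#' Ordinary least squares of \eqn{\ln y} on \eqn{x} (i.e.
#' \eqn{y = A e^{bx}}).  Points with \eqn{y \le 0} are excluded and
#' logged; \eqn{x = 0} is eligible here.
#'
#' @inheritParams fit_loglog
#' @return A \code{regression_result}; see [fit_loglog()].
#' @export
fit_exponential <- function(points) {
  check_points(points)
  excl <- exclusion_log(points, drop_x_zero = FALSE)
  use <- !(points$genotype_id %in% excl$genotype_id)
  n_used <- sum(use)
  if (n_used < 3)
    stop("insufficient data: ", n_used,
         " eligible points (need >= 3 with y > 0)")
  fit <- stats::lm(log(y) ~ x, data = points[use, ])
  regression_result("exponential", fit, n_used, excl)
}

#' Fit both adaptability models and pick the better one
#'
#' Fits [fit_loglog()] and [fit_exponential()] on the same points and
#' prefers the form with the higher \eqn{r^2}; exact ties go to the
#' log-log form and are flagged.
#'
#' @inheritParams fit_loglog
#' @return A list with elements \code{loglog}, \code{exponential},
#'   \code{preferred} (\code{"loglog"} or \code{"exponential"}) and
#'   \code{tie} (logical).
#' @export
compare_fits <- function(points) {
  ll <- fit_loglog(points)
  ex <- fit_exponential(points)
  tie <- ll$r_squared == ex$r_squared
  list(loglog = ll, exponential = ex,
       preferred = if (ex$r_squared > ll$r_squared) "exponential"
                   else "loglog",
       tie = tie)
}

check_points <- function(points) {
  if (!is.data.frame(points) ||
      !all(c("genotype_id", "x", "y") %in% names(points)))
    stop("points must be a data frame with genotype_id, x and y columns")
  if (any(points$x > 0))
    stop("standardized deficits x must be <= 0")
  invisible(points)
}

exclusion_log <- function(points, drop_x_zero) {
  reasons <- character(0)
  ids <- character(0)
  if (drop_x_zero) {
    at_ref <- points$x == 0
    ids <- c(ids, points$genotype_id[at_ref])
    reasons <- c(reasons,
                 rep("x = 0 (reference deficit), log(-x) undefined",
                     sum(at_ref)))
  } else {
    at_ref <- rep(FALSE, nrow(points))
  }
  bad_y <- points$y <= 0 & !at_ref
  ids <- c(ids, points$genotype_id[bad_y])
  reasons <- c(reasons,
               rep("y <= 0 (no excess gain), log(y) undefined",
                   sum(bad_y)))
  data.frame(genotype_id = ids, reason = reasons,
             stringsAsFactors = FALSE)
}

regression_result <- function(model_form, fit, n_used, excluded) {
  # summary.lm warns on noise-free ("essentially perfect") fits, which
  # are a legitimate calibration case here
  sm <- suppressWarnings(summary(fit))
  slope <- unname(stats::coef(fit)[2])
  fstat <- sm$fstatistic
  f_p <- if (is.null(fstat)) NA_real_ else
    unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  structure(list(
    model_form = model_form,
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    beta = abs(slope),
    r = sign(slope) * sqrt(sm$r.squared),
    r_squared = sm$r.squared,
    f_pvalue = f_p,
    n_used = n_used,
    excluded = excluded,
    fit = fit
  ), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat("<regression_result>", x$model_form, "fit of ln(y) on",
      if (x$model_form == "loglog") "ln(-x)" else "x", "\n")
  cat(sprintf("  slope = %.6g (beta = %.6g), intercept = %.6g\n",
              x$slope, x$beta, x$intercept))
  cat(sprintf("  r = %.4f, r^2 = %.4f, F-test p = %.3g, n = %d\n",
              x$r, x$r_squared, x$f_pvalue, x$n_used))
  if (nrow(x$excluded))
    cat("  excluded:", nrow(x$excluded), "point(s):",
        paste(x$excluded$genotype_id, collapse = ", "), "\n")
  invisible(x)
}

#' Write a regression report as JSON
#'
#' @param result a \code{regression_result} or the list returned by
#'   [compare_fits()].
#' @param path output file.
#' @return The input, invisibly.
#' @export
write_regression_report <- function(result, path) {
  strip <- function(r) {
    r$fit <- NULL
    unclass(r)
  }
  out <- if (inherits(result, "regression_result")) strip(result)
    else {
      result$loglog <- strip(result$loglog)
      result$exponential <- strip(result$exponential)
      result
    }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(result)
}
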