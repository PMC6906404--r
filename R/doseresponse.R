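#' Through-origin linear yield fit
#'
#' Least-squares slope of mean counts per cell against dose for a line through
#' the origin: \eqn{m = \sum D N / \sum D^2}.
#'
#' @param doses doses in Gy (>= 2 points, not all zero).
#' @param mean_counts mean counts per cell at each dose.
#' @param endpoint label, e.g. \code{"DSB"} or \code{"cDSB"}.
#' @return object of class \code{yield_fit}: slope (per Gy per cell), its
#'   standard error and the endpoint label.
#' @examples
#' fit_yield(c(0.5, 1), 30.1 * c(0.5, 1))$slope
#' @export
fit_yield <- function(doses, mean_counts, endpoint = "DSB") {
  .check_doses(doses, mean_counts)
  m <- sum(doses * mean_counts) / sum(doses^2)
  res <- mean_counts - m * doses
  dfree <- length(doses) - 1L
  se <- if (dfree > 0) sqrt(sum(res^2) / dfree / sum(doses^2)) else NA_real_
  structure(list(slope = m, se = se, endpoint = endpoint),
            class = "yield_fit")
}

.check_doses <- function(doses, y) {
  if (length(doses) < 2)
    stop("dose-response fits need at least 2 dose points", call. = FALSE)
  if (length(doses) != length(y))
    stop("doses and responses differ in length", call. = FALSE)
  if (any(doses < 0)) stop("doses must be >= 0", call. = FALSE)
  if (all(doses == 0)) stop("all doses are zero", call. = FALSE)
  invisible(TRUE)
}

# unweighted least squares of y on (D, D^2) without intercept; refit to the
# pure quadratic when the linear coefficient is negative (strict < 0)
.lq_ls <- function(doses, y) {
  X <- cbind(doses, doses^2)
  fit <- stats::lm.fit(X, y)
  alpha <- unname(fit$coefficients[1])
  beta <- unname(fit$coefficients[2])
  refit <- FALSE
  if (is.na(alpha) || alpha < 0) {
    beta <- sum(doses^2 * y) / sum(doses^4)
    alpha <- 0
    refit <- TRUE
  }
  list(alpha = alpha, beta = beta, refit = refit)
}

#' Linear-quadratic fit of mean counts per cell
#'
#' Unweighted least squares of \eqn{N = \alpha D + \beta D^2}; if the fitted
#' \eqn{\alpha < 0} the fit is re-performed as a pure quadratic
#' (\eqn{N = \beta D^2}) and flagged.
#'
#' @inheritParams fit_yield
#' @param target label, e.g. \code{"misrejoinings"}.
#' @return object of class \code{lq_fit} with \code{alpha} (per Gy),
#'   \code{beta} (per Gy^2), \code{refit_pure_quadratic} and \code{target}.
#' @examples
#' d <- c(0.001, 0.003, 0.01, 0.03, 0.06, 0.1, 0.3, 0.5, 0.7, 1)
#' f <- fit_lq_counts(d, 0.02 * d + 0.37 * d^2)
#' c(f$alpha, f$beta)
#' @export
fit_lq_counts <- function(doses, mean_counts, target = "misrejoinings") {
  .check_doses(doses, mean_counts)
  r <- .lq_ls(doses, mean_counts)
  structure(list(alpha = r$alpha, beta = r$beta,
                 refit_pure_quadratic = r$refit, target = target),
            class = "lq_fit")
}

#' Linear-quadratic fit of mean survival
#'
#' Fits \eqn{-\ln(\bar{P}_{surv}) = \alpha D + \beta D^2} on the mean survival
#' probability across cells at each dose (not the mean of the logs), with the
#' same negative-alpha refit rule as \code{\link{fit_lq_counts}}.
#'
#' @inheritParams fit_yield
#' @param mean_survival mean survival probabilities in (0, 1].
#' @return an \code{lq_fit} with target \code{"killing"}.
#' @export
fit_lq_survival <- function(doses, mean_survival) {
  .check_doses(doses, mean_survival)
  if (any(mean_survival <= 0))
    stop("survival must be > 0", call. = FALSE)
  if (any(mean_survival > 1))
    stop("survival must be <= 1", call. = FALSE)
  r <- .lq_ls(doses, -log(mean_survival))
  structure(list(alpha = r$alpha, beta = r$beta,
                 refit_pure_quadratic = r$refit, target = "killing"),
            class = "lq_fit")
}

#' @export
print.lq_fit <- function(x, ...) {
  cat(sprintf("lq_fit (%s): alpha = %.4g /Gy, beta = %.4g /Gy^2%s\n",
              x$target, x$alpha, x$beta,
              if (x$refit_pure_quadratic) " (refit pure quadratic)" else ""))
  invisible(x)
}

#' @export
print.yield_fit <- function(x, ...) {
  cat(sprintf("yield_fit (%s): slope = %.4g /Gy/cell (se %.3g)\n",
              x$endpoint, x$slope, x$se))
  invisible(x)
}

#' Oxygen enhancement ratio of a yield endpoint
#'
#' Ratio of fitted slopes, full oxia over anoxia.
#'
#' @param fit_oxic,fit_anoxic \code{yield_fit} objects.
#' @return the slope ratio.
#' @export
oer_yield <- function(fit_oxic, fit_anoxic) {
  if (fit_anoxic$slope == 0)
    stop("anoxic slope is zero; OER undefined", call. = FALSE)
  fit_oxic$slope / fit_anoxic$slope
}

#' Dose for 10\% survival
#'
#' Positive root of \eqn{\alpha D + \beta D^2 = \ln 10}.
#'
#' @param lq an \code{lq_fit} (killing coefficients).
#' @return D10 in Gy.
#' @examples
#' d10(structure(list(alpha = 0, beta = 0.02), class = "lq_fit")) # 10.73 Gy
#' @export
d10 <- function(lq) {
  a <- lq$alpha
  b <- lq$beta
  L <- log(10)
  if (a <= 0 && b <= 0)
    stop("D10 undefined: alpha and beta are both zero", call. = FALSE)
  if (b == 0) return(L / a)
  (-a + sqrt(a^2 + 4 * b * L)) / (2 * b)
}

#' Surviving fraction at a dose
#'
#' \eqn{\exp(-\alpha D - \beta D^2)}; \code{sf_at_dose(lq, 2)} is SF2.
#'
#' @param lq an \code{lq_fit}.
#' @param dose dose in Gy.
#' @return survival fraction.
#' @export
sf_at_dose <- function(lq, dose) {
  exp(-lq$alpha * dose - lq$beta * dose^2)
}

#' Oxygen enhancement ratio for cell killing
#'
#' \eqn{D_{10}(\mathrm{anoxia}) / D_{10}(\mathrm{oxia})}.
#'
#' @param lq_oxic,lq_anoxic killing \code{lq_fit} objects.
#' @return the D10 ratio.
#' @export
oer_killing <- function(lq_oxic, lq_anoxic) {
  d10(lq_anoxic) / d10(lq_oxic)
}

#' Assemble a fit report
#'
#' @param endpoint endpoint label.
#' @param condition condition label (e.g. "oxic", "anoxic").
#' @param fit a \code{yield_fit} or \code{lq_fit}.
#' @return one-row data frame suitable for rbinding into a report table.
#' @export
fit_report <- function(endpoint, condition, fit) {
  if (inherits(fit, "yield_fit")) {
    data.frame(endpoint = endpoint, condition = condition, slope = fit$slope,
               alpha = NA_real_, beta = NA_real_, refit = NA)
  } else {
    data.frame(endpoint = endpoint, condition = condition, slope = NA_real_,
               alpha = fit$alpha, beta = fit$beta,
               refit = fit$refit_pure_quadratic)
  }
}
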