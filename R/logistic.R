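#' Logistic trend fit with separation flagging
#'
#' Maximum-likelihood fit of `logit P(y = 1) = a + b * (t - mean(t))` by
#' iteratively reweighted least squares on centered time (centering for
#' conditioning only: the reported slope is per original time unit and is
#' invariant to shifts of the time origin). Convergence tolerance 1e-8 on
#' the coefficient step, iteration cap 25.
#'
#' Complete or quasi-separation (including a constant response) makes the
#' maximum-likelihood estimates diverge; the fit is then flagged rather than
#' failed, and the last iterate is reported — the diverged estimate with its
#' huge standard error is itself the recognizable signature. Detection rule:
#' at the iteration cap, `|slope| > 15`, `se_slope > 100`, `|intercept| > 15`
#' or `se_intercept > 100` (or any non-finite iterate).
#'
#' @param t numeric time values (at least 2 distinct).
#' @param y binary response in {0, 1}.
#' @return object of class `logit_fit`: `intercept` (at the centered origin,
#'   i.e. at `t_center`), `slope`, `se_intercept`, `se_slope`, `z_wald`,
#'   `p_wald`, `converged`, `separation`, `t_center`, `n`, `iterations`.
#' @export
fit_logit_trend <- function(t, y) {
  ok <- !is.na(t) & !is.na(y)
  t <- t[ok]; y <- y[ok]
  if (length(unique(t)) < 2) stop("need at least 2 distinct time values")
  if (!all(y %in% c(0, 1))) stop("y must be binary in {0, 1}")
  n <- length(y)
  t_center <- mean(t)
  X <- cbind(1, t - t_center)
  beta <- c(stats::qlogis((sum(y) + 0.5) / (n + 1)), 0)
  converged <- FALSE
  max_iter <- 25L
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    fit <- stats::lm.wfit(X, z, w)
    beta_new <- fit$coefficients
    if (any(!is.finite(beta_new))) { beta_new <- beta; break }
    step <- max(abs(beta_new - beta))
    beta <- beta_new
    if (step < 1e-8) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  info <- crossprod(X, X * w)
  cov <- tryCatch(solve(info), error = function(e) matrix(Inf, 2, 2))
  se <- sqrt(pmax(diag(cov), 0))
  separation <- !converged && (abs(beta[2]) > 15 || se[2] > 100 ||
                                 abs(beta[1]) > 15 || se[1] > 100)
  z_wald <- beta[2] / se[2]
  p_wald <- 2 * stats::pnorm(-abs(z_wald))
  structure(list(intercept = unname(beta[1]), slope = unname(beta[2]),
                 se_intercept = unname(se[1]), se_slope = unname(se[2]),
                 z_wald = unname(z_wald), p_wald = unname(p_wald),
                 converged = converged, separation = separation,
                 t_center = t_center, n = n, iterations = iter),
            class = "logit_fit")
}

#' @export
print.logit_fit <- function(x, ...) {
  cat(sprintf("logit_fit: slope = %.6g (SE %.4g), z = %.3f, p = %.4g, n = %d%s\n",
              x$slope, x$se_slope, x$z_wald, x$p_wald, x$n,
              if (x$separation) " [separation]" else ""))
  invisible(x)
}

#' Odds and probability summary of a logistic trend
#'
#' Converts a fitted logistic trend into the change over a time interval:
#' the total odds ratio `exp(slope * (t1 - t0))` and the change in fitted
#' probability `plogis(a + b (t1 - c)) - plogis(a + b (t0 - c))` evaluated in
#' the centered parameterization. A separation flag on the fit propagates.
#'
#' @param fit a [fit_logit_trend()] result.
#' @param t0,t1 interval endpoints on the fit's time scale, `t1 > t0`.
#' @return list with `odds_ratio_total`, `delta_probability`, `separation`.
#' @export
odds_summary <- function(fit, t0, t1) {
  stopifnot(inherits(fit, "logit_fit"))
  if (t1 <= t0) stop("t1 must be greater than t0")
  p <- function(tt) stats::plogis(fit$intercept + fit$slope * (tt - fit$t_center))
  list(odds_ratio_total = exp(fit$slope * (t1 - t0)),
       delta_probability = p(t1) - p(t0),
       separation = fit$separation)
}
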