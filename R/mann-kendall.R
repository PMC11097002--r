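#' Mann-Kendall trend test
#'
#' Non-parametric test for a monotonic trend in a series. The statistic is
#' the pair-sign sum `S = sum_{i<j} sign(x_j - x_i)`; its variance under the
#' null uses the tie correction
#' `var_S = [n(n-1)(2n+5) - sum_t t(t-1)(2t+5)] / 18` over tie groups of
#' size `t`. Kendall's tau is `S / sqrt(D (D - T))` with `D = n(n-1)/2` and
#' `T = sum_t t(t-1)/2` (tau-b against a tie-free time axis). The normal
#' score applies the +/-1 continuity correction; the p-value is two-sided.
#' Missing values are removed, which is equivalent to skipping incomplete
#' pairs.
#'
#' An all-equal series is the documented degenerate case: `tau = 0, p = 1`.
#' Fewer than 3 usable values yields a missing result carrying a reason.
#'
#' @param x numeric series, ordered in time.
#' @return object of class `mk_result` with fields `S`, `var_S`, `tau`, `z`,
#'   `p`, `n`, and `reason` (`NA` unless the result is missing).
#' @export
mann_kendall <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  mk <- function(S, var_S, tau, z, p, n, reason = NA_character_)
    structure(list(S = S, var_S = var_S, tau = tau, z = z, p = p, n = n,
                   reason = reason), class = "mk_result")
  if (n < 3)
    return(mk(NA, NA, NA, NA, NA, n, "fewer than 3 non-missing values"))

  d <- sign(outer(x, x, "-"))  # d[i, j] = sign(x_i - x_j)
  S <- sum(d[lower.tri(d)])
  ties <- table(x)
  t_sizes <- as.numeric(ties[ties > 1])
  var_S <- (n * (n - 1) * (2 * n + 5) - sum(t_sizes * (t_sizes - 1) * (2 * t_sizes + 5))) / 18
  D <- n * (n - 1) / 2
  T_ties <- sum(t_sizes * (t_sizes - 1) / 2)
  if (D - T_ties <= 0)  # all values equal
    return(mk(0L, var_S, 0, 0, 1, n))
  tau <- S / sqrt(D * (D - T_ties))
  z <- if (S > 0) (S - 1) / sqrt(var_S) else if (S < 0) (S + 1) / sqrt(var_S) else 0
  p <- 2 * stats::pnorm(-abs(z))
  mk(as.integer(S), var_S, tau, z, p, n)
}

#' @export
print.mk_result <- function(x, ...) {
  if (!is.na(x$reason)) {
    cat("mk_result: missing (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("mk_result: S = %d, tau = %.4f, z = %.3f, p = %.4g (n = %d)\n",
                x$S, x$tau, x$z, x$p, x$n))
  }
  invisible(x)
}
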