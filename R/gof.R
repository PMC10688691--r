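#' Kolmogorov-Smirnov goodness of fit against a fitted inverse Pareto law
#'
#' One-sample KS test of `data` against the IPD cdf with the supplied
#' shape (in practice the MLE, per the usual plug-in work flow). The
#' statistic is the sup-distance between the empirical cdf and
#' \eqn{(x/(1+x))^\alpha}; the p-value uses the asymptotic Kolmogorov
#' distribution (`exact = FALSE`), a known anti-conservative
#' simplification when the shape was estimated from the same data. Ties in
#' the data (rounded recordings) only affect the p-value warning, which is
#' suppressed; the statistic itself is the correct sup-distance.
#'
#' @param data non-empty vector of positive observations.
#' @param alpha IPD shape to test against.
#' @return an object of class `"htest"` from [stats::ks.test()].
#' @examples
#' set.seed(1)
#' ks_test_ipd(ripd(100, 2), alpha = 2)
#' @export
ks_test_ipd <- function(data, alpha) {
  if (length(data) == 0L) stop("'data' must be non-empty", call. = FALSE)
  check_alpha(alpha)
  suppressWarnings(
    stats::ks.test(data, function(q) pipd(q, alpha), exact = FALSE)
  )
}
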