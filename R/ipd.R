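#' The inverse Pareto distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the one-parameter inverse Pareto distribution (IPD) with shape
#' `alpha`, defined on the positive half-line by the distribution function
#' \deqn{F(x \mid \alpha) = \left(\frac{x}{1+x}\right)^{\alpha}, \quad x > 0,\ \alpha > 0,}
#' and density
#' \deqn{f(x \mid \alpha) = \frac{\alpha x^{\alpha-1}}{(1+x)^{\alpha+1}}.}
#'
#' The IPD is a heavy-tailed lifetime law whose hazard is decreasing or
#' upside-down bathtub shaped; it arises as the distribution of `1/Z` for a
#' Pareto variable `Z`. All computations are carried out on the log scale
#' (`alpha * log(x/(1+x))` and friends) so that large shapes (the jute-fibre
#' fit needs `alpha` near 19) do not underflow.
#'
#' @param x,q vector of positive quantiles.
#' @param p vector of probabilities in (0, 1).
#' @param n number of draws; a non-negative integer.
#' @param alpha positive shape parameter.
#' @param log,log.p logical; if `TRUE`, probabilities/densities are returned
#'   on the log scale.
#' @param lower.tail logical; if `TRUE` (default), probabilities are
#'   \eqn{P(X \le x)}, otherwise \eqn{P(X > x)}.
#' @param seed optional integer; if supplied, the generator is seeded locally
#'   so the draw is reproducible independent of the surrounding RNG state.
#'
#' @return `dipd` gives the density, `pipd` the distribution function,
#'   `qipd` the quantile function and `ripd` a vector of `n` random draws.
#'
#' @examples
#' dipd(1, alpha = 1)        # 0.25
#' pipd(3, alpha = 2)        # 0.5625
#' qipd(0.5, alpha = 1)      # 1
#' x <- ripd(5, alpha = 2, seed = 1)
#' @name ipd
NULL

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("'alpha' must be a single positive finite number", call. = FALSE)
  invisible(alpha)
}

# log(x / (1 + x)) computed as -log1p(1/x): accurate for both tails
log_u <- function(x) -log1p(1 / x)

#' @rdname ipd
#' @export
dipd <- function(x, alpha, log = FALSE) {
  check_alpha(alpha)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("'x' must be positive and finite", call. = FALSE)
  ld <- base::log(alpha) + (alpha - 1) * base::log(x) - (alpha + 1) * log1p(x)
  if (log) ld else exp(ld)
}

#' @rdname ipd
#' @export
pipd <- function(q, alpha, lower.tail = TRUE, log.p = FALSE) {
  check_alpha(alpha)
  if (any(!is.finite(q)) || any(q <= 0))
    stop("'q' must be positive and finite", call. = FALSE)
  lp <- alpha * log_u(q)
  if (lower.tail) {
    if (log.p) lp else exp(lp)
  } else {
    s <- -expm1(lp)
    if (log.p) base::log(s) else s
  }
}

#' @rdname ipd
#' @export
qipd <- function(p, alpha, lower.tail = TRUE, log.p = FALSE) {
  check_alpha(alpha)
  lp <- if (log.p) p else base::log(p)
  if (!lower.tail) lp <- base::log(-expm1(lp))
  if (any(!is.finite(lp)) || any(lp >= 0))
    stop("'p' must lie in the open interval (0, 1)", call. = FALSE)
  # u = p^(1/alpha); x = u / (1 - u), stable via expm1 for u near 1
  lu <- lp / alpha
  exp(lu) / -expm1(lu)
}

#' @rdname ipd
#' @export
ripd <- function(n, alpha, seed = NULL) {
  check_alpha(alpha)
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n))
    stop("'n' must be a non-negative integer", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(numeric(0))
  qipd(stats::runif(n), alpha)
}

#' Stress-strength reliability of two inverse Pareto populations
#'
#' Closed-form reliability \eqn{\phi = P(Y < X)} when the strength
#' \eqn{X \sim \mathrm{IPD}(\alpha_1)} and the stress
#' \eqn{Y \sim \mathrm{IPD}(\alpha_2)} are independent:
#' \deqn{\phi = \frac{\alpha_1}{\alpha_1 + \alpha_2}.}
#'
#' @param alpha1,alpha2 positive shape parameters of the strength and
#'   stress populations.
#' @return the reliability, a number in (0, 1).
#' @examples
#' ssr(2, 0.5)   # 0.8
#' ssr(1.2, 0.8) # 0.6
#' @export
ssr <- function(alpha1, alpha2) {
  check_alpha(alpha1)
  check_alpha(alpha2)
  alpha1 / (alpha1 + alpha2)
}
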