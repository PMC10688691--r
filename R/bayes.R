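#' Gamma prior specification for the two IPD shapes
#'
#' Independent gamma priors \eqn{\alpha_i \sim \mathrm{Gamma}(r_i, s_i)}
#' (shape \eqn{r_i}, rate \eqn{s_i}). The default `r = s = 1e-4` is the
#' near-flat analysis prior used when no prior information is available;
#' informative choices set the prior mean \eqn{r_i/s_i} to a plausible
#' shape value.
#'
#' @param r1,s1 shape and rate for the strength parameter `alpha1`.
#' @param r2,s2 shape and rate for the stress parameter `alpha2`.
#' @return an object of class `"prior_spec"`.
#' @export
prior_spec <- function(r1 = 1e-4, s1 = 1e-4, r2 = r1, s2 = s1) {
  vals <- c(r1 = r1, s1 = s1, r2 = r2, s2 = s2)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all prior hyper-parameters must be positive", call. = FALSE)
  structure(as.list(vals), class = "prior_spec")
}

#' Log conditional posterior of one IPD shape
#'
#' Up to an additive constant, the marginal posterior of the shape given
#' its own PFFC sample under a Gamma(r, s) prior:
#' \deqn{(m + r - 1)\ln\alpha - \alpha\left[s - \sum_i \ln u_i\right]
#'  + \sum_i [k(G_i+1)-1]\ln(1 - u_i^{\alpha}),}
#' with \eqn{u_i = x_i/(1+x_i)}. When `k = 1` and all removals are zero the
#' survivor sum vanishes and this is exactly a gamma kernel with shape
#' \eqn{m + r} and rate \eqn{s - \sum \ln u_i} — the conjugate case used to
#' validate the sampler.
#'
#' @param alpha positive evaluation point.
#' @param sample a `"pffc_sample"`.
#' @param r,s gamma prior shape and rate for this parameter.
#' @return the unnormalized log posterior density.
#' @export
log_conditional_alpha <- function(alpha, sample, r, s) {
  check_alpha(alpha)
  stopifnot(inherits(sample, "pffc_sample"))
  lu <- log_u(sample$times)
  (sample$scheme$m + r - 1) * base::log(alpha) -
    alpha * (s - sum(lu)) +
    sum(censor_exponent(sample$scheme) * log1p(-exp(alpha * lu)))
}

#' Component-wise Metropolis-Hastings sampler for (alpha1, alpha2, phi)
#'
#' Random-walk Metropolis-Hastings with normal proposals, updating
#' `alpha1` and `alpha2` in turn against their respective conditional
#' posteriors ([log_conditional_alpha()]); non-positive proposals are
#' rejected outright so the support is respected. Because the posterior
#' factorizes over the two shapes, each component chain targets its own
#' marginal. The reliability chain is the deterministic image
#' \eqn{\phi^{(t)} = \alpha_1^{(t)}/(\alpha_1^{(t)} + \alpha_2^{(t)})}.
#'
#' Defaults follow standard practice for this model: chains start at the
#' MLEs, proposal standard deviations are the delta-method standard errors
#' from the observed Fisher information (falling back to `0.1 * init` if
#' the information is degenerate), `M = 10000` draws with `M0 = 2000`
#' burn-in.
#'
#' @param sample_x,sample_y strength and stress `"pffc_sample"` objects.
#' @param prior a [prior_spec()].
#' @param M total number of draws.
#' @param M0 burn-in length (`0 <= M0 < M`), stored with the chain.
#' @param scales length-2 positive proposal standard deviations, or NULL.
#' @param init length-2 positive starting values, or NULL for the MLEs.
#' @param seed optional integer for a locally seeded, reproducible chain.
#' @return an object of class `"posterior_chain"`: a list with `draws`
#'   (an `M` x 3 matrix, columns `alpha1`, `alpha2`, `phi`), `M0`,
#'   `acceptance` rates per parameter, and the configuration used.
#' @export
mh_sample <- function(sample_x, sample_y, prior = prior_spec(),
                      M = 10000, M0 = 2000, scales = NULL, init = NULL,
                      seed = NULL) {
  stopifnot(inherits(prior, "prior_spec"))
  if (M < 1 || M0 < 0 || M0 >= M)
    stop("need 0 <= M0 < M", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init))
    init <- c(ml_estimate(sample_x), ml_estimate(sample_y))
  if (any(init <= 0)) stop("'init' must be positive", call. = FALSE)
  if (is.null(scales)) {
    info <- c(info_half(init[1], sample_x), info_half(init[2], sample_y))
    scales <- ifelse(is.finite(info) & info > 0, 1 / sqrt(info), 0.1 * init)
  }
  if (any(scales <= 0)) stop("'scales' must be positive", call. = FALSE)

  samples <- list(sample_x, sample_y)
  rs <- list(c(prior$r1, prior$s1), c(prior$r2, prior$s2))
  cur <- init
  cur_lp <- vapply(1:2, function(j)
    log_conditional_alpha(cur[j], samples[[j]], rs[[j]][1], rs[[j]][2]), 1)
  draws <- matrix(NA_real_, M, 3,
                  dimnames = list(NULL, c("alpha1", "alpha2", "phi")))
  acc <- c(0L, 0L)
  for (t in seq_len(M)) {
    for (j in 1:2) {
      prop <- stats::rnorm(1, cur[j], scales[j])
      if (prop > 0) {
        lp <- log_conditional_alpha(prop, samples[[j]], rs[[j]][1], rs[[j]][2])
        if (base::log(stats::runif(1)) < lp - cur_lp[j]) {
          cur[j] <- prop
          cur_lp[j] <- lp
          acc[j] <- acc[j] + 1L
        }
      }
    }
    draws[t, 1:2] <- cur
    draws[t, 3] <- cur[1] / (cur[1] + cur[2])
  }
  rate <- acc / M
  if (any(rate < 0.01))
    warning("very low Metropolis-Hastings acceptance rate (",
            paste(sprintf("%.3f", rate), collapse = ", "),
            "); consider adjusting 'scales'", call. = FALSE)
  structure(list(draws = draws, M = M, M0 = M0,
                 acceptance = c(alpha1 = rate[1], alpha2 = rate[2]),
                 scales = scales, init = init, prior = prior),
            class = "posterior_chain")
}

#' @export
print.posterior_chain <- function(x, ...) {
  cat(sprintf("Posterior chain: M = %d draws (burn-in %d)\n", x$M, x$M0))
  cat(sprintf("acceptance: alpha1 %.3f, alpha2 %.3f\n",
              x$acceptance[1], x$acceptance[2]))
  kept <- x$draws[(x$M0 + 1):x$M, , drop = FALSE]
  print(round(rbind(mean = colMeans(kept), sd = apply(kept, 2, stats::sd)), 4))
  invisible(x)
}

#' Trace and posterior-density diagnostics for an MCMC chain
#'
#' @param x a `"posterior_chain"`.
#' @param which column to display (default `"phi"`).
#' @param ... passed on to [plot()].
#' @return invisibly, `x`.
#' @export
plot.posterior_chain <- function(x, which = "phi", ...) {
  kept <- x$draws[(x$M0 + 1):x$M, which]
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(kept, type = "l", xlab = "iteration (post burn-in)", ylab = which,
       main = paste("trace of", which), ...)
  plot(stats::density(kept), main = paste("posterior of", which),
       xlab = which)
  invisible(x)
}

#' Export a posterior chain to CSV
#'
#' Writes the full chain (all `M` rows, columns `alpha1`, `alpha2`, `phi`)
#' as plain CSV.
#'
#' @param chain a `"posterior_chain"`.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_chain_csv <- function(chain, path) {
  stopifnot(inherits(chain, "posterior_chain"))
  utils::write.csv(as.data.frame(chain$draws), path, row.names = FALSE)
  invisible(path)
}

#' Bayes (posterior mean) estimate of the stress-strength reliability
#'
#' The squared-error-loss point estimate is the posterior mean of the
#' reliability chain after burn-in:
#' \deqn{\hat\phi_{Bayes} = \frac{1}{M - M_0} \sum_{t = M_0 + 1}^{M} \phi^{(t)}.}
#'
#' @param chain a `"posterior_chain"`.
#' @param level if non-NULL, also attach the HPD credible interval at this
#'   level (computed from the post-burn-in phi draws).
#' @return an `"ssr_estimate"` with method `"bayes-self"`.
#' @export
bayes_ssr <- function(chain, level = NULL) {
  stopifnot(inherits(chain, "posterior_chain"))
  kept <- chain$draws[(chain$M0 + 1):chain$M, , drop = FALSE]
  ci <- if (!is.null(level)) hpd_interval(kept[, "phi"], level) else NULL
  ssr_estimate("bayes-self",
               alpha1 = mean(kept[, "alpha1"]),
               alpha2 = mean(kept[, "alpha2"]),
               phi = mean(kept[, "phi"]),
               ci = ci, level = level)
}

#' Highest-posterior-density interval from MCMC draws
#'
#' Scans every window of \eqn{\lfloor(1-\xi) M\rfloor} consecutive order
#' statistics of the draws and returns the shortest (the Chen-Shao
#' construction); ties are broken at the smallest starting index, and the
#' endpoints are observed draws.
#'
#' @param draws numeric vector of at least 10 draws.
#' @param level credible level in (0, 1), default 0.95.
#' @return length-2 numeric vector (lower, upper).
#' @examples
#' hpd_interval(1:100, 0.95)  # c(1, 96)
#' @export
hpd_interval <- function(draws, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("'level' must be in (0, 1)", call. = FALSE)
  if (length(draws) < 10L)
    stop("need at least 10 draws for an HPD interval", call. = FALSE)
  s <- sort(draws)
  M <- length(s)
  w <- floor(level * M)          # window span in order statistics
  n_start <- M - w
  if (n_start < 1L) return(c(s[1], s[M]))
  widths <- s[(1 + w):M] - s[1:n_start]
  t0 <- which.min(widths)        # which.min takes the first minimum: ties at smallest t
  c(s[t0], s[t0 + w])
}
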