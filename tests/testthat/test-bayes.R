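test_that("prior specification rejects non-positive hyper-parameters", {
  expect_error(prior_spec(r1 = 0), "positive")
  p <- prior_spec(2, 4)
  expect_equal(p$r2, 2)  # defaults mirror the first pair
})

test_that("conditional posterior reduces to a gamma kernel without censoring", {
  # k = 1, no removals: the survivor sum vanishes, leaving a
  # Gamma(m + r, s - sum log u) kernel
  set.seed(3)
  sch <- censoring_scheme(rep(0, 12), k = 1)
  s <- rpffc(2, sch)
  r <- 1.5; rate0 <- 0.7
  shape <- sch$m + r
  rate <- rate0 - sum(log(s$times / (1 + s$times)))
  for (a in c(0.5, 1, 2, 4)) {
    expect_equal(
      log_conditional_alpha(a, s, r, rate0) - log_conditional_alpha(1, s, r, rate0),
      dgamma(a, shape, rate, log = TRUE) - dgamma(1, shape, rate, log = TRUE),
      tolerance = 1e-10)
  }
})

test_that("conditional log-density derivative matches finite differences", {
  j <- pffc_dataset("jute")
  s <- j$schemes[[1]]$x
  f <- function(a) log_conditional_alpha(a, s, 1e-4, 1e-4)
  for (a in c(10, 25)) {
    h <- 1e-5 * a
    fd <- (f(a + h) - f(a - h)) / (2 * h)
    u <- s$times / (1 + s$times); ua <- u^a
    cvec <- s$scheme$k * (s$scheme$removals + 1) - 1
    an <- (s$scheme$m + 1e-4 - 1) / a + (sum(log(u)) - 1e-4) -
      sum(cvec * ua * log(u) / (1 - ua))
    expect_equal(fd, an, tolerance = 1e-6)
  }
  # decays to -Inf at the origin when m + r > 1
  expect_lt(f(1e-8), f(1) - 100)
})

test_that("chains are reproducible and phi is the image of the alphas", {
  j <- pffc_dataset("jute")
  sx <- j$schemes[[1]]$x; sy <- j$schemes[[1]]$y
  ch1 <- mh_sample(sx, sy, M = 500, M0 = 100, seed = 77)
  ch2 <- mh_sample(sx, sy, M = 500, M0 = 100, seed = 77)
  expect_identical(ch1$draws, ch2$draws)
  expect_equal(ch1$draws[, "phi"],
               ch1$draws[, "alpha1"] /
                 (ch1$draws[, "alpha1"] + ch1$draws[, "alpha2"]))
  expect_true(all(ch1$draws > 0))
  expect_true(all(ch1$acceptance > 0))
})

test_that("M-H machinery reproduces the exact conjugate posterior", {
  # without censoring the marginal posterior is exactly gamma; the chain
  # mean and quantiles must match the closed form within Monte Carlo error
  set.seed(10)
  sch <- censoring_scheme(rep(0, 10), k = 1)
  sx <- rpffc(2, sch); sy <- rpffc(1, sch)
  r <- 0.5; s0 <- 0.5
  ch <- mh_sample(sx, sy, prior = prior_spec(r, s0), M = 20000, M0 = 2000,
                  seed = 101)
  kept <- ch$draws[2001:20000, "alpha1"]
  shape <- sch$m + r
  rate <- s0 - sum(log(sx$times / (1 + sx$times)))
  mcse <- sd(kept) / sqrt(length(kept) / 20)  # conservative ESS guess
  expect_lt(abs(mean(kept) - shape / rate), 3 * mcse)
  for (p in c(0.25, 0.5, 0.75)) {
    expect_equal(unname(quantile(kept, p)), qgamma(p, shape, rate),
                 tolerance = 0.06)
  }
})

test_that("an overwhelming prior dominates the data", {
  set.seed(12)
  sch <- censoring_scheme(rep(0, 10), k = 1)
  sx <- rpffc(2, sch); sy <- rpffc(1, sch)
  cval <- 3
  ch <- mh_sample(sx, sy, prior = prior_spec(r1 = 1e6 * cval, s1 = 1e6,
                                             r2 = 1e6 * cval, s2 = 1e6),
                  M = 8000, M0 = 1000,
                  init = c(cval, cval), scales = c(0.003, 0.003), seed = 5)
  expect_equal(mean(ch$draws[1001:8000, "alpha1"]), cval, tolerance = 0.01 * cval)
})

test_that("posterior-mean estimate uses only post-burn-in draws", {
  j <- pffc_dataset("jute")
  ch <- mh_sample(j$schemes[[1]]$x, j$schemes[[1]]$y, M = 2000, M0 = 500,
                  seed = 2)
  est <- bayes_ssr(ch)
  expect_equal(est$phi, mean(ch$draws[501:2000, "phi"]))
  expect_equal(est$method, "bayes-self")
  # burn-in draws are irrelevant to the estimate
  ch_mod <- ch
  ch_mod$draws[1:500, ] <- 0.123
  expect_equal(bayes_ssr(ch_mod)$phi, est$phi)
  # constant chain degenerates to the constant
  ch_const <- ch
  ch_const$draws[, "phi"] <- 0.4
  expect_equal(bayes_ssr(ch_const)$phi, 0.4)
})

test_that("HPD interval equals brute-force scan and minimizes width", {
  expect_equal(hpd_interval(1:100, 0.95), c(1, 96))
  expect_equal(hpd_interval(rep(2.5, 50), 0.9), c(2.5, 2.5))
  set.seed(31)
  for (draws in list(rnorm(500), rgamma(1000, 2, 1), rbeta(4999, 2, 5))) {
    for (lev in c(0.9, 0.95)) {
      got <- hpd_interval(draws, lev)
      expect_equal(got, hpd_brute(draws, lev))
      eq_tail <- unname(quantile(draws, c((1 - lev) / 2, 1 - (1 - lev) / 2)))
      expect_lte(diff(got), diff(eq_tail) + 1e-12)
    }
  }
  expect_error(hpd_interval(1:100, 1.2), "level")
  expect_error(hpd_interval(1:5), "at least 10")
})

test_that("chains export to CSV and round-trip", {
  j <- pffc_dataset("jute")
  ch <- mh_sample(j$schemes[[1]]$x, j$schemes[[1]]$y, M = 200, M0 = 50,
                  seed = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_chain_csv(ch, f)
  back <- read.csv(f)
  expect_equal(as.matrix(back), ch$draws, ignore_attr = TRUE)
})
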