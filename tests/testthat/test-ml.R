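test_that("complete-sample MLE has its closed form", {
  sch1 <- censoring_scheme(0, k = 1)
  expect_equal(ml_estimate(pffc_sample(1, sch1)), 1 / log(2),
               tolerance = 1e-12)
  # closed-form equivalence on every complete-sample fixture
  for (nm in c("jute", "insulation")) {
    ds <- pffc_dataset(nm)
    for (v in list(ds$x, ds$y)) {
      s <- pffc_sample(sort(v), censoring_scheme(rep(0, length(v)), k = 1))
      closed <- length(v) / (-sum(log(v / (1 + v))))
      expect_equal(ml_estimate(s), closed, tolerance = 1e-10)
    }
  }
})

test_that("score vanishes at the censored-sample MLE", {
  for (nm in c("jute", "insulation")) {
    ds <- pffc_dataset(nm)
    for (sc in ds$schemes) {
      for (s in list(sc$x, sc$y)) {
        a <- ml_estimate(s)
        h <- 1e-6 * a
        grad <- (ll(a + h, s) - ll(a - h, s)) / (2 * h)
        expect_lt(abs(grad) * a, 1e-5)   # scale-free stationarity
      }
    }
  }
})

test_that("log-likelihood separates additively with zero cross-partial", {
  j <- pffc_dataset("jute")
  sx <- j$schemes[[1]]$x; sy <- j$schemes[[1]]$y
  base <- pffc_loglik(20, 18, sx, sy)
  # moving alpha2 changes the total by the same amount at any alpha1
  d1 <- pffc_loglik(20, 19, sx, sy) - base
  d2 <- pffc_loglik(27, 19, sx, sy) - pffc_loglik(27, 18, sx, sy)
  expect_equal(d1, d2, tolerance = 1e-10)
  # finite-difference cross partial is zero
  h <- 1e-3
  cross <- (pffc_loglik(20 + h, 18 + h, sx, sy) -
            pffc_loglik(20 + h, 18 - h, sx, sy) -
            pffc_loglik(20 - h, 18 + h, sx, sy) +
            pffc_loglik(20 - h, 18 - h, sx, sy)) / (4 * h^2)
  expect_lt(abs(cross), 1e-8)
})

test_that("gradient of the log-likelihood matches finite differences", {
  j <- pffc_dataset("jute")
  sx <- j$schemes[[1]]$x; sy <- j$schemes[[1]]$y
  for (a in c(5, 20, 40)) {
    h <- 1e-5 * a
    fd <- (ll(a + h, sx) - ll(a - h, sx)) / (2 * h)
    an <- ml_score(a, sx)
    expect_equal(an, fd, tolerance = 1e-6)
  }
  # single observation x = 1, k = 1, no removals, alpha = 1: the variable
  # part of the log-likelihood is ln(alpha) + alpha ln(1/2) = -ln 2
  s1 <- pffc_sample(1, censoring_scheme(0, k = 1))
  expect_equal(ll(1, s1), log(1) + log(0.5), tolerance = 1e-12)
})

test_that("observed information matches a numerical Hessian", {
  j <- pffc_dataset("jute")
  sx <- j$schemes[[1]]$x; sy <- j$schemes[[1]]$y
  a1 <- ml_estimate(sx); a2 <- ml_estimate(sy)
  info <- fisher_info(a1, a2, sx, sy)
  expect_equal(info[1, 2], 0)
  expect_equal(info[2, 1], 0)
  for (j_ in 1:2) {
    a <- c(a1, a2)[j_]; s <- list(sx, sy)[[j_]]
    h <- 1e-4 * a
    num <- -(ll(a + h, s) - 2 * ll(a, s) + ll(a - h, s)) / h^2
    expect_equal(info[j_, j_], num, tolerance = 1e-5)
  }
})

test_that("joint optimization equals the two marginal solutions", {
  i <- pffc_dataset("insulation")
  sx <- i$schemes[[2]]$x; sy <- i$schemes[[2]]$y
  a1 <- ml_estimate(sx); a2 <- ml_estimate(sy)
  joint <- optim(c(2, 2),
                 function(p) -pffc_loglik(p[1], p[2], sx, sy, constant = FALSE),
                 method = "L-BFGS-B", lower = c(1e-4, 1e-4))
  expect_equal(joint$par, c(a1, a2), tolerance = 1e-4)
})

test_that("ACI is symmetric about the MLE and respects its level", {
  j <- pffc_dataset("jute")
  e95 <- aci_ssr(j$schemes[[1]]$x, j$schemes[[1]]$y, level = 0.95)
  expect_equal(mean(e95$ci), e95$phi, tolerance = 1e-12)
  e90 <- aci_ssr(j$schemes[[1]]$x, j$schemes[[1]]$y, level = 0.90)
  expect_lt(diff(e90$ci), diff(e95$ci))
  expect_equal(ml_ssr(j$schemes[[1]]$x, j$schemes[[1]]$x)$phi, 0.5)
})

test_that("interval length shrinks as the number of failures grows", {
  sch20 <- parse_scheme("(5 * 1, 0 * 19)", k = 2)
  sch40 <- parse_scheme("(10 * 1, 0 * 39)", k = 2)
  set.seed(19)
  al20 <- mean(replicate(200, diff(aci_ssr(rpffc(2, sch20), rpffc(0.5, sch20))$ci)))
  al40 <- mean(replicate(200, diff(aci_ssr(rpffc(2, sch40), rpffc(0.5, sch40))$ci)))
  expect_lt(al40, al20)
})
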