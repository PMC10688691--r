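# Independent re-derivations used as oracles: written straight from the
# model formulas, sharing no code with the package internals.

# single-sample log-likelihood (variable part) for a PFFC sample
ll <- function(alpha, sample) {
  x <- sample$times
  sch <- sample$scheme
  cvec <- sch$k * (sch$removals + 1) - 1
  u <- x / (1 + x)
  sch$m * log(alpha) + alpha * sum(log(u)) + sum(cvec * log(1 - u^alpha))
}

# analytic score of ll
ml_score <- function(alpha, sample) {
  x <- sample$times
  sch <- sample$scheme
  cvec <- sch$k * (sch$removals + 1) - 1
  u <- x / (1 + x)
  ua <- u^alpha
  sch$m / alpha + sum(log(u)) - sum(cvec * ua * log(u) / (1 - ua))
}

# brute-force HPD: scan every admissible window of order statistics
hpd_brute <- function(draws, level) {
  s <- sort(draws)
  M <- length(s)
  w <- floor(level * M)
  starts <- seq_len(M - w)
  widths <- s[starts + w] - s[starts]
  t0 <- starts[which.min(widths)]
  c(s[t0], s[t0 + w])
}
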