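# Independent transcription of the empirical-Bayes moderated-t formulas:
# per-gene two-group least squares, then (d0, s0^2) by moment matching on
# the log sample variances (digamma/trigamma inversion), posterior
# variances and t on d0 + d degrees of freedom.
eb_oracle <- function(expr, case_idx) {
  n1 <- sum(case_idx); n0 <- sum(!case_idx)
  d <- n1 + n0 - 2
  b <- rowMeans(expr[, case_idx, drop = FALSE]) -
    rowMeans(expr[, !case_idx, drop = FALSE])
  rss <- apply(expr[, case_idx, drop = FALSE], 1, function(v)
    sum((v - mean(v))^2)) +
    apply(expr[, !case_idx, drop = FALSE], 1, function(v)
      sum((v - mean(v))^2))
  s2 <- rss / d
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  target <- mean((e - ebar)^2 * length(e) / (length(e) - 1)) -
    trigamma(d / 2)
  trigamma_inv <- function(y) {
    x <- 0.5 + 1 / y
    for (i in 1:75) x <- x + (trigamma(x) - y) / -psigamma(x, 2)
    x
  }
  if (target <= 0) {
    d0 <- Inf
    s0_sq <- exp(ebar)
  } else {
    d0 <- 2 * trigamma_inv(target)
    s0_sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  }
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2))
             else (d0 * s0_sq + d * s2) / (d0 + d)
  cc <- sqrt(1 / n1 + 1 / n0)
  t_mod <- b / (sqrt(s2_post) * cc)
  list(d0 = d0, s0_sq = s0_sq, t = t_mod,
       p = 2 * pt(-abs(t_mod), df = d0 + d))
}
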