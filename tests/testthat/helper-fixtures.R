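# Small configurations shared across tests.  All simulation fixtures are
# generated in code at test time; nothing is read from disk unless a test
# writes it first.

quick_config <- function(N = 200L, generations = 400L, window = 100L,
                         seed = 7L, n_replicates = 2L, ...) {
  sim_config(N = N, generations = generations, window = window, seed = seed,
             n_replicates = n_replicates, ...)
}

# closed-form weighted least squares (the independent oracle used against
# fit_rate_regression); unit weights give ordinary least squares
wls_oracle <- function(x, y, w = rep(1, length(x))) {
  W <- sum(w)
  xb <- sum(w * x) / W
  yb <- sum(w * y) / W
  sxx <- sum(w * (x - xb)^2)
  sxy <- sum(w * (x - xb) * (y - yb))
  slope <- sxy / sxx
  intercept <- yb - slope * xb
  res <- y - intercept - slope * x
  n <- length(x)
  sigma2 <- sum(w * res^2) / (n - 2)
  se <- sqrt(sigma2 / sxx)
  tval <- slope / se
  p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  ybar_res <- y - yb
  r2 <- 1 - sum(w * res^2) / sum(w * ybar_res^2)
  list(slope = slope, intercept = intercept, r_squared = r2, p_value = p)
}

# exact Fisher p by brute-force enumeration over all tables with the
# observed margins, using only factorials (independent of dhyper)
fisher_enum_oracle <- function(tab, sidedness) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  logp <- vapply(support, function(k) {
    lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1)
  }, numeric(1))
  dens <- exp(logp)
  dens <- dens / sum(dens)
  obs <- dens[match(a, support)]
  switch(sidedness,
         greater = sum(dens[support >= a]),
         less = sum(dens[support <= a]),
         two.sided = sum(dens[dens <= obs * (1 + 1e-7)]))
}
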