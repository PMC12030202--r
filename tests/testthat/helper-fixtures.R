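# shared fixtures and independent oracles

noisefree_config <- function(seed = 1L, ...) {
  trial_config(noise = list(dm = 0, n = 0, reflectance = 0, yield = 0),
               seed = seed, ...)
}

# direct nested-loop implementation of the Deng gray relational
# coefficient/degree formulas, independent of the package's vectorised path
gra_oracle <- function(ref, cmp, rho = 0.5) {
  n <- length(ref); m <- ncol(cmp)
  delta <- matrix(0, n, m)
  for (i in seq_len(m)) for (k in seq_len(n))
    delta[k, i] <- abs(ref[k] - cmp[k, i])
  dmin <- Inf; dmax <- -Inf
  for (i in seq_len(m)) for (k in seq_len(n)) {
    if (delta[k, i] < dmin) dmin <- delta[k, i]
    if (delta[k, i] > dmax) dmax <- delta[k, i]
  }
  g <- matrix(0, n, m)
  for (i in seq_len(m)) for (k in seq_len(n))
    g[k, i] <- if (dmax == 0) 1 else
      (dmin + rho * dmax) / (delta[k, i] + rho * dmax)
  deg <- numeric(m)
  for (i in seq_len(m)) {
    s <- 0
    for (k in seq_len(n)) s <- s + g[k, i]
    deg[i] <- s / n
  }
  list(coefficients = g, degrees = deg)
}

# loop-summation RMSE, independent of evaluate_inversion()
rmse_oracle <- function(pred, meas) {
  s <- 0
  for (i in seq_along(pred)) s <- s + (meas[i] - pred[i])^2
  sqrt(s / length(pred))
}
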