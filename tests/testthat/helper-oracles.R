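# Independent oracles used across the suite. Each re-derives a quantity by
# a route separate from the implementation it checks.

# Naive double-loop evaluation of the per-trajectory MSD estimator:
# MSD_i(n dt) = (1 / (N - n - 1)) * sum_{i=1}^{N-n-1} [dx^2 + dy^2]
msd_bruteforce <- function(x, y, dt) {
  N <- length(x)
  lags <- seq_len(N - 2)
  msd <- numeric(length(lags))
  for (n in lags) {
    acc <- 0
    m <- N - n - 1
    for (i in seq_len(m)) {
      acc <- acc + (x[i + n] - x[i])^2 + (y[i + n] - y[i])^2
    }
    msd[n] <- acc / m
  }
  data.frame(lag_s = lags * dt, msd_um2 = msd, weight = N - lags - 1)
}

# Grid argmax of the crowding rate law over phi in [lo, hi]
argmax_eq2_grid <- function(d_p, a, lo = 0.01, hi = 20, step = 1e-4) {
  phi <- seq(lo, hi, by = step)
  phi[which.max(phi^2 * exp(-a * d_p * (phi - 1)))]
}

# Grid search over (A0, k, C) for the constrained securin decay fit
securin_grid_search <- function(t, A,
                                A0_grid = seq(0.95, 1.2, by = 0.005),
                                k_grid = seq(0, 0.5, by = 0.002),
                                C_grid = seq(0, 0.05, by = 0.005)) {
  best <- list(sse = Inf)
  for (A0 in A0_grid) for (k in k_grid) for (C in C_grid) {
    sse <- sum((A - (A0 * exp(-k * t) + C))^2)
    if (sse < best$sse) best <- list(A0 = A0, k = k, C = C, sse = sse)
  }
  best
}

# Random short 2-D trajectory tibble for oracle-equivalence checks
random_trajectory <- function(N, dt = 1 / 3, id = 1L) {
  tibble::tibble(
    particle_id = id,
    frame = 0:(N - 1),
    x_um = cumsum(rnorm(N)),
    y_um = cumsum(rnorm(N))
  )
}
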