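# Independent oracles and shared fixtures for the test suite.
# Oracles are deliberately written against the definitions, not the
# package's implementation paths.

# Monte-Carlo oracle for the differential information of a normalized
# profile: I = E_x[p(x) log2 p(x)] under uniform x.  Returns the
# estimate and its standard error.
mc_information <- function(map, n = 1e6, seed = 1) {
  set.seed(seed)
  x <- runif(n)
  p <- evaluate_ratemap(map, x)
  f <- ifelse(p > 0, p * log2(p), 0)
  list(value = mean(f), se = sd(f) / sqrt(n))
}

# Dense-grid spline + trapezoid re-evaluation oracle at 10x the
# package's grid resolution.
dense_profile_oracle <- function(map, x) {
  g <- seq(0, 1, length.out = 100001)
  s <- splinefun(map$nodes$x, map$nodes$y, method = "natural")
  z <- exp(s(g))
  zint <- sum((g[-1] - g[-length(g)]) * (z[-1] + z[-length(z)])) / 2
  exp(s(x)) / zint
}

# Direct plug-in MI (bits/sample) from paired discrete labels.
plugin_mi_oracle <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p); py <- colSums(p)
  tot <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] > 0) tot <- tot + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  }
  as.numeric(tot)
}

# Hand-rolled rate-map information from occupancy/activity vectors
# (direct transcription of the defining sum).
smgm_oracle_sec <- function(p, lam) {
  p <- p / sum(p)
  m <- sum(p * lam)
  tot <- 0
  for (i in seq_along(p)) {
    if (lam[i] > 0) tot <- tot + lam[i] * p[i] * log2(lam[i] / m)
  }
  tot
}

# A short behavior trace shared by several test files (memoized).
.test_env <- new.env(parent = emptyenv())
short_trace <- function() {
  if (is.null(.test_env$trace)) {
    .test_env$trace <- synth_behavior(300, seed = 42)
  }
  .test_env$trace
}

# A constant-speed sweep trace: no pauses, no teleport delay.
sweep_trace <- function(duration = 300) {
  synth_behavior(duration, mean_speed = 20, pause_rate = 0,
                 teleport_delay = 0, speed_sd = 0, seed = 9)
}
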