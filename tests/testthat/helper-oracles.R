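# Independent brute-force oracles used to pin the implementations.

# O(n^2) double-loop sample entropy (Chebyshev distance, self-matches
# excluded), literal transcription of the definition.
oracle_sampen <- function(x, m = 2, r = 0.2 * sd(x)) {
  n <- length(x)
  nm <- n - m
  B <- A <- 0
  for (i in 1:(nm - 1)) {
    for (j in (i + 1):nm) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  if (B == 0 || A == 0) return(NA_real_)
  -log(A / B)
}

# Literal Benjamini-Hochberg step-up: sort, find largest k with
# p_(k) <= k/m * q, reject 1..k; adjusted p by the usual cummin from the top.
oracle_bh <- function(p, q = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- rev(cummin(rev(ps * m / seq_len(m))))
  adj <- pmin(adj, 1)
  out_adj <- numeric(m)
  out_adj[o] <- adj
  k <- which(ps <= seq_len(m) / m * q)
  reject <- logical(m)
  if (length(k) > 0) reject[o[seq_len(max(k))]] <- TRUE
  list(adj = out_adj, reject = reject)
}

# Exact signed-rank two-sided p by enumerating all 2^n sign assignments.
oracle_wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  ev <- n * (n + 1) / 4
  p <- mean(abs(v_all - ev) >= abs(v_obs - ev) - 1e-12)
  list(V = v_obs, p = p)
}

# Exact Mann-Whitney two-sided p by enumerating all group assignments.
oracle_mann_whitney_exact <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(n1 + n2, n1)
  w_all <- apply(combs, 2, function(idx) sum(r[idx]))
  ew <- n1 * (n1 + n2 + 1) / 2
  p <- mean(abs(w_all - ew) >= abs(w_obs - ew) - 1e-12)
  u_obs <- w_obs - n1 * (n1 + 1) / 2
  list(U = u_obs, p = p)
}

# Centered local least-squares polynomial fit evaluated at the window center.
oracle_savgol_point <- function(x, i, window, polyorder) {
  h <- (window - 1) / 2
  idx <- (i - h):(i + h)
  t <- idx - i
  fit <- lm(x[idx] ~ poly(t, polyorder, raw = TRUE))
  unname(predict(fit, newdata = data.frame(t = 0)))
}

# A stabilogram object built directly from exact coordinates (no smoothing,
# no centering) so geometric features can be checked against hand
# computations.
raw_stab <- function(ap, ml, fs = 1) {
  structure(list(ap = ap, ml = ml, fs = fs, duration = length(ap) / fs),
            class = "stabilogram")
}

# Small null cohort configuration: no planted effects anywhere.
null_config <- function(n_concussion = 10, n_non_concussion = 10,
                        master_seed = 1) {
  sway <- c(baseline = 0.4, pre = 0.4, p25 = 0.4, p50 = 0.4, p75 = 0.4,
            post = 0.4)
  cohort_config(
    n_concussion = n_concussion, n_non_concussion = n_non_concussion,
    master_seed = master_seed,
    cop = list(alpha_post = c(concussion = 1.2, non_concussion = 1.2),
               sway_scale = list(concussion = sway, non_concussion = sway)),
    eeg = list(theta_delta_post_gain = 1),
    emg = list(soleus_post_power_gain = 1, bp_right_soleus_mdf_shift = 0),
    hr = list(noise_sd = c(concussion = 2, non_concussion = 2))
  )
}
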