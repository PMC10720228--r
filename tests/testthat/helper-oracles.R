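# Independent brute-force oracles, deliberately naive and loop-based so they
# share no code path with the package implementations they check.

# Higher Criticism by direct enumeration over order statistics.
hc_brute <- function(pvalues, variant = "hc_plus", alpha0 = 0.5) {
  n <- length(pvalues)
  ps <- sort(pvalues)
  ps[ps < 1e-10] <- 1e-10
  ps[ps > 1 - 1e-10] <- 1 - 1e-10
  best <- -Inf
  restricted <- -Inf
  any_restricted <- FALSE
  for (i in seq_len(max(1, floor(alpha0 * n)))) {
    v <- sqrt(n) * (i / n - ps[i]) / sqrt(ps[i] * (1 - ps[i]))
    best <- max(best, v)
    if (ps[i] > 1 / n) {
      restricted <- max(restricted, v)
      any_restricted <- TRUE
    }
  }
  if (variant == "hc2004" || !any_restricted) best else restricted
}

# Benjamini-Hochberg step-up by definition: largest k with p_(k) <= k q / m
# is the rejection cutoff; adjusted value is min_{j >= i} m p_(j) / j.
bh_brute <- function(pvalues, q = 0.05) {
  m <- length(pvalues)
  ord <- order(pvalues)
  ps <- pvalues[ord]
  k_max <- 0
  for (k in seq_len(m)) if (ps[k] <= k * q / m) k_max <- k
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- list(adjusted = numeric(m), discovered = logical(m))
  out$adjusted[ord] <- adj
  out$discovered[ord] <- seq_len(m) <= k_max
  out
}

# State-dynamics metrics by explicit scanning (no rle()).
state_metrics_brute <- function(states, n_states = max(states)) {
  nt <- 0
  runs <- list()
  cur_state <- states[1]; cur_len <- 1
  for (t in seq_along(states)[-1]) {
    if (states[t] == cur_state) {
      cur_len <- cur_len + 1
    } else {
      nt <- nt + 1
      runs[[length(runs) + 1]] <- c(cur_state, cur_len)
      cur_state <- states[t]; cur_len <- 1
    }
  }
  runs[[length(runs) + 1]] <- c(cur_state, cur_len)
  mdt <- rep(NA_real_, n_states)
  for (s in seq_len(n_states)) {
    lens <- vapply(runs, function(r) if (r[1] == s) r[2] else NA_real_,
                   numeric(1))
    lens <- lens[!is.na(lens)]
    if (length(lens)) mdt[s] <- mean(lens)
  }
  frc <- vapply(seq_len(n_states), function(s) mean(states == s), numeric(1))
  list(nt = nt, mdt = mdt, frc = frc)
}
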