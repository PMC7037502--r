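# Small study configurations reused across the suite. `tiny_cfg()` keeps
# every stochastic component on; `clean_cfg()` switches all of them off so
# samples equal their class templates exactly.

tiny_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_classes = 3L, samples_per_class = 10L,
                   train_per_class = 8L, n_points = 120L,
                   n_replicates = 2L, noise_sd = 0.01, seed = 42L)
  do.call(synth_config, utils::modifyList(defaults, args))
}

clean_cfg <- function(...) {
  tiny_cfg(noise_sd = 0, baseline_slope_sd = 0, baseline_offset_sd = 0,
           n_replicates = 1L, ...)
}

# brute-force oracles, written independently of the package internals
oracle_conv1d <- function(x, W, b) {
  m <- ncol(W)
  out <- matrix(NA_real_, nrow(W), length(x) - m + 1L)
  for (i in seq_len(nrow(W))) {
    for (t in seq_len(ncol(out))) {
      s <- 0
      for (k in seq_len(m)) s <- s + x[t + k - 1L] * W[i, k]
      out[i, t] <- s + b[i]
    }
  }
  out
}

oracle_conv2d <- function(x, kern, b) {
  kh <- nrow(kern); kw <- ncol(kern)
  oh <- nrow(x) - kh + 1L; ow <- ncol(x) - kw + 1L
  out <- matrix(NA_real_, oh, ow)
  for (r in seq_len(oh)) for (c in seq_len(ow)) {
    s <- 0
    for (i in seq_len(kh)) for (j in seq_len(kw)) {
      s <- s + x[r + i - 1L, c + j - 1L] * kern[i, j]
    }
    out[r, c] <- s + b
  }
  out
}

oracle_pool <- function(x, w, mode) {
  n_out <- length(x) %/% w
  vapply(seq_len(n_out), function(j) {
    win <- x[((j - 1L) * w + 1L):(j * w)]
    if (mode == "max") max(win) else mean(win)
  }, numeric(1L))
}
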