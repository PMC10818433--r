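# Shared fixtures and independent oracles for the test suite.

# direct-summation DFT magnitude of one frame (oracle for stft)
dft_oracle <- function(frame, K = floor(length(frame) / 2) + 1L) {
  N <- length(frame)
  vapply(0:(K - 1L), function(k)
    Mod(sum(frame * exp(-2i * pi * k * (0:(N - 1L)) / N))), 0)
}

# brute-force STFT over all frames (rectangular or supplied window)
stft_oracle <- function(x, n, hop, w = rep(1, n)) {
  L <- floor((length(x) - n) / hop) + 1L
  sapply(seq_len(L), function(m)
    dft_oracle(x[((m - 1) * hop + 1):((m - 1) * hop + n)] * w))
}

# periodogram peak frequency in Hz
peak_freq <- function(x, fs) {
  p <- Mod(stats::fft(x))^2
  f <- (seq_along(x) - 1) * fs / length(x)
  keep <- f <= fs / 2
  f[keep][which.max(p[keep])]
}

# fraction of periodogram energy inside [lo, hi] Hz
band_energy_fraction <- function(x, fs, lo, hi) {
  p <- Mod(stats::fft(x))^2
  f <- (seq_along(x) - 1) * fs / length(x)
  keep <- f <= fs / 2
  sum(p[keep & f >= lo & f <= hi]) / sum(p[keep])
}

# desk-scale transformer profile used across the classifier tests
tiny_vit_config <- function(n_classes = 2, ...) {
  vit_config(image_size = 64, patch_size = 16, d_model = 64, n_layers = 2,
             n_heads = 4, d_ff = 256, n_classes = n_classes, ...)
}

# images whose two classes differ by the intensity of a corner block:
# linearly separable by construction
separable_images <- function(n, seed, side = 64) {
  set.seed(seed)
  y <- factor(rep(c("a", "b"), length.out = n))
  imgs <- lapply(seq_len(n), function(i) {
    a <- array(runif(side * side * 3, 0, 0.4), c(side, side, 3))
    if (y[i] == "b") a[1:16, 1:16, ] <- a[1:16, 1:16, ] + 0.6
    a
  })
  list(images = imgs, labels = y)
}

# exact two-sided Mann-Whitney p by complete enumeration of group labels
mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  m <- length(a); n <- length(b)
  u_stat <- function(ia) {
    av <- pooled[ia]; bv <- pooled[-ia]
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  }
  obs <- u_stat(seq_len(m))
  us <- combn(m + n, m, u_stat)
  min(1, 2 * min(mean(us <= obs), mean(us >= obs)))
}

# exact two-sided Wilcoxon signed-rank p by enumerating all sign patterns
sr_exact_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- signs %*% r
  min(1, 2 * min(mean(vs <= obs), mean(vs >= obs)))
}
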