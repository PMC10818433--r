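fs <- 4000

test_that("stft matches the direct-summation DFT oracle on random signals", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(c(32L, 64L, 128L), 1)
    hop <- sample(c(n %/% 4, n %/% 2, n), 1)
    x <- rnorm(sample(300:1024, 1))
    S <- stft(x, fs, n = n, hop = hop, window = "rectangular")
    expect_lt(max(abs(S$values - stft_oracle(x, n, hop))), 1e-8)
  }
  # windowed case
  x <- rnorm(600)
  w <- 0.5 * (1 - cos(2 * pi * (0:63) / 63))
  S <- stft(x, fs, n = 64, hop = 32, window = "hann")
  expect_lt(max(abs(S$values - stft_oracle(x, 64, 32, w))), 1e-8)
})

test_that("stft handles canonical spectra: silence, impulse, frame-aligned sine", {
  z <- stft(numeric(1000), fs, n = 256, hop = 128)
  expect_true(all(z$values == 0))

  imp <- c(1, numeric(511))
  S <- stft(imp, fs, n = 256, hop = 256, window = "rectangular")
  expect_equal(S$values[, 1], rep(1, 129), tolerance = 1e-12)

  x <- sin(2 * pi * (fs / 4) * (0:(fs - 1)) / fs)
  S <- stft(x, fs, n = 256, hop = 256, window = "rectangular")
  expect_equal(unname(which.max(S$values[, 1])), 65L)   # bin index 64 (0-based)
  expect_equal(max(S$values[, 1]), 128, tolerance = 1e-9)

  expect_error(stft(numeric(100), fs, n = 256), "shorter")
})

test_that("the Mel scale evaluates to its reference points", {
  expect_equal(mel_scale(0), 0)
  expect_equal(mel_scale(700), 1127 * log(2), tolerance = 1e-12)
  expect_equal(mel_scale(700), 781.177, tolerance = 1e-6)
  expect_equal(mel_scale(1000), 999.99, tolerance = 1e-4)
  expect_error(mel_scale(-1))
  # inverse round trip
  f <- c(0, 123.4, 700, 1999)
  expect_equal(mel_scale_inv(mel_scale(f)), f, tolerance = 1e-9)
})

test_that("Mel filter peaks are equispaced on the Mel scale with growing bandwidths", {
  H <- mel_filterbank(fs, 512, n_mels = 24, fmin = 0, fmax = 2000)
  pk <- attr(H, "peak_freqs")
  dm <- diff(mel_scale(pk))
  expect_lt(max(abs(dm - dm[1])) / dm[1], 1e-9)
  # supports lie inside [fmin, fmax] and are non-negative
  bin_freq <- (0:256) * fs / 512
  expect_true(all(H >= 0))
  expect_true(all(H[, bin_freq > 2000] == 0))
  # triangular supports widen with frequency (in Hz)
  widths <- apply(H, 1, function(row) diff(range(bin_freq[row > 0])))
  expect_gt(widths[24], widths[2])

  # middle peak of a 3-filter bank sits at the Mel midpoint (inverse solved
  # independently via root finding)
  H3 <- mel_filterbank(fs, 512, n_mels = 3, fmin = 0, fmax = 2000)
  target <- mel_scale(2000) / 2
  f_mid <- uniroot(function(f) mel_scale(f) - target, c(1, 2000),
                   tol = 1e-10)$root
  expect_equal(attr(H3, "peak_freqs")[2], f_mid, tolerance = 1e-6)

  expect_error(mel_filterbank(fs, 64, n_mels = 60, fmin = 0, fmax = 2000),
               "collide")
})

test_that("mfcc equals the direct DCT of the log-Mel energies, frame for frame", {
  set.seed(4)
  x <- rnorm(3000)
  M <- 32; nc <- 13
  cep <- mfcc(x, fs, n = 256, hop = 128, n_mels = M, n_mfcc = nc)
  lm <- mfcc(x, fs, n = 256, hop = 128, n_mels = M, n_mfcc = nc,
             output = "logmel")
  sp <- stft(x, fs, n = 256, hop = 128)
  expect_equal(ncol(cep$values), ncol(sp$values))
  expect_equal(nrow(cep$values), nc)
  # direct-summation DCT oracle per frame
  oracle <- matrix(0, nc, ncol(lm$values))
  for (nn in 0:(nc - 1)) for (fr in seq_len(ncol(lm$values)))
    oracle[nn + 1, fr] <- sqrt(2 / M) *
      sum(lm$values[, fr] * cos(pi * nn * ((0:(M - 1)) + 0.5) / M))
  expect_equal(cep$values, oracle, tolerance = 1e-10)
})

test_that("the mfcc DCT maps constant and unit-impulse energy vectors correctly", {
  # these identities pin the DCT convention: constant S -> only Y_0 nonzero;
  # S = (1,0,0,0) with M = 4 -> Y_n = sqrt(1/2) cos(pi n / 8)
  M <- 4
  D <- sqrt(2 / M) * cos(pi * outer(0:(M - 1), (0:(M - 1)) + 0.5) / M)
  cc <- 3.7
  y_const <- D %*% rep(cc, M)
  expect_equal(y_const[1], sqrt(2 / M) * M * cc, tolerance = 1e-12)
  expect_equal(y_const[-1], rep(0, M - 1), tolerance = 1e-12)
  y_imp <- D %*% c(1, 0, 0, 0)
  expect_equal(as.numeric(y_imp), sqrt(1 / 2) * cos(pi * (0:3) / 8),
               tolerance = 1e-12)
  # the same DCT matrix drives mfcc: a signal whose band energies are flat
  # in Mel has all cepstra beyond Y_0 far smaller than Y_0
  set.seed(5)
  cep <- mfcc(rnorm(4000), fs, n = 256, hop = 128, n_mels = M, n_mfcc = 4)
  expect_true(all(abs(rowMeans(cep$values)[2:4]) <
                    abs(rowMeans(cep$values)[1])))
})

test_that("silent frames are floored before the log instead of failing", {
  x <- c(numeric(600), rnorm(600))
  expect_message(cep <- mfcc(x, fs, n = 256, hop = 128), "floored")
  expect_true(all(is.finite(cep$values)))
})

test_that("CQT bins double each octave exactly and share one Q factor", {
  x <- sin(2 * pi * 400 * (0:11999) / fs)
  cq <- cqt(x, fs, f1 = 100, bins_per_octave = 12)
  expect_identical(cq$freqs[13], 2 * cq$freqs[1])
  expect_identical(cq$freqs[25], 2 * cq$freqs[13])
  q <- cq$q_factors
  expect_lt(max(abs(q - q[1])) / q[1], 1e-9)
  # atom lengths shrink inversely with frequency
  expect_true(all(diff(cq$atom_lengths) <= 0))
  # pure 400 Hz tone peaks in the bin whose centre frequency is nearest
  k_hat <- which.max(rowMeans(cq$values))
  expect_equal(k_hat, which.min(abs(cq$freqs - 400)))

  expect_error(cqt(x, fs, f1 = -5), "positive")
  expect_error(cqt(rnorm(100), fs, f1 = 20, bins_per_octave = 12),
               "exceeds the signal")
})

test_that("all four front-ends agree on the time span of a 6 s cycle", {
  set.seed(6)
  x <- rnorm(6 * fs) * 0.1
  reps <- list(stft(x, fs), mfcc(x, fs), cqt(x, fs), cochleogram(x, fs))
  spans <- t(vapply(reps, function(r) range(r$frame_times), numeric(2)))
  hop <- 0.042
  expect_lt(max(spans[, 1]) - min(spans[, 1]), hop + 1e-9)
  expect_lt(max(spans[, 2]) - min(spans[, 2]), hop + 1e-9)
})
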