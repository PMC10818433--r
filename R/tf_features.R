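# Time-frequency front-ends: STFT magnitude spectrogram, Mel filterbank /
# MFCC, and constant-Q transform. All return a common `tfrep` container.

#' Construct a time-frequency representation
#'
#' @param values K x L numeric matrix (rows = frequency channels / coefficient
#'   indices, columns = time frames).
#' @param freqs Length-K centre frequencies in Hz (coefficient indices for the
#'   cepstral scale).
#' @param frame_times Length-L frame-centre times in seconds.
#' @param scale One of `"linear"`, `"mel"`, `"logfreq"`, `"erb"`, `"cepstral"`.
#' @return An object of class `tfrep`.
#' @export
tfrep <- function(values, freqs, frame_times,
                  scale = c("linear", "mel", "logfreq", "erb", "cepstral")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("tfrep values must be finite")
  if (scale != "cepstral") {
    if (any(values < 0)) stop("magnitude/energy representations must be >= 0")
    if (is.unsorted(freqs)) stop("freqs must be non-decreasing")
  }
  if (nrow(values) != length(freqs) || ncol(values) != length(frame_times))
    stop("values dimensions must match freqs x frame_times")
  structure(list(values = values, freqs = freqs, frame_times = frame_times,
                 scale = scale),
            class = "tfrep")
}

#' @export
print.tfrep <- function(x, ...) {
  cat(sprintf("<tfrep> %d x %d (%s scale), %.3f-%.3f s\n",
              nrow(x$values), ncol(x$values), x$scale,
              min(x$frame_times), max(x$frame_times)))
  invisible(x)
}

#' @export
plot.tfrep <- function(x, ...) {
  graphics::image(x$frame_times, seq_along(x$freqs), t(x$values),
                  xlab = "time (s)",
                  ylab = if (x$scale == "cepstral") "coefficient" else "channel",
                  col = viridis_colors(256), ...)
  invisible(x)
}

.make_window <- function(window, n) {
  if (is.numeric(window)) {
    if (length(window) != n) stop("window vector must have length N")
    return(window)
  }
  switch(match.arg(window, c("hann", "hamming", "rectangular")),
         hann = 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1))),
         hamming = 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1)),
         rectangular = rep(1, n))
}

# frame start indices (1-based) and centre times for length-n signal
.frame_grid <- function(n, N, J, fs) {
  if (n < N) stop("signal shorter than one analysis frame")
  L <- floor((n - N) / J) + 1L
  starts <- (seq_len(L) - 1L) * J + 1L
  times <- ((starts - 1L) + N / 2) / fs
  list(L = L, starts = starts, times = times)
}

#' Short-time Fourier transform magnitude spectrogram
#'
#' Frame m (1-based) covers samples `(m-1)*hop + 1 .. (m-1)*hop + n`;
#' the windowed DFT is taken and the magnitudes of the `n/2 + 1`
#' non-redundant bins are returned (phase is discarded).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param n Window length in samples (default 84 ms worth, matching the
#'   cochleogram frame for comparability).
#' @param hop Frame hop in samples (default `n/2`).
#' @param window Window name (`"hann"`, `"hamming"`, `"rectangular"`) or a
#'   numeric vector of length `n`.
#' @return A [tfrep] on the linear frequency scale.
#' @export
stft <- function(x, fs, n = round(0.084 * fs), hop = floor(n / 2),
                 window = "hann") {
  n <- as.integer(n); hop <- as.integer(hop)
  if (n < 2L) stop("window length must be at least 2")
  if (hop < 1L || hop > n) stop("hop must satisfy 1 <= hop <= n")
  w <- .make_window(window, n)
  g <- .frame_grid(length(x), n, hop, fs)
  frames <- matrix(x[outer(0:(n - 1L), g$starts, "+")], nrow = n) * w
  spec <- stats::mvfft(frames)
  K <- floor(n / 2) + 1L
  mag <- abs(spec[seq_len(K), , drop = FALSE])
  tfrep(mag, freqs = (seq_len(K) - 1L) * fs / n, frame_times = g$times,
        scale = "linear")
}

# ---- Mel scale and MFCC -----------------------------------------------------

#' Mel scale
#'
#' `Mel(f) = 1127 * ln(1 + f/700)`.
#'
#' @param f Frequency in Hz (>= 0, vectorized).
#' @return Mel value(s).
#' @export
mel_scale <- function(f) {
  if (any(f < 0)) stop("frequency must be non-negative")
  1127 * log(1 + f / 700)
}

#' Inverse Mel scale
#'
#' @param m Mel value(s) (>= 0).
#' @return Frequency in Hz.
#' @export
mel_scale_inv <- function(m) 700 * (exp(m / 1127) - 1)

#' Triangular Mel filterbank
#'
#' `n_mels` triangular filters whose peaks sit at points uniformly spaced on
#' the Mel scale between `mel_scale(fmin)` and `mel_scale(fmax)` (inclusive).
#' Interior filters span their two neighbouring peaks; the edge filters are
#' half-triangles, so every support lies inside `[fmin, fmax]` and bandwidths
#' grow with frequency.
#'
#' @param fs Sampling rate in Hz.
#' @param n_fft FFT length used for the spectra the bank will be applied to.
#' @param n_mels Number of filters (>= 2).
#' @param fmin,fmax Band edges in Hz, `0 <= fmin < fmax <= fs/2`.
#' @return `n_mels` x `(n_fft/2 + 1)` filter matrix with attribute
#'   `"peak_freqs"` (Hz).
#' @export
mel_filterbank <- function(fs, n_fft, n_mels = 64, fmin = 0, fmax = fs / 2) {
  if (n_mels < 2) stop("n_mels must be at least 2")
  if (!(fmin >= 0 && fmin < fmax && fmax <= fs / 2))
    stop("need 0 <= fmin < fmax <= fs/2")
  K <- floor(n_fft / 2) + 1L
  bin_freq <- (seq_len(K) - 1L) * fs / n_fft
  peaks_mel <- seq(mel_scale(fmin), mel_scale(fmax), length.out = n_mels)
  peaks_hz <- mel_scale_inv(peaks_mel)
  peak_bins <- round(peaks_hz / fs * n_fft)
  if (any(diff(peak_bins) < 1))
    stop("n_mels too large for n_fft: adjacent filter peaks collide")
  bin_mel <- mel_scale(bin_freq)
  H <- matrix(0, n_mels, K)
  for (m in seq_len(n_mels)) {
    lo <- if (m == 1L) peaks_mel[1] else peaks_mel[m - 1]
    pk <- peaks_mel[m]
    hi <- if (m == n_mels) peaks_mel[n_mels] else peaks_mel[m + 1]
    up <- if (pk > lo) (bin_mel - lo) / (pk - lo) else as.numeric(bin_mel >= pk)
    dn <- if (hi > pk) (hi - bin_mel) / (hi - pk) else as.numeric(bin_mel <= pk)
    H[m, ] <- pmax(0, pmin(up, dn))
    # keep supports inside [fmin, fmax]
    H[m, bin_freq < fmin | bin_freq > fmax] <- 0
  }
  attr(H, "peak_freqs") <- peaks_hz
  H
}

#' Mel-frequency cepstral coefficients
#'
#' Per frame: power spectrum `|X(k)|^2`, Mel filterbank energies, logarithm
#' (with a floor applied before the log so silent frames stay finite), then a
#' DCT `Y_n = sqrt(2/M) * sum_m S_m cos(pi n (m + 1/2) / M)` of which the
#' first `n_mfcc` coefficients are retained.
#'
#' @inheritParams stft
#' @param n_mels,fmin,fmax Filterbank geometry, see [mel_filterbank()].
#' @param n_mfcc Number of DCT coefficients retained (default 20).
#' @param log_floor Floor applied to filterbank energies before the log.
#' @param output `"cepstra"` (default) for the coefficient matrix, or
#'   `"logmel"` for the log-Mel spectrogram `S_m` feeding the DCT.
#' @return A [tfrep] (`"cepstral"` or `"mel"` scale); frame count equals the
#'   STFT frame count.
#' @export
mfcc <- function(x, fs, n = round(0.084 * fs), hop = floor(n / 2),
                 window = "hann", n_mels = 64, n_mfcc = 20,
                 fmin = 0, fmax = fs / 2, log_floor = 1e-10,
                 output = c("cepstra", "logmel")) {
  output <- match.arg(output)
  if (n_mfcc < 1 || n_mfcc > n_mels) stop("need 1 <= n_mfcc <= n_mels")
  sp <- stft(x, fs, n = n, hop = hop, window = window)
  H <- mel_filterbank(fs, n, n_mels = n_mels, fmin = fmin, fmax = fmax)
  E <- H %*% (sp$values^2)
  if (any(E < log_floor))
    message("mfcc: zero/near-zero filter energies floored before log")
  S <- log(pmax(E, log_floor))
  if (output == "logmel") {
    # log energies may be negative, so bypass the >= 0 magnitude invariant
    return(structure(list(values = S,
                          freqs = attr(H, "peak_freqs"),
                          frame_times = sp$frame_times, scale = "mel"),
                     class = "tfrep"))
  }
  M <- n_mels
  D <- sqrt(2 / M) *
    cos(pi * outer(0:(n_mfcc - 1L), (0:(M - 1L)) + 0.5) / M)
  Y <- D %*% S
  structure(list(values = Y, freqs = 0:(n_mfcc - 1L),
                 frame_times = sp$frame_times, scale = "cepstral"),
            class = "tfrep")
}

# ---- constant-Q transform ---------------------------------------------------

#' Constant-Q transform magnitude
#'
#' Bin centre frequencies follow `f_k = f1 * 2^((k-1)/b)` so that `b` bins
#' span one octave and `f_(k+b) = 2 f_k` holds exactly; every bin shares the
#' quality factor `Q = 1 / (2^(1/b) - 1)` because atom lengths
#' `N_k = round(Q fs / f_k)` shrink inversely with frequency. Atoms are
#' window-shaped complex exponentials evaluated by direct summation on a
#' regular hop grid (centred frames, zero-padded at the edges).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param f1 Centre frequency of the lowest bin in Hz (> 0).
#' @param bins_per_octave Bins per octave `b` (>= 1).
#' @param fmax Highest admissible centre frequency (<= fs/2).
#' @param hop Hop between frame centres in seconds (default 42 ms, matching
#'   the other front-ends).
#' @param window Atom window name (default Hann).
#' @return A [tfrep] on the log-frequency scale with attribute `"Q"` on the
#'   values (stored in field `q_factors`).
#' @export
cqt <- function(x, fs, f1 = 100, bins_per_octave = 12, fmax = fs / 2,
                hop = 0.042, window = "hann") {
  b <- bins_per_octave
  if (f1 <= 0) stop("f1 must be positive")
  if (b < 1) stop("bins_per_octave must be >= 1")
  if (fmax > fs / 2) stop("fmax must not exceed fs/2")
  K <- floor(b * log2(fmax / f1)) + 1L
  if (K < 1L) stop("no CQT bins between f1 and fmax")
  # f_k via integer octave decomposition so f_(k+b) = 2 f_k is exact
  j <- 0:(K - 1L)
  fk <- f1 * 2^(j %/% b) * 2^((j %% b) / b)
  Q <- 1 / (2^(1 / b) - 1)
  Nk <- pmax(2L, as.integer(round(Q * fs / fk)))
  if (max(Nk) > length(x))
    stop("longest CQT atom exceeds the signal; raise f1 or shorten atoms")
  Nref <- round(0.084 * fs)
  Hs <- max(1L, as.integer(round(hop * fs)))
  g <- .frame_grid(length(x), Nref, Hs, fs)
  centres <- g$starts + as.integer(Nref / 2)   # frame-centre samples
  pad <- max(Nk)
  xp <- c(numeric(pad), x, numeric(pad))
  V <- matrix(0, K, g$L)
  for (k in seq_len(K)) {
    nk <- Nk[k]
    nn <- 0:(nk - 1L)
    atom <- (1 / nk) * .make_window(window, nk) *
      exp(1i * 2 * pi * nn * fk[k] / fs)
    starts <- centres - as.integer(floor(nk / 2)) + pad
    idx <- outer(nn, starts, "+")
    seg <- matrix(xp[idx], nrow = nk)
    V[k, ] <- Mod(crossprod(seg, Conj(atom)))
  }
  out <- tfrep(V, freqs = fk, frame_times = g$times, scale = "logfreq")
  out$q_factors <- rep(Q, K)
  out$atom_lengths <- Nk
  out
}
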