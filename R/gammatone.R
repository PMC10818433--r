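# Gammatone filterbank and cochleogram: an auditory time-frequency
# representation whose channel centre frequencies and bandwidths follow the
# equivalent rectangular bandwidth (ERB) scale of the human cochlea.

#' Equivalent rectangular bandwidth
#'
#' `ERB(fc) = 24.7 * (4.37 * fc/1000 + 1)` Hz.
#'
#' @param fc Centre frequency in Hz (>= 0, vectorized).
#' @return Bandwidth in Hz.
#' @export
erb <- function(fc) {
  if (any(fc < 0)) stop("centre frequency must be non-negative")
  24.7 * (4.37 * fc / 1000 + 1)
}

#' ERB-rate scale
#'
#' The ERB-number of a frequency: the integral of `1/ERB(f)` from 0 to `f`,
#' i.e. `(1000 / (24.7 * 4.37)) * ln(1 + 4.37 f / 1000)`. Uniform spacing on
#' this scale mimics the cochlea's frequency map.
#'
#' @param f Frequency in Hz (vectorized).
#' @return ERB-rate value(s).
#' @export
erb_rate <- function(f) (1000 / (24.7 * 4.37)) * log(1 + 4.37 * f / 1000)

#' Inverse ERB-rate scale
#'
#' @param r ERB-rate value(s).
#' @return Frequency in Hz.
#' @export
erb_rate_inv <- function(r) (exp(r * 24.7 * 4.37 / 1000) - 1) * 1000 / 4.37

#' Design a gammatone filterbank
#'
#' `n_filters` channels with centre frequencies between `fmin` and `fmax`,
#' uniformly spaced on the ERB-rate scale (default) or linearly in Hz.
#' Channel bandwidths are `1.019 * ERB(fc)`.
#'
#' @param fs Sampling rate in Hz.
#' @param n_filters Number of channels (default 64, >= 2).
#' @param fmin,fmax Centre-frequency range in Hz; `fmin < fmax <= fs/2`
#'   (defaults 100 Hz and `fs/2`, the band carrying adventitious sounds).
#' @param order Gammatone filter order (default 4).
#' @param spacing `"erb"` (default) or `"linear"`.
#' @return An object of class `gammatone_bank` with fields `fc`, `bw`,
#'   `order`, `rate`.
#' @export
gammatone_bank <- function(fs, n_filters = 64, fmin = 100, fmax = fs / 2,
                           order = 4, spacing = c("erb", "linear")) {
  spacing <- match.arg(spacing)
  if (n_filters < 2) stop("n_filters must be at least 2")
  if (!(fmin < fmax)) stop("fmin must be below fmax")
  if (fmax > fs / 2) stop("fmax must not exceed fs/2")
  if (order < 1) stop("order must be >= 1")
  fc <- switch(spacing,
               erb = erb_rate_inv(seq(erb_rate(fmin), erb_rate(fmax),
                                      length.out = n_filters)),
               linear = seq(fmin, fmax, length.out = n_filters))
  structure(list(fc = fc, bw = 1.019 * erb(fc), order = order, rate = fs,
                 n_filters = n_filters, spacing = spacing),
            class = "gammatone_bank")
}

#' @export
print.gammatone_bank <- function(x, ...) {
  cat(sprintf(
    "<gammatone_bank> %d filters (order %d, %s spacing), %.1f-%.1f Hz @ %g Hz\n",
    x$n_filters, x$order, x$spacing, min(x$fc), max(x$fc), x$rate))
  invisible(x)
}

# time at which the gamma envelope t^(o-1) exp(-2 pi b t) drops to `frac`
# of its peak (peak at t = (o-1)/(2 pi b))
.gamma_env_cutoff <- function(order, bw, frac = 1e-3) {
  a <- 2 * pi * bw
  if (order == 1L) return(-log(frac) / a)
  tp <- (order - 1) / a
  log_env <- function(t) (order - 1) * log(t) - a * t
  target <- log_env(tp) + log(frac)
  stats::uniroot(function(t) log_env(t) - target,
                 lower = tp, upper = tp + 50 / a, tol = 1e-10)$root
}

#' Gammatone impulse response
#'
#' `g(t) = t^(o-1) exp(-2 pi b t) cos(2 pi fc t)` sampled at `fs` and
#' peak-normalized to unit maximum absolute amplitude. When `duration` is
#' `NULL` the response is truncated where the gamma envelope falls below
#' 0.1% of its peak, which keeps the FIR absolutely summable and short.
#'
#' @param fc Centre frequency in Hz.
#' @param order Filter order `o` (>= 1).
#' @param bandwidth Exponential decay coefficient `b(fc)` in Hz.
#' @param fs Sampling rate in Hz.
#' @param duration Length in seconds, or `NULL` for automatic truncation.
#' @return Numeric vector of samples.
#' @export
gammatone_ir <- function(fc, order, bandwidth, fs, duration = NULL) {
  if (is.null(duration)) duration <- .gamma_env_cutoff(order, bandwidth)
  if (duration <= 0) stop("duration must be positive")
  n <- max(2L, as.integer(round(duration * fs)))
  t <- (0:(n - 1L)) / fs
  g <- t^(order - 1) * exp(-2 * pi * bandwidth * t) * cos(2 * pi * fc * t)
  g / max(abs(g))
}

#' Cochleogram
#'
#' The signal is passed through every gammatone channel (FFT convolution with
#' the truncated impulse response) and the per-channel energy is summed over
#' Hann-windowed frames: `C(k, m) = sum_n Xhat(k, n)^2 w(n)`, which is
#' non-negative everywhere.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param bank A [gammatone_bank]; defaults to the 64-channel ERB-spaced bank
#'   over 100 Hz to `fs/2`.
#' @param frame_len Frame length in seconds (default 84 ms).
#' @param hop Frame hop in seconds (default half a frame).
#' @return A [tfrep] on the ERB scale.
#' @export
cochleogram <- function(x, fs, bank = NULL, frame_len = 0.084,
                        hop = frame_len / 2) {
  if (is.null(bank)) bank <- gammatone_bank(fs)
  if (bank$rate != fs) stop("bank was designed for a different sampling rate")
  n <- length(x)
  Fr <- as.integer(round(frame_len * fs))
  Hs <- max(1L, as.integer(round(hop * fs)))
  if (n < Fr) stop("signal shorter than one cochleogram frame")
  kern <- .coch_kernels(bank, n)
  X <- stats::fft(c(x, numeric(kern$nfft - n)))
  g <- .frame_grid(n, Fr, Hs, fs)
  w <- .make_window("hann", Fr)
  idx <- outer(0:(Fr - 1L), g$starts, "+")
  C <- matrix(0, bank$n_filters, g$L)
  for (k in seq_len(bank$n_filters)) {
    y <- Re(stats::fft(X * kern$Hf[[k]], inverse = TRUE))[seq_len(n)] /
      kern$nfft
    e <- y * y
    C[k, ] <- colSums(matrix(e[idx], nrow = Fr) * w)
  }
  tfrep(C, freqs = bank$fc, frame_times = g$times, scale = "erb")
}

# frequency-domain gammatone kernels, cached per (bank geometry, fft size):
# featurizing a corpus applies the same bank to thousands of equal-length
# cycles, and the kernel FFTs dominate the per-call cost
.coch_cache <- new.env(parent = emptyenv())

.coch_kernels <- function(bank, n) {
  key <- paste(bank$rate, bank$n_filters, bank$order, bank$spacing,
               signif(bank$fc[1], 10), signif(bank$fc[bank$n_filters], 10),
               n, sep = "|")
  hit <- .coch_cache[[key]]
  if (!is.null(hit)) return(hit)
  irs <- lapply(seq_len(bank$n_filters), function(k)
    gammatone_ir(bank$fc[k], bank$order, bank$bw[k], bank$rate))
  nfft <- stats::nextn(n + max(lengths(irs)) - 1L, c(2, 3))
  Hf <- lapply(irs, function(h) stats::fft(c(h, numeric(nfft - length(h)))))
  out <- list(nfft = nfft, Hf = Hf)
  .coch_cache[[key]] <- out
  out
}
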