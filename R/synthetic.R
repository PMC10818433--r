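# Synthetic respiratory-cycle simulator. Generates labelled cycles (normal /
# crackle / wheeze / both) with the spectro-temporal structure of real
# auscultation sounds: broadband breath noise concentrated in 100-2000 Hz,
# tonal wheezes (fundamental 100-1000 Hz, >= 80 ms), and transient crackles
# (coarse < 15 ms low pitch, fine < 5 ms high pitch), grouped by synthetic
# patients so patient-wise cross-validation is meaningful.

# evaluate fn under a temporary seed, restoring the caller's RNG state
.with_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  fn()
}

#' Simulation configuration
#'
#' Defaults mirror the working conditions of the classification task:
#' 4 kHz sampling, 6 s cycles, and class proportions matching the ICBHI
#' corpus (normal 0.528, crackle 0.270, wheeze 0.128, both 0.073).
#'
#' @param n_patients Number of synthetic patients (>= 1).
#' @param cycles_per_patient Cycles generated per patient.
#' @param class_probs Length-4 probabilities for (normal, crackle, wheeze,
#'   both); must sum to 1.
#' @param snr_db Event-to-base signal-to-noise ratio in dB, defined on event
#'   energy over the base sound's energy within the event's support.
#' @param rate Sampling rate in Hz (default 4000).
#' @param duration Cycle duration in seconds (default 6).
#' @param seed Integer RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 10, cycles_per_patient = 8,
                       class_probs = c(normal = 0.528, crackle = 0.270,
                                       wheeze = 0.128, both = 0.074),
                       snr_db = 10, rate = 4000, duration = 6, seed = 1) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  if (length(class_probs) != 4L || any(class_probs < 0) ||
      abs(sum(class_probs) - 1) > 1e-9)
    stop("class_probs must be 4 non-negative values summing to 1")
  if (!is.finite(snr_db)) stop("snr_db must be finite")
  names(class_probs) <- c("normal", "crackle", "wheeze", "both")
  structure(list(n_patients = n_patients,
                 cycles_per_patient = cycles_per_patient,
                 class_probs = class_probs, snr_db = snr_db,
                 rate = rate, duration = duration, seed = as.integer(seed)),
            class = "sim_config")
}

#' Specify a single adventitious event
#'
#' Validates the spectro-temporal bounds of each event family: wheezes last
#' at least 80 ms with fundamental in \[100, 1000\] Hz; coarse crackles last
#' under 15 ms; fine crackles under 5 ms.
#'
#' @param kind `"wheeze"`, `"coarse_crackle"` or `"fine_crackle"`.
#' @param onset Event onset within the cycle, seconds.
#' @param duration Event duration, seconds.
#' @param f0 Fundamental (wheeze) or dominant (crackle) frequency, Hz.
#' @return An object of class `event_spec`.
#' @export
event_spec <- function(kind = c("wheeze", "coarse_crackle", "fine_crackle"),
                       onset, duration, f0) {
  kind <- match.arg(kind)
  if (onset < 0) stop("onset must be non-negative")
  if (duration <= 0 || f0 <= 0) stop("duration and f0 must be positive")
  if (kind == "wheeze") {
    if (duration < 0.08)
      stop("wheeze duration must be at least 80 ms")
    if (f0 < 100 || f0 > 1000)
      stop("wheeze fundamental must lie in [100, 1000] Hz")
  } else if (kind == "coarse_crackle" && duration >= 0.015) {
    stop("coarse crackles must last less than 15 ms")
  } else if (kind == "fine_crackle" && duration >= 0.005) {
    stop("fine crackles must last less than 5 ms")
  }
  structure(list(kind = kind, onset = onset, duration = duration, f0 = f0),
            class = "event_spec")
}

#' Generate a normal (vesicular) breath sound
#'
#' Gaussian noise band-limited to 100-2000 Hz (zero-phase Butterworth) and
#' amplitude-modulated by a two-phase breath envelope: a raised-cosine
#' inspiration lobe followed by a longer, weaker expiration lobe. At least
#' 90% of the spectral energy falls inside 100-2000 Hz.
#'
#' @param duration Length in seconds.
#' @param rate Sampling rate in Hz.
#' @return Numeric vector of `round(rate * duration)` samples. Uses the
#'   current RNG state; seed the generator for reproducibility.
#' @export
gen_normal <- function(duration, rate) {
  if (duration <= 0) stop("duration must be positive")
  n <- round(rate * duration)
  noise <- stats::rnorm(n)
  nyq <- rate / 2
  if (2000 < nyq) {
    flt <- signal::butter(4, c(100, 2000) / nyq, type = "pass")
  } else {
    flt <- signal::butter(4, 100 / nyq, type = "high")
  }
  x <- signal::filtfilt(flt, noise)
  t <- (0:(n - 1)) / n                       # normalized cycle time
  lobe <- function(c0, w, a) {
    v <- numeric(n)
    in_lobe <- t >= c0 & t < c0 + w
    v[in_lobe] <- a * sin(pi * (t[in_lobe] - c0) / w)^2
    v
  }
  env <- lobe(0.02, 0.38, 1) + lobe(0.45, 0.5, 0.65) + 0.03
  y <- x * env
  0.3 * y / max(abs(y))
}

#' Generate a wheeze event
#'
#' A tonal, narrowband sound: a fundamental at `f0` plus two weaker
#' harmonics (those below Nyquist), with a slow sinusoidal frequency drift
#' of at most 3% of `f0` and raised-cosine onset/offset ramps. The dominant
#' periodogram peak stays within 5% of `f0`.
#'
#' @param spec An [event_spec] of kind `"wheeze"`.
#' @param rate Sampling rate in Hz.
#' @return Numeric vector of `round(rate * duration)` samples, peak
#'   amplitude 1. Uses the current RNG state.
#' @export
gen_wheeze <- function(spec, rate) {
  stopifnot(inherits(spec, "event_spec"))
  if (spec$kind != "wheeze") stop("spec kind must be 'wheeze'")
  n <- round(rate * spec$duration)
  t <- (0:(n - 1)) / rate
  depth <- stats::runif(1, 0.005, 0.03)      # relative drift <= 3%
  fd <- stats::runif(1, 0.3, 1.5)            # drift rate, Hz
  ph0 <- stats::runif(1, 0, 2 * pi)
  finst <- spec$f0 * (1 + depth * sin(2 * pi * fd * t + ph0))
  phase <- 2 * pi * cumsum(finst) / rate
  amps <- c(1, 0.3, 0.12)
  y <- numeric(n)
  for (h in 1:3) {
    if (h * spec$f0 * 1.03 >= 0.95 * rate / 2) next
    y <- y + amps[h] * sin(h * phase + stats::runif(1, 0, 2 * pi))
  }
  ramp_n <- max(2L, round(min(0.1 * spec$duration, 0.02) * rate))
  ramp <- sin(pi * (0:(ramp_n - 1)) / (2 * (ramp_n - 1)))^2
  env <- rep(1, n)
  env[seq_len(ramp_n)] <- ramp
  env[n + 1 - seq_len(ramp_n)] <- ramp
  y <- y * env
  y / max(abs(y))
}

#' Generate a crackle event
#'
#' An exponentially damped sinusoid burst at the dominant frequency, hard
#' truncated at the event duration (well below the kind's duration bound,
#' so the energy outside the support is nil). Coarse crackles carry a low
#' pitch, fine crackles a high pitch.
#'
#' @param spec An [event_spec] of kind `"coarse_crackle"` or
#'   `"fine_crackle"`.
#' @param rate Sampling rate in Hz.
#' @return Numeric vector of `round(rate * duration)` samples, peak
#'   amplitude 1.
#' @export
gen_crackle <- function(spec, rate) {
  stopifnot(inherits(spec, "event_spec"))
  if (!spec$kind %in% c("coarse_crackle", "fine_crackle"))
    stop("spec kind must be a crackle")
  n <- max(4L, round(rate * spec$duration))
  t <- (0:(n - 1)) / rate
  tau <- spec$duration / 6
  y <- sin(2 * pi * spec$f0 * t) * exp(-t / tau)
  y / max(abs(y))
}

# draw the event list for one cycle of the given class
.draw_events <- function(label, duration) {
  ev <- list()
  if (label %in% c("wheeze", "both")) {
    for (i in seq_len(sample(1:3, 1))) {
      d <- stats::runif(1, 0.15, 0.8)
      ev[[length(ev) + 1L]] <- event_spec(
        "wheeze", onset = stats::runif(1, 0.2, duration - d - 0.2),
        duration = d, f0 = stats::runif(1, 150, 850))
    }
  }
  if (label %in% c("crackle", "both")) {
    for (i in seq_len(sample(3:8, 1))) {
      coarse <- stats::runif(1) < 0.5
      d <- if (coarse) stats::runif(1, 0.008, 0.014) else
        stats::runif(1, 0.002, 0.0045)
      ev[[length(ev) + 1L]] <- event_spec(
        if (coarse) "coarse_crackle" else "fine_crackle",
        onset = stats::runif(1, 0.2, duration - 0.25),
        duration = d,
        f0 = if (coarse) stats::runif(1, 120, 600) else
          stats::runif(1, 600, 1800))
    }
  }
  ev
}

#' Generate a labelled synthetic dataset
#'
#' For every patient and cycle a four-class label is drawn from
#' `class_probs`; the base breath sound is synthesized and the labelled
#' kinds of events are mixed in at `snr_db` (event energy over base energy
#' within the event's support). Fully reproducible from `cfg$seed`; the
#' caller's RNG state is left untouched.
#'
#' @param cfg A [sim_config].
#' @return An object of class `resp_dataset`: `cycles` (list of
#'   [respiratory_cycle]), `manifest` (data frame), `events` (per-event
#'   inventory), and `config`.
#' @export
gen_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed, function() {
    classes <- names(cfg$class_probs)
    n_cyc <- cfg$n_patients * cfg$cycles_per_patient
    cycles <- vector("list", n_cyc)
    man <- vector("list", n_cyc)
    inv <- list()
    idx <- 0L
    for (p in seq_len(cfg$n_patients)) {
      pid <- sprintf("SP%03d", p)
      for (j in seq_len(cfg$cycles_per_patient)) {
        idx <- idx + 1L
        label <- sample(classes, 1, prob = cfg$class_probs)
        base <- gen_normal(cfg$duration, cfg$rate)
        x <- base
        events <- .draw_events(label, cfg$duration)
        for (ev in events) {
          e <- switch(ev$kind,
                      wheeze = gen_wheeze(ev, cfg$rate),
                      gen_crackle(ev, cfg$rate))
          i0 <- round(ev$onset * cfg$rate) + 1L
          ii <- i0:(i0 + length(e) - 1L)
          ii <- ii[ii <= length(x)]
          e <- e[seq_along(ii)]
          e_base <- sum(base[ii]^2)
          e_ev <- sum(e^2)
          alpha <- if (e_ev > 0) sqrt(10^(cfg$snr_db / 10) * e_base / e_ev)
                   else 0
          x[ii] <- x[ii] + alpha * e
          inv[[length(inv) + 1L]] <- data.frame(
            cycle = idx, patient_id = pid, kind = ev$kind,
            onset = ev$onset, duration = ev$duration, f0 = ev$f0)
        }
        if (max(abs(x)) > 0.99) x <- 0.99 * x / max(abs(x))
        crackle <- label %in% c("crackle", "both")
        wheeze <- label %in% c("wheeze", "both")
        cycles[[idx]] <- respiratory_cycle(x, cfg$rate, cfg$duration, pid,
                                           crackle, wheeze)
        man[[idx]] <- data.frame(cycle = idx, patient_id = pid,
                                 label4 = label, crackle = crackle,
                                 wheeze = wheeze)
      }
    }
    structure(list(cycles = cycles, manifest = do.call(rbind, man),
                   events = if (length(inv)) do.call(rbind, inv) else
                     data.frame(),
                   config = cfg),
              class = "resp_dataset")
  })
}

#' @export
print.resp_dataset <- function(x, ...) {
  tab <- table(x$manifest$label4)
  cat(sprintf("<resp_dataset> %d cycles from %d patients (%s)\n",
              nrow(x$manifest), x$config$n_patients,
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Write a synthetic dataset to disk in the ICBHI dialect
#'
#' One WAV and one 4-column annotation text file per cycle (file names
#' `<patient>_<cycle>`), plus a `manifest.csv`, so the synthetic corpus is
#' consumable by the rest of the pipeline exactly as real data would be.
#'
#' @param ds A `resp_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "resp_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(ds$cycles)) {
    cy <- ds$cycles[[i]]
    base <- sprintf("%s_%04d", cy$patient_id, i)
    write_wav(cy$samples, file.path(dir, paste0(base, ".wav")),
              rate = cy$rate)
    write_annotations(
      data.frame(start = 0, end = cy$duration,
                 crackle = cy$crackle, wheeze = cy$wheeze),
      file.path(dir, paste0(base, ".txt")))
  }
  utils::write.csv(ds$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}
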