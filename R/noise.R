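#' Pressure-noise records
#'
#' A `noise_record` is a tibble with columns `time_s` and `pressure_mmHg`
#' holding a zero-mean pressure-fluctuation time series, with its sample
#' rate (Hz), regime label, and generating seed (if synthetic) attached as
#' attributes.  Records are added to the measured system pressure during
#' simulation to emulate the IOP variability of real preparations.
#'
#' Three synthetic regimes are provided:
#'
#' * `noise_exvivo()` -- enucleated-eye noise: Gaussian white noise at
#'   10 Hz passed through a first-order lowpass filter (cutoff 0.4 Hz) and
#'   rescaled to SD 0.04 mmHg.
#' * `noise_surrogate("anesthetized")` -- the same lowpass-Gaussian base
#'   scaled to SD 0.23 mmHg plus sporadic transient events with Poisson
#'   arrivals.
#' * `noise_surrogate("conscious")` -- a larger Gaussian base plus
#'   frequent, strictly positive, exponentially decaying IOP bumps, giving
#'   the positively skewed distribution characteristic of awake
#'   free-moving animals.
#'
#' Surrogate event-rate and amplitude parameters are calibrated only to
#' the summary statistics above plus qualitative bump structure; they are
#' defaults, not measurements.
#'
#' @param duration Record length (min).
#' @param seed Integer seed; equal seeds give identical records.
#' @param sd Target record standard deviation (mmHg).
#' @param rate Sample rate (Hz).
#' @param cutoff Lowpass -3 dB cutoff (Hz).
#' @param rescale Rescale the filtered record so its SD equals `sd`
#'   exactly (the filter otherwise reduces the white-noise SD).
#' @return A `noise_record` tibble.
#' @examples
#' r <- noise_exvivo(duration = 2, seed = 1)
#' sd(r$pressure_mmHg)
#' @export
noise_exvivo <- function(duration = 120, seed = NULL, sd = 0.04, rate = 10,
                         cutoff = 0.4, rescale = TRUE) {
  stopifnot(duration > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * 60 * rate)
  x <- rnorm(n, 0, sd)
  y <- lowpass1(x, cutoff, rate)
  if (rescale) y <- y * (sd / stats::sd(y))
  new_noise_record(y - mean(y), rate, "exvivo", seed)
}

#' @rdname noise_exvivo
#' @param regime `"anesthetized"` or `"conscious"`.
#' @param params Named list overriding surrogate event parameters:
#'   `base_sd` (mmHg), `event_rate` (events/min), `event_amp` (mean event
#'   amplitude, mmHg), `event_decay` (event decay time constant, s),
#'   `event_signed` (logical: events in both directions).
#' @export
noise_surrogate <- function(regime = c("anesthetized", "conscious"),
                            duration = 120, seed = NULL, rate = 10,
                            params = list()) {
  regime <- match.arg(regime)
  if (!is.null(seed)) set.seed(seed)
  defaults <- switch(regime,
    anesthetized = list(base_sd = 0.23, event_rate = 0.3, event_amp = 0.5,
                        event_decay = 5, event_signed = TRUE, cutoff = 0.4),
    conscious = list(base_sd = 0.30, event_rate = 0.4, event_amp = 3.0,
                     event_decay = 45, event_signed = FALSE, cutoff = 0.4)
  )
  p <- utils::modifyList(defaults, params)
  n <- round(duration * 60 * rate)
  base <- lowpass1(rnorm(n), p$cutoff, rate)
  base <- base * (p$base_sd / stats::sd(base))
  y <- base + event_train(n, rate, p$event_rate, p$event_amp, p$event_decay,
                          p$event_signed)
  new_noise_record(y - mean(y), rate, regime, seed)
}

# superposition of exponentially decaying events with Poisson arrivals
event_train <- function(n, rate, events_per_min, amp_mean, decay_s, signed) {
  if (events_per_min <= 0 || amp_mean <= 0) return(numeric(n))
  y <- numeric(n)
  n_ev <- rpois(1, events_per_min * n / (rate * 60))
  if (n_ev == 0) return(y)
  starts <- sample.int(n, n_ev, replace = TRUE)
  amps <- rexp(n_ev, 1 / amp_mean)
  if (signed) amps <- amps * sample(c(-1, 1), n_ev, replace = TRUE)
  tail_len <- min(n, ceiling(5 * decay_s * rate))
  shape <- exp(-(seq_len(tail_len) - 1) / (decay_s * rate))
  for (i in seq_len(n_ev)) {
    idx <- starts[i]:min(n, starts[i] + tail_len - 1L)
    y[idx] <- y[idx] + amps[i] * shape[seq_along(idx)]
  }
  y
}

# single-pole IIR lowpass from the bilinear transform
lowpass1 <- function(x, cutoff, rate) {
  c0 <- tan(pi * cutoff / rate)
  b <- c0 / (1 + c0)
  a1 <- (c0 - 1) / (1 + c0)
  xp <- b * (x + c(0, x[-length(x)]))
  as.numeric(stats::filter(xp, -a1, method = "recursive"))
}

new_noise_record <- function(samples, rate, label, seed = NULL) {
  out <- tibble(
    time_s = (seq_along(samples) - 1) / rate,
    pressure_mmHg = as.numeric(samples)
  )
  attr(out, "rate_hz") <- rate
  attr(out, "label") <- label
  attr(out, "seed") <- seed
  class(out) <- c("noise_record", class(out))
  out
}

#' Generate a cohort of noise records
#'
#' Produces `n` independent records of one regime, with each record's seed
#' derived deterministically from the cohort seed so the full set can be
#' regenerated from a manifest.
#'
#' @param regime `"exvivo"`, `"anesthetized"` or `"conscious"`.
#' @param n Number of records.
#' @param duration Record length (min).
#' @param seed Cohort seed.
#' @return A list of `noise_record`s; the per-record seeds are in the
#'   `manifest` attribute.
#' @examples
#' recs <- noise_cohort("exvivo", n = 2, duration = 1, seed = 1)
#' @export
noise_cohort <- function(regime = c("exvivo", "anesthetized", "conscious"),
                         n = 12, duration = 120, seed = 1) {
  regime <- match.arg(regime)
  seeds <- (as.integer(seed) %% 1000000L) * 1000L + seq_len(n)
  recs <- map(seeds, function(s) {
    if (regime == "exvivo") noise_exvivo(duration, seed = s)
    else noise_surrogate(regime, duration, seed = s)
  })
  attr(recs, "manifest") <- tibble(record = seq_len(n), regime = regime,
                                   duration_min = duration, seed = seeds)
  recs
}

#' Resample a noise record
#'
#' Downsampling averages consecutive groups of samples (an integer
#' decimation factor is required); upsampling repeats each sample
#' (zero-order hold) or linearly interpolates.
#'
#' @param record A [noise_record][noise_exvivo].
#' @param target_rate Target sample rate (Hz); the model update rate of
#'   10 Hz by default.
#' @param method Upsampling method, `"hold"` or `"linear"`.
#' @return A `noise_record` at `target_rate`.
#' @export
resample_noise <- function(record, target_rate = 10,
                           method = c("hold", "linear")) {
  method <- match.arg(method)
  stopifnot(inherits(record, "noise_record"), target_rate > 0)
  rate <- attr(record, "rate_hz")
  x <- record$pressure_mmHg
  if (length(x) == 0) {
    abort("cannot resample an empty record", class = "perfusim_input_error")
  }
  if (abs(rate - target_rate) < 1e-9) return(record)
  if (rate > target_rate) {
    fac <- rate / target_rate
    if (abs(fac - round(fac)) > 1e-9) {
      abort("downsampling requires an integer decimation factor",
            class = "perfusim_input_error")
    }
    fac <- as.integer(round(fac))
    nfull <- (length(x) %/% fac) * fac
    y <- colMeans(matrix(x[seq_len(nfull)], nrow = fac))
  } else {
    fac <- target_rate / rate
    if (abs(fac - round(fac)) > 1e-9) {
      abort("upsampling requires an integer factor",
            class = "perfusim_input_error")
    }
    fac <- as.integer(round(fac))
    if (method == "hold") {
      y <- rep(x, each = fac)
    } else {
      y <- approx(seq_along(x), x, xout = seq(1, length(x), by = 1 / fac))$y
    }
  }
  new_noise_record(y, target_rate, attr(record, "label"),
                   attr(record, "seed"))
}

#' Summary statistics and spectrum of a noise record
#'
#' Computes the record SD, sample skewness, an amplitude histogram, and a
#' Welch-averaged power spectral density (segments of `2^12` samples, 50%
#' overlap, Hann window).
#'
#' @param record A [noise_record][noise_exvivo].
#' @param segment Welch segment length (samples).
#' @param breaks Number of histogram bins.
#' @return A list of class `noise_summary`: `sd`, `skewness`, `histogram`
#'   (tibble of bin midpoints and densities), `psd` (tibble of frequency
#'   and density).
#' @examples
#' characterize_noise(noise_exvivo(duration = 10, seed = 1))$sd
#' @export
characterize_noise <- function(record, segment = 2^12, breaks = 40) {
  stopifnot(inherits(record, "noise_record"))
  x <- record$pressure_mmHg
  rate <- attr(record, "rate_hz")
  if (length(x) < 2 * segment) {
    abort(sprintf("record too short: need at least %d samples (2 segments)",
                  2 * segment),
          class = "perfusim_input_error")
  }
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  structure(
    list(
      sd = stats::sd(x),
      skewness = sample_skewness(x),
      histogram = tibble(mid = h$mids, density = h$density),
      psd = welch_psd(x, rate, segment)
    ),
    class = "noise_summary"
  )
}

sample_skewness <- function(x) {
  x <- x - mean(x)
  mean(x^3) / (mean(x^2)^1.5)
}

# Welch-averaged periodogram: Hann window, 50% overlap, one-sided density
welch_psd <- function(x, rate, segment = 2^12) {
  n <- length(x)
  step <- segment %/% 2
  starts <- seq(1, n - segment + 1, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(segment) / (segment + 1)))
  u <- sum(w^2)
  acc <- numeric(segment %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + segment - 1)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(fft(seg))^2 / (u * rate)
    acc <- acc + sp[seq_len(segment %/% 2 + 1)]
  }
  psd <- acc / length(starts)
  psd[2:(segment %/% 2)] <- 2 * psd[2:(segment %/% 2)]
  tibble(freq_hz = (0:(segment %/% 2)) * rate / segment, psd = psd)
}

#' @importFrom stats fft
NULL

#' Read and write noise records
#'
#' The CSV format is either a single `pressure_mmHg` column (with the
#' sample rate passed as `rate`) or two columns `time_s, pressure_mmHg`
#' with uniform timestamps.  Records are mean-subtracted on load.
#'
#' @param path CSV file path.
#' @param rate Sample rate (Hz); required for single-column files.
#' @param label Regime label to attach.
#' @return A [noise_record][noise_exvivo].
#' @export
read_noise_record <- function(path, rate = NULL, label = "custom") {
  df <- read.csv(path)
  if (ncol(df) == 1) {
    if (is.null(rate)) {
      abort("single-column records need an explicit `rate` (Hz)",
            class = "perfusim_input_error")
    }
    x <- df[[1]]
  } else if (all(c("time_s", "pressure_mmHg") %in% names(df))) {
    dtv <- diff(df$time_s)
    if (max(dtv) - min(dtv) > 1e-6 * stats::median(dtv)) {
      abort("irregular timestamps; resample the record to a uniform grid first",
            class = "perfusim_input_error")
    }
    rate <- 1 / stats::median(dtv)
    x <- df$pressure_mmHg
  } else {
    abort("expected a `pressure_mmHg` column or `time_s, pressure_mmHg` pair",
          class = "perfusim_input_error")
  }
  if (!is.numeric(x) || anyNA(x)) {
    abort("non-numeric pressure data", class = "perfusim_input_error")
  }
  new_noise_record(x - mean(x), rate, label)
}

#' @rdname read_noise_record
#' @param record A `noise_record` to write.
#' @export
write_noise_record <- function(record, path) {
  write.csv(
    data.frame(time_s = record$time_s, pressure_mmHg = record$pressure_mmHg),
    path, row.names = FALSE
  )
  invisible(path)
}
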