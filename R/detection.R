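#' Steady-state detection configuration
#'
#' Collects the thresholds of the three steady-state criteria:
#'
#' * **window**: steady state when the measured pressure varies (max minus
#'   min) by less than `window_threshold_fraction` of the input step size
#'   over a trailing window of `window_length` minutes.
#' * **ratio**: steady state when the least-squares slope of the flow to
#'   pressure ratio over a trailing `window_length`-minute window stays
#'   below `ratio_slope_threshold` (nl/min^2/mmHg) for `ratio_hold`
#'   minutes.
#' * **fitting**: exponential pressure and flow predictions are refit to
#'   all accumulated data every `fit_update` seconds from `fit_start`
#'   minutes after step onset; steady state when the predictions vary by
#'   less than `fit_press_tol` mmHg and `fit_flow_tol` ul/min over a
#'   trailing `fit_hold`-minute period later than `fit_min_elapsed` fitted
#'   time constants after onset.
#'
#' @param window_length Trailing window (min).
#' @param window_threshold_fraction Fraction of the pressure step size.
#' @param ratio_slope_threshold Slope threshold (nl/min^2/mmHg).
#' @param ratio_hold Time the slope must stay sub-threshold (min).
#' @param filter_width Moving-average width applied to the trace before
#'   the window/ratio criteria (min; 0 = raw data).
#' @param fit_start Delay from onset to first fit (min).
#' @param fit_update Refit interval (s).
#' @param fit_press_tol,fit_flow_tol Allowed variation of the fitted
#'   pressure (mmHg) and flow (ul/min) predictions.
#' @param fit_hold Length of the stability window (min).
#' @param fit_min_elapsed Minimum elapsed time, in fitted time constants.
#' @param timeout Give-up time per step (min).
#' @return A list of class `criterion_config`.
#' @examples
#' criterion_config()
#' criterion_config(filter_width = 3)
#' @export
criterion_config <- function(window_length = 5,
                             window_threshold_fraction = 0.10,
                             ratio_slope_threshold = 0.1,
                             ratio_hold = 1,
                             filter_width = 0,
                             fit_start = 2,
                             fit_update = 1,
                             fit_press_tol = 0.5,
                             fit_flow_tol = 0.05,
                             fit_hold = 2,
                             fit_min_elapsed = 6,
                             timeout = 90) {
  cfg <- as.list(environment())
  num <- setdiff(names(cfg), "filter_width")
  for (nm in num) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0) {
      abort(sprintf("`%s` must be positive", nm),
            class = "perfusim_parameter_error")
    }
  }
  if (filter_width < 0) {
    abort("`filter_width` must be >= 0", class = "perfusim_parameter_error")
  }
  structure(cfg, class = "criterion_config")
}

#' Trailing moving-average smoothing of a trace
#'
#' Applies a trailing (causal) moving average of width `width` minutes to
#' the measured pressure and flow.  While fewer samples than the full
#' window are available the average runs over all samples so far (growing
#' window).  `width = 0` returns the trace unchanged.
#'
#' @param trace A `perfusion_trace`.
#' @param width Filter width (min).
#' @return The trace with `p_s` and `f_s` smoothed.
#' @examples
#' tr <- simulate_perfusion(cpg_controller(0.6), 20, duration = 10,
#'                          noise = noise_exvivo(10, seed = 1))
#' smooth_trace(tr, width = 1)
#' @export
smooth_trace <- function(trace, width) {
  if (width <= 0) return(trace)
  dt_min <- trace$time_min[2] - trace$time_min[1]
  w <- max(1L, as.integer(round(width / dt_min)))
  trace$p_s <- trailing_mean(trace$p_s, w)
  trace$f_s <- trailing_mean(trace$f_s, w)
  trace
}

trailing_mean <- function(x, w) {
  n <- length(x)
  cs <- cumsum(x)
  lag <- c(rep(0, w), cs[seq_len(max(0, n - w))])
  cnt <- pmin(seq_len(n), w)
  (cs - lag) / cnt
}

#' Apply a steady-state criterion to a step response
#'
#' Evaluates one criterion on a trace that starts at the step onset and
#' returns the detection time together with the steady-state pressure and
#' flow estimates.  For the window and ratio criteria the steady values
#' are means over the final trailing window; for the fitting criterion
#' they are the fitted asymptotes.  Eye-side values use the plateau
#' relations `F_E = F_S` and `P_E = P_S - R_C F_S`.
#'
#' When the trace has been smoothed (`config$filter_width > 0`) criterion
#' windows are restricted to data recorded after the filter has filled,
#' so detection cannot occur before `filter_width + window_length`
#' minutes.
#'
#' @param trace A `perfusion_trace` beginning at the step onset.
#' @param criterion `"window"`, `"ratio"` or `"fitting"`.
#' @param step_size The input step size in pressure units (mmHg).  For CF
#'   experiments pass the plateau pressure change `(R_C + R_T) * dF`.
#' @param config A [criterion_config()].
#' @param sys [system_params()], for the eye-side mapping.
#' @return A one-row tibble: `criterion`, `settle_min`, `steady_p_s`,
#'   `steady_f_s`, `steady_p_e`, `steady_f_e`, `converged`.
#' @examples
#' ctrl <- cpg_controller(0.6)
#' tr <- simulate_perfusion(ctrl, 20, duration = 30,
#'                          noise = noise_exvivo(30, seed = 1))
#' detect_steady_state(tr, "window", step_size = 5)
#' @export
detect_steady_state <- function(trace, criterion = c("window", "ratio",
                                                     "fitting"),
                                step_size, config = criterion_config(),
                                sys = system_params(),
                                signal = c("raw", "fitted")) {
  criterion <- match.arg(criterion)
  signal <- match.arg(signal)
  if (criterion == "fitting") {
    return(fitting_criterion(trace, config, sys))
  }
  if (signal == "fitted") {
    trace <- fitted_trace(trace, config)
    if (nrow(trace) == 0) return(no_detection(criterion))
    config$filter_width <- 0 # the regression replaces data smoothing
  }
  switch(criterion,
    window = window_criterion(trace, step_size, config, sys),
    ratio = ratio_criterion(trace, config, sys)
  )
}

# recast the recursive-regression predictions as a trace so the window and
# ratio criteria can run on fitted responses
fitted_trace <- function(trace, config = criterion_config()) {
  fit <- recursive_fit_path(trace, config)
  out <- tibble(time_min = fit$time_min, p_s = fit$ps_fit, f_s = fit$fs_fit)
  attr(out, "fit") <- fit
  out
}

no_detection <- function(criterion) {
  tibble(criterion = criterion, settle_min = NA_real_,
         steady_p_s = NA_real_, steady_f_s = NA_real_,
         steady_p_e = NA_real_, steady_f_e = NA_real_, converged = FALSE)
}

steady_row <- function(criterion, t_min, ps, fs, sys) {
  tibble(criterion = criterion, settle_min = t_min,
         steady_p_s = ps, steady_f_s = fs,
         steady_p_e = ps - sys$cannula_resistance * fs, steady_f_e = fs,
         converged = TRUE)
}

#' @rdname detect_steady_state
#' @export
window_criterion <- function(trace, step_size, config = criterion_config(),
                             sys = system_params()) {
  tr <- smooth_trace(trace, config$filter_width)
  dt_min <- tr$time_min[2] - tr$time_min[1]
  w <- as.integer(round(config$window_length / dt_min)) + 1L
  if (nrow(tr) < w) return(no_detection("window"))
  thr <- config$window_threshold_fraction * step_size
  rr <- roll_range_cpp(tr$p_s, w)
  k0 <- first_valid_index(config, dt_min, w)
  ok <- which(!is.na(rr) & rr < thr & seq_along(rr) >= k0 &
                tr$time_min <= config$timeout)
  if (length(ok) == 0) return(no_detection("window"))
  k <- ok[1]
  idx <- (k - w + 1L):k
  steady_row("window", tr$time_min[k], mean(tr$p_s[idx]), mean(tr$f_s[idx]),
             sys)
}

#' @rdname detect_steady_state
#' @export
ratio_criterion <- function(trace, config = criterion_config(),
                            sys = system_params()) {
  tr <- smooth_trace(trace, config$filter_width)
  dt_min <- tr$time_min[2] - tr$time_min[1]
  w <- as.integer(round(config$window_length / dt_min)) + 1L
  hold <- as.integer(round(config$ratio_hold / dt_min))
  if (nrow(tr) < w + hold) return(no_detection("ratio"))
  if (any(tr$p_s <= 0)) {
    abort("non-positive pressure in trace; flow/pressure ratio undefined",
          class = "perfusim_input_error")
  }
  ratio <- 1000 * tr$f_s / tr$p_s # nl/min/mmHg
  sl <- roll_slope(ratio, tr$time_min, w)
  below <- !is.na(sl) & abs(sl) < config$ratio_slope_threshold
  k0 <- first_valid_index(config, dt_min, w)
  below[seq_len(min(length(below), k0 - 1L))] <- FALSE
  # sub-threshold continuously over the trailing hold interval (hold+1 samples)
  h1 <- hold + 1L
  run <- cumsum(below)
  lag <- c(rep(0L, h1), run[seq_len(max(0, length(run) - h1))])
  all_below <- seq_along(run) >= h1 & (run - lag) == h1
  ok <- which(all_below & tr$time_min <= config$timeout)
  if (length(ok) == 0) return(no_detection("ratio"))
  k <- ok[1]
  idx <- (k - w + 1L):k
  steady_row("ratio", tr$time_min[k], mean(tr$p_s[idx]), mean(tr$f_s[idx]),
             sys)
}

# least-squares slope of y against time over a trailing window of w samples
roll_slope <- function(y, t, w) {
  n <- length(y)
  if (n < w) return(rep(NA_real_, n))
  dt <- t[2] - t[1]
  i <- seq_len(n)
  c1 <- cumsum(y)
  c2 <- cumsum(i * y)
  lag1 <- c(rep(0, w), c1[seq_len(n - w)])
  lag2 <- c(rep(0, w), c2[seq_len(n - w)])
  Sy <- c1 - lag1
  Siy <- c2 - lag2
  i0 <- i - w + 1L # window start index
  # local coordinates j = 0..w-1: sum_j j*y = Siy - i0*Sy
  Sjy <- Siy - i0 * Sy
  Sj <- w * (w - 1) / 2
  Sjj <- w * (w - 1) * (2 * w - 1) / 6
  denom <- (Sjj - Sj^2 / w) * dt
  out <- (Sjy - Sj * Sy / w) / denom
  out[seq_len(w - 1L)] <- NA_real_
  out
}

first_valid_index <- function(config, dt_min, w) {
  filt <- as.integer(round(config$filter_width / dt_min))
  w + filt
}

#' @rdname detect_steady_state
#' @details
#' `fitting_criterion()` runs the recursive exponential regression over
#' the whole trace (see [recursive_fit()]), applies the stability rule to
#' the fitted predictions, and reports the fitted asymptotes as steady
#' values.
#' @export
fitting_criterion <- function(trace, config = criterion_config(),
                              sys = system_params()) {
  fit <- recursive_fit_path(trace, config)
  if (nrow(fit) == 0) return(no_detection("fitting"))
  upd_min <- config$fit_update / 60
  hold <- as.integer(round(config$fit_hold / upd_min))
  if (nrow(fit) <= hold) return(no_detection("fitting"))
  rng_p <- roll_range_cpp(fit$ps_fit, hold + 1L)
  rng_f <- roll_range_cpp(fit$fs_fit, hold + 1L)
  # the stability window must lie wholly beyond fit_min_elapsed time constants
  ok <- !is.na(rng_p) & rng_p < config$fit_press_tol &
    rng_f < config$fit_flow_tol &
    (fit$time_min - config$fit_hold) > config$fit_min_elapsed * fit$tau &
    fit$time_min <= config$timeout
  k <- which(ok)
  if (length(k) == 0) return(no_detection("fitting"))
  k <- k[1]
  ps_inf <- fit$A[k] + fit$B[k]
  fs_inf <- fit$D[k]
  out <- steady_row("fitting", fit$time_min[k], ps_inf, fs_inf, sys)
  out$tau <- fit$tau[k]
  out
}

#' Recursive exponential regression of a step response
#'
#' Fits first-order predictions `PS*(t) = A (1 - exp(-t/tau)) + B` and
#' `FS*(t) = C exp(-t/tau) + D` (shared time constant `tau`) to all data
#' accumulated since step onset, refitting every `fit_update` seconds from
#' `fit_start` minutes onward.  For a fixed `tau` both channels are linear
#' least-squares problems; `tau` is profiled by golden-section search,
#' warm-started from the previous refit.  Flow residuals are weighted by
#' the ratio of typical pressure to flow scales (1 mmHg : 0.01 ul/min) so
#' both channels inform the shared time constant.
#'
#' Because every refit uses all accumulated data, transient IOP bumps are
#' progressively outvoted as the record grows, which is what makes the
#' fitted predictions usable for steady-state detection under conscious
#' noise.
#'
#' `recursive_fit_path()` returns the full history of refits on a 1-Hz
#' data grid; `recursive_fit()` returns the single fit using data up to
#' `at_time`.
#'
#' @param trace A `perfusion_trace` starting at the step onset.
#' @param config A [criterion_config()].
#' @param flow_weight Weight on flow residuals in the shared-tau profile.
#' @param tau_range Search range for `tau` (min).
#' @return A tibble with one row per refit: `time_min`, `tau`, `A`, `B`,
#'   `C`, `D`, `ps_fit`, `fs_fit` (predictions at the refit time), and
#'   `converged` (`FALSE` when the exponential is unidentifiable and the
#'   fit fell back to asymptote-only means).
#' @examples
#' ctrl <- cpg_controller(0.6)
#' tr <- simulate_perfusion(ctrl, 20, duration = 12)
#' fit <- recursive_fit_path(tr)
#' tail(fit, 1)
#' @export
recursive_fit_path <- function(trace, config = criterion_config(),
                               flow_weight = 100, tau_range = c(0.05, 45)) {
  dt_min <- trace$time_min[2] - trace$time_min[1]
  dec <- max(1L, as.integer(round(1 / 60 / dt_min))) # fit on a 1-Hz grid
  idx <- seq(1, nrow(trace), by = dec)
  res <- recursive_fit_path_cpp(
    trace$time_min[idx], trace$p_s[idx], trace$f_s[idx],
    config$fit_start, config$fit_update / 60,
    flow_weight, tau_range[1], tau_range[2]
  )
  out <- as_tibble(res)
  out$converged <- out$converged > 0
  out
}

#' @rdname recursive_fit_path
#' @param at_time Use data up to this time after onset (min).
#' @export
recursive_fit <- function(trace, at_time, config = criterion_config(),
                          flow_weight = 100, tau_range = c(0.05, 45)) {
  tr <- trace[trace$time_min <= at_time + 1e-9, , drop = FALSE]
  if (nrow(tr) < 4 || at_time < config$fit_start) {
    abort(sprintf("fitting starts %g min after onset", config$fit_start),
          class = "perfusim_input_error")
  }
  cfg <- config
  cfg$fit_start <- at_time - 1e-9
  path <- recursive_fit_path(tr, cfg, flow_weight, tau_range)
  path[nrow(path), , drop = FALSE]
}
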