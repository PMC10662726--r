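#' Simulate a perfusion experiment trace
#'
#' Integrates the lumped-parameter eye-plus-system circuit with a
#' fourth-order Runge-Kutta scheme at a fixed recording interval `dt`
#' (default 0.1 s, matching digital controller updates).  The circuit has
#' three states: the pressure across the system compliance (`P_S`) and the
#' pressures across the two wall compliance elements; sub-steps are
#' inserted automatically when high feedback gain makes the system stiff
#' relative to `dt`.
#'
#' An optional pressure-noise record perturbs the measured system pressure
#' additively at every update.  The noisy measurement is what the recorded
#' trace, the detection criteria, and the controllers see, so constant-
#' pressure controllers transfer pressure noise into flow noise in
#' proportion to their gain.
#'
#' @param ctrl A [controllers] specification.
#' @param input A single commanded level (applied from `t = 0`), or a
#'   [step_schedule()] of levels.
#' @param eye,sys Model parameters.
#' @param duration Simulated time (min).
#' @param dt Recording/update interval (s).
#' @param noise Optional [noise_record] (resampled to `dt` if needed), or a
#'   plain numeric vector of per-sample pressure perturbations (mmHg).
#' @param noise_offset Index of the noise sample to start from (wraps
#'   around the record if it is exhausted).
#' @param init Initial state: `NULL` for the resting eye, or the `state`
#'   attribute of a previous trace to continue from.
#' @return A tibble of class `perfusion_trace` with columns `time_min`,
#'   `p_s` (measured system pressure, mmHg), `f_s` (source flow, ul/min),
#'   `p_e` (eye pressure, mmHg), `f_e` (eye inflow, ul/min).  The final
#'   integrator state is attached as attribute `state`.
#' @examples
#' tr <- simulate_perfusion(cpp_controller(7), 20, duration = 10)
#' tail(tr)
#' @export
simulate_perfusion <- function(ctrl, input, eye = eye_params(),
                               sys = system_params(), duration = 60,
                               dt = sys$update_interval, noise = NULL,
                               noise_offset = 1L, init = NULL) {
  stopifnot(inherits(ctrl, "controller_spec"), duration > 0, dt > 0)
  dt_min <- dt / 60
  n <- floor(duration / dt_min + 1e-9) + 1L
  time_min <- (seq_len(n) - 1) * dt_min

  baseline <- if (ctrl$mode == "CF") 0 else eye$resting_iop
  if (inherits(input, "data.frame")) {
    lv <- schedule_to_input(input, time_min, baseline)
  } else {
    stopifnot(is.numeric(input), length(input) == 1)
    lv <- rep(as.numeric(input), n)
  }

  nz <- prepare_noise(noise, n, dt, noise_offset)

  if (is.null(init)) {
    init <- c(eye$resting_iop, eye$resting_iop, 0)
  }
  stopifnot(length(init) == 3)

  RS <- if (ctrl$mode == "CPg") 1 / ctrl$gain else Inf
  K <- if (ctrl$mode == "CPp") ctrl$gain else 0
  fb_steps <- max(1L, as.integer(round(ctrl$feedback_filter_width / dt)))
  n_sub <- required_substeps(ctrl, eye, sys, dt_min)

  res <- sim_perfusion_cpp(
    controller_mode_code(ctrl), lv, nz, dt_min, n_sub,
    unclass(eye), unclass(sys), RS, K,
    sys$feedback_delay, fb_steps,
    ctrl$flow_limit[1], ctrl$flow_limit[2],
    init, numeric(0)
  )

  out <- tibble(
    time_min = time_min,
    p_s = res$p_s, f_s = res$f_s, p_e = res$p_e, f_e = res$f_e
  )
  attr(out, "state") <- res$state
  attr(out, "states") <- res$states
  attr(out, "dt_s") <- dt
  attr(out, "controller") <- controller_label(ctrl)
  class(out) <- c("perfusion_trace", class(out))
  out
}

# stiffness-aware sub-stepping: RK4 needs |lambda| h < ~2.8 on the real
# axis; stay well inside with a factor-2 margin
required_substeps <- function(ctrl, eye, sys, dt_min) {
  g <- 0
  if (ctrl$mode == "CPg") g <- ctrl$gain
  if (ctrl$mode == "CPp" && isTRUE(ctrl$analog)) g <- ctrl$gain
  A <- system_matrix(eye, sys, feedback_gain = g)
  lam <- max(abs(Re(eigen(A, only.values = TRUE)$values)))
  max(1L, as.integer(ceiling(dt_min * lam / 1.4)))
}

prepare_noise <- function(noise, n, dt, offset = 1L) {
  if (is.null(noise)) return(numeric(n))
  if (inherits(noise, "noise_record")) {
    rate <- attr(noise, "rate_hz")
    if (abs(rate - 1 / dt) > 1e-9) {
      noise <- resample_noise(noise, target_rate = 1 / dt)
    }
    noise <- noise$pressure_mmHg
  }
  stopifnot(is.numeric(noise), length(noise) >= 1)
  idx <- ((as.integer(offset) - 1L + seq_len(n) - 1L) %% length(noise)) + 1L
  noise[idx]
}

#' Recover eye pressure and inflow from system measurements
#'
#' The eye-side signals are fully determined by the measured system
#' pressure and source flow: `P_E = R_C C_S dP_S/dt + P_S - R_C F_S` and
#' `F_E = F_S - C_S dP_S/dt`.  The derivative is estimated by centered
#' first differences on the uniform grid (one-sided at the endpoints).
#'
#' @param trace A data frame with columns `time_min`, `p_s`, `f_s`.
#' @param sys The [system_params()] the trace was recorded with.
#' @return The input with columns `p_e` and `f_e` replaced by the
#'   recovered estimates.
#' @examples
#' tr <- simulate_perfusion(cf_controller(), 0.1, duration = 5)
#' recover_eye_state(tr, system_params())
#' @export
recover_eye_state <- function(trace, sys = system_params()) {
  stopifnot(all(c("time_min", "p_s", "f_s") %in% names(trace)))
  n <- nrow(trace)
  if (n < 3) {
    abort("need at least 3 samples to estimate the pressure derivative",
          class = "perfusim_input_error")
  }
  t <- trace$time_min
  p <- trace$p_s
  dp <- numeric(n)
  dp[2:(n - 1)] <- (p[3:n] - p[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  dp[1] <- (p[2] - p[1]) / (t[2] - t[1])
  dp[n] <- (p[n] - p[n - 1]) / (t[n] - t[n - 1])
  RC <- sys$cannula_resistance
  CS <- sys$system_compliance
  trace$p_e <- RC * CS * dp + p - RC * trace$f_s
  trace$f_e <- trace$f_s - CS * dp
  trace
}

#' Settling time of a noise-free step response
#'
#' The settling time is the time after which both the pressure and the
#' flow trace remain within 1% of their plateau levels.  By default the 1%
#' band is measured against the step excursion (plateau minus pre-step
#' level); `reference = "absolute"` measures it against the plateau value
#' itself.  Channels with zero excursion (e.g. the constant source flow of
#' a CF experiment) are ignored, so the CF settling time is governed by
#' pressure alone.
#'
#' @param trace A `perfusion_trace` covering the step from its onset.
#' @param plateau The analytic plateau from [steady_state()].
#' @param baseline Pre-step levels (a row like `plateau`), e.g.
#'   [steady_state()] at the pre-step input.  Defaults to the first trace
#'   sample, which is correct for experiments started from rest with a
#'   flow command but overstates the flow excursion of constant-pressure
#'   steps (whose commanded flow spikes at onset); pass the pre-step
#'   plateau explicitly in that case.
#' @param threshold Band half-width as a fraction of the reference
#'   (default 0.01, i.e. 99% settling).
#' @param reference `"excursion"` or `"absolute"`.
#' @param channels Columns that must settle (default `p_s` and `f_s`).
#' @return Settling time in minutes, or `NA` if the trace never settles
#'   (i.e. is still outside the band at its end).
#' @examples
#' ctrl <- cpp_controller(7)
#' tr <- simulate_perfusion(ctrl, 20, duration = 20)
#' settling_time(tr, steady_state(ctrl, 20))
#' @export
settling_time <- function(trace, plateau, baseline = NULL, threshold = 0.01,
                          reference = c("excursion", "absolute"),
                          channels = c("p_s", "f_s")) {
  reference <- match.arg(reference)
  if (is.null(baseline)) baseline <- trace[1, , drop = FALSE]
  t_settle <- 0
  n <- nrow(trace)
  for (ch in channels) {
    pl <- plateau[[ch]][1]
    ref <- if (reference == "excursion") abs(pl - baseline[[ch]][1]) else abs(pl)
    band <- threshold * ref
    if (band == 0) next
    out <- abs(trace[[ch]] - pl) > band
    if (out[n]) return(NA_real_)
    last_out <- if (any(out)) max(which(out)) else 0L
    tm <- if (last_out == 0L) 0 else trace$time_min[last_out + 1L]
    t_settle <- max(t_settle, tm)
  }
  t_settle
}

#' Write or read a trace as CSV
#'
#' The on-disk schema is `time_s, p_s_mmHg, f_s_ul_min, p_e_mmHg,
#' f_e_ul_min`.
#'
#' @param trace A `perfusion_trace`.
#' @param path File path.
#' @return `read_trace()` returns a `perfusion_trace` tibble;
#'   `write_trace()` returns `path` invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(
    time_s = trace$time_min * 60,
    p_s_mmHg = trace$p_s, f_s_ul_min = trace$f_s,
    p_e_mmHg = trace$p_e, f_e_ul_min = trace$f_e
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- read.csv(path)
  need <- c("time_s", "p_s_mmHg", "f_s_ul_min", "p_e_mmHg", "f_e_ul_min")
  if (!all(need %in% names(df))) {
    abort(sprintf("trace file must have columns: %s",
                  paste(need, collapse = ", ")),
          class = "perfusim_input_error")
  }
  out <- tibble(
    time_min = df$time_s / 60,
    p_s = df$p_s_mmHg, f_s = df$f_s_ul_min,
    p_e = df$p_e_mmHg, f_e = df$f_e_ul_min
  )
  dt <- diff(out$time_min[1:2]) * 60
  attr(out, "dt_s") <- dt
  class(out) <- c("perfusion_trace", class(out))
  out
}
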