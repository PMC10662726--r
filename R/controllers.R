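#' Perfusion controller specifications
#'
#' A controller turns a commanded input level (a flow for constant-flow
#' perfusion, a reservoir or target pressure for constant-pressure
#' perfusion) into the source flow delivered to the system:
#'
#' * `cf_controller()` -- constant flow: the pump delivers the commanded
#'   flow regardless of pressure.
#' * `cpg_controller()` -- gravity-driven constant pressure: flow is driven
#'   through the system resistance by the reservoir head,
#'   `F_S = (P - P_S)/R_S`.  Feedback is analog and instantaneous; the
#'   effective proportional gain is `1/R_S`.
#' * `cpp_controller()` -- pump-driven constant pressure: a digital
#'   proportional controller, `F_S = K (P_T - P_S)`, updated every control
#'   interval with a one-interval measurement delay.
#' * `cppx_controller()` -- a low-gain CPp variant whose feedback signal is
#'   smoothed with a trailing moving average before entering the control
#'   law; the default gain 0.3 ul/min/mmHg with a 15-s filter trades a
#'   little speed for much lower flow noise.
#'
#' @param gain Commanded flow per unit pressure error: `1/R_S` is implied
#'   for `cpg_controller()` (pass `system_resistance`), `K` for the pump
#'   controllers (ul/min/mmHg).
#' @param system_resistance `R_S` of the gravity system (mmHg min/ul).
#' @param feedback_filter_width Trailing moving-average width applied to
#'   the measured pressure before the control law (s; 0 = none).
#' @param flow_limit Optional saturation for the commanded source flow
#'   (ul/min), as `c(min, max)` or a single maximum.  Default: unlimited.
#' @param analog If `TRUE` the pump feedback law is evaluated continuously
#'   inside the integrator stages instead of at discrete updates.  An
#'   analog pump with gain `K` is mathematically identical to a gravity
#'   system with `R_S = 1/K`.
#' @return A list of class `controller_spec`.
#' @examples
#' cpg_controller(0.6)
#' cpp_controller(7)
#' cppx_controller()
#' @name controllers
NULL

new_controller <- function(mode, gain, feedback_filter_width = 0,
                           flow_limit = NULL, analog = FALSE) {
  lim <- c(-Inf, Inf)
  if (!is.null(flow_limit)) {
    lim <- if (length(flow_limit) == 1) c(-flow_limit, flow_limit)
           else as.numeric(flow_limit)
  }
  structure(
    list(mode = mode, gain = gain,
         feedback_filter_width = feedback_filter_width,
         flow_limit = lim, analog = analog),
    class = "controller_spec"
  )
}

#' @rdname controllers
#' @export
cf_controller <- function(flow_limit = NULL) {
  new_controller("CF", gain = NA_real_, flow_limit = flow_limit)
}

#' @rdname controllers
#' @export
cpg_controller <- function(system_resistance, flow_limit = NULL) {
  if (system_resistance <= 0) {
    abort("`system_resistance` must be positive",
          class = "perfusim_parameter_error")
  }
  new_controller("CPg", gain = 1 / system_resistance, flow_limit = flow_limit)
}

#' @rdname controllers
#' @export
cpp_controller <- function(gain = 7, feedback_filter_width = 0,
                           flow_limit = NULL, analog = FALSE) {
  if (gain <= 0) {
    abort("`gain` must be positive", class = "perfusim_parameter_error")
  }
  new_controller("CPp", gain = gain,
                 feedback_filter_width = feedback_filter_width,
                 flow_limit = flow_limit, analog = analog)
}

#' @rdname controllers
#' @export
cppx_controller <- function(gain = 0.3, feedback_filter_width = 15,
                            flow_limit = NULL) {
  if (feedback_filter_width <= 0) {
    abort("a CPpx controller requires `feedback_filter_width` > 0",
          class = "perfusim_parameter_error")
  }
  ctrl <- new_controller("CPp", gain = gain,
                         feedback_filter_width = feedback_filter_width,
                         flow_limit = flow_limit)
  ctrl$mode_label <- "CPpx"
  ctrl
}

#' @export
print.controller_spec <- function(x, ...) {
  lab <- controller_label(x)
  cat(sprintf("<controller_spec> %s", lab))
  if (x$mode == "CPg") cat(sprintf("  R_S = %g mmHg min/ul", 1 / x$gain))
  if (x$mode == "CPp") cat(sprintf("  K = %g ul/min/mmHg", x$gain))
  if (x$feedback_filter_width > 0)
    cat(sprintf("  feedback filter %g s", x$feedback_filter_width))
  if (isTRUE(x$analog)) cat("  (analog feedback)")
  cat("\n")
  invisible(x)
}

controller_label <- function(ctrl) {
  if (!is.null(ctrl$mode_label)) ctrl$mode_label else ctrl$mode
}

# integer mode code used by the C++ kernel
controller_mode_code <- function(ctrl) {
  switch(ctrl$mode,
    CF = 0L,
    CPg = 1L,
    CPp = if (isTRUE(ctrl$analog)) 3L else 2L,
    abort(sprintf("unknown controller mode '%s'", ctrl$mode))
  )
}

#' Step-input schedules
#'
#' Describes a staircase command: the input level starts at `start` and
#' increases by `step_size` at each onset.  For CF controllers the level is
#' a flow (ul/min, conventional default steps of 0.1); for CPg/CPp it is a
#' reservoir or target pressure (mmHg, default steps of 5 starting from
#' resting IOP).
#'
#' @param onsets Step onset times (min).
#' @param levels Input level from each onset onwards.
#' @return A tibble with columns `onset_min` and `level`.
#' @examples
#' step_schedule(onsets = c(0, 10), levels = c(20, 25))
#' @export
step_schedule <- function(onsets, levels) {
  stopifnot(length(onsets) == length(levels), !is.unsorted(onsets))
  tibble(onset_min = as.numeric(onsets), level = as.numeric(levels))
}

# evaluate a schedule on a sample grid; before the first onset the input
# holds at `baseline`
schedule_to_input <- function(schedule, time_min, baseline) {
  lv <- rep(baseline, length(time_min))
  for (i in seq_len(nrow(schedule))) {
    lv[time_min >= schedule$onset_min[i] - 1e-12] <- schedule$level[i]
  }
  lv
}

#' Settling time across a gain grid
#'
#' Simulates a noise-free step for each gain in `gains` and measures the
#' settling time, reproducing the dependence of response speed on feedback
#' gain.  CF controllers have no gain, so their settling time is constant;
#' for CPg the gain is `1/R_S`, for CPp it is `K`.  Settling time falls
#' monotonically with gain towards a floor set by the viscoelastic
#' properties of the eye, which no amount of gain can beat.
#'
#' @param mode `"CF"`, `"CPg"` or `"CPp"`.
#' @param gains Gain grid (`1/R_S` or `K` in ul/min/mmHg); ignored for CF.
#' @param step Input step: target/reservoir pressure (mmHg) for CP modes,
#'   flow (ul/min) for CF.
#' @param eye,sys Model parameters.
#' @param dt Integration and update interval (s).
#' @param max_duration Longest simulation per gain (min).
#' @return A tibble with columns `mode`, `gain`, `settling_min`.
#' @examples
#' gain_sweep("CPp", gains = c(0.1, 1, 7), step = 20, max_duration = 60)
#' @export
gain_sweep <- function(mode = c("CPp", "CPg", "CF"), gains = NULL,
                       step = 20, eye = eye_params(), sys = system_params(),
                       dt = 0.1, max_duration = 120) {
  mode <- match.arg(mode)
  if (mode == "CF") {
    ctrl <- cf_controller()
    st <- settle_one(ctrl, step, eye, sys, dt, max_duration)
    gains <- if (is.null(gains)) NA_real_ else gains
    return(tibble(mode = mode, gain = gains, settling_min = st))
  }
  stopifnot(!is.null(gains), all(gains > 0))
  st <- map_dbl(gains, function(g) {
    ctrl <- if (mode == "CPg") cpg_controller(1 / g) else cpp_controller(g)
    settle_one(ctrl, step, eye, sys, dt, max_duration)
  })
  tibble(mode = mode, gain = gains, settling_min = st)
}

settle_one <- function(ctrl, level, eye, sys, dt, max_duration) {
  tr <- simulate_perfusion(ctrl, level, eye = eye, sys = sys,
                           duration = max_duration, dt = dt)
  plateau <- steady_state(ctrl, level, eye = eye, sys = sys)
  rest <- if (ctrl$mode == "CF") 0 else eye$resting_iop
  settling_time(tr, plateau, baseline = steady_state(ctrl, rest, eye, sys))
}
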