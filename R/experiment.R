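#' Run a simulated outflow facility experiment
#'
#' Drives a full facility measurement: the commanded input is raised in
#' `n_steps` increments, each next step starting the instant the chosen
#' steady-state criterion detects a plateau (or at `config$timeout`).  The
#' steady-state eye pressures and inflows collected at each plateau are
#' then regressed (`F_E` on `P_E`) to estimate outflow facility; for the
#' model eye the true value is `1/R_T`.
#'
#' A single noise record supplies the disturbance for the whole
#' experiment; it is consumed sequentially across steps and wraps around
#' if exhausted.  Steps that time out are excluded from the regression but
#' still count towards the experiment duration.
#'
#' @param ctrl A [controllers] specification.
#' @param criterion `"window"`, `"ratio"` or `"fitting"`.
#' @param n_steps Number of input steps (needs >= 2 for a regression).
#' @param step_size Input increment per step: ul/min for CF (default 0.1),
#'   mmHg for CP modes (default 5).
#' @param noise Optional [noise_record][noise_exvivo].
#' @param config A [criterion_config()].
#' @param signal Apply the window/ratio criterion to the `"raw"`
#'   (optionally moving-average filtered) trace or to the recursively
#'   `"fitted"` predictions.  The fitting criterion always uses fitted
#'   predictions.
#' @param eye,sys Model parameters.
#' @param dt Update interval (s).
#' @return An object of class `facility_fit`; see [tidy.facility_fit()]
#'   and [glance.facility_fit()].
#' @examples
#' fit <- run_experiment(cpg_controller(0.6), "window",
#'                       noise = noise_exvivo(60, seed = 1))
#' glance(fit)
#' @export
run_experiment <- function(ctrl, criterion = c("window", "ratio", "fitting"),
                           n_steps = 5,
                           step_size = if (ctrl$mode == "CF") 0.1 else 5,
                           noise = NULL, config = criterion_config(),
                           signal = c("raw", "fitted"),
                           eye = eye_params(), sys = system_params(),
                           dt = sys$update_interval) {
  criterion <- match.arg(criterion)
  signal <- match.arg(signal)
  stopifnot(n_steps >= 1, step_size > 0)
  dt_min <- dt / 60

  base_level <- if (ctrl$mode == "CF") 0 else eye$resting_iop
  levels <- base_level + step_size * seq_len(n_steps)
  press_step <- if (ctrl$mode == "CF") {
    (sys$cannula_resistance + eye$trabecular_resistance) * step_size
  } else {
    step_size
  }

  state <- c(eye$resting_iop, eye$resting_iop, 0)
  noise_pos <- 1L
  onset <- 0
  rows <- vector("list", n_steps)

  for (i in seq_len(n_steps)) {
    res <- run_one_step(ctrl, levels[i], press_step, criterion, signal,
                        config, eye, sys, dt, noise, noise_pos, state)
    det <- res$det
    t_adv <- if (det$converged) det$settle_min else config$timeout
    k_adv <- as.integer(round(t_adv / dt_min)) + 1L
    state <- res$states[k_adv, ]
    noise_pos <- noise_pos + (k_adv - 1L)
    rows[[i]] <- mutate(det, step = i, level = levels[i], onset_min = onset,
                        settle_min = t_adv)
    onset <- onset + t_adv
  }

  steps <- bind_rows(rows)
  steps <- steps[, c("step", "level", "onset_min", "settle_min",
                     "steady_p_s", "steady_f_s", "steady_p_e", "steady_f_e",
                     "converged")]
  good <- steps[steps$converged, , drop = FALSE]
  if (nrow(good) >= 2) {
    fit <- lm(steady_f_e ~ steady_p_e, data = good)
    facility <- unname(coef(fit)[2])
    intercept <- unname(coef(fit)[1])
    r <- cor(good$steady_p_e, good$steady_f_e)
  } else {
    facility <- intercept <- r <- NA_real_
  }
  structure(
    list(
      steps = steps,
      facility = facility,
      intercept = intercept,
      pearson_r = r,
      duration_min = onset,
      controller = controller_label(ctrl),
      criterion = criterion,
      signal = if (criterion == "fitting") "fitted" else signal,
      converged = all(steps$converged),
      eye = eye, sys = sys
    ),
    class = "facility_fit"
  )
}

# simulate one step with an adaptively grown horizon until the criterion
# fires (the criteria are causal, so detection on a longer trace equals
# online detection)
run_one_step <- function(ctrl, level, press_step, criterion, signal, config,
                         eye, sys, dt, noise, noise_pos, state) {
  horizon <- min(config$timeout,
                 max(12, config$filter_width + config$window_length + 2))
  repeat {
    tr <- simulate_perfusion(ctrl, level, eye = eye, sys = sys,
                             duration = horizon, dt = dt, noise = noise,
                             noise_offset = noise_pos, init = state)
    det <- detect_steady_state(tr, criterion, step_size = press_step,
                               config = config, sys = sys, signal = signal)
    if (isTRUE(det$converged) || horizon >= config$timeout) {
      return(list(det = det, states = attr(tr, "states")))
    }
    horizon <- min(config$timeout, 2 * horizon)
  }
}

#' @export
print.facility_fit <- function(x, ...) {
  cat(sprintf("<facility_fit> %s, %s criterion (%s signal)\n",
              x$controller, x$criterion, x$signal))
  cat(sprintf("  facility  %.4f ul/min/mmHg (%.2f nl/min/mmHg)\n",
              x$facility, 1000 * x$facility))
  cat(sprintf("  intercept %.4f ul/min, Pearson R %.5f\n",
              x$intercept, x$pearson_r))
  cat(sprintf("  duration  %.1f min over %d steps%s\n", x$duration_min,
              nrow(x$steps),
              if (x$converged) "" else " (some steps timed out)"))
  invisible(x)
}

#' Tidy per-step results of a facility experiment
#'
#' @param x A `facility_fit` from [run_experiment()].
#' @param ... Unused.
#' @return `tidy()` returns the per-step tibble (one row per pressure or
#'   flow step); `glance()` returns a one-row experiment summary with the
#'   facility estimate (`facility`, ul/min/mmHg), intercept, Pearson R,
#'   and total duration.
#' @export
tidy.facility_fit <- function(x, ...) {
  x$steps
}

#' @rdname tidy.facility_fit
#' @export
glance.facility_fit <- function(x, ...) {
  tibble(
    controller = x$controller,
    criterion = x$criterion,
    signal = x$signal,
    n_steps = nrow(x$steps),
    n_converged = sum(x$steps$converged),
    facility = x$facility,
    intercept = x$intercept,
    pearson_r = x$pearson_r,
    duration_min = x$duration_min
  )
}

#' Run a facility experiment over a cohort of noise records
#'
#' Repeats [run_experiment()] for each record in a cohort and binds the
#' per-experiment summaries.
#'
#' @inheritParams run_experiment
#' @param records A list of [noise_record][noise_exvivo]s (e.g. from
#'   [noise_cohort()]).
#' @return A tibble with one row per record (columns as
#'   [glance.facility_fit()] plus `record`).
#' @examples
#' recs <- noise_cohort("exvivo", n = 2, duration = 40, seed = 1)
#' run_cohort(cpg_controller(0.6), recs, criterion = "window", n_steps = 2)
#' @export
run_cohort <- function(ctrl, records, criterion = "window", ...,
                       config = criterion_config()) {
  out <- map(seq_along(records), function(i) {
    g <- glance(run_experiment(ctrl, criterion, noise = records[[i]],
                               config = config, ...))
    g$record <- i
    g
  })
  bind_rows(out)
}

#' Summarise a cohort of facility experiments
#'
#' @param cohort Output of [run_cohort()] (rows from several cohorts may
#'   be bound together first).
#' @param stat `"mean"` (mean and SD) or `"median"` (median and
#'   quartiles).
#' @return A tibble with duration and facility summaries per
#'   controller/criterion/signal combination.  Facility summaries are in
#'   nl/min/mmHg.
#' @export
summarize_cohort <- function(cohort, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  g <- dplyr::group_by(cohort, .data$controller, .data$criterion,
                       .data$signal)
  if (stat == "mean") {
    out <- dplyr::summarise(
      g,
      n = dplyr::n(),
      duration_mean = mean(.data$duration_min),
      duration_sd = sd(.data$duration_min),
      facility_mean_nl = mean(1000 * .data$facility, na.rm = TRUE),
      facility_sd_nl = sd(1000 * .data$facility, na.rm = TRUE),
      n_timeout = sum(!(.data$n_converged == .data$n_steps)),
      .groups = "drop"
    )
  } else {
    out <- dplyr::summarise(
      g,
      n = dplyr::n(),
      duration_median = median(.data$duration_min),
      duration_q1 = quantile(.data$duration_min, 0.25, names = FALSE),
      duration_q3 = quantile(.data$duration_min, 0.75, names = FALSE),
      facility_median_nl = median(1000 * .data$facility, na.rm = TRUE),
      facility_q1_nl = quantile(1000 * .data$facility, 0.25, na.rm = TRUE,
                                names = FALSE),
      facility_q3_nl = quantile(1000 * .data$facility, 0.75, na.rm = TRUE,
                                names = FALSE),
      n_timeout = sum(!(.data$n_converged == .data$n_steps)),
      .groups = "drop"
    )
  }
  out
}

#' Pick the moving-average filter width that settles fastest
#'
#' Simulates a single pressure step for each record and candidate filter
#' width, measures the criterion settling time (timeouts count at the
#' timeout), and scores each width by mean plus SD of settling time across
#' records.  The returned best width minimises that score -- the "fastest
#' with least variability" choice.
#'
#' @inheritParams run_experiment
#' @param records List of noise records.
#' @param widths Candidate filter widths (min).
#' @param step_to Step target pressure (mmHg; CF: flow in ul/min).
#' @param criterion Criterion whose settling time is scored; `"both"`
#'   sums the window and ratio scores, selecting one width per model the
#'   way a single experimental configuration must serve both criteria.
#' @return A list with `table` (per-width and per-criterion mean, SD,
#'   score, timeouts) and `best` (the selected width, min).
#' @export
optimize_filter_width <- function(ctrl, records, widths,
                                  criterion = c("window", "ratio", "both"),
                                  step_to = NULL, config = criterion_config(),
                                  eye = eye_params(), sys = system_params()) {
  criterion <- match.arg(criterion)
  crits <- if (criterion == "both") c("window", "ratio") else criterion
  stopifnot(length(records) >= 2)
  if (is.null(step_to)) {
    step_to <- if (ctrl$mode == "CF") 0.1 else eye$resting_iop + 5
  }
  press_step <- if (ctrl$mode == "CF") {
    (sys$cannula_resistance + eye$trabecular_resistance) * step_to
  } else {
    step_to - eye$resting_iop
  }
  grid <- vector("list", length(widths) * length(crits))
  gi <- 0
  for (wi in seq_along(widths)) {
    cfg <- config
    cfg$filter_width <- widths[wi]
    for (cr in crits) {
      st <- map_dbl(records, function(rec) {
        res <- run_one_step(ctrl, step_to, press_step, cr, "raw", cfg,
                            eye, sys, sys$update_interval, rec, 1L,
                            c(eye$resting_iop, eye$resting_iop, 0))
        if (res$det$converged) res$det$settle_min else cfg$timeout
      })
      gi <- gi + 1
      grid[[gi]] <- tibble(
        filter_width = widths[wi], criterion = cr,
        settling_mean = mean(st), settling_sd = sd(st),
        score = mean(st) + sd(st),
        n_timeout = sum(st >= config$timeout)
      )
    }
  }
  tab <- bind_rows(grid)
  total <- dplyr::summarise(dplyr::group_by(tab, .data$filter_width),
                            score = sum(.data$score),
                            n_timeout = sum(.data$n_timeout),
                            .groups = "drop")
  if (all(total$n_timeout == length(records) * length(crits))) {
    warning("all candidate widths timed out on every record")
  }
  list(table = tab, best = total$filter_width[which.min(total$score)])
}

#' Sweep facility-experiment step design
#'
#' Evaluates facility experiments over a grid of step sizes and step
#' counts for each noise record, summarising duration, facility accuracy,
#' and the maximum IOP elevation (`step_size * n_steps`) of each series.
#' Cells with fewer than two steps cannot support a regression and are
#' flagged.
#'
#' @inheritParams run_experiment
#' @param records List of noise records.
#' @param step_sizes Step sizes (mmHg for CP modes).
#' @param step_counts Numbers of steps.
#' @return A tibble with one row per (step size, step count) cell.
#' @export
sweep_step_design <- function(ctrl, records, step_sizes = c(3, 5, 8),
                              step_counts = c(2, 3, 5),
                              criterion = "window", signal = "raw",
                              config = criterion_config(),
                              eye = eye_params(), sys = system_params()) {
  cells <- tidyr::expand_grid(step_size = step_sizes,
                              n_steps = step_counts)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    ss <- cells$step_size[i]
    ns <- cells$n_steps[i]
    runs <- map(records, function(rec) {
      glance(run_experiment(ctrl, criterion, n_steps = ns, step_size = ss,
                            noise = rec, config = config, signal = signal,
                            eye = eye, sys = sys))
    })
    runs <- bind_rows(runs)
    out[[i]] <- tibble(
      step_size = ss, n_steps = ns,
      max_elevation_mmHg = ss * ns,
      regression_ok = ns >= 2,
      duration_mean = mean(runs$duration_min),
      duration_sd = sd(runs$duration_min),
      facility_mean_nl = mean(1000 * runs$facility),
      facility_sd_nl = sd(1000 * runs$facility)
    )
  }
  bind_rows(out)
}
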