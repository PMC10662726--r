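#' Physical parameters of the model eye
#'
#' Builds the parameter set describing the eye as a pressurized vessel with
#' viscoelastic walls (a standard linear solid: two compliances `C_W1`,
#' `C_W2` and a wall resistance `R_W`) drained through the trabecular
#' pathway of resistance `R_T`.  Aqueous production, uveoscleral outflow,
#' and episcleral venous pressure are constant on experimental time scales
#' and are absorbed into the resting IOP.
#'
#' Defaults are for an adult rat eye.  The two wall compliances default to
#' `2 * wall_compliance` each, so that their series combination
#' `1/C_W = 1/C_W1 + 1/C_W2` equals the measured ocular compliance.
#'
#' @param resting_iop Resting IOP (mmHg).
#' @param trabecular_resistance Trabecular outflow resistance `R_T`
#'   (mmHg min/ul).  Outflow facility is `1/R_T`.
#' @param wall_resistance Corneoscleral wall resistance `R_W`
#'   (mmHg min/ul).  `0` gives a purely elastic globe.
#' @param wall_compliance Total ocular compliance `C_W` (ul/mmHg).
#' @param wall_compliance_1,wall_compliance_2 The two wall compliance
#'   elements (ul/mmHg); default `2 * wall_compliance` each.
#' @return A list of class `eye_params`.
#' @examples
#' eye_params()
#' eye_params(trabecular_resistance = 50)
#' @export
eye_params <- function(resting_iop = 15,
                       trabecular_resistance = 43,
                       wall_resistance = 2.3,
                       wall_compliance = 0.09,
                       wall_compliance_1 = 2 * wall_compliance,
                       wall_compliance_2 = 2 * wall_compliance) {
  p <- list(
    resting_iop = resting_iop,
    trabecular_resistance = trabecular_resistance,
    wall_resistance = wall_resistance,
    wall_compliance_1 = wall_compliance_1,
    wall_compliance_2 = wall_compliance_2
  )
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || !is.finite(p[[nm]]) ||
        p[[nm]] < 0) {
      abort(sprintf("`%s` must be a single non-negative finite number", nm),
            class = "perfusim_parameter_error")
    }
  }
  if (trabecular_resistance <= 0) {
    abort("`trabecular_resistance` must be positive",
          class = "perfusim_parameter_error")
  }
  if (wall_compliance_1 <= 0 || wall_compliance_2 <= 0) {
    abort("wall compliances must be positive",
          class = "perfusim_parameter_error")
  }
  structure(p, class = "eye_params")
}

#' Physical parameters of the perfusion system
#'
#' Describes the hardware between the flow or pressure source and the eye:
#' the cannula resistance `R_C`, the system (tubing and sensor) compliance
#' `C_S`, and -- for gravity-driven perfusion -- the system resistance `R_S`
#' dominated by the flow transducer.  Digital pump control runs at a fixed
#' update interval with a one-interval feedback delay.
#'
#' @param cannula_resistance Cannula resistance `R_C` (mmHg min/ul); the
#'   default is a 33-gauge needle.
#' @param system_compliance System compliance `C_S` (ul/mmHg).
#' @param update_interval Controller and recording interval (s).
#' @param feedback_delay Digital feedback delay, in update intervals.
#' @return A list of class `system_params`.
#' @examples
#' system_params()
#' @export
system_params <- function(cannula_resistance = 0.36,
                          system_compliance = 0.05,
                          update_interval = 0.1,
                          feedback_delay = 1) {
  if (cannula_resistance <= 0) {
    abort("`cannula_resistance` must be positive",
          class = "perfusim_parameter_error")
  }
  if (system_compliance < 0) {
    abort("`system_compliance` must be non-negative",
          class = "perfusim_parameter_error")
  }
  if (update_interval <= 0) {
    abort("`update_interval` must be positive",
          class = "perfusim_parameter_error")
  }
  structure(
    list(
      cannula_resistance = cannula_resistance,
      system_compliance = system_compliance,
      update_interval = update_interval,
      feedback_delay = as.integer(feedback_delay)
    ),
    class = "system_params"
  )
}

#' @export
print.eye_params <- function(x, ...) {
  cat("<eye_params>\n")
  cat(sprintf("  resting IOP            %g mmHg\n", x$resting_iop))
  cat(sprintf("  trabecular resistance  %g mmHg min/ul (facility %.4f ul/min/mmHg)\n",
              x$trabecular_resistance, 1 / x$trabecular_resistance))
  cat(sprintf("  wall resistance        %g mmHg min/ul\n", x$wall_resistance))
  cat(sprintf("  wall compliances       %g + %g ul/mmHg (series %g)\n",
              x$wall_compliance_1, x$wall_compliance_2,
              1 / (1 / x$wall_compliance_1 + 1 / x$wall_compliance_2)))
  invisible(x)
}

#' @export
print.system_params <- function(x, ...) {
  cat("<system_params>\n")
  cat(sprintf("  cannula resistance  %g mmHg min/ul\n", x$cannula_resistance))
  cat(sprintf("  system compliance   %g ul/mmHg\n", x$system_compliance))
  cat(sprintf("  update interval     %g s (delay %d interval)\n",
              x$update_interval, x$feedback_delay))
  invisible(x)
}

#' Coefficients of the governing third-order dynamics
#'
#' Returns the three lumped coefficients `alpha`, `beta`, `gamma` of the
#' third-order differential equation relating system pressure to source
#' flow.  The characteristic polynomial of the full eye-plus-system circuit
#' is `alpha*R_C*C_S s^3 + (alpha + beta*C_S) s^2 + gamma s + 1`; the
#' simulator's state-space realization is checked against it in the test
#' suite.
#'
#' @param eye An [eye_params()] object.
#' @param sys A [system_params()] object.
#' @return A one-row tibble with columns `alpha` (mmHg min^3/ul), `beta`
#'   (mmHg min^2/ul), and `gamma` (min).
#' @examples
#' perfusion_coefficients(eye_params(), system_params())
#' @export
perfusion_coefficients <- function(eye = eye_params(), sys = system_params()) {
  stopifnot(inherits(eye, "eye_params"), inherits(sys, "system_params"))
  RT <- eye$trabecular_resistance
  RW <- eye$wall_resistance
  C1 <- eye$wall_compliance_1
  C2 <- eye$wall_compliance_2
  RC <- sys$cannula_resistance
  CS <- sys$system_compliance
  tibble(
    alpha = RT * RW * C1 * C2,
    beta = RC * RW * C1 + RC * RW * C2 + RC * RT * C2 + RT * RW * C1 +
      RT * RW * C2,
    gamma = RC * CS + RT * CS + RW * C1 + RW * C2 + RT * C2
  )
}

# continuous-time state matrix of the circuit (3 states), used for
# stiffness-aware sub-stepping and the characteristic-polynomial check
system_matrix <- function(eye, sys, feedback_gain = 0) {
  RT <- eye$trabecular_resistance
  RW <- eye$wall_resistance
  C1 <- eye$wall_compliance_1
  C2 <- eye$wall_compliance_2
  RC <- sys$cannula_resistance
  CS <- sys$system_compliance
  g <- feedback_gain # 1/R_S for gravity feedback, K for an analog pump
  q <- 1 / RC + 1 / RT
  a31 <- if (RW > 0) 1 / (RC * C1) else 0
  a32 <- if (RW > 0) -q / C1 else 0
  a33 <- if (RW > 0) -(q + 1 / RW) / C1 else 0
  matrix(c(
    -(g + 1 / RC) / CS, 1 / (RC * CS), 1 / (RC * CS),
    1 / (RC * C2), -q / C2, -q / C2,
    a31, a32, a33
  ), nrow = 3, byrow = TRUE)
}
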