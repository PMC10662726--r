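#' Closed-form steady state of a perfusion model
#'
#' With all time derivatives at zero the circuit reduces to resistances in
#' series, giving the plateau pressures and flows directly:
#'
#' * CF: `P_S = P_rest + (R_C + R_T) F_S`
#' * CPg: `F_S = (P - P_rest) / (R_S + R_C + R_T)`
#' * CPp: `F_S = K (P_T - P_rest) / (1 + K (R_C + R_T))`
#'
#' and in every mode `F_E = F_S` and `P_E = P_S - R_C F_S` at the plateau
#' (no flow is stored in any compliance).
#'
#' @param ctrl A [controllers] specification.
#' @param input_level Commanded flow (CF, ul/min) or reservoir/target
#'   pressure (CPg/CPp, mmHg).
#' @param eye,sys Model parameters.
#' @return A one-row tibble with columns `p_s`, `f_s`, `p_e`, `f_e`.
#' @examples
#' steady_state(cf_controller(), 0.1)
#' steady_state(cpg_controller(10), 20)
#' steady_state(cpp_controller(7), 20)
#' @export
steady_state <- function(ctrl, input_level, eye = eye_params(),
                         sys = system_params()) {
  stopifnot(inherits(ctrl, "controller_spec"))
  Pbar <- eye$resting_iop
  RT <- eye$trabecular_resistance
  RC <- sys$cannula_resistance
  fs <- switch(ctrl$mode,
    CF = input_level,
    CPg = (input_level - Pbar) / (1 / ctrl$gain + RC + RT),
    CPp = ctrl$gain * (input_level - Pbar) / (1 + ctrl$gain * (RC + RT))
  )
  ps <- Pbar + (RC + RT) * fs
  pe <- ps - RC * fs
  if (pe < 0) {
    abort("input level implies a negative steady-state eye pressure",
          class = "perfusim_parameter_error")
  }
  tibble(p_s = ps, f_s = fs, p_e = pe, f_e = fs)
}
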