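# shared fixtures: rat-eye defaults and the four reference controllers
eye0 <- eye_params()
sys0 <- system_params()

controllers0 <- list(
  CF = cf_controller(),
  CPg1 = cpg_controller(10),
  CPg2 = cpg_controller(0.6),
  CPp = cpp_controller(7)
)

# settling time of a noise-free step from rest, with the pre-step plateau
# as flow baseline
settle_from_rest <- function(ctrl, level, duration, reference = "excursion") {
  tr <- simulate_perfusion(ctrl, level, duration = duration)
  rest <- if (ctrl$mode == "CF") 0 else eye0$resting_iop
  settling_time(tr, steady_state(ctrl, level),
                baseline = steady_state(ctrl, rest),
                reference = reference)
}

true_facility <- 1 / eye0$trabecular_resistance
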