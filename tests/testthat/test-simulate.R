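test_that("resting equilibrium is preserved exactly", {
  for (ctrl in controllers0) {
    lev <- if (ctrl$mode == "CF") 0 else 15
    tr <- simulate_perfusion(ctrl, lev, duration = 2)
    expect_equal(tr$p_s, rep(15, nrow(tr)), tolerance = 1e-12)
    expect_equal(tr$f_s, rep(0, nrow(tr)), tolerance = 1e-12)
    expect_equal(tr$p_e, rep(15, nrow(tr)), tolerance = 1e-12)
  }
})

test_that("long simulations converge to the closed-form plateaus", {
  tr <- simulate_perfusion(cf_controller(), 0.1, duration = 160)
  expect_equal(tail(tr$p_s, 1), 19.336, tolerance = 1e-6)

  ctrl <- cpp_controller(7)
  tr <- simulate_perfusion(ctrl, 20, duration = 60)
  ss <- steady_state(ctrl, 20)
  expect_equal(tail(tr$f_s, 1), ss$f_s, tolerance = 1e-6)
  expect_equal(tail(tr$p_s, 1), ss$p_s, tolerance = 1e-6)

  ctrl <- cpg_controller(0.6)
  tr <- simulate_perfusion(ctrl, 20, duration = 60)
  ss <- steady_state(ctrl, 20)
  expect_equal(tail(tr$f_s, 1), ss$f_s, tolerance = 1e-6)
})

test_that("flow is conserved: F_E = F_S - C_S dP_S/dt at every sample", {
  for (ctrl in list(cf_controller(), cpg_controller(0.6))) {
    lev <- if (ctrl$mode == "CF") 0.1 else 20
    tr <- simulate_perfusion(ctrl, lev, duration = 10)
    n <- nrow(tr)
    dps <- (tr$p_s[3:n] - tr$p_s[1:(n - 2)]) / (tr$time_min[3:n] -
                                                  tr$time_min[1:(n - 2)])
    resid <- tr$f_e[2:(n - 1)] -
      (tr$f_s[2:(n - 1)] - sys0$system_compliance * dps)
    # centered-difference truncation error; the first seconds of a CP
    # step carry extreme curvature, so bound them separately
    late <- tr$time_min[2:(n - 1)] > 0.2
    expect_lt(max(abs(resid[late])), 5e-4)
    expect_lt(max(abs(resid)), 0.05)
  }
})

test_that("halving dt changes the terminal pressure below RK4 tolerance", {
  tr1 <- simulate_perfusion(cpg_controller(0.6), 20, duration = 20, dt = 0.1)
  tr2 <- simulate_perfusion(cpg_controller(0.6), 20, duration = 20, dt = 0.05)
  expect_lt(abs(tail(tr1$p_s, 1) - tail(tr2$p_s, 1)), 1e-8)
})

test_that("analog pump with K = 1/R_S duplicates the gravity model exactly", {
  tr_g <- simulate_perfusion(cpg_controller(10), 20, duration = 30)
  tr_p <- simulate_perfusion(cpp_controller(0.1, analog = TRUE), 20,
                             duration = 30)
  expect_lt(max(abs(tr_g$p_s - tr_p$p_s)), 1e-6)
  expect_lt(max(abs(tr_g$f_s - tr_p$f_s)), 1e-6)
})

test_that("purely elastic globe follows the reduced second-order dynamics", {
  eye_el <- eye_params(wall_resistance = 0)
  tr <- simulate_perfusion(cf_controller(), 0.1, eye = eye_el, sys = sys0,
                           duration = 30)
  # independent oracle: matrix-exponential solution of the 2-state system
  RC <- sys0$cannula_resistance; CS <- sys0$system_compliance
  RT <- eye_el$trabecular_resistance; C2 <- eye_el$wall_compliance_2
  A <- matrix(c(-1 / (RC * CS), 1 / (RC * CS),
                1 / (RC * C2), -(1 / RC + 1 / RT) / C2), 2, byrow = TRUE)
  xss <- c(19.336, 19.3)
  eg <- eigen(A)
  co <- solve(eg$vectors, c(15, 15) - xss)
  pred <- sapply(tr$time_min, function(t) {
    Re((eg$vectors %*% (co * exp(eg$values * t)))[1]) + xss[1]
  })
  expect_equal(tr$p_s, pred, tolerance = 1e-6)
})

test_that("eye state is recovered from system measurements", {
  # constant pressure, zero flow
  tr <- tibble::tibble(time_min = seq(0, 1, by = 1 / 600),
                       p_s = 17, f_s = 0)
  rec <- recover_eye_state(tr, sys0)
  expect_equal(rec$p_e, rep(17, nrow(tr)))
  expect_equal(rec$f_e, rep(0, nrow(tr)))

  # plateau of a noise-free step: P_E = P_S - R_C F_S, F_E = F_S
  tr <- simulate_perfusion(cf_controller(), 0.1, duration = 120)
  rec <- recover_eye_state(tr, sys0)
  n <- nrow(rec)
  expect_equal(rec$p_e[n - 1], tr$p_s[n - 1] - 0.36 * 0.1, tolerance = 1e-5)
  expect_equal(rec$f_e[n - 1], 0.1, tolerance = 1e-5)

  # ramping pressure at rate r with no source flow: F_E = -C_S r exactly
  r <- 2 # mmHg/min
  tr <- tibble::tibble(time_min = seq(0, 2, by = 1 / 600))
  tr$p_s <- 15 + r * tr$time_min
  tr$f_s <- 0
  rec <- recover_eye_state(tr, sys0)
  inner <- 2:(nrow(rec) - 1)
  expect_equal(rec$f_e[inner], rep(-sys0$system_compliance * r, length(inner)),
               tolerance = 1e-9)

  expect_error(recover_eye_state(tr[1:2, ], sys0),
               class = "perfusim_input_error")
})

test_that("settling time conventions behave as documented", {
  ctrl <- cpp_controller(7)
  st_exc <- settle_from_rest(ctrl, 20, 20, reference = "excursion")
  st_abs <- settle_from_rest(ctrl, 20, 20, reference = "absolute")
  expect_gt(st_exc, 0)
  # for a pressure rising from 15 the absolute band is wider, so the
  # absolute convention can only settle earlier or equal
  expect_lte(st_abs, st_exc)
  # too-short trace reports a sentinel
  tr <- simulate_perfusion(ctrl, 20, duration = 0.5)
  expect_true(is.na(settling_time(tr, steady_state(ctrl, 20),
                                  baseline = steady_state(ctrl, 15))))
})

test_that("noise offsets wrap and feed the controllers", {
  rec <- noise_exvivo(duration = 1, seed = 3)
  tr <- simulate_perfusion(cpg_controller(0.6), 20, duration = 3, noise = rec)
  # measured pressure is perturbed, and flow inherits gain-amplified noise
  base <- simulate_perfusion(cpg_controller(0.6), 20, duration = 3)
  dev_p <- tr$p_s - base$p_s
  dev_f <- tr$f_s - base$f_s
  expect_gt(sd(dev_p), 0.02)
  expect_gt(sd(dev_f), sd(dev_p)) # 1/R_S = 1.67 amplification
  # same record, same offset: reproducible
  tr2 <- simulate_perfusion(cpg_controller(0.6), 20, duration = 3, noise = rec)
  expect_identical(tr$p_s, tr2$p_s)
})

test_that("traces round-trip through CSV", {
  tr <- simulate_perfusion(cpg_controller(0.6), 20, duration = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$p_s, tr$p_s, tolerance = 1e-9)
  expect_equal(back$f_e, tr$f_e, tolerance = 1e-9)
})
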