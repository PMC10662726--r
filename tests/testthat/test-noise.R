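test_that("enucleated-eye noise has the stated amplitude and is reproducible", {
  for (s in c(1, 7, 99)) {
    r <- noise_exvivo(duration = 30, seed = s)
    expect_equal(sd(r$pressure_mmHg), 0.04, tolerance = 0.1)
    expect_lt(abs(mean(r$pressure_mmHg)), 0.01 * sd(r$pressure_mmHg))
  }
  a <- noise_exvivo(duration = 5, seed = 11)
  b <- noise_exvivo(duration = 5, seed = 11)
  expect_identical(a$pressure_mmHg, b$pressure_mmHg)
  expect_false(identical(a$pressure_mmHg,
                         noise_exvivo(duration = 5, seed = 12)$pressure_mmHg))
})

test_that("lowpassed noise power decreases with frequency above the cutoff", {
  r <- noise_exvivo(duration = 60, seed = 2)
  psd <- characterize_noise(r)$psd
  # octave-averaged bins from the cutoff to Nyquist
  edges <- 0.4 * 2^(0:3)
  pw <- sapply(seq_len(length(edges) - 1), function(i) {
    sel <- psd$freq_hz >= edges[i] & psd$freq_hz < edges[i + 1]
    mean(psd$psd[sel])
  })
  expect_true(all(diff(pw) < 0))
})

test_that("rescaling to the target SD preserves spectral shape", {
  r1 <- noise_exvivo(duration = 30, seed = 5, rescale = TRUE)
  r2 <- noise_exvivo(duration = 30, seed = 5, rescale = FALSE)
  p1 <- characterize_noise(r1)$psd
  p2 <- characterize_noise(r2)$psd
  sel <- p1$freq_hz > 0.05 & p1$freq_hz < 4
  ratio <- p1$psd[sel] / p2$psd[sel]
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-6)
  expect_lt(sd(r2$pressure_mmHg), 0.04) # filtering alone shrinks the SD
})

test_that("surrogate regimes match their calibration statistics", {
  for (s in 1:3) {
    ra <- noise_surrogate("anesthetized", 30, seed = s)
    expect_equal(sd(ra$pressure_mmHg), 0.23, tolerance = 0.13)
    rc <- noise_surrogate("conscious", 30, seed = s)
    expect_gt(characterize_noise(rc)$skewness, 0.5)
  }
  # zero event rate degenerates to the pure Gaussian base
  r0 <- noise_surrogate("anesthetized", 15, seed = 1,
                        params = list(event_rate = 0))
  expect_equal(sd(r0$pressure_mmHg), 0.23, tolerance = 1e-6)
  expect_lt(abs(characterize_noise(r0)$skewness), 0.2)
})

test_that("cohorts regenerate exactly from their manifest seeds", {
  recs <- noise_cohort("exvivo", n = 3, duration = 2, seed = 9)
  man <- attr(recs, "manifest")
  expect_equal(nrow(man), 3)
  again <- noise_exvivo(duration = 2, seed = man$seed[2])
  expect_identical(recs[[2]]$pressure_mmHg, again$pressure_mmHg)
})

test_that("resampling behaves like averaging down and holding up", {
  r20 <- perfusim:::new_noise_record(rep(c(0.3, -0.3), 50), 20, "custom")
  d <- resample_noise(r20, 10)
  expect_equal(d$pressure_mmHg, rep(0, 50)) # pair averages cancel
  expect_equal(attr(d, "rate_hz"), 10)

  r1 <- perfusim:::new_noise_record(c(1, 2, 3), 1, "custom")
  u <- resample_noise(r1, 10)
  expect_equal(length(u$pressure_mmHg), 30)
  expect_equal(u$pressure_mmHg[1:10], rep(1, 10))

  rc <- perfusim:::new_noise_record(rep(0.7, 40), 20, "custom")
  expect_equal(resample_noise(rc, 10)$pressure_mmHg, rep(0.7, 20))
  expect_error(resample_noise(perfusim:::new_noise_record(numeric(0), 10,
                                                          "custom"), 20),
               class = "perfusim_input_error")
})

test_that("characterization finds a sine's frequency and Gaussian symmetry", {
  rate <- 10
  t <- seq(0, 60 * 60 - 1 / rate, by = 1 / rate)
  r <- perfusim:::new_noise_record(0.5 * sin(2 * pi * 0.8 * t), rate, "custom")
  psd <- characterize_noise(r)$psd
  expect_equal(psd$freq_hz[which.max(psd$psd)], 0.8, tolerance = 0.01)

  set.seed(31)
  g <- perfusim:::new_noise_record(rnorm(36000), 10, "custom")
  expect_lt(abs(characterize_noise(g)$skewness), 0.1)

  short <- perfusim:::new_noise_record(rnorm(100), 10, "custom")
  expect_error(characterize_noise(short), class = "perfusim_input_error")
})

test_that("noise records round-trip through CSV and reject bad files", {
  r <- noise_exvivo(duration = 1, seed = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_noise_record(r, path)
  back <- read_noise_record(path)
  expect_equal(back$pressure_mmHg, r$pressure_mmHg, tolerance = 1e-9)
  expect_equal(attr(back, "rate_hz"), 10, tolerance = 1e-6)

  # constant single-column file becomes a zero record after mean removal
  p2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(pressure_mmHg = rep(4.2, 50)), p2, row.names = FALSE)
  z <- read_noise_record(p2, rate = 10)
  expect_equal(z$pressure_mmHg, rep(0, 50))
  expect_error(read_noise_record(p2), class = "perfusim_input_error")

  # irregular timestamps are rejected with a resampling hint
  p3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(time_s = cumsum(runif(20)), pressure_mmHg = rnorm(20)),
            p3, row.names = FALSE)
  expect_error(read_noise_record(p3), regexp = "resample",
               class = "perfusim_input_error")
})
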