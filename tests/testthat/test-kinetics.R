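# Stopped-flow kinetics: model closed forms, fitting, order selection,
# half-times and directionality.

test_that("multi-exponential model obeys its closed forms", {
  expect_equal(multiexp_model(0, 1, c(-0.5, 0.3), c(0.1, 10)), 0.8)
  expect_equal(multiexp_model(1e6, 2, c(-0.5, 0.3), c(0.1, 10)), 2,
               tolerance = 1e-12)
  # single term at tau * ln 2: halfway to the baseline
  expect_equal(multiexp_model(0.1 * log(2), 1, -0.5, 0.1), 1 - 0.25)
})

test_that("half-time conversions follow the ln 2 identity", {
  expect_equal(half_time(100), 100 * log(2))
  expect_equal(half_time(100), 69.31, tolerance = 1e-4)
  expect_equal(tau_from_half_time(128), 128 / log(2))
  expect_equal(tau_from_half_time(128), 184.66, tolerance = 1e-4)
  expect_equal(tau_from_half_time(half_time(3.7)), 3.7)
  expect_lt(half_time(1e-9), 1e-8)
  expect_error(half_time(-1))
})

test_that("noiseless traces are recovered to near machine precision", {
  tr1 <- gen_trace(1, -0.5, 0.1, noise_sd = 0, n_points = 100, duration = 1)
  f1 <- fit_trace(tr1, 1)
  expect_equal(f1$baseline, 1, tolerance = 1e-6)
  expect_equal(f1$amplitudes, -0.5, tolerance = 1e-6)
  expect_equal(f1$time_constants, 0.1, tolerance = 1e-6)

  tr3 <- gen_trace(1, c(-0.5, -0.2, 0.3), c(0.0826, 5, 200), noise_sd = 0,
                   n_points = 300, duration = 1000)
  f3 <- fit_trace(tr3, 3)
  expect_equal(f3$time_constants, c(0.0826, 5, 200), tolerance = 1e-6)
  expect_equal(f3$amplitudes, c(-0.5, -0.2, 0.3), tolerance = 1e-6)
  expect_true(all(diff(f3$time_constants) > 0))
})

test_that("fitting is scale-equivariant and time-shift leaves tau alone", {
  tr <- gen_trace(1, c(-0.5, 0.3), c(0.1, 10), noise_sd = 0.005,
                  n_points = 200, duration = 50, seed = 11)
  f <- fit_trace(tr, 2)
  sc <- kinetic_trace(tr$times, tr$intensities * 7,
                      channel = tr$channel, dead_time = tr$dead_time)
  fs <- fit_trace(sc, 2)
  expect_equal(fs$baseline, 7 * f$baseline, tolerance = 1e-6)
  expect_equal(fs$amplitudes, 7 * f$amplitudes, tolerance = 1e-6)
  expect_equal(fs$time_constants, f$time_constants, tolerance = 1e-8)

  sh <- kinetic_trace(tr$times + 0.5, tr$intensities,
                      channel = tr$channel, dead_time = tr$dead_time)
  fsh <- fit_trace(sh, 2)
  expect_equal(fsh$time_constants, f$time_constants, tolerance = 1e-3)
})

test_that("stochastic fits recover injected time constants within 3 SE", {
  taus <- c(0.0826, 5, 200)
  tr <- gen_trace(1, c(-0.5, -0.2, 0.3), taus, noise_sd = 0.01,
                  n_points = 300, duration = 1000, seed = 42)
  f <- fit_trace(tr, 3)
  for (i in 1:3)
    expect_lte(abs(f$time_constants[i] - taus[i]),
               3 * f$se$time_constants[i])
})

test_that("a flat trace is flagged as degenerate", {
  tr <- gen_trace(1, numeric(0), numeric(0), noise_sd = 0.002,
                  n_points = 100, duration = 10, seed = 2)
  f <- fit_trace(tr, 1)
  expect_true(f$degenerate)
})

test_that("order selection finds the true order and returns candidates", {
  tr2 <- gen_trace(1, c(-0.5, -0.3), c(0.08, 5), noise_sd = 0.01,
                   n_points = 300, duration = 25, seed = 3)
  s2 <- select_model(tr2)
  expect_equal(s2$n_terms, 2L)
  expect_true(all(c("1", "2") %in% names(s2$candidates)))

  tr3 <- gen_trace(1, c(-0.5, -0.2, 0.3), c(0.0826, 5, 200),
                   noise_sd = 0.01, n_points = 300, duration = 1000,
                   seed = 3)
  expect_equal(select_model(tr3)$n_terms, 3L)

  flat <- gen_trace(1, numeric(0), numeric(0), noise_sd = 0.002,
                    n_points = 120, duration = 10, seed = 4)
  sf <- select_model(flat)
  expect_equal(sf$n_terms, 1L)
  expect_true(sf$fit$degenerate)
})

test_that("runs test flags structured residuals and passes white noise", {
  structured <- sin(seq(0, 6 * pi, length.out = 120))
  expect_lt(runs_test(structured)$p_value, 0.001)
  white <- withr::with_seed(9, rnorm(200))
  expect_gt(runs_test(white)$p_value, 0.01)
  expect_equal(runs_test(rep(1, 10))$p_value, 1)
})

test_that("directionality calls match the printed fast-phase orderings", {
  # self-quench series on the chaperone: bottom -> waist -> top, seconds
  skp_sets <- list(
    OmpC = list(tau = c(0.0826, 0.125, 0.188), se = c(0.0055, 0.0078, 0.012)),
    OmpA = list(tau = c(0.0386, 0.0617, 0.1047), se = c(0.0027, 0.0042, 0.0073)),
    OmpF = list(tau = c(0.0613, 0.182, 0.270), se = c(0.0049, 0.011, 0.016)))
  for (nm in names(skp_sets)) {
    rep <- infer_directionality(c("K55C", "E82C", "D128C"),
                                skp_sets[[nm]]$tau, skp_sets[[nm]]$se)
    expect_equal(rep$monotonicity, "increasing", info = nm)
    expect_true(all(rep$pair_significant), info = nm)
    expect_equal(rep$conclusion, "bottom_first", info = nm)
  }
  # FRET series on the substrate: N -> mid -> C
  fret <- infer_directionality(c("D25C", "L139C", "D290C"),
                               c(0.143, 0.208, 0.285),
                               c(0.010, 0.014, 0.019))
  expect_equal(fret$conclusion, "N_first")
})

test_that("directionality is inconclusive without strict significant order", {
  flat <- infer_directionality(c("K55C", "E82C", "D128C"),
                               rep(0.1, 3), rep(0.01, 3))
  expect_equal(flat$conclusion, "inconclusive")
  # large errors destroy significance even with a monotone ordering
  noisy <- infer_directionality(c("K55C", "E82C"), c(0.10, 0.11),
                                c(0.05, 0.05))
  expect_equal(noisy$conclusion, "inconclusive")
  single <- infer_directionality(list(site_label("Skp", "K55C")),
                                 0.08, 0.005)
  expect_equal(single$conclusion, "inconclusive")
})

test_that("directionality is invariant to input order", {
  tau <- c(0.188, 0.0826, 0.125); se <- c(0.012, 0.0055, 0.0078)
  a <- infer_directionality(c("D128C", "K55C", "E82C"), tau, se)
  b <- infer_directionality(c("K55C", "E82C", "D128C"),
                            tau[c(2, 3, 1)], se[c(2, 3, 1)])
  expect_equal(a$conclusion, b$conclusion)
  expect_equal(a$table, b$table)
})

test_that("trace CSV IO round-trips data and metadata", {
  tr <- gen_trace(2, c(-1), c(0.2), noise_sd = 0.01, n_points = 80,
                  duration = 2, seed = 5,
                  channel = "fret_acceptor",
                  label_site = site_label("Skp", "E82C"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, f)
  back <- read_trace(f)
  expect_equal(back$times, tr$times, tolerance = 1e-9)
  expect_equal(back$intensities, tr$intensities, tolerance = 1e-9)
  expect_equal(back$channel, "fret_acceptor")
  expect_equal(back$label_site$site, "E82C")
  expect_equal(back$dead_time, tr$dead_time)
})

test_that("fit reports serialize the phase table", {
  tr <- gen_trace(1, c(-0.5), c(0.1), noise_sd = 0.01, n_points = 100,
                  duration = 1, seed = 6)
  f <- fit_trace(tr, 1)
  j <- withr::local_tempfile(fileext = ".json")
  fit_report_json(f, j)
  got <- jsonlite::read_json(j, simplifyVector = TRUE)
  expect_equal(got$n_terms, 1)
  expect_equal(got$phases$tau_s, f$time_constants, tolerance = 1e-9)
})
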