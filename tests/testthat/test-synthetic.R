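# Synthetic-data generators: determinism, fidelity to the models, scenario
# construction and schedule validation.

test_that("trace generation is exact at zero noise and seed-deterministic", {
  tr0 <- gen_trace(1, c(-0.5, 0.3), c(0.1, 10), noise_sd = 0,
                   n_points = 100, duration = 50)
  expect_equal(tr0$intensities,
               multiexp_model(tr0$times, 1, c(-0.5, 0.3), c(0.1, 10)))
  expect_equal(tr0$times[1], 0.0024)
  a <- gen_trace(1, -0.5, 0.1, noise_sd = 0.02, seed = 99)
  b <- gen_trace(1, -0.5, 0.1, noise_sd = 0.02, seed = 99)
  expect_identical(a$intensities, b$intensities)
  expect_false(identical(
    a$intensities, gen_trace(1, -0.5, 0.1, noise_sd = 0.02,
                             seed = 100)$intensities))
})

test_that("the triphasic regime rises fast and decays late", {
  tr <- gen_trace(1, c(-0.5, -0.2, 0.3), c(0.0826, 5, 200), noise_sd = 0,
                  n_points = 400, duration = 1000)
  d <- diff(tr$intensities)
  expect_true(all(d[tr$times[-1] < 0.05] > 0))   # fast rising phase
  expect_true(all(d[tr$times[-1] > 100] < 0))    # slow terminal decay
})

test_that("FCS generation is exact at zero noise and scales as 1/N", {
  cv <- gen_fcs_curve(2, 1e-4, c(0.3), c(5e-6), noise_sd = 0)
  expect_equal(cv$G, fcs_model(cv$lags, 2, 1e-4, c(0.3), c(5e-6)))
  cv2 <- gen_fcs_curve(4, 1e-4, c(0.3), c(5e-6), noise_sd = 0)
  expect_equal(cv$G / 2, cv2$G, tolerance = 1e-12)
  s1 <- gen_fcs_curve(2, 1e-4, noise_sd = 0.02, seed = 5)
  s2 <- gen_fcs_curve(2, 1e-4, noise_sd = 0.02, seed = 5)
  expect_identical(s1$G, s2$G)
})

test_that("bundled fragments are byte-identical to the study sequences", {
  p <- bundled_peptides()
  expect_equal(paste(p$OmpC_N$residues, collapse = ""),
               "AEVYNKDGNKLDLYGKVDGL")
  expect_equal(paste(p$OmpA_N$residues, collapse = ""),
               "APKDNTWYTGAKLGFSQYHDT")
  expect_equal(paste(p$OmpF_N$residues, collapse = ""),
               "AEIYNKDGNKVDLYGKAVGL")
  expect_equal(paste(p$OmpC_C$residues, collapse = ""),
               "FTRDAGINTDNIVALGLVYQF")
  expect_equal(length(p$OmpA_N$residues), 21)
  for (nm in grep("mut", names(p), value = TRUE))
    expect_equal(classify_residues(p[[nm]])$n_charged, 0, info = nm)
})

test_that("trajectory generation is a pure function of scenario + seed", {
  a <- gen_entry_trajectory(entry_scenario("n_first_entry", seed = 12))
  b <- gen_entry_trajectory(entry_scenario("n_first_entry", seed = 12))
  expect_identical(a$trajectory$coords, b$trajectory$coords)
  expect_identical(a$log$crossing_frames, b$log$crossing_frames)
  c <- gen_entry_trajectory(entry_scenario("n_first_entry", seed = 13))
  expect_false(identical(a$trajectory$coords, c$trajectory$coords))
})

test_that("generated trajectories satisfy the container invariants", {
  for (nm in scenario_names()) {
    g <- gen_entry_trajectory(entry_scenario(nm, seed = 1))
    traj <- g$trajectory
    expect_true(all(is.finite(traj$coords)), info = nm)
    expect_equal(dim(traj$coords)[1], nrow(traj$roster), info = nm)
    expect_equal(dim(traj$coords)[3], g$log$n_frames, info = nm)
    # both formats parse back
    d <- withr::local_tempdir()
    for (fmt in c("xyz", "pdb")) {
      f <- file.path(d, paste0(nm, ".", fmt))
      write_trajectory(traj, f)
      expect_s3_class(read_trajectory(f), "skp_trajectory")
    }
  }
})

test_that("unknown scenario names list the valid ones", {
  expect_error(entry_scenario("nope"), "n_first_entry")
})

test_that("infeasible bridge schedules are rejected", {
  sc <- entry_scenario("closed_gate_adhesion", seed = 1)
  # bridge to a site deep inside the cavity while the gate is closed and
  # the peptide is still outside
  sc$bridges <- data.frame(pep_resno = 2L, skp_chain = "A",
                           skp_resno = 91L, form = 70L, brk = 100L,
                           stringsAsFactors = FALSE)
  expect_error(gen_entry_trajectory(sc), "infeasible")
})

test_that("malformed schedules are rejected with a reason", {
  sc <- entry_scenario("n_first_entry", seed = 1)
  bad_sign <- sc
  bad_sign$bridges <- data.frame(pep_resno = 6L, skp_chain = "B",
                                 skp_resno = 71L, form = 20L, brk = 40L,
                                 stringsAsFactors = FALSE)
  expect_error(gen_entry_trajectory(bad_sign), "like charges")

  uncharged <- sc
  uncharged$bridges <- data.frame(pep_resno = 3L, skp_chain = "B",
                                  skp_resno = 71L, form = 20L, brk = 40L,
                                  stringsAsFactors = FALSE)
  expect_error(gen_entry_trajectory(uncharged), "uncharged")

  overlap <- sc
  overlap$bridges <- data.frame(pep_resno = c(2L, 2L),
                                skp_chain = c("B", "C"),
                                skp_resno = c(71L, 71L),
                                form = c(20L, 30L), brk = c(40L, 60L),
                                stringsAsFactors = FALSE)
  expect_error(gen_entry_trajectory(overlap), "overlapping")
})

test_that("closed-gate frames keep the mouth closed and open frames open", {
  g <- gen_entry_trajectory(entry_scenario("n_first_entry", seed = 9))
  gate <- gate_distances(g$trajectory)
  expect_equal(gate$state == "open", g$log$gate_open)
})
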