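# Trajectory IO and the entry analytics: gate states, entry coordinate,
# salt bridges and verdicts.

test_that("XYZ and PDB round trips preserve roster and coordinates", {
  g <- gen_entry_trajectory(entry_scenario("n_first_entry", seed = 2))
  traj <- g$trajectory
  d <- withr::local_tempdir()

  xyz <- file.path(d, "t.xyz")
  write_trajectory(traj, xyz)
  bx <- read_trajectory(xyz)
  expect_equal(bx$roster, traj$roster)
  expect_equal(bx$coords, traj$coords, tolerance = 1e-5)
  expect_equal(bx$frame_time, traj$frame_time)

  pdb <- file.path(d, "t.pdb")
  write_trajectory(traj, pdb)
  bp <- read_trajectory(pdb)
  # PDB carries 0.001 A coordinate precision
  expect_equal(bp$coords, traj$coords, tolerance = 2e-3)
  expect_equal(bp$roster$chain, traj$roster$chain)
  expect_equal(bp$roster$resno, traj$roster$resno)
  expect_equal(bp$roster$sign, traj$roster$sign)
  expect_equal(bp$roster$entity, traj$roster$entity)
  expect_equal(bp$roster$role, traj$roster$role)
})

test_that("PDB reading splits the roster by entity", {
  g <- gen_entry_trajectory(entry_scenario("closed_gate_adhesion", seed = 1))
  d <- withr::local_tempdir()
  pdb <- file.path(d, "c.pdb")
  write_trajectory(g$trajectory, pdb)
  back <- read_trajectory_pdb(pdb)
  expect_setequal(unique(back$roster$chain[back$roster$entity == "skp"]),
                  c("A", "B", "C"))
  expect_true(all(back$roster$chain[back$roster$entity == "peptide"] == "P"))
  expect_equal(sum(back$roster$entity == "peptide" &
                     back$roster$role == "charge_site"), 7)
})

test_that("a frame with a missing particle is rejected by name", {
  g <- gen_entry_trajectory(entry_scenario("uncharged_escape", seed = 1))
  d <- withr::local_tempdir()
  pdb <- file.path(d, "bad.pdb")
  write_trajectory(g$trajectory, pdb)
  lines <- readLines(pdb)
  # drop one ATOM line from the second MODEL block
  second <- grep("^MODEL", lines)[2]
  drop <- grep("^ATOM", lines)
  drop <- drop[drop > second][1]
  writeLines(lines[-drop], pdb)
  expect_error(read_trajectory(pdb), "frame 2")

  xyz <- file.path(d, "bad.xyz")
  write_trajectory(g$trajectory, xyz)
  expect_error({
    xl <- readLines(xyz)
    writeLines(xl[-3], xyz)
    read_trajectory(xyz)
  }, "frame|inconsistent")
})

test_that("missing XYZ sidecar is reported", {
  g <- gen_entry_trajectory(entry_scenario("side_approach", seed = 1))
  d <- withr::local_tempdir()
  xyz <- file.path(d, "s.xyz")
  write_trajectory(g$trajectory, xyz)
  file.remove(file.path(d, "s.roster.json"))
  expect_error(read_trajectory(xyz), "sidecar")
})

test_that("gate states follow the two-of-three pair rule", {
  closed <- make_mini_traj(list(k55_triangle(10)))
  gc <- gate_distances(closed)
  expect_equal(unname(c(gc$d_AB, gc$d_AC, gc$d_BC)), rep(10, 3),
               tolerance = 1e-9)
  expect_equal(gc$state, "closed")

  # chain B displaced 30 A: only the A-C pair stays short -> open
  tri <- k55_triangle(10)
  triB <- tri; triB[2, ] <- triB[2, ] + c(0, -30, 0)
  go <- gate_distances(make_mini_traj(list(triB)))
  expect_gt(go$d_AB, 15); expect_gt(go$d_BC, 15)
  expect_equal(go$d_AC, 10, tolerance = 1e-9)
  expect_equal(go$state, "open")

  all_far <- gate_distances(make_mini_traj(list(k55_triangle(40))))
  expect_equal(all_far$state, "open")
})

test_that("the entry coordinate is zero at the mouth plane and tracks sign", {
  tri <- k55_triangle(10)
  at_plane <- make_mini_traj(list(tri),
                             peptide_xyz_per_frame = list(c(0, 0, 0)))
  expect_equal(delta_z(at_plane)$delta_z, 0, tolerance = 1e-9)
  above <- make_mini_traj(list(tri),
                          peptide_xyz_per_frame = list(c(1, 1, 12)))
  expect_equal(delta_z(above)$delta_z, 12, tolerance = 1e-6)
  below <- make_mini_traj(list(tri),
                          peptide_xyz_per_frame = list(c(0, 2, -7)))
  expect_equal(delta_z(below)$delta_z, -7, tolerance = 1e-6)
})

test_that("gate state and entry coordinate survive global rigid motion", {
  g <- gen_entry_trajectory(entry_scenario("n_first_entry", seed = 3))
  traj <- g$trajectory
  moved <- rigid_transform_traj(traj, random_rotation(5), c(30, -12, 80))
  g0 <- gate_distances(traj); g1 <- gate_distances(moved)
  expect_equal(g1$d_AB, g0$d_AB, tolerance = 1e-6)
  expect_equal(g1$state, g0$state)
  d0 <- delta_z(traj); d1 <- delta_z(moved)
  expect_equal(d1$delta_z, d0$delta_z, tolerance = 1e-6)
})

test_that("the entry crossing frame matches the generator log", {
  # jitter-free script: the crossing is sharp
  g <- gen_entry_trajectory(entry_scenario("n_first_entry", seed = 1),
                            jitter_sd = 0, charge_jitter_sd = 0)
  dz <- delta_z(g$trajectory)
  first_pos <- min(dz$frame[dz$residue == 1 & dz$delta_z > 0])
  expect_lte(abs(first_pos - g$log$crossing_frames[["NT"]]), 1)
  # default jitter: sustained crossing within a few frames of the script
  gj <- gen_entry_trajectory(entry_scenario("n_first_entry", seed = 4))
  rep <- entry_report(gj$trajectory)
  expect_lte(abs(rep$crossing_frames[["NT"]] -
                   gj$log$crossing_frames[["NT"]]), 4)
})

test_that("salt-bridge detection respects sign and cutoff", {
  tri <- k55_triangle(10)
  site <- data.frame(entity = "skp", chain = "A", resno = 55L,
                     resname = "LYS", role = "charge_site", sign = 1L,
                     stringsAsFactors = FALSE)
  site$xyz <- list(c(0, 0, 0))
  mk <- function(pep_xyz, sign) {
    t <- make_mini_traj(list(tri), peptide_xyz_per_frame = list(pep_xyz),
                        pep_sign = sign, skp_charge_sites = site)
    detect_salt_bridges(t, 1)
  }
  expect_equal(nrow(mk(c(3, 0, 0), -1L)), 1)   # opposite at 3 A
  expect_equal(nrow(mk(c(3, 0, 0), +1L)), 0)   # like charges at 3 A
  expect_equal(nrow(mk(c(6, 0, 0), -1L)), 0)   # opposite but beyond cutoff
})

test_that("hysteresis suppresses chatter inside the on/off band", {
  tri <- k55_triangle(10)
  site <- data.frame(entity = "skp", chain = "A", resno = 55L,
                     resname = "LYS", role = "charge_site", sign = 1L,
                     stringsAsFactors = FALSE)
  site$xyz <- list(c(0, 0, 0))
  # approach to 4.4 A, then oscillate between 4.4 and 5.5 A
  xs <- c(8, 4.4, 5.5, 4.4, 5.5, 4.4, 5.5)
  frames <- lapply(xs, function(x) c(x, 0, 0))
  traj <- make_mini_traj(rep(list(tri), length(xs)),
                         peptide_xyz_per_frame = frames, pep_sign = -1L,
                         skp_charge_sites = site)
  ev <- extract_bridge_events(traj)
  expect_equal(nrow(ev$events), 1)
  expect_equal(ev$events$kind, "formed")
  expect_equal(ev$events$frame, 2)
  expect_true(all(ev$counts$n_bridges[-1] == 1))
})

test_that("no opposite-sign pairs means no events and zero counts", {
  g <- gen_entry_trajectory(entry_scenario("uncharged_escape", seed = 1))
  ev <- extract_bridge_events(g$trajectory)
  expect_equal(nrow(ev$events), 0)
  expect_true(all(ev$counts$n_bridges == 0))
})

test_that("events alternate formed/broken for every pair", {
  for (nm in c("n_first_entry", "closed_gate_adhesion", "c_term_escape")) {
    g <- gen_entry_trajectory(entry_scenario(nm, seed = 6))
    ev <- extract_bridge_events(g$trajectory)$events
    if (nrow(ev) == 0) next
    key <- paste(ev$pep_resno, ev$skp_chain, ev$skp_resno)
    for (k in unique(key)) {
      kinds <- ev$kind[key == k]
      expect_equal(kinds, rep(c("formed", "broken"),
                              length.out = length(kinds)), info = nm)
    }
  }
})

test_that("the bridge chain renders in residue-pair notation", {
  g <- gen_entry_trajectory(entry_scenario("n_first_entry", seed = 1))
  chain <- format_bridge_chain(extract_bridge_events(g$trajectory)$events)
  expect_match(chain, "^Glu2–Arg71 \\(chain B\\) → Glu2–Arg71 \\(chain C\\)")
})

test_that("entry reports reproduce the scripted scenario outcomes", {
  cases <- list(n_first_entry = c("entered", "N_first"),
                closed_gate_adhesion = c("adhered_outside", "none"),
                uncharged_escape = c("escaped", "none"))
  for (nm in names(cases)) {
    g <- gen_entry_trajectory(entry_scenario(nm, seed = 7))
    rep <- entry_report(g$trajectory)
    expect_equal(rep$verdict, cases[[nm]][1], info = nm)
    expect_equal(rep$terminus_first, cases[[nm]][2], info = nm)
  }
})
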