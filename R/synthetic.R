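# Synthetic-data generators: seeded noisy kinetic traces, FCS curves, the
# bundled OMP fragment sequences, and scripted coarse-grained entry
# trajectories with ground-truth logs.
#
# The trajectory generator is kinematic, not dynamic: bead positions follow
# a scripted schedule (peptide motion, gate opening, salt-bridge intervals)
# so that every analytic quantity has an exact known answer. Geometry: three
# tentacle chains spanning ~60 A from the Lys55 mouth ring to the Asp128
# core ring, side-to-side 25 A at and above the waist, tapering to tip
# radius 6.5 A so the closed mouth registers as closed under the default
# 15 A gate rule. Chaperone charge sites are a sparse subset (K49, K55,
# R71, E82, R91, D128 per chain) spaced widely enough that scheduled
# bridges are unambiguous under the 4.5/6.0 A hysteresis.

#' Bundled OMP fragment sequences
#'
#' The four terminal fragments used throughout (N-terminal 20-mers of OmpC
#' and OmpF, the 21-residue OmpA fragment, the C-terminal 21-mer of OmpC)
#' plus the charge-neutralized Ala and Asn mutants of the OmpC and OmpA
#' N-terminal fragments.
#'
#' @return named list of [peptide_sequence()] objects.
#' @export
bundled_peptides <- function() {
  base <- list(
    OmpC_N = peptide_sequence("OmpC_N", "AEVYNKDGNKLDLYGKVDGL"),
    OmpA_N = peptide_sequence("OmpA_N", "APKDNTWYTGAKLGFSQYHDT"),
    OmpF_N = peptide_sequence("OmpF_N", "AEIYNKDGNKVDLYGKAVGL"),
    OmpC_C = peptide_sequence("OmpC_C", "FTRDAGINTDNIVALGLVYQF"))
  muts <- list(
    OmpC_N_Amut = neutralize_charges(base$OmpC_N, "A"),
    OmpC_N_Nmut = neutralize_charges(base$OmpC_N, "N"),
    OmpA_N_Amut = neutralize_charges(base$OmpA_N, "A"),
    OmpA_N_Nmut = neutralize_charges(base$OmpA_N, "N"))
  # keep the plain fixture names
  for (nm in names(muts)) muts[[nm]]$id <- nm
  c(base, muts)
}

#' Generate a noisy multi-exponential kinetic trace
#'
#' Evaluates [multiexp_model()] on a log- or linear-spaced time grid
#' starting at the instrument dead time and adds zero-mean Gaussian noise
#' whose standard deviation is `noise_sd` times the dynamic range of the
#' noiseless signal (falling back to `|baseline|` for a flat signal).
#' Bit-reproducible for a given seed.
#'
#' @param baseline asymptotic intensity.
#' @param amplitudes signed amplitudes (may be empty for a flat trace).
#' @param time_constants seconds, same length as `amplitudes`.
#' @param noise_sd noise SD as a fraction of the dynamic range (default 0.01).
#' @param n_points number of samples (>= 50; default 300).
#' @param duration trace length in seconds (default 5x the slowest phase).
#' @param dead_time first sample time, seconds (default 0.0024).
#' @param grid `"log"` (default, suits decade-spanning kinetics) or
#'   `"linear"`.
#' @param seed RNG seed.
#' @param channel,label_site passed to [kinetic_trace()].
#' @return a [kinetic_trace()].
#' @export
gen_trace <- function(baseline = 1, amplitudes = c(-0.5),
                      time_constants = c(0.1), noise_sd = 0.01,
                      n_points = 300, duration = NULL, dead_time = 0.0024,
                      grid = c("log", "linear"), seed = 1,
                      channel = "self_quench", label_site = NULL) {
  grid <- match.arg(grid)
  stopifnot(n_points >= 50, length(amplitudes) == length(time_constants),
            all(time_constants > 0))
  if (is.null(duration))
    duration <- if (length(time_constants)) 5 * max(time_constants) else 10
  stopifnot(duration > dead_time)
  times <- if (grid == "log")
    exp(seq(log(dead_time), log(duration), length.out = n_points))
  else seq(dead_time, duration, length.out = n_points)
  clean <- multiexp_model(times, baseline, amplitudes, time_constants)
  dr <- diff(range(clean))
  scale <- if (dr > 0) dr else if (abs(baseline) > 0) abs(baseline) else 1
  noise <- if (noise_sd > 0)
    withr::with_seed(seed, stats::rnorm(n_points, 0, noise_sd * scale))
  else rep(0, n_points)
  kinetic_trace(times, clean + noise, channel = channel,
                label_site = label_site, dead_time = dead_time)
}

#' Generate a noisy FCS correlation curve
#'
#' Evaluates [fcs_model()] on log-spaced lags and applies multiplicative
#' (shot-noise-like) Gaussian noise `G * (1 + eps)`. Bit-reproducible for a
#' given seed.
#'
#' @param N,tau_d,relax_a,relax_tau model parameters, see [fcs_model()].
#' @param noise_sd relative noise SD (default 0.02).
#' @param n_points number of lags (default 200).
#' @param lag_min,lag_max lag range in seconds.
#' @param seed RNG seed.
#' @return an [fcs_curve()].
#' @export
gen_fcs_curve <- function(N, tau_d, relax_a = numeric(0),
                          relax_tau = numeric(0), noise_sd = 0.02,
                          n_points = 200, lag_min = 1e-6, lag_max = 1,
                          seed = 1) {
  lags <- exp(seq(log(lag_min), log(lag_max), length.out = n_points))
  G <- fcs_model(lags, N, tau_d, relax_a, relax_tau)
  eps <- if (noise_sd > 0)
    withr::with_seed(seed, stats::rnorm(n_points, 0, noise_sd))
  else rep(0, n_points)
  fcs_curve(lags, G * (1 + eps))
}

# ---- chaperone scaffold geometry -----------------------------------------

# per-chain residue table: bead z follows the tentacle span (~60 A from the
# Lys55 mouth at z = 0 to the Asp128 core ring at z = 60)
.SKP_RES <- data.frame(
  resno   = c(43L, 49L, 55L, 60L, 65L, 71L, 76L, 82L, 88L, 91L, 94L, 100L,
              106L, 112L, 118L, 123L, 128L),
  resname = c("GLY", "LYS", "LYS", "GLY", "GLY", "ARG", "GLY", "GLU", "GLY",
              "ARG", "GLY", "GLY", "GLY", "GLY", "GLY", "GLY", "ASP"),
  sign    = c(0L, 1L, 1L, 0L, 0L, 1L, 0L, -1L, 0L, 1L, 0L, 0L, 0L, 0L, 0L,
              0L, -1L),
  stringsAsFactors = FALSE)

.SKP_CHAIN_ANGLES <- c(A = 90, B = 210, C = 330) * pi / 180

.skp_z <- function(resno) (resno - 55) * 60 / 73

# tentacle radius: 6.5 A at the tips (closed mouth), widening to 12.5 A
# (side-to-side 25 A) at and above the waist
.skp_radius <- function(z) pmin(12.5, pmax(6.5, 6.5 + 6 * z / 20))

# outward displacement weight of the mobile chain B when the gate is open
.gate_weight <- function(z) pmin(1, pmax(0, (20 - z) / 20))

# roster of the chaperone scaffold: one backbone bead per residue per chain,
# plus a charge-site bead (same position) for charged residues
.skp_roster <- function() {
  rows <- list()
  for (ch in c("A", "B", "C")) {
    rows[[length(rows) + 1L]] <- data.frame(
      entity = "skp", chain = ch, resno = .SKP_RES$resno,
      resname = .SKP_RES$resname, role = "backbone_ref", sign = 0L,
      stringsAsFactors = FALSE)
    charged <- .SKP_RES[.SKP_RES$sign != 0L, ]
    rows[[length(rows) + 1L]] <- data.frame(
      entity = "skp", chain = ch, resno = charged$resno,
      resname = charged$resname, role = "charge_site", sign = charged$sign,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# ideal (jitter-free) chaperone coordinates for one frame
.skp_coords <- function(roster_skp, open, gate_amp = 18) {
  z <- .skp_z(roster_skp$resno)
  r <- .skp_radius(z)
  if (open) {
    b <- roster_skp$chain == "B"
    r[b] <- r[b] + gate_amp * .gate_weight(z[b])
  }
  ang <- .SKP_CHAIN_ANGLES[roster_skp$chain]
  cbind(r * cos(ang), r * sin(ang), z)
}

# ---- entry scenarios -----------------------------------------------------

#' Names of the bundled entry scenarios
#' @return character vector.
#' @export
scenario_names <- function() {
  files <- list.files(system.file("scenarios", package = "skpentry"),
                      pattern = "\\.yaml$")
  sort(sub("\\.yaml$", "", files))
}

#' Load a bundled entry scenario
#'
#' Scenario scripts live as YAML configs under `scenarios/` in the installed
#' package: peptide, orientation (which terminus leads), frame count, motion
#' script, gate open intervals and the salt-bridge schedule, plus the
#' scripted ground truth.
#'
#' @param name one of [scenario_names()].
#' @param seed RNG seed for the jitter (default 1).
#' @return object of class `entry_scenario`.
#' @export
entry_scenario <- function(name, seed = 1) {
  path <- system.file("scenarios", paste0(name, ".yaml"),
                      package = "skpentry")
  if (!nzchar(path) || !file.exists(path))
    stop(sprintf("unknown scenario '%s'; valid names: %s", name,
                 paste(scenario_names(), collapse = ", ")))
  cfg <- yaml::read_yaml(path)
  peps <- bundled_peptides()
  if (!cfg$peptide %in% names(peps))
    stop("scenario references unknown peptide ", cfg$peptide)
  bridges <- if (length(cfg$bridges))
    do.call(rbind, lapply(cfg$bridges, function(b) data.frame(
      pep_resno = as.integer(b$pep_resno), skp_chain = b$skp_chain,
      skp_resno = as.integer(b$skp_resno), form = as.integer(b$form),
      brk = if (is.null(b$`break`) || is.na(b$`break`)) NA_integer_
            else as.integer(b$`break`), stringsAsFactors = FALSE)))
  else data.frame(pep_resno = integer(), skp_chain = character(),
                  skp_resno = integer(), form = integer(), brk = integer(),
                  stringsAsFactors = FALSE)
  gate_open <- if (length(cfg$gate_open))
    lapply(cfg$gate_open, function(iv) as.integer(unlist(iv)))
  else list()
  structure(list(
    name = cfg$name, peptide = peps[[cfg$peptide]],
    orientation = cfg$orientation %||% "n_lead",
    n_frames = as.integer(cfg$n_frames), motion = cfg$motion,
    gate_open = gate_open, bridges = bridges,
    truth = cfg$truth, seed = as.integer(seed)),
    class = "entry_scenario")
}

#' @export
print.entry_scenario <- function(x, ...) {
  cat(sprintf("<entry_scenario %s> peptide %s, %d frames, %d bridges, seed %d\n",
              x$name, x$peptide$id, x$n_frames, nrow(x$bridges), x$seed))
  invisible(x)
}

# frames (logical vector) during which the gate is open
.gate_open_frames <- function(scenario) {
  open <- rep(FALSE, scenario$n_frames)
  for (iv in scenario$gate_open)
    open[seq.int(iv[1], min(iv[2], scenario$n_frames))] <- TRUE
  open
}

# scripted z of the leading residue at frame f
.head_z <- function(motion, f) {
  fc <- pmin(pmax(f, motion$move_start), motion$move_end)
  motion$z_start + motion$speed * (fc - motion$move_start)
}

# schedule validation: alternation/overlap per peptide residue, partners
# exist with opposite sign, frames in range, feasibility vs closed gate
.validate_schedule <- function(scenario, pep_profile) {
  b <- scenario$bridges
  if (nrow(b) == 0) return(invisible(TRUE))
  nf <- scenario$n_frames
  if (any(b$form < 1 | b$form > nf) || any(!is.na(b$brk) & b$brk > nf))
    stop("bridge schedule outside the frame range")
  if (any(!is.na(b$brk) & b$brk <= b$form))
    stop("bridge break frame must follow its form frame")
  cp <- pep_profile$charge_positions
  for (i in seq_len(nrow(b))) {
    row <- cp[cp$position == b$pep_resno[i], ]
    if (nrow(row) == 0)
      stop("bridge references uncharged peptide residue ", b$pep_resno[i])
    srow <- .SKP_RES[.SKP_RES$resno == b$skp_resno[i], ]
    if (nrow(srow) == 0 || srow$sign == 0L)
      stop("bridge references unknown chaperone charge site ", b$skp_resno[i])
    pep_sign <- if (row$sign == "+") 1L else -1L
    if (pep_sign * srow$sign >= 0)
      stop("bridge pairs like charges: peptide residue ", b$pep_resno[i],
           " with chaperone residue ", b$skp_resno[i])
  }
  # per-residue interval overlap (one partner at a time)
  for (rn in unique(b$pep_resno)) {
    iv <- b[b$pep_resno == rn, ]
    iv <- iv[order(iv$form), ]
    end <- ifelse(is.na(iv$brk), nf + 1L, iv$brk)
    if (nrow(iv) > 1 && any(iv$form[-1] < end[-nrow(iv)]))
      stop("overlapping bridge intervals for peptide residue ", rn)
  }
  # infeasible: forming a bridge deep inside the cavity while the gate is
  # closed and the peptide residue is still outside (below the mouth)
  open <- .gate_open_frames(scenario)
  for (i in seq_len(nrow(b))) {
    z_site <- .skp_z(b$skp_resno[i])
    z_pep <- .residue_z(scenario, b$pep_resno[i], b$form[i])
    if (!open[b$form[i]] && z_site > 10 && z_pep < 0)
      stop(sprintf(paste0("infeasible schedule: bridge to residue %d ",
                          "(z = %.1f A, inside the cavity) at frame %d ",
                          "while the gate is closed and peptide residue %d ",
                          "is outside"),
                   b$skp_resno[i], z_site, b$form[i], b$pep_resno[i]))
  }
  invisible(TRUE)
}

# scripted z of peptide residue rn at frame f (before jitter)
.residue_z <- function(scenario, rn, f) {
  n <- length(scenario$peptide$residues)
  zh <- .head_z(scenario$motion, f)
  if (identical(scenario$orientation, "c_lead")) zh - (n - rn) * 2.0
  else zh - (rn - 1) * 2.0
}

#' Generate a scripted coarse-grained entry trajectory
#'
#' Emits a bead trajectory following the scenario script -- peptide motion
#' along (or beside) the cavity axis, chain-B gate opening/closing, and the
#' salt-bridge schedule, with seeded Gaussian jitter -- together with a
#' ground-truth log. Bridged charge beads are pinned 2.8 A from their
#' partner site (side-chain reach is not modelled); free charge beads are
#' kept clear of every opposite-sign site so the emitted event sequence
#' equals the schedule exactly, which the generator verifies before
#' returning.
#'
#' @param scenario an [entry_scenario()].
#' @param jitter_sd positional jitter SD in Angstrom for backbone beads
#'   (default 0.5).
#' @param charge_jitter_sd jitter SD for charge-site beads (default 0.1;
#'   kept small so the bridge schedule is unambiguous).
#' @param gate_amp outward tip displacement of chain B when open, Angstrom.
#' @param verify re-run the bridge detector on the emitted frames and stop
#'   on any mismatch with the schedule (default TRUE).
#' @return list with `trajectory` (an [trajectory()]) and `log` (class
#'   `ground_truth_log`: `scenario`, `seed`, `verdict`, `terminus_first`,
#'   `crossing_frames` (NT/CT), `events` (scheduled event data.frame),
#'   `gate_open` (logical per frame), `n_frames`).
#' @export
gen_entry_trajectory <- function(scenario, jitter_sd = 0.5,
                                 charge_jitter_sd = 0.1, gate_amp = 18,
                                 verify = TRUE) {
  stopifnot(inherits(scenario, "entry_scenario"))
  pep <- scenario$peptide
  profile <- classify_residues(pep)
  .validate_schedule(scenario, profile)

  nf <- scenario$n_frames
  open <- .gate_open_frames(scenario)
  rost_skp <- .skp_roster()

  n_res <- length(pep$residues)
  aa3 <- toupper(seqinr::aaa(pep$residues))
  rost_pep <- data.frame(entity = "peptide", chain = "P",
                         resno = seq_len(n_res), resname = aa3,
                         role = "backbone_ref", sign = 0L,
                         stringsAsFactors = FALSE)
  cp <- profile$charge_positions
  if (nrow(cp) > 0)
    rost_pep <- rbind(rost_pep, data.frame(
      entity = "peptide", chain = "P", resno = cp$position,
      resname = aa3[cp$position], role = "charge_site",
      sign = ifelse(cp$sign == "+", 1L, -1L), stringsAsFactors = FALSE))
  roster <- rbind(rost_skp, rost_pep)

  skp_rows <- seq_len(nrow(rost_skp))
  pep_rows <- nrow(rost_skp) + seq_len(nrow(rost_pep))
  pep_bb_row <- function(rn)
    pep_rows[rost_pep$role == "backbone_ref" & rost_pep$resno == rn]
  pep_cs_row <- function(rn)
    pep_rows[rost_pep$role == "charge_site" & rost_pep$resno == rn]
  skp_cs <- which(roster$entity == "skp" & roster$role == "charge_site")

  b <- scenario$bridges
  active_at <- function(f) which(b$form <= f & (is.na(b$brk) | f < b$brk))

  coords <- array(NA_real_, c(nrow(roster), 3, nf))
  withr::with_seed(scenario$seed, {
    for (f in seq_len(nf)) {
      X <- matrix(NA_real_, nrow(roster), 3)
      X[skp_rows, ] <- .skp_coords(rost_skp, open[f], gate_amp)
      # peptide scripted positions
      for (i in seq_len(nrow(rost_pep))) {
        rn <- rost_pep$resno[i]
        if (identical(scenario$motion$kind, "side")) {
          r0 <- scenario$motion$r_start +
            scenario$motion$speed * (f - 1) + (rn - 1) * 2.0
          X[pep_rows[i], ] <- c(r0, 0, scenario$motion$z_level)
        } else {
          X[pep_rows[i], ] <- c(0, 0, .residue_z(scenario, rn, f))
        }
      }
      # jitter
      sdv <- ifelse(roster$role == "charge_site", charge_jitter_sd, jitter_sd)
      X <- X + matrix(stats::rnorm(length(X), 0, rep(sdv, 3)),
                      ncol = 3)
      # pin scheduled bridges: partner site + 2.8 A toward the axis
      for (k in active_at(f)) {
        site <- which(roster$entity == "skp" & roster$role == "charge_site" &
                        roster$chain == b$skp_chain[k] &
                        roster$resno == b$skp_resno[k])
        p <- X[site, ]
        inward <- -c(p[1], p[2], 0)
        inward <- inward / max(sqrt(sum(inward^2)), 1e-9)
        X[pep_cs_row(b$pep_resno[k]), ] <-
          p + 2.8 * inward + stats::rnorm(3, 0, charge_jitter_sd)
      }
      # keep free charge beads clear of every opposite-sign site
      free_cs <- setdiff(
        pep_rows[rost_pep$role == "charge_site"],
        vapply(active_at(f), function(k) pep_cs_row(b$pep_resno[k]),
               integer(1)))
      for (pass in 1:3) {
        moved <- FALSE
        for (i in free_cs) {
          opp <- skp_cs[roster$sign[skp_cs] * roster$sign[i] < 0]
          d <- sqrt(rowSums((X[opp, , drop = FALSE] -
                               matrix(X[i, ], length(opp), 3,
                                      byrow = TRUE))^2))
          j <- which.min(d)
          if (d[j] < 5.5) {
            dir <- X[i, ] - X[opp[j], ]
            dir <- dir / max(sqrt(sum(dir^2)), 1e-9)
            X[i, ] <- X[opp[j], ] + 5.5 * dir
            moved <- TRUE
          }
        }
        if (!moved) break
      }
      coords[, , f] <- X
    }
  })

  traj <- trajectory(roster, coords)

  # ground truth from the emitted coordinates along the construction axis
  k55 <- which(roster$entity == "skp" & roster$role == "backbone_ref" &
                 roster$resno == 55L)
  nt_rn <- 1L; ct_rn <- n_res
  z_ref <- vapply(seq_len(nf), function(f) mean(coords[k55, 3, f]),
                  numeric(1))
  dz_nt <- coords[pep_bb_row(nt_rn), 3, ] - z_ref
  dz_ct <- coords[pep_bb_row(ct_rn), 3, ] - z_ref
  cross <- c(NT = .first_sustained_crossing(dz_nt, 5),
             CT = .first_sustained_crossing(dz_ct, 5))

  sched <- b
  events <- rbind(
    if (nrow(sched)) data.frame(kind = "formed", frame = sched$form,
                                pep_resno = sched$pep_resno,
                                skp_chain = sched$skp_chain,
                                skp_resno = sched$skp_resno,
                                stringsAsFactors = FALSE),
    if (nrow(sched) && any(!is.na(sched$brk)))
      data.frame(kind = "broken", frame = sched$brk[!is.na(sched$brk)],
                 pep_resno = sched$pep_resno[!is.na(sched$brk)],
                 skp_chain = sched$skp_chain[!is.na(sched$brk)],
                 skp_resno = sched$skp_resno[!is.na(sched$brk)],
                 stringsAsFactors = FALSE))
  if (is.null(events))
    events <- data.frame(kind = character(), frame = integer(),
                         pep_resno = integer(), skp_chain = character(),
                         skp_resno = integer(), stringsAsFactors = FALSE)
  events <- events[order(events$frame, events$pep_resno, events$skp_chain), ]
  rownames(events) <- NULL

  log <- structure(list(
    scenario = scenario$name, seed = scenario$seed,
    verdict = scenario$truth$verdict,
    terminus_first = scenario$truth$terminus_first,
    crossing_frames = cross,
    events = events, gate_open = open, n_frames = nf),
    class = "ground_truth_log")

  if (verify) {
    got <- extract_bridge_events(traj)$events
    got <- got[order(got$frame, got$pep_resno, got$skp_chain),
               c("kind", "frame", "pep_resno", "skp_chain", "skp_resno")]
    rownames(got) <- NULL
    if (!identical(got, events))
      stop("internal error: emitted bridge events do not match the schedule",
           " (scenario ", scenario$name, ", seed ", scenario$seed, ")")
  }

  list(trajectory = traj, log = log)
}

#' @export
print.ground_truth_log <- function(x, ...) {
  cat(sprintf("<ground_truth_log %s seed %d> verdict %s, terminus %s, %d events\n",
              x$scenario, x$seed, x$verdict, x$terminus_first,
              nrow(x$events)))
  invisible(x)
}
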