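# Brute-force oracles and small fixture builders shared across tests.

# quaternion (possibly unnormalized) -> rotation matrix for column vectors
quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
}

# dense-rotation-search RMSD oracle, independent of the SVD route:
# quaternion grid (Shoemake uniform construction) followed by a Nelder-Mead
# polish of the best grid point
oracle_min_rmsd <- function(mobile, reference, n_grid = 14) {
  P <- sweep(as.matrix(mobile), 2, colMeans(mobile))
  Q <- sweep(as.matrix(reference), 2, colMeans(reference))
  obj <- function(q) {
    R <- quat_to_rot(q)
    sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  }
  u <- seq(0.01, 0.99, length.out = n_grid)
  best <- list(val = Inf, q = c(1, 0, 0, 0))
  for (u1 in u) for (u2 in u) for (u3 in u) {
    q <- c(sqrt(1 - u1) * sin(2 * pi * u2),
           sqrt(1 - u1) * cos(2 * pi * u2),
           sqrt(u1) * sin(2 * pi * u3),
           sqrt(u1) * cos(2 * pi * u3))
    v <- obj(q)
    if (v < best$val) best <- list(val = v, q = q)
  }
  polish <- stats::optim(best$q, obj, method = "Nelder-Mead",
                         control = list(maxit = 5000, reltol = 1e-16))
  polish <- stats::optim(polish$par, obj, method = "Nelder-Mead",
                         control = list(maxit = 5000, reltol = 1e-16))
  min(best$val, polish$value)
}

# random proper rotation from a seeded quaternion
random_rotation <- function(seed) {
  withr::with_seed(seed, quat_to_rot(stats::rnorm(4)))
}

# apply one rigid transform (rotation + translation) to every frame
rigid_transform_traj <- function(traj, R, shift) {
  coords <- traj$coords
  for (f in seq_len(dim(coords)[3]))
    coords[, , f] <- sweep(coords[, , f] %*% t(R), 2, shift, `+`)
  trajectory(traj$roster, coords, traj$frame_time)
}

# minimal hand-built trajectory: three chaperone chains carrying Lys55 tip
# and Asp128 top backbone beads (plus optional charge sites), and an
# optional single-residue peptide; coordinates supplied per frame
make_mini_traj <- function(k55_xyz_per_frame, top_offset = c(0, 0, 60),
                           peptide_xyz_per_frame = NULL,
                           pep_sign = 0L,
                           skp_charge_sites = NULL) {
  nf <- length(k55_xyz_per_frame)
  roster <- do.call(rbind, lapply(c("A", "B", "C"), function(ch) data.frame(
    entity = "skp", chain = ch, resno = c(55L, 128L),
    resname = c("LYS", "ASP"), role = "backbone_ref", sign = 0L,
    stringsAsFactors = FALSE)))
  cs_xyz <- NULL
  if (!is.null(skp_charge_sites)) {
    cs_xyz <- skp_charge_sites$xyz
    roster <- rbind(roster,
                    skp_charge_sites[, c("entity", "chain", "resno",
                                         "resname", "role", "sign")])
  }
  has_pep <- !is.null(peptide_xyz_per_frame)
  if (has_pep) {
    roster <- rbind(roster, data.frame(
      entity = "peptide", chain = "P", resno = 1L, resname = "ALA",
      role = "backbone_ref", sign = 0L, stringsAsFactors = FALSE))
    if (pep_sign != 0L)
      roster <- rbind(roster, data.frame(
        entity = "peptide", chain = "P", resno = 1L, resname = "GLU",
        role = "charge_site", sign = as.integer(pep_sign),
        stringsAsFactors = FALSE))
  }
  coords <- array(NA_real_, c(nrow(roster), 3, nf))
  for (f in seq_len(nf)) {
    k <- k55_xyz_per_frame[[f]]  # 3 x 3 matrix: rows = chains A, B, C
    X <- matrix(NA_real_, nrow(roster), 3)
    for (i in 1:3) {
      X[(i - 1) * 2 + 1, ] <- k[i, ]
      X[(i - 1) * 2 + 2, ] <- k[i, ] + top_offset
    }
    if (!is.null(cs_xyz)) {
      cs_rows <- which(roster$entity == "skp" & roster$role == "charge_site")
      for (j in seq_along(cs_rows))
        X[cs_rows[j], ] <- cs_xyz[[j]]
    }
    if (has_pep) {
      pep_rows <- which(roster$entity == "peptide")
      for (j in pep_rows) X[j, ] <- peptide_xyz_per_frame[[f]]
    }
    coords[, , f] <- X
  }
  trajectory(roster[, c("entity", "chain", "resno", "resname", "role",
                        "sign")], coords)
}

# equilateral Lys55 triangle of side `side` in the z = 0 plane
k55_triangle <- function(side) {
  r <- side / sqrt(3)
  ang <- c(90, 210, 330) * pi / 180
  cbind(r * cos(ang), r * sin(ang), 0)
}

# sort an event table into the canonical comparison order
canon_events <- function(ev) {
  ev <- ev[order(ev$frame, ev$pep_resno, ev$skp_chain, ev$skp_resno),
           c("kind", "frame", "pep_resno", "skp_chain", "skp_resno")]
  rownames(ev) <- NULL
  ev
}
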