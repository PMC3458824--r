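# Entry analytics: cavity axis, gate distances and open/closed states,
# axial entry coordinate (delta-Z), salt-bridge detection with hysteresis,
# ordered bridge events, and the combined per-trajectory entry report.

# Cavity axis of one frame: principal axis of the chaperone backbone cloud,
# oriented so the core-domain ring (largest residue number, the Asp128
# level) projects higher than the Lys55 mouth ring. Recomputed per frame so
# all downstream quantities are invariant under global rigid transforms.
.cavity_axis <- function(X_skp, resno_skp) {
  C <- sweep(X_skp, 2, colMeans(X_skp))
  u <- svd(C, nu = 0, nv = 1)$v[, 1]
  top <- resno_skp == max(resno_skp)
  bottom <- if (any(resno_skp == 55L)) resno_skp == 55L
            else resno_skp == min(resno_skp)
  if (mean(X_skp[top, , drop = FALSE] %*% u) <
      mean(X_skp[bottom, , drop = FALSE] %*% u)) u <- -u
  u
}

.k55_idx <- function(roster) {
  idx <- which(roster$entity == "skp" & roster$role == "backbone_ref" &
                 roster$resno == 55L)
  if (length(idx) != 3)
    stop("trajectory must carry one Lys55 backbone bead per chain (found ",
         length(idx), ")")
  idx[order(roster$chain[idx])]
}

#' Inter-chain gate distances and open/closed states
#'
#' Per-frame pairwise distances between the Lys55 backbone beads of the
#' three chains, the geometric gate of the cavity mouth. The frame is
#' `closed` when at least two of the three pair distances are within
#' `d_close`, `open` otherwise (one chain swinging away from the other two
#' leaves only one short pair, hence an open mouth).
#'
#' @param traj an [trajectory()].
#' @param d_close closed-pair threshold in Angstrom (default 15).
#' @return data.frame with columns `frame`, `time`, `d_AB`, `d_AC`, `d_BC`,
#'   `state` (`"open"`/`"closed"`).
#' @export
gate_distances <- function(traj, d_close = 15) {
  stopifnot(inherits(traj, "skp_trajectory"))
  k <- .k55_idx(traj$roster)
  out <- t(vapply(seq_len(n_frames(traj)), function(f) {
    X <- frame_coords(traj, f)
    c(sqrt(sum((X[k[1], ] - X[k[2], ])^2)),
      sqrt(sum((X[k[1], ] - X[k[3], ])^2)),
      sqrt(sum((X[k[2], ] - X[k[3], ])^2)))
  }, numeric(3)))
  closed <- rowSums(out <= d_close) >= 2
  data.frame(frame = seq_len(n_frames(traj)), time = traj$frame_time,
             d_AB = out[, 1], d_AC = out[, 2], d_BC = out[, 3],
             state = ifelse(closed, "closed", "open"),
             stringsAsFactors = FALSE)
}

#' Axial entry coordinate of tracked peptide residues
#'
#' Signed distance along the cavity axis between a tracked peptide residue
#' and the mouth reference level, defined per frame as the centroid of the
#' three Lys55 backbone beads. Positive values mean the residue is above the
#' Lys55 level, i.e. inside the cavity; negative means outside. The axis is
#' the principal axis of the chaperone backbone cloud, oriented
#' mouth-to-core, recomputed each frame.
#'
#' @param traj an [trajectory()].
#' @param tracked peptide residue indices to track; defaults to the two
#'   termini (smallest and largest peptide residue number).
#' @return data.frame with columns `frame`, `time`, `residue`, `delta_z`.
#' @export
delta_z <- function(traj, tracked = NULL) {
  stopifnot(inherits(traj, "skp_trajectory"))
  r <- traj$roster
  skp_bb <- which(r$entity == "skp" & r$role == "backbone_ref")
  pep_bb <- which(r$entity == "peptide" & r$role == "backbone_ref")
  if (length(pep_bb) == 0) stop("trajectory has no peptide backbone beads")
  if (is.null(tracked))
    tracked <- c(min(r$resno[pep_bb]), max(r$resno[pep_bb]))
  tracked <- unique(as.integer(tracked))
  tr_idx <- lapply(tracked, function(rn) {
    i <- pep_bb[r$resno[pep_bb] == rn]
    if (length(i) != 1) stop("tracked peptide residue ", rn, " not found")
    i
  })
  k <- .k55_idx(r)
  rows <- lapply(seq_len(n_frames(traj)), function(f) {
    X <- frame_coords(traj, f)
    u <- .cavity_axis(X[skp_bb, , drop = FALSE], r$resno[skp_bb])
    ref <- colMeans(X[k, , drop = FALSE])
    dz <- vapply(tr_idx, function(i) sum((X[i, ] - ref) * u), numeric(1))
    data.frame(frame = f, time = traj$frame_time[f], residue = tracked,
               delta_z = dz)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# opposite-sign peptide/chaperone charge-site pair table
.charge_pairs <- function(roster) {
  pep <- which(roster$entity == "peptide" & roster$role == "charge_site" &
                 roster$sign != 0L)
  skp <- which(roster$entity == "skp" & roster$role == "charge_site" &
                 roster$sign != 0L)
  if (length(pep) == 0 || length(skp) == 0)
    return(data.frame(pep = integer(), skp = integer()))
  g <- expand.grid(pep = pep, skp = skp)
  g[roster$sign[g$pep] * roster$sign[g$skp] < 0, , drop = FALSE]
}

#' Salt bridges present in one frame
#'
#' A peptide charge site and a chaperone charge site of opposite sign are
#' bridged when their distance is at most `r_on` (default 4.5 Angstrom).
#' Only peptide-chaperone pairs are considered.
#'
#' @param traj an [trajectory()].
#' @param frame frame index.
#' @param r_on bridge distance cutoff, Angstrom.
#' @return data.frame with columns `pep_resno`, `pep_resname`, `skp_chain`,
#'   `skp_resno`, `skp_resname`, `distance`.
#' @export
detect_salt_bridges <- function(traj, frame = 1, r_on = 4.5) {
  stopifnot(inherits(traj, "skp_trajectory"))
  r <- traj$roster
  pairs <- .charge_pairs(r)
  X <- frame_coords(traj, frame)
  d <- sqrt(rowSums((X[pairs$pep, , drop = FALSE] -
                       X[pairs$skp, , drop = FALSE])^2))
  hit <- which(d <= r_on)
  data.frame(pep_resno = r$resno[pairs$pep[hit]],
             pep_resname = r$resname[pairs$pep[hit]],
             skp_chain = r$chain[pairs$skp[hit]],
             skp_resno = r$resno[pairs$skp[hit]],
             skp_resname = r$resname[pairs$skp[hit]],
             distance = d[hit], stringsAsFactors = FALSE)
}

#' Ordered salt-bridge formation/breaking events
#'
#' Tracks every opposite-sign peptide-chaperone charge pair through the
#' trajectory with a hysteresis rule: a pair forms when its distance drops
#' to `r_on` or below and breaks only when it exceeds `r_off`, so
#' oscillation inside the band emits no chatter. Events for a given pair
#' therefore alternate formed/broken in time.
#'
#' @param traj an [trajectory()].
#' @param r_on formation cutoff, Angstrom (default 4.5).
#' @param r_off breaking cutoff, Angstrom (default 6.0, must exceed `r_on`).
#' @return list with `events` (data.frame `kind`, `frame`, `time`,
#'   `pep_resno`, `pep_resname`, `skp_chain`, `skp_resno`, `skp_resname`,
#'   ordered by frame) and `counts` (data.frame `frame`, `time`, `n_bridges`
#'   of simultaneously formed pairs).
#' @export
extract_bridge_events <- function(traj, r_on = 4.5, r_off = 6.0) {
  stopifnot(inherits(traj, "skp_trajectory"), r_off > r_on)
  r <- traj$roster
  pairs <- .charge_pairs(r)
  nf <- n_frames(traj)
  counts <- integer(nf)
  ev <- list()
  if (nrow(pairs) > 0) {
    # distance series per pair, frames x pairs
    D <- vapply(seq_len(nf), function(f) {
      X <- frame_coords(traj, f)
      sqrt(rowSums((X[pairs$pep, , drop = FALSE] -
                      X[pairs$skp, , drop = FALSE])^2))
    }, numeric(nrow(pairs)))
    D <- matrix(D, nrow = nrow(pairs))
    active <- rep(FALSE, nrow(pairs))
    for (f in seq_len(nf)) {
      form <- !active & D[, f] <= r_on
      brk <- active & D[, f] > r_off
      for (p in which(form | brk)) {
        ev[[length(ev) + 1L]] <- data.frame(
          kind = if (form[p]) "formed" else "broken",
          frame = f, time = traj$frame_time[f],
          pep_resno = r$resno[pairs$pep[p]],
          pep_resname = r$resname[pairs$pep[p]],
          skp_chain = r$chain[pairs$skp[p]],
          skp_resno = r$resno[pairs$skp[p]],
          skp_resname = r$resname[pairs$skp[p]],
          stringsAsFactors = FALSE)
      }
      active[form] <- TRUE
      active[brk] <- FALSE
      counts[f] <- sum(active)
    }
  }
  events <- if (length(ev)) do.call(rbind, ev)
            else data.frame(kind = character(), frame = integer(),
                            time = numeric(), pep_resno = integer(),
                            pep_resname = character(),
                            skp_chain = character(), skp_resno = integer(),
                            skp_resname = character(),
                            stringsAsFactors = FALSE)
  rownames(events) <- NULL
  list(events = events,
       counts = data.frame(frame = seq_len(nf), time = traj$frame_time,
                           n_bridges = counts))
}

# "GLU" -> "Glu"
.title_aa <- function(x) paste0(substr(x, 1, 1), tolower(substr(x, 2, 3)))

#' Render a salt-bridge formation chain in residue-pair notation
#'
#' Formats the ordered formation events as
#' `"Glu2–Arg71 (chain B) → Glu2–Arg71 (chain C) → ..."`.
#'
#' @param events the `events` data.frame from [extract_bridge_events()].
#' @param kinds which event kinds to render (default `"formed"`).
#' @return single string.
#' @export
format_bridge_chain <- function(events, kinds = "formed") {
  e <- events[events$kind %in% kinds, , drop = FALSE]
  if (nrow(e) == 0) return("")
  paste(sprintf("%s%d–%s%d (chain %s)",
                .title_aa(e$pep_resname), e$pep_resno,
                .title_aa(e$skp_resname), e$skp_resno, e$skp_chain),
        collapse = " → ")
}

# first frame where the series stays > 0 for `sustain` consecutive frames
.first_sustained_crossing <- function(dz, sustain) {
  pos <- dz > 0
  if (sustain <= 1) return(if (any(pos)) which(pos)[1] else NA_integer_)
  run <- stats::filter(as.numeric(pos), rep(1, sustain), sides = 1)
  hit <- which(run == sustain)
  if (length(hit) == 0) NA_integer_ else hit[1] - sustain + 1L
}

#' Combined entry report for one trajectory
#'
#' Runs the full analytics chain (axial entry coordinate of the two
#' termini, gate states, salt-bridge events) and issues the verdict:
#' `entered` when both termini sit above the Lys55 level throughout the
#' final window (default last 10% of frames); otherwise `adhered_outside`
#' when at least one salt bridge is formed in every frame of that window;
#' `escaped` otherwise. The terminus-first call is the terminus whose entry
#' coordinate first crosses zero sustainedly (`sustain` consecutive
#' positive frames).
#'
#' @param traj an [trajectory()].
#' @param final_window fraction of trailing frames used for the verdict
#'   (default 0.1).
#' @param sustain frames a crossing must persist to count (default 5).
#' @param d_close gate threshold, Angstrom (see [gate_distances()]).
#' @param r_on,r_off salt-bridge hysteresis cutoffs, Angstrom.
#' @return object of class `entry_report`: `verdict`, `terminus_first`
#'   (`"N_first"`, `"C_first"` or `"none"`), `crossing_frames` (named
#'   NT/CT), `max_delta_z` (named NT/CT), `gate_open_fraction`, `gate`
#'   (series), `delta_z` (series), `events`, `bridge_counts`,
#'   `bridge_chain` (formatted string), and the parameters used.
#' @export
entry_report <- function(traj, final_window = 0.1, sustain = 5,
                         d_close = 15, r_on = 4.5, r_off = 6.0) {
  stopifnot(inherits(traj, "skp_trajectory"))
  r <- traj$roster
  pep_bb <- which(r$entity == "peptide" & r$role == "backbone_ref")
  if (length(pep_bb) == 0) stop("entry_report needs a peptide entity")
  nt_res <- min(r$resno[pep_bb]); ct_res <- max(r$resno[pep_bb])
  dz <- delta_z(traj, tracked = c(nt_res, ct_res))
  gate <- gate_distances(traj, d_close = d_close)
  bridges <- extract_bridge_events(traj, r_on = r_on, r_off = r_off)

  nf <- n_frames(traj)
  win <- seq.int(max(1L, nf - ceiling(final_window * nf) + 1L), nf)
  dz_nt <- dz$delta_z[dz$residue == nt_res]
  dz_ct <- dz$delta_z[dz$residue == ct_res]

  entered <- all(dz_nt[win] > 0) && all(dz_ct[win] > 0)
  adhered <- !entered && all(bridges$counts$n_bridges[win] >= 1)
  verdict <- if (entered) "entered" else if (adhered) "adhered_outside"
             else "escaped"

  cross <- c(NT = .first_sustained_crossing(dz_nt, sustain),
             CT = .first_sustained_crossing(dz_ct, sustain))
  terminus_first <- if (all(is.na(cross))) "none"
    else if (is.na(cross["CT"]) ||
             (!is.na(cross["NT"]) && cross["NT"] < cross["CT"])) "N_first"
    else if (is.na(cross["NT"]) || cross["CT"] < cross["NT"]) "C_first"
    else "none"

  structure(list(
    verdict = verdict,
    terminus_first = terminus_first,
    crossing_frames = cross,
    max_delta_z = c(NT = max(dz_nt), CT = max(dz_ct)),
    gate_open_fraction = mean(gate$state == "open"),
    gate = gate, delta_z = dz,
    events = bridges$events, bridge_counts = bridges$counts,
    bridge_chain = format_bridge_chain(bridges$events),
    params = list(final_window = final_window, sustain = sustain,
                  d_close = d_close, r_on = r_on, r_off = r_off)),
    class = "entry_report")
}

#' @export
print.entry_report <- function(x, ...) {
  cat(sprintf("<entry_report> verdict: %s (terminus first: %s)\n",
              x$verdict, x$terminus_first))
  cat(sprintf("  max dZ  NT %+.1f A, CT %+.1f A; gate open %.0f%% of frames\n",
              x$max_delta_z["NT"], x$max_delta_z["CT"],
              100 * x$gate_open_fraction))
  cat(sprintf("  %d bridge events", nrow(x$events)))
  if (nzchar(x$bridge_chain)) cat(":\n  ", x$bridge_chain, "\n")
  else cat("\n")
  invisible(x)
}
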