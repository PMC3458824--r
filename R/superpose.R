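# Optimal rigid-body superposition (Kabsch algorithm) and RMSD series.

#' Optimal rigid superposition of two point sets (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' `mobile` and `reference` (matched rows), via SVD of the cross-covariance
#' with the determinant sign corrected so only proper rotations are
#' returned.
#'
#' @param mobile,reference `n x 3` matrices with matched rows, `n >= 3`,
#'   neither set collinear.
#' @return list with `rotation` (3x3, applied to row vectors as
#'   `x %*% rotation`), `translation` (length 3), `rmsd` (Angstrom) and
#'   `transform(X)`, a function applying the fitted map to any `m x 3` set.
#' @examples
#' P <- matrix(rnorm(12), 4, 3)
#' kabsch_superpose(P, P)$rmsd # 0
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (ncol(mobile) != 3 || ncol(reference) != 3)
    stop("point sets must be n x 3 matrices")
  if (nrow(mobile) != nrow(reference))
    stop("point sets must have the same number of points")
  if (nrow(mobile) < 3)
    stop("superposition needs at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  # degenerate (collinear or coincident) sets have rank < 2
  if (sum(svd(Q)$d > 1e-9 * max(1, max(abs(Q)))) < 2 ||
      sum(svd(P)$d > 1e-9 * max(1, max(abs(P)))) < 2)
    stop("degenerate (collinear) point set: superposition is not unique")
  H <- crossprod(P, Q)            # 3x3 cross-covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)   # row-vector convention
  moved <- P %*% R
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  translation <- cr - cm %*% R
  list(rotation = R, translation = as.numeric(translation), rmsd = rmsd,
       transform = function(X) sweep(as.matrix(X) %*% R, 2,
                                     as.numeric(translation), `+`))
}

#' Root-mean-square deviation between matched point sets
#' @param a,b `n x 3` matrices with matched rows.
#' @return Angstrom.
#' @export
rmsd <- function(a, b) sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))

#' Per-frame RMSD of the chaperone relative to a reference frame
#'
#' Each frame is superposed onto the reference frame over the full set of
#' chaperone backbone beads and the RMSD is then reported over the selected
#' beads without re-superposition, so per-chain values decompose the global
#' deviation (e.g. a mobile chain B against quiet chains A and C). With
#' `per_chain_superpose = TRUE` the selection itself is superposed, giving
#' internal per-chain deviation instead.
#'
#' @param traj an [trajectory()].
#' @param reference_frame frame index used as reference (default 1).
#' @param selection `"all"` or a chain id (`"A"`, `"B"`, `"C"`).
#' @param per_chain_superpose superpose on the selection instead of the
#'   whole chaperone backbone.
#' @return data.frame with columns `frame`, `time`, `rmsd`.
#' @export
rmsd_series <- function(traj, reference_frame = 1,
                        selection = c("all", "A", "B", "C"),
                        per_chain_superpose = FALSE) {
  stopifnot(inherits(traj, "skp_trajectory"))
  selection <- match.arg(selection)
  r <- traj$roster
  fit_idx <- which(r$entity == "skp" & r$role == "backbone_ref")
  if (length(fit_idx) == 0) stop("no chaperone backbone beads in trajectory")
  sel_idx <- if (selection == "all") fit_idx
             else fit_idx[r$chain[fit_idx] == selection]
  if (length(sel_idx) == 0) stop("empty selection: chain ", selection)
  if (per_chain_superpose) fit_idx <- sel_idx
  ref <- frame_coords(traj, reference_frame)
  out <- vapply(seq_len(n_frames(traj)), function(f) {
    X <- frame_coords(traj, f)
    sup <- kabsch_superpose(X[fit_idx, , drop = FALSE],
                            ref[fit_idx, , drop = FALSE])
    rmsd(sup$transform(X[sel_idx, , drop = FALSE]),
         ref[sel_idx, , drop = FALSE])
  }, numeric(1))
  data.frame(frame = seq_len(n_frames(traj)), time = traj$frame_time,
             rmsd = out)
}
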