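# Rigid-body superposition, RMSD traces, dihedrals, minimum distances.
# All coordinates in Angstrom, all angles in degrees on [0, 360).

#' Kabsch superposition of two point sets
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' `mobile` and `reference` (SVD solution with determinant correction).
#'
#' @param mobile,reference `M x 3` matrices of paired points, M >= 3 and
#'   not collinear.
#' @return list with `rotation` (3x3, det = +1), `translation`
#'   (length 3) and `rmsd` after superposition; the aligned mobile set is
#'   `sweep(mobile, 2, cm) %*% rotation + rep(cr, each = M)` with `cm`,
#'   `cr` the centroids (see `apply_superposition()`).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3) {
    abort("mobile and reference must be matching M x 3 matrices")
  }
  m <- nrow(mobile)
  if (m < 3) abort("superposition needs at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  a <- sweep(mobile, 2, cm); b <- sweep(reference, 2, cr)
  sv_b <- svd(b)
  if (sv_b$d[2] < 1e-8 * max(sv_b$d[1], 1)) {
    abort("degenerate (collinear) reference point set")
  }
  h <- crossprod(a, b)               # 3x3 covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  aligned <- a %*% rot
  rmsd <- sqrt(mean(rowSums((aligned - b)^2)))
  list(rotation = rot, translation = cr - cm %*% rot, rmsd = rmsd)
}

#' @rdname kabsch_superpose
#' @param coords `N x 3` matrix to transform with a fit result.
#' @param fit result of `kabsch_superpose()`.
#' @export
apply_superposition <- function(coords, fit) {
  sweep(as.matrix(coords) %*% fit$rotation, 2, as.numeric(fit$translation), `+`)
}

rmsd_between <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Per-frame RMSD trace of a trajectory
#'
#' RMSD of a selection against a reference frame, optionally after
#' least-squares superposition. When `fit_sel` is given the frame is
#' superposed on that selection and the RMSD of `sel` is then measured
#' without re-fitting -- the mode used for ligand pose drift in the
#' receptor frame.
#'
#' @param traj a `md_trajectory`.
#' @param sel selection (string or indices) whose RMSD is reported.
#' @param reference frame index, `"first"`, `"final"`, or a
#'   `md_structure` with identical topology (e.g. a crystal structure).
#' @param superpose superpose before measuring (default TRUE).
#' @param fit_sel optional separate selection used for the superposition.
#' @param bw optional [bw_map()] for BW-aware selections.
#' @return tibble of class `rmsd_trace`: `frame`, `time` (ns),
#'   `rmsd` (Angstrom); reference and selection descriptors as attributes.
#' @export
rmsd_trace <- function(traj, sel, reference = "first", superpose = TRUE,
                       fit_sel = NULL, bw = NULL) {
  stopifnot(inherits(traj, "md_trajectory"))
  idx <- select_atoms(traj, sel, bw)
  if (length(idx) < 3) abort("selection must resolve to at least 3 atoms")
  fit_idx <- if (is.null(fit_sel)) idx else select_atoms(traj, fit_sel, bw)
  tt <- n_frames(traj)
  ref_desc <- reference
  if (inherits(reference, "md_structure")) {
    if (n_atoms(reference) != n_atoms(traj)) {
      abort("reference structure must share the trajectory topology")
    }
    ref_all <- coords_matrix(reference)
    ref_desc <- "structure"
  } else {
    if (identical(reference, "first")) reference <- 1L
    if (identical(reference, "final")) reference <- tt
    reference <- as.integer(reference)
    if (reference < 1 || reference > tt) abort("reference frame out of range")
    ref_all <- coords_matrix(traj, reference)
    ref_desc <- paste0("frame ", reference)
  }
  ref_fit <- ref_all[fit_idx, , drop = FALSE]
  ref_sel <- ref_all[idx, , drop = FALSE]
  vals <- vapply(seq_len(tt), function(i) {
    m <- coords_matrix(traj, i)
    if (superpose) {
      fit <- kabsch_superpose(m[fit_idx, , drop = FALSE], ref_fit)
      rmsd_between(apply_superposition(m[idx, , drop = FALSE], fit), ref_sel)
    } else {
      rmsd_between(m[idx, , drop = FALSE], ref_sel)
    }
  }, numeric(1))
  out <- tibble::tibble(frame = seq_len(tt), time = traj$times, rmsd = vals)
  attr(out, "selection") <- if (is.character(sel)) sel else "indices"
  attr(out, "reference") <- ref_desc
  attr(out, "superposed") <- superpose
  class(out) <- c("rmsd_trace", class(out))
  out
}

#' Dihedral angle of four points
#'
#' IUPAC sign convention computed from the two plane normals, then mapped
#' from (-180, 180] onto [0, 360) by adding 360 to negative values:
#' an eclipsed (cis) arrangement gives 0, anti-periplanar gives 180.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors, Angstrom.
#' @return angle in degrees on [0, 360).
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10) {
    abort("collinear point triple: dihedral undefined")
  }
  ang <- atan2(sum(cross3(n1, n2) * b2) / sqrt(sum(b2^2)), sum(n1 * n2)) * 180 / pi
  if (ang < 0) ang <- ang + 360
  ang %% 360
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Minimum cross-pair distance between two atom groups
#'
#' @param x a `md_structure`, or a trajectory together with `frame`.
#' @param sel_a,sel_b selections for the two groups (must be non-empty;
#'   hydrogens are excluded by default).
#' @param frame frame index for trajectories.
#' @param heavy_only drop hydrogens before measuring (default TRUE).
#' @param bw optional [bw_map()].
#' @return minimum distance in Angstrom.
#' @export
min_pair_distance <- function(x, sel_a, sel_b, frame = 1L, heavy_only = TRUE,
                              bw = NULL) {
  ia <- select_atoms(x, sel_a, bw); ib <- select_atoms(x, sel_b, bw)
  if (heavy_only) {
    el <- toupper(atoms(x)$element)
    ia <- ia[el[ia] != "H"]; ib <- ib[el[ib] != "H"]
  }
  if (length(ia) == 0 || length(ib) == 0) abort("empty atom group")
  m <- coords_matrix(x, frame)
  min_dist_mat(m[ia, , drop = FALSE], m[ib, , drop = FALSE])
}

# vectorized min over all cross pairs
min_dist_mat <- function(a, b) sqrt(min(cross_dist2(a, b)))

# squared cross-distance matrix, |A| x |B|
cross_dist2 <- function(a, b) {
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, `+`) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}
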