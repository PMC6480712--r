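# Independent oracles used to cross-check the package's geometric and
# energetic kernels. These deliberately use different algorithms from
# the implementation (quaternion eigenproblem vs SVD, axis-projection vs
# plane normals, explicit double loops vs vectorized forms).

# --- quaternion (Horn) RMSD oracle ----------------------------------------
# Minimal RMSD between paired point sets from the largest eigenvalue of
# the 4x4 quaternion key matrix.
oracle_rmsd_quaternion <- function(mobile, reference) {
  a <- sweep(mobile, 2, colMeans(mobile))
  b <- sweep(reference, 2, colMeans(reference))
  m <- nrow(a)
  s <- crossprod(a, b)   # Sxy = sum a_x b_y
  sxx <- s[1, 1]; sxy <- s[1, 2]; sxz <- s[1, 3]
  syx <- s[2, 1]; syy <- s[2, 2]; syz <- s[2, 3]
  szx <- s[3, 1]; szy <- s[3, 2]; szz <- s[3, 3]
  k <- matrix(c(
    sxx + syy + szz, syz - szy,        szx - sxz,        sxy - syx,
    syz - szy,       sxx - syy - szz,  sxy + syx,        szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz,  syz + szy,
    sxy - syx,       szx + sxz,        syz + szy,       -sxx - syy + szz),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(k, symmetric = TRUE, only.values = TRUE)$values)
  val <- (sum(a^2) + sum(b^2) - 2 * lambda) / m
  sqrt(max(val, 0))
}

# --- axis-projection dihedral oracle --------------------------------------
oracle_dihedral <- function(p1, p2, p3, p4) {
  t <- p3 - p2; t <- t / sqrt(sum(t^2))
  v1 <- (p1 - p2) - sum((p1 - p2) * t) * t
  v2 <- (p4 - p3) - sum((p4 - p3) * t) * t
  cs <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
  cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  ang <- acos(pmin(1, pmax(-1, cs))) * 180 / pi
  # oriented sign; note v1 points from axis toward p1 (cis at 0)
  if (sum(cr * t) < 0) ang <- 360 - ang
  ang %% 360
}

# --- brute-force double loops ---------------------------------------------
oracle_min_distance <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt(sum((a[i, ] - b[j, ])^2))
      if (d < best) best <- d
    }
  }
  best
}

oracle_interface_energy <- function(ma, mb, pa, pb, cutoff) {
  e <- 0
  for (i in seq_len(nrow(ma))) {
    for (j in seq_len(nrow(mb))) {
      r <- sqrt(sum((ma[i, ] - mb[j, ])^2))
      if (r < cutoff && r > 0) {
        sig <- (pa$sigma[i] + pb$sigma[j]) / 2
        eps <- sqrt(pa$epsilon[i] * pb$epsilon[j])
        e <- e + pa$q[i] * pb$q[j] * 332.0636 / (4 * r^2) +
          4 * eps * ((sig / r)^12 - (sig / r)^6)
      }
    }
  }
  e
}

# --- small builders --------------------------------------------------------
# a structure from a bare coordinate matrix: one carbon per atom, each
# its own residue so contact bookkeeping is per-atom
atoms_from_coords <- function(m, chain = "A", het = FALSE, resSeq = NULL,
                              element = "C") {
  n <- nrow(m)
  rotadimer::md_structure(tibble::tibble(
    serial = seq_len(n), name = paste0("C", seq_len(n)),
    element = element, resName = "UNK",
    resSeq = resSeq %||% seq_len(n), chainId = chain, het = het,
    x = m[, 1], y = m[, 2], z = m[, 3]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# single- or multi-frame trajectory from a list of coordinate matrices
traj_from_frames <- function(topo, frames, dt = 1) {
  arr <- array(NA_real_, c(length(frames), rotadimer::n_atoms(topo), 3))
  for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]
  rotadimer::md_trajectory(topo, arr, times = (seq_along(frames) - 1) * dt)
}

random_rotation <- function() {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, 2 * pi)
  ct <- cos(th); st <- sin(th)
  kx <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
               3, 3, byrow = TRUE)
  diag(3) * ct + st * kx + (1 - ct) * (ax %o% ax)
}
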