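# Synthetic toy structures and trajectories with exact ground truth.
#
# The generator emulates the statistical structure of receptor MD
# output without any physics: ideal alpha-helices carry one full-atom
# Tyr and Phe sidechain whose chi1 follows a two-state Markov chain
# (pseudo-stable centers 300 deg "cis" and 180 deg "trans" plus wrapped
# Gaussian noise), a rigid 5-atom pseudo-ligand is scripted into and out
# of contact, and a second protomer is placed at scripted separations
# with Tyr-OH pairs posed to satisfy the H-bond criterion in a requested
# fraction of frames. Every scripted quantity is recorded so the
# corresponding analysis operation can be checked against ground truth.

# --- internal-coordinate building -----------------------------------------

# NeRF atom placement: d such that |d-c| = bond, angle(b,c,d) = ang and
# dihedral_angle(a,b,c,d) = tor (degrees).
place_atom <- function(a, b, c, bond, ang, tor) {
  ang <- ang * pi / 180; tor <- tor * pi / 180
  bc <- (c - b); bc <- bc / sqrt(sum(bc^2))
  ab <- (b - a); ab <- ab / sqrt(sum(ab^2))
  n <- cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  as.numeric(c + cbind(bc, m, n) %*% d2)
}

# ideal helix backbone (phi -57, psi -47, omega 180) with optional
# aromatic sidechains; returns a plain atom table in the build frame
build_helix_atoms <- function(resSeqs, resnames, chain, chi1 = c(), chi2 = 90) {
  stopifnot(length(resSeqs) == length(resnames))
  rows <- list()
  # seed triad
  n1 <- c(0, 0, 0); ca1 <- c(1.458, 0, 0)
  c1 <- ca1 + 1.525 * c(cos(111 * pi / 180), sin(111 * pi / 180), 0) *
    c(-1, 1, 1)  # angle N-CA-C = 111 deg
  prev <- list(N = n1, CA = ca1, C = c1)
  for (i in seq_along(resSeqs)) {
    res <- list(N = prev$N, CA = prev$CA, C = prev$C)
    nm <- resnames[i]
    # next backbone nitrogen defines psi; O is anti to it
    n_next <- place_atom(res$N, res$CA, res$C, 1.329, 117, -47)
    res$O <- place_atom(res$N, res$CA, res$C, 1.231, 121, -47 + 180)
    add <- function(name, xyz, element = substr(name, 1, 1)) {
      rows[[length(rows) + 1]] <<- tibble::tibble(
        name = name, element = element, resName = nm,
        resSeq = resSeqs[i], chainId = chain, het = FALSE,
        x = xyz[1], y = xyz[2], z = xyz[3])
    }
    add("N", res$N, "N"); add("CA", res$CA)
    if (nm %in% c("TYR", "PHE", "ALA")) {
      cb <- place_atom(res$N, res$C, res$CA, 1.53, 110.1, 122.6)
      add("CB", cb)
      if (nm %in% c("TYR", "PHE")) {
        x1 <- if (as.character(resSeqs[i]) %in% names(chi1)) {
          chi1[[as.character(resSeqs[i])]]
        } else 180
        cg <- place_atom(res$N, res$CA, cb, 1.52, 113.8, x1)
        cd1 <- place_atom(res$CA, cb, cg, 1.40, 120.8, chi2)
        cd2 <- place_atom(res$CA, cb, cg, 1.40, 120.8, chi2 - 180)
        ce1 <- place_atom(cb, cg, cd1, 1.40, 120, 180)
        ce2 <- place_atom(cb, cg, cd2, 1.40, 120, 180)
        cz <- place_atom(cg, cd1, ce1, 1.40, 120, 0)
        add("CG", cg); add("CD1", cd1); add("CD2", cd2)
        add("CE1", ce1); add("CE2", ce2); add("CZ", cz)
        if (nm == "TYR") add("OH", place_atom(cd1, ce1, cz, 1.38, 120, 180), "O")
      }
    }
    add("C", res$C, "C"); add("O", res$O, "O")
    ca_next <- place_atom(res$CA, res$C, n_next, 1.458, 121, 180)
    c_next <- place_atom(res$C, n_next, ca_next, 1.525, 111, -57)
    prev <- list(N = n_next, CA = ca_next, C = c_next)
  }
  dplyr::bind_rows(rows)
}

rot_axis <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  ct <- cos(theta); st <- sin(theta)
  k <- axis
  kx <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * kx + (1 - ct) * (k %o% k)
}

# rigid-place a helix: axis onto +/- z, centroid to `at`, and the target
# residue's CB azimuth rotated onto +x
orient_helix <- function(tab, target_res, at = c(0, 0, 0), flip = FALSE) {
  m <- as.matrix(tab[, c("x", "y", "z")])
  ca <- m[tab$name == "CA", , drop = FALSE]
  axis <- ca[nrow(ca), ] - ca[1, ]; axis <- axis / sqrt(sum(axis^2))
  target_z <- if (flip) c(0, 0, -1) else c(0, 0, 1)
  v <- cross3(axis, target_z); s <- sqrt(sum(v^2)); cth <- sum(axis * target_z)
  r1 <- if (s < 1e-12) diag(3) * sign(cth) else rot_axis(v, atan2(s, cth))
  ctr <- colMeans(ca)
  m2 <- sweep(m, 2, ctr) %*% t(r1)
  cb <- m2[tab$name == "CB" & tab$resSeq == target_res, ]
  theta <- atan2(cb[2], cb[1])
  m3 <- m2 %*% t(rot_axis(c(0, 0, 1), -theta))
  m3 <- sweep(m3, 2, at, `+`)
  tab$x <- m3[, 1]; tab$y <- m3[, 2]; tab$z <- m3[, 3]
  tab
}

#' Build a toy two-helix protomer
#'
#' Two ideal alpha-helices labeled TM5 and TM6 (antiparallel, axes 10 A
#' apart along y), glycine backbones except a full-atom Tyr199 on TM5
#' and Phe390 on TM6 whose chi1 torsions are settable; a matching
#' Ballesteros-Weinstein map (Tyr199 = 5.48, Phe390 = 6.52) is emitted
#' alongside.
#'
#' @param chain chain identifier (default "A").
#' @param chi1 named vector of chi1 values in degrees for residues 199
#'   and 390 (default both 300).
#' @return list with `structure` (a [md_structure()]) and `bw` (a
#'   [bw_map()]).
#' @export
build_toy_protomer <- function(chain = "A", chi1 = c("199" = 300, "390" = 300)) {
  tm5_res <- 192:201
  tm6_res <- 383:392
  tm5 <- build_helix_atoms(tm5_res, ifelse(tm5_res == 199, "TYR", "GLY"),
                           chain, chi1 = chi1)
  tm6 <- build_helix_atoms(tm6_res, ifelse(tm6_res == 390, "PHE", "GLY"),
                           chain, chi1 = chi1)
  tm5 <- orient_helix(tm5, 199, at = c(0, -5, 0), flip = FALSE)
  tm6 <- orient_helix(tm6, 390, at = c(0, 5, 0), flip = TRUE)
  at <- dplyr::bind_rows(tm5, tm6)
  at$serial <- seq_len(nrow(at))
  bw <- bw_map(tibble::tibble(
    chainId = chain,
    resSeq = c(tm5_res, tm6_res),
    bw = c(sprintf("5.%d", 41:50), sprintf("6.%d", 45:54)),
    segment = rep(c("TM5", "TM6"), each = 10)))
  list(structure = md_structure(at), bw = bw)
}

# --- specification ---------------------------------------------------------

default_p_stay <- function(p_trans) {
  if (p_trans <= 0 || p_trans >= 1) return(1)
  max(0.9, 1 - (1 - p_trans) / (2 * p_trans))
}

#' Tracked-residue rotamer plan
#'
#' @param chain,resSeq residue identity.
#' @param p_trans stationary probability of the trans state.
#' @param p_stay persistence P(trans stays trans) per frame; default
#'   picks a feasible value (>= 0.9 where reachable).
#' @param sigma angular noise SD, degrees (default 15; 3 sigma stays
#'   inside each side of the 240-degree boundary).
#' @param centers state centers, degrees.
#' @return list describing the plan.
#' @export
rotamer_plan <- function(chain, resSeq, p_trans, p_stay = NULL, sigma = 15,
                         centers = c(trans = 180, cis = 300)) {
  stopifnot(p_trans >= 0, p_trans <= 1, sigma > 0)
  p_stay <- p_stay %||% default_p_stay(p_trans)
  list(chain = chain, resSeq = resSeq, p_trans = p_trans, p_stay = p_stay,
       sigma = sigma, centers = centers)
}

#' Synthetic trajectory specification
#'
#' Parameters of the toy generator. Defaults reproduce the study
#' conditions emulated throughout the package tests: a 3 us-equivalent
#' run (1000 frames x 3 ns), clozapine-like monomer occupancies
#' (P(trans) = 0.99 for both tracked residues), a ligand in contact 30%
#' of frames at the 3.5 A threshold, a dimer at 15 A center separation
#' (TM5/TM6 faces in van-der-Waals contact)
#' with protomer-specific occupancies (0.94/0.90 on protomer 1,
#' 0.04/0.93 on protomer 2) and 4% scripted H-bond frames.
#'
#' @param n_frames number of frames (>= 1).
#' @param dt frame spacing, ns.
#' @param seed integer seed; the generator is a deterministic function
#'   of the spec.
#' @param rotamers list of [rotamer_plan()]s for chain-A residues
#'   199/390 (monomer) -- the dimer generator applies `rotamers` to
#'   protomer A and `rotamers_b` to protomer B.
#' @param rotamers_b plans for protomer B (dimer only).
#' @param ligand list: `resSeq` (planted residue; default 196, a
#'   backbone-only glycine site so the ligand anchor is decoupled from
#'   sidechain flips), `target` distance (A), `contact_fraction`,
#'   optional `switch_frame` (1-based; frames before it are displaced
#'   by 6 A so the pose stabilizes exactly there).
#' @param dimer list: `separation` (scalar or per-frame vector, A,
#'   center-of-geometry protomer offset), `hbond_fraction`.
#' @param jitter apply a global rigid-body rotation/translation per
#'   frame (exercises superposition; default TRUE for the monomer).
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_frames = 1000, dt = 3, seed = 1,
                           rotamers = list(rotamer_plan("A", 199, 0.99),
                                           rotamer_plan("A", 390, 0.99)),
                           rotamers_b = list(rotamer_plan("B", 199, 0.04),
                                             rotamer_plan("B", 390, 0.93)),
                           ligand = list(resSeq = 196, target = 3.5,
                                         contact_fraction = 0.30,
                                         switch_frame = NULL),
                           dimer = list(separation = 15, hbond_fraction = 0.04),
                           jitter = TRUE) {
  stopifnot(n_frames >= 1, dt > 0)
  spec <- list(n_frames = as.integer(n_frames), dt = dt, seed = as.integer(seed),
               rotamers = rotamers, rotamers_b = rotamers_b,
               ligand = ligand, dimer = dimer, jitter = jitter)
  class(spec) <- "synthetic_spec"
  spec
}

# dimer protomer-1 defaults mirror 0.94/0.90
dimer_default_rotamers <- function() {
  list(rotamer_plan("A", 199, 0.94), rotamer_plan("A", 390, 0.90))
}

# --- Markov rotamer sequences ----------------------------------------------

markov_rates <- function(plan) {
  p <- plan$p_trans
  q_tc <- 1 - plan$p_stay
  if (p >= 1) return(list(q_tc = 0, q_ct = 1))
  if (p <= 0) return(list(q_tc = 1, q_ct = 0))
  q_ct <- q_tc * p / (1 - p)
  if (q_ct > 1) {
    abort(sprintf("unreachable stationary/persistence combination: P(trans)=%g with p_stay=%g needs P(cis->trans)=%g > 1",
                  p, plan$p_stay, q_ct))
  }
  list(q_tc = q_tc, q_ct = q_ct)
}

#' Standard error of an occupancy estimate from a Markov rotamer chain
#'
#' Accounts for chain autocorrelation: the effective sample size is
#' `n / tau` with `tau = (1 + lambda) / (1 - lambda)` and `lambda` the
#' chain's second eigenvalue.
#'
#' @param p_trans,p_stay chain parameters as in [rotamer_plan()].
#' @param n number of frames.
#' @return standard error of the trans-fraction estimator.
#' @export
rotamer_recovery_se <- function(p_trans, p_stay, n) {
  r <- markov_rates(rotamer_plan("A", 1, p_trans, p_stay))
  lambda <- 1 - r$q_tc - r$q_ct
  tau <- (1 + lambda) / (1 - lambda)
  sqrt(p_trans * (1 - p_trans) / (n / tau))
}

seq_seed <- function(spec, idx) (spec$seed + 7919L * idx) %% .Machine$integer.max

#' Generate a two-state chi1 rotamer sequence
#'
#' Simulates the spec's Markov chain for one tracked residue and decorates
#' states with wrapped-Gaussian angular noise around the state centers.
#' Deterministic in (spec$seed, residue position): standalone calls
#' reproduce the sequences embedded in generated trajectories.
#'
#' @param spec a [synthetic_spec()].
#' @param which_residue index into `spec$rotamers`, or a plan list.
#' @param protomer "A" or "B" (selects `rotamers` vs `rotamers_b`).
#' @return list: `states` (character), `angles` (degrees in [0, 360)),
#'   `plan`.
#' @export
generate_rotamer_sequence <- function(spec, which_residue = 1, protomer = "A") {
  plans <- if (protomer == "A") spec$rotamers else spec$rotamers_b
  offset <- if (protomer == "A") 0L else 100L
  if (is.list(which_residue) && !is.null(which_residue$p_trans)) {
    plan <- which_residue
    idx <- offset + 50L
  } else {
    plan <- plans[[which_residue]]
    idx <- offset + as.integer(which_residue)
  }
  r <- markov_rates(plan)
  n <- spec$n_frames
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seq_seed(spec, idx))
  states <- character(n)
  u <- stats::runif(n)
  states[1] <- if (u[1] < plan$p_trans) "trans" else "cis"
  if (n > 1) {
    for (i in 2:n) {
      go <- if (states[i - 1] == "trans") r$q_tc else r$q_ct
      states[i] <- if (u[i] < go) {
        if (states[i - 1] == "trans") "cis" else "trans"
      } else states[i - 1]
    }
  }
  centers <- plan$centers[ifelse(states == "trans", "trans", "cis")]
  angles <- wrap_angle(centers + stats::rnorm(n, 0, plan$sigma))
  list(states = states, angles = as.numeric(angles), plan = plan)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# --- trajectory generators -------------------------------------------------

# Re-pose a tracked aromatic sidechain in place: only CG..CZ(+OH) move,
# rebuilt by the same internal-coordinate rules as the initial build, so
# chi1 read back from coordinates equals the requested value exactly.
set_sidechain_chi1 <- function(m, at, chain, resSeq, chi1, chi2 = 90) {
  res <- which(at$chainId == chain & at$resSeq == resSeq)
  ix <- function(nm) res[match(nm, at$name[res])]
  n <- m[ix("N"), ]; ca <- m[ix("CA"), ]; cb <- m[ix("CB"), ]
  cg <- place_atom(n, ca, cb, 1.52, 113.8, chi1)
  cd1 <- place_atom(ca, cb, cg, 1.40, 120.8, chi2)
  cd2 <- place_atom(ca, cb, cg, 1.40, 120.8, chi2 - 180)
  ce1 <- place_atom(cb, cg, cd1, 1.40, 120, 180)
  ce2 <- place_atom(cb, cg, cd2, 1.40, 120, 180)
  cz <- place_atom(cg, cd1, ce1, 1.40, 120, 0)
  m[ix("CG"), ] <- cg; m[ix("CD1"), ] <- cd1; m[ix("CD2"), ] <- cd2
  m[ix("CE1"), ] <- ce1; m[ix("CE2"), ] <- ce2; m[ix("CZ"), ] <- cz
  if (!is.na(ix("OH"))) m[ix("OH"), ] <- place_atom(cd1, ce1, cz, 1.38, 120, 180)
  m
}

protomer_frame_coords <- function(base, chi1_199, chi1_390) {
  at <- base$structure$atoms
  m <- as.matrix(at[, c("x", "y", "z")])
  m <- set_sidechain_chi1(m, at, at$chainId[1], 199, chi1_199)
  set_sidechain_chi1(m, at, at$chainId[1], 390, chi1_390)
}

ligand_template <- function() {
  offs <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(1.06, 1.06, 0),
                c(1.06, -1.06, 0), c(1.06, 0, 1.06))
  tibble::tibble(name = paste0("C", 1:5), element = "C", resName = "LIG",
                 resSeq = 1L, chainId = "L", het = TRUE,
                 x = offs[, 1], y = offs[, 2], z = offs[, 3])
}

rigid_jitter <- function(m) {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  r <- rot_axis(ax, stats::runif(1, 0, 8) * pi / 180)
  t <- stats::rnorm(3, 0, 1)
  sweep(m %*% t(r), 2, t, `+`)
}

# deterministic pick of exactly round(f * n) frames
scripted_frames <- function(n, fraction) {
  k <- round(fraction * n)
  if (k == 0) return(logical(n))
  pick <- sample.int(n, k)
  out <- logical(n)
  out[pick] <- TRUE
  out
}

#' Generate a monomer + pseudo-ligand trajectory with ground truth
#'
#' The receptor backbone is fixed; tracked sidechains follow their
#' rotamer sequences. A rigid 5-atom ligand is placed each frame on the
#' +x side of the planted residue: at `target - 0.3` A (min heavy-atom
#' distance, below the contact cutoff) in scripted contact frames, at
#' `target + 2` A otherwise; with the default backbone-only anchor the
#' pose drift never exceeds the 3 A stability threshold, emulating a
#' stably bound ligand. An optional scripted pose excursion displaces
#' the ligand by 6 A before `switch_frame` so the stability onset is
#' known exactly (the recorded onset truth is NA when no excursion was
#' scripted). A global rigid-body jitter exercises superposition.
#'
#' @param spec a [synthetic_spec()].
#' @return list: `traj` ([md_trajectory()] incl. ligand chain "L"),
#'   `bw`, `truth` (states, occupancies, contact frames, onset, seed).
#' @export
generate_monomer_trajectory <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_frames
  seqs <- lapply(seq_along(spec$rotamers), function(i)
    generate_rotamer_sequence(spec, i))
  names(seqs) <- vapply(spec$rotamers, function(p) paste0(p$chain, ":", p$resSeq), "")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seq_seed(spec, 7L))
  contact <- scripted_frames(n, spec$ligand$contact_fraction)
  lig <- ligand_template()
  proto0 <- build_toy_protomer("A")
  n_prot <- n_atoms(proto0$structure)
  n_all <- n_prot + nrow(lig)
  coords <- array(NA_real_, c(n, n_all, 3))
  switch_frame <- spec$ligand$switch_frame
  res_target <- spec$ligand$resSeq
  truth_contact <- logical(n)
  topo_at <- NULL
  at <- proto0$structure$atoms
  for (f in seq_len(n)) {
    m <- protomer_frame_coords(proto0,
                               seqs[["A:199"]]$angles[f],
                               seqs[["A:390"]]$angles[f])
    resi <- which(at$resSeq == res_target & at$chainId == "A")
    ref <- m[resi[which.max(m[resi, 1])], ]
    d <- if (contact[f]) spec$ligand$target - 0.3 else spec$ligand$target + 2
    lpos <- as.matrix(lig[, c("x", "y", "z")])
    lpos <- sweep(lpos, 2, ref + c(d, 0, 0), `+`)
    excursion <- !is.null(switch_frame) && f < switch_frame
    if (excursion) lpos <- sweep(lpos, 2, c(0, 0, 6), `+`)
    truth_contact[f] <- contact[f] && !excursion
    frame <- rbind(m, lpos)
    if (spec$jitter) frame <- rigid_jitter(frame)
    coords[f, , ] <- frame
    if (f == 1) {
      lig2 <- lig; lig2$x <- lpos[, 1]; lig2$y <- lpos[, 2]; lig2$z <- lpos[, 3]
      topo_at <- dplyr::bind_rows(at, lig2)
      topo_at$serial <- seq_len(nrow(topo_at))
      topo_at$x <- frame[, 1]; topo_at$y <- frame[, 2]; topo_at$z <- frame[, 3]
    }
  }
  times <- (seq_len(n) - 1) * spec$dt
  # onset is only a scripted quantity when an excursion was scripted:
  # without one the pose trace is governed by sidechain/contact motion
  truth <- list(
    seed = spec$seed,
    states = lapply(seqs, `[[`, "states"),
    angles = lapply(seqs, `[[`, "angles"),
    occupancy_trans = vapply(seqs, function(s) mean(s$states == "trans"), 0),
    contact_frames = truth_contact,
    contact_fraction = mean(truth_contact),
    onset = if (is.null(switch_frame)) NA_real_ else times[min(switch_frame, n)],
    onset_frame = if (is.null(switch_frame)) NA_integer_ else
      as.integer(min(switch_frame, n)))
  list(traj = md_trajectory(md_structure(topo_at), coords, times),
       bw = proto0$bw, truth = truth)
}

#' Generate a homodimer trajectory with ground truth
#'
#' Protomer A is the toy protomer; protomer B is a copy rotated 180
#' degrees about z through its centroid (so the TM5/TM6 faces oppose)
#' and offset along +x by the scripted separation, which therefore
#' equals the inter-protomer center-of-geometry distance by
#' construction. Tyr199 hydroxyls are posed at 2.8 A (O-O) in exactly
#' the requested fraction of frames and pushed beyond 4 A elsewhere.
#'
#' @param spec a [synthetic_spec()]; protomer A uses
#'   `dimer_default_rotamers()` when `spec$rotamers` carries the monomer
#'   defaults -- pass explicit plans to override.
#' @param rotamers_a optional explicit protomer-A plans.
#' @return list: `traj` (chains A and B), `bw` (both chains), `truth`
#'   (per-protomer states/occupancies, hbond frames, separations, seed).
#' @export
generate_dimer_trajectory <- function(spec, rotamers_a = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_frames
  spec_a <- spec
  spec_a$rotamers <- rotamers_a %||% dimer_default_rotamers()
  seqs_a <- lapply(seq_along(spec_a$rotamers), function(i)
    generate_rotamer_sequence(spec_a, i))
  names(seqs_a) <- vapply(spec_a$rotamers, function(p) paste0("A:", p$resSeq), "")
  seqs_b <- lapply(seq_along(spec$rotamers_b), function(i)
    generate_rotamer_sequence(spec, i, protomer = "B"))
  names(seqs_b) <- vapply(spec$rotamers_b, function(p) paste0("B:", p$resSeq), "")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seq_seed(spec, 13L))
  hb <- scripted_frames(n, spec$dimer$hbond_fraction)
  sep <- spec$dimer$separation
  if (length(sep) == 1) sep <- rep(sep, n)
  stopifnot(length(sep) == n)
  proto0 <- build_toy_protomer("A")
  n_prot <- n_atoms(proto0$structure)
  coords <- array(NA_real_, c(n, 2 * n_prot, 3))
  topo_at <- NULL
  sep_actual <- numeric(n)
  r180 <- rot_axis(c(0, 0, 1), pi)
  proto0_b <- build_toy_protomer("B")
  at_a <- proto0$structure$atoms
  at_b <- proto0_b$structure$atoms
  for (f in seq_len(n)) {
    ma <- protomer_frame_coords(proto0, seqs_a[["A:199"]]$angles[f],
                                seqs_a[["A:390"]]$angles[f])
    mb <- protomer_frame_coords(proto0_b, seqs_b[["B:199"]]$angles[f],
                                seqs_b[["B:390"]]$angles[f])
    cog_a <- colMeans(ma)
    # center B on A's centroid, flip, then offset: COG distance == sep[f]
    mb <- sweep(mb, 2, colMeans(mb))
    mb <- mb %*% t(r180)
    mb <- sweep(mb, 2, cog_a + c(sep[f], 0, 0), `+`)
    # pose the Tyr hydroxyl pair
    oh_a <- which(at_a$resSeq == 199 & toupper(at_a$name) == "OH")
    oh_b <- which(at_b$resSeq == 199 & toupper(at_b$name) == "OH")
    v <- mb[oh_b, ] - ma[oh_a, ]
    dv <- sqrt(sum(v^2))
    if (hb[f]) {
      mb[oh_b, ] <- ma[oh_a, ] + v / dv * 2.8
    } else if (dv <= 4.0) {
      mb[oh_b, ] <- ma[oh_a, ] + v / dv * 4.5
    }
    frame <- rbind(ma, mb)
    if (spec$jitter) frame <- rigid_jitter(frame)
    coords[f, , ] <- frame
    sep_actual[f] <- sqrt(sum((colMeans(frame[seq_len(n_prot), , drop = FALSE]) -
                               colMeans(frame[n_prot + seq_len(n_prot), , drop = FALSE]))^2))
    if (f == 1) {
      topo_at <- dplyr::bind_rows(at_a, at_b)
      topo_at$serial <- seq_len(nrow(topo_at))
      topo_at$x <- frame[, 1]; topo_at$y <- frame[, 2]; topo_at$z <- frame[, 3]
    }
  }
  times <- (seq_len(n) - 1) * spec$dt
  bw_b <- proto0$bw; bw_b$chainId <- "B"
  truth <- list(
    seed = spec$seed,
    states_a = lapply(seqs_a, `[[`, "states"),
    states_b = lapply(seqs_b, `[[`, "states"),
    occupancy_trans_a = vapply(seqs_a, function(s) mean(s$states == "trans"), 0),
    occupancy_trans_b = vapply(seqs_b, function(s) mean(s$states == "trans"), 0),
    hbond_frames = hb,
    hbond_fraction = mean(hb),
    separation_script = sep,
    separations = sep_actual)
  list(traj = md_trajectory(md_structure(topo_at), coords, times),
       bw = bw_map(dplyr::bind_rows(tibble::as_tibble(proto0$bw),
                                    tibble::as_tibble(bw_b))),
       truth = truth)
}

#' Write a synthetic dataset to disk
#'
#' Emits the multi-MODEL PDB trajectory, the BW-map TSV and the ground
#' truth as JSON (seed included), the generator's on-disk interface.
#'
#' @param gen result of [generate_monomer_trajectory()] or
#'   [generate_dimer_trajectory()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pdb(gen$traj, file.path(dir, "trajectory.pdb"))
  write_bw_map(gen$bw, file.path(dir, "bw_map.tsv"))
  jsonlite::write_json(gen$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
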