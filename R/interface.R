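# Homodimer interface characterization: inter-protomer distance traces,
# geometric hydrogen-bond occupancy, a simplified pairwise interaction
# energy (screened Coulomb + Lennard-Jones), and computational alanine
# scanning by sidechain truncation.
#
# The energy model is deliberately simple and self-consistent rather
# than force-field faithful:
#   E = sum over inter-protomer heavy-atom pairs with r < cutoff of
#       q_i q_j * 332.0636 / (4 r^2)            (eps(r) = 4r dielectric)
#     + 4 eps_ij [ (sig_ij/r)^12 - (sig_ij/r)^6 ]  (Lorentz-Berthelot)
# in kcal/mol, with per-element LJ parameters and per-residue formal
# charges from the packaged tables. Alanine scanning re-evaluates the
# same energy on truncated sidechains over identical backbone frames, so
# a mutation's contribution is exactly the sum of pair terms it removes.

COULOMB_CONST <- 332.0636  # kcal mol^-1 A e^-2

#' Energy model parameters
#'
#' Loads the packaged per-element Lennard-Jones table and per-residue
#' formal charge assignments (neutral sidechains except Asp/Glu/Lys/Arg
#' and protonated His). Both files are plain TSV under
#' `system.file("extdata", package = "rotadimer")` and can be swapped for
#' custom tables.
#'
#' @param lj_file,charge_file optional overriding TSV paths.
#' @param cutoff pair cutoff, Angstrom (default 12).
#' @return list of class `energy_params`.
#' @export
energy_params <- function(lj_file = NULL, charge_file = NULL, cutoff = 12) {
  lj_file <- lj_file %||% system.file("extdata", "lj_params.tsv", package = "rotadimer")
  charge_file <- charge_file %||% system.file("extdata", "charges.tsv", package = "rotadimer")
  lj <- utils::read.delim(lj_file, stringsAsFactors = FALSE)
  ch <- utils::read.delim(charge_file, stringsAsFactors = FALSE)
  stopifnot(all(c("element", "sigma", "epsilon") %in% names(lj)),
            all(c("resName", "name", "charge") %in% names(ch)),
            cutoff > 0)
  structure(list(lj = lj, charges = ch, cutoff = cutoff), class = "energy_params")
}

atom_params <- function(at, params) {
  i <- match(toupper(at$element), toupper(params$lj$element))
  if (anyNA(i)) {
    abort(paste0("no LJ parameters for element: ",
                 paste(unique(at$element[is.na(i)]), collapse = ", ")))
  }
  q <- params$charges$charge[match(paste(at$resName, toupper(at$name)),
                                   paste(params$charges$resName,
                                         toupper(params$charges$name)))]
  q[is.na(q)] <- 0
  list(sigma = params$lj$sigma[i], epsilon = params$lj$epsilon[i], q = q)
}

# energy between two coordinate blocks given their parameter vectors
pair_energy <- function(ma, mb, pa, pb, cutoff) {
  d2 <- cross_dist2(ma, mb)
  r <- sqrt(d2)
  keep <- r < cutoff & r > 0
  if (!any(keep)) return(0)
  r <- r[keep]
  qq <- outer(pa$q, pb$q)[keep]
  sig <- outer(pa$sigma, pb$sigma, `+`)[keep] / 2
  eps <- sqrt(outer(pa$epsilon, pb$epsilon))[keep]
  sr6 <- (sig / r)^6
  sum(qq * COULOMB_CONST / (4 * r^2) + 4 * eps * (sr6^2 - sr6))
}

#' Inter-protomer distance trace
#'
#' Per-frame center-of-geometry distance and minimum heavy-atom distance
#' between two selections that must sit on distinct chains.
#'
#' @param traj a `md_trajectory`.
#' @param sel_a,sel_b the two (helix) selections, one per protomer.
#' @param bw optional [bw_map()].
#' @return tibble of class `distance_trace`: `frame`, `time`, `cog_dist`,
#'   `min_dist` (Angstrom).
#' @export
interface_distance_trace <- function(traj, sel_a, sel_b, bw = NULL) {
  stopifnot(inherits(traj, "md_trajectory"))
  ia <- select_atoms(traj, sel_a, bw); ib <- select_atoms(traj, sel_b, bw)
  if (length(ia) == 0 || length(ib) == 0) abort("empty selection")
  at <- atoms(traj)
  if (length(intersect(unique(at$chainId[ia]), unique(at$chainId[ib]))) > 0) {
    abort("protomer selections must be on distinct chains")
  }
  el <- toupper(at$element)
  ha <- ia[el[ia] != "H"]; hb <- ib[el[ib] != "H"]
  rows <- lapply(seq_len(n_frames(traj)), function(f) {
    m <- coords_matrix(traj, f)
    tibble::tibble(frame = f, time = traj$times[f],
                   cog_dist = sqrt(sum((colMeans(m[ia, , drop = FALSE]) -
                                        colMeans(m[ib, , drop = FALSE]))^2)),
                   min_dist = min_dist_mat(m[ha, , drop = FALSE],
                                           m[hb, , drop = FALSE]))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("distance_trace", class(out))
  out
}

#' Cross-protomer residue-pair minimum distance
#'
#' Per-frame minimum heavy-atom distance between a residue group on
#' protomer 1 and one on protomer 2, summarized over a window.
#'
#' @param traj a `md_trajectory`.
#' @param res_a,res_b residue selections (e.g. `"chain A and resid 199"`
#'   or a `bw`-based selection); vectorized over frames.
#' @param window `c(t_start, t_end)` ns, or NULL.
#' @param bw optional [bw_map()].
#' @return tibble of class `distance_trace` with columns `frame`, `time`,
#'   `dist`; mean and population SD over the window attached as the
#'   `"summary"` attribute (also via `glance()`).
#' @export
residue_pair_min_distance <- function(traj, res_a, res_b, window = NULL, bw = NULL) {
  stopifnot(inherits(traj, "md_trajectory"))
  ia <- select_atoms(traj, res_a, bw); ib <- select_atoms(traj, res_b, bw)
  at <- atoms(traj); el <- toupper(at$element)
  ia <- ia[el[ia] != "H"]; ib <- ib[el[ib] != "H"]
  if (length(ia) == 0 || length(ib) == 0) abort("empty atom group")
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    m <- coords_matrix(traj, f)
    min_dist_mat(m[ia, , drop = FALSE], m[ib, , drop = FALSE])
  }, numeric(1))
  out <- tibble::tibble(frame = seq_len(n_frames(traj)), time = traj$times,
                        dist = vals)
  keep <- frames_in_window(out$time, window)
  if (length(keep) == 0) abort("window overlaps no frames")
  attr(out, "summary") <- summarize_trace(out$dist[keep])
  attr(out, "window") <- window
  class(out) <- c("distance_trace", class(out))
  out
}

#' Geometric hydrogen-bond criterion
#'
#' Donor-acceptor heavy-atom distance cutoff plus a D-H...A angle cutoff
#' that is applied only when an explicit hydrogen is present on the
#' donor; heavy-atom-only inputs fall back to the distance test alone.
#'
#' @param dist_cutoff Angstrom (default 3.5, inclusive).
#' @param angle_cutoff degrees in (0, 180] (default 150).
#' @return list of class `hbond_criterion`.
#' @export
hbond_criterion <- function(dist_cutoff = 3.5, angle_cutoff = 150) {
  if (dist_cutoff <= 0) abort("distance cutoff must be positive")
  if (angle_cutoff <= 0 || angle_cutoff > 180) abort("angle cutoff must be in (0, 180]")
  structure(list(dist_cutoff = dist_cutoff, angle_cutoff = angle_cutoff),
            class = "hbond_criterion")
}

#' Hydrogen-bond occupancy between two polar atoms
#'
#' Fraction of window frames in which the geometric criterion holds. In
#' `symmetric` mode either atom may act as donor, the natural setting for
#' Tyr-Tyr hydroxyl pairs across a dimer interface.
#'
#' @param traj a `md_trajectory`.
#' @param donor,acceptor single-atom selections (chain/resid/name), e.g.
#'   `"chain A and resid 199 and name OH"`.
#' @param criterion a [hbond_criterion()].
#' @param window `c(t_start, t_end)` ns, or NULL.
#' @param symmetric allow either partner to donate (default TRUE).
#' @param bw optional [bw_map()].
#' @return one-row tibble: `n_frames`, `n_bonded`, `occupancy`, plus the
#'   criterion parameters echoed as columns.
#' @export
hbond_occupancy <- function(traj, donor, acceptor, criterion = hbond_criterion(),
                            window = NULL, symmetric = TRUE, bw = NULL) {
  stopifnot(inherits(traj, "md_trajectory"), inherits(criterion, "hbond_criterion"))
  id <- select_atoms(traj, donor, bw)
  ia <- select_atoms(traj, acceptor, bw)
  if (length(id) == 0 || length(ia) == 0) abort("donor/acceptor atom not found")
  if (length(id) > 1 || length(ia) > 1) abort("donor/acceptor selections must be single atoms")
  at <- atoms(traj)
  keep <- frames_in_window(traj$times, window)
  if (length(keep) == 0) abort("window overlaps no frames")
  # hydrogens covalently bound to a heavy atom (within 1.25 A, same residue)
  find_h <- function(m, heavy_idx) {
    res <- which(at$chainId == at$chainId[heavy_idx] &
                 at$resSeq == at$resSeq[heavy_idx] &
                 toupper(at$element) == "H")
    if (length(res) == 0) return(integer(0))
    d <- sqrt(rowSums((m[res, , drop = FALSE] -
                       matrix(m[heavy_idx, ], length(res), 3, byrow = TRUE))^2))
    res[d <= 1.25]
  }
  ok_direction <- function(m, d_idx, a_idx) {
    r <- sqrt(sum((m[d_idx, ] - m[a_idx, ])^2))
    if (r > criterion$dist_cutoff) return(FALSE)
    hs <- find_h(m, d_idx)
    if (length(hs) == 0) return(TRUE)    # heavy-atom-only fallback
    for (h in hs) {
      v1 <- m[d_idx, ] - m[h, ]; v2 <- m[a_idx, ] - m[h, ]
      ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                 (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
      if (ang >= criterion$angle_cutoff) return(TRUE)
    }
    FALSE
  }
  bonded <- vapply(keep, function(f) {
    m <- coords_matrix(traj, f)
    ok_direction(m, id, ia) || (symmetric && ok_direction(m, ia, id))
  }, logical(1))
  tibble::tibble(n_frames = length(keep), n_bonded = sum(bonded),
                 occupancy = sum(bonded) / length(keep),
                 dist_cutoff = criterion$dist_cutoff,
                 angle_cutoff = criterion$angle_cutoff,
                 symmetric = symmetric)
}

#' Simplified inter-protomer interaction energy
#'
#' Sums the screened-Coulomb plus Lennard-Jones pair energy (see the
#' model note in this file's header and the vignette) over all
#' inter-protomer heavy-atom pairs within the cutoff. Intra-protomer
#' terms are excluded. Protomers are the two chains of the input.
#'
#' @param x a two-chain `md_structure` or `md_trajectory`.
#' @param params an [energy_params()] object.
#' @param chains optional length-2 chain ids defining the protomers
#'   (defaults to the two chains present, ligand/hetero chains excluded).
#' @return object of class `interface_energy_report`: list with
#'   `energies` (tibble `frame`, `time`, `energy` in kcal/mol), `mean`,
#'   `sd` (population), and the embedded `model` descriptor.
#' @export
interface_energy <- function(x, params = energy_params(), chains = NULL) {
  at <- atoms(x)
  if (is.null(chains)) {
    chains <- unique(at$chainId[!at$het])
  }
  if (length(chains) != 2) {
    abort("interface energy needs exactly two protomer chains")
  }
  heavy <- toupper(at$element) != "H"
  ia <- which(at$chainId == chains[1] & heavy)
  ib <- which(at$chainId == chains[2] & heavy)
  if (length(ia) == 0 || length(ib) == 0) abort("a protomer chain has no atoms")
  pa <- atom_params(at[ia, ], params)
  pb <- atom_params(at[ib, ], params)
  tt <- n_frames(x)
  times <- if (inherits(x, "md_trajectory")) x$times else 0
  e <- vapply(seq_len(tt), function(f) {
    m <- coords_matrix(x, f)
    pair_energy(m[ia, , drop = FALSE], m[ib, , drop = FALSE], pa, pb, params$cutoff)
  }, numeric(1))
  structure(list(
    energies = tibble::tibble(frame = seq_len(tt), time = times, energy = e),
    mean = mean(e),
    sd = sqrt(mean((e - mean(e))^2)),
    model = list(form = "q_i q_j 332.0636/(4 r^2) + 4 eps_ij [(sig/r)^12 - (sig/r)^6]",
                 dielectric = "distance-dependent, eps(r) = 4r",
                 combination = "Lorentz-Berthelot",
                 cutoff = params$cutoff, chains = chains)),
    class = "interface_energy_report")
}

#' @export
print.interface_energy_report <- function(x, ...) {
  cat(sprintf("<interface_energy_report> %d frame(s): mean %.3f kcal/mol (sd %.3f), cutoff %g A\n",
              nrow(x$energies), x$mean, x$sd, x$model$cutoff))
  invisible(x)
}

#' Truncate residues to alanine
#'
#' Removes all sidechain atoms beyond CB (CB is retained) and renames the
#' residue ALA; the backbone is untouched and coordinates are reused
#' as-is (single-point, FoldX-style scanning: no repacking). Mutating a
#' residue that is already alanine is the identity. Glycine (no CB) is
#' refused.
#'
#' @param x a `md_structure` or `md_trajectory`.
#' @param residues data frame (or list) with `chainId` and `resSeq` of
#'   the residues to truncate.
#' @return object of the same class as `x`.
#' @export
mutate_to_alanine <- function(x, residues) {
  residues <- tibble::as_tibble(residues)
  stopifnot(all(c("chainId", "resSeq") %in% names(residues)))
  at <- atoms(x)
  keep_names <- c("N", "CA", "C", "O", "CB", "OXT", "H", "HA")
  drop <- rep(FALSE, nrow(at))
  for (i in seq_len(nrow(residues))) {
    res <- which(at$chainId == residues$chainId[i] &
                 at$resSeq == residues$resSeq[i])
    if (length(res) == 0) {
      abort(sprintf("residue %s:%d not in topology",
                    residues$chainId[i], residues$resSeq[i]))
    }
    if (!"CB" %in% toupper(at$name[res])) {
      abort(sprintf("residue %s:%d has no CB (glycine?): cannot truncate",
                    residues$chainId[i], residues$resSeq[i]))
    }
    drop[res[!toupper(at$name[res]) %in% keep_names]] <- TRUE
    at$resName[res] <- "ALA"
  }
  if (inherits(x, "md_trajectory")) {
    topo <- md_structure(at[!drop, ])
    md_trajectory(topo, x$coords[, !drop, , drop = FALSE], x$times)
  } else {
    md_structure(at[!drop, ])
  }
}

#' Computational alanine scan of interface residues
#'
#' Interface energies are evaluated on the wild type and on the
#' alanine-truncated mutant over identical frames; the contribution of
#' the truncated sidechains is `E_wt - E_mut` (negative when the removed
#' atoms interacted favorably across the interface).
#'
#' @inheritParams interface_energy
#' @param residues residues to mutate, as in [mutate_to_alanine()].
#' @return object of class `ala_scan_result`: list with `residues`,
#'   `E_wt`, `E_mut`, `contribution` (kcal/mol) and both per-frame
#'   reports.
#' @export
alanine_scan <- function(x, residues, params = energy_params(), chains = NULL) {
  wt <- interface_energy(x, params, chains)
  mut <- interface_energy(mutate_to_alanine(x, residues), params, chains)
  structure(list(residues = tibble::as_tibble(residues),
                 E_wt = wt$mean, E_mut = mut$mean,
                 contribution = energy_contribution(wt$mean, mut$mean),
                 wt_report = wt, mut_report = mut),
            class = "ala_scan_result")
}

#' @export
print.ala_scan_result <- function(x, ...) {
  cat(sprintf("<ala_scan_result> %d residue(s): E_wt %.3f, E_mut %.3f, contribution %.3f kcal/mol\n",
              nrow(x$residues), x$E_wt, x$E_mut, x$contribution))
  invisible(x)
}

#' Energy contribution of a mutated interaction network
#'
#' The bookkeeping used for alanine scanning: a wild-type interface mean
#' of -11.7 kcal/mol and a mutant mean of -8.6 kcal/mol give a
#' contribution of -3.1 kcal/mol.
#'
#' @param e_wt,e_mut mean interface energies, kcal/mol.
#' @return `e_wt - e_mut`, kcal/mol.
#' @export
energy_contribution <- function(e_wt, e_mut) e_wt - e_mut

#' Annotate an externally supplied docking interface score
#'
#' Protein-protein docking servers report an interface score ("I_sc") on
#' a 0 to -10 scale; values below -5.0 are conventionally considered
#' satisfactory. The score is annotated, never computed here.
#'
#' @param i_sc numeric score(s).
#' @param satisfactory_below threshold (default -5.0).
#' @return tibble: `i_sc`, `satisfactory`.
#' @export
annotate_interface_score <- function(i_sc, satisfactory_below = -5.0) {
  tibble::tibble(i_sc = i_sc, satisfactory = i_sc < satisfactory_below)
}
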