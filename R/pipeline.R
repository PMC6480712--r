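# End-to-end monomer / dimer / partition analyses driven by a config.

#' Analysis configuration
#'
#' Collects the inputs and thresholds of a pipeline run. Inputs may be
#' file paths (PDB trajectory, BW-map TSV, fingerprint TSVs) or
#' in-memory objects. All cutoffs that affect a number are echoed in the
#' run report.
#'
#' @param trajectory a `md_trajectory` or PDB path.
#' @param bw a [bw_map()] or TSV path.
#' @param mode "monomer", "dimer" or "partition".
#' @param ligand_chain chain id of the ligand (monomer mode).
#' @param contact_cutoff Angstrom, strict, protein-ligand contacts
#'   (default 3.5).
#' @param rotamer_threshold degrees, chi1 cis/trans split (default 240).
#' @param stability_threshold Angstrom, RMSD-to-final pose stability
#'   (default 3.0).
#' @param energy_cutoff Angstrom, interface energy pair cutoff
#'   (default 12).
#' @param hbond hydrogen-bond criterion, a [hbond_criterion()].
#' @param min_fraction "frequent contact" frequency threshold
#'   (default 0.5).
#' @param tracked_bw generic labels of the tracked sidechains
#'   (default 5.48 and 6.52).
#' @param backbone_atoms TMD backbone atom names for RMSD (default
#'   N, CA, C, O; set to "CA" for CA-only traces).
#' @param fingerprints named list of contact sets / fingerprint TSV
#'   paths (partition mode).
#' @param dt ns/frame used when reading PDB trajectories (default 1).
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(trajectory = NULL, bw = NULL,
                            mode = c("monomer", "dimer", "partition"),
                            ligand_chain = NULL,
                            contact_cutoff = 3.5,
                            rotamer_threshold = ROTAMER_THRESHOLD,
                            stability_threshold = 3.0,
                            energy_cutoff = 12,
                            hbond = hbond_criterion(),
                            min_fraction = 0.5,
                            tracked_bw = c("5.48", "6.52"),
                            backbone_atoms = c("N", "CA", "C", "O"),
                            fingerprints = NULL,
                            dt = 1) {
  mode <- match.arg(mode)
  stopifnot(contact_cutoff > 0, rotamer_threshold > 0,
            stability_threshold > 0, energy_cutoff > 0, min_fraction >= 0)
  cfg <- list(trajectory = trajectory, bw = bw, mode = mode,
              ligand_chain = ligand_chain, contact_cutoff = contact_cutoff,
              rotamer_threshold = rotamer_threshold,
              stability_threshold = stability_threshold,
              energy_cutoff = energy_cutoff, hbond = hbond,
              min_fraction = min_fraction, tracked_bw = tracked_bw,
              backbone_atoms = backbone_atoms, fingerprints = fingerprints,
              dt = dt)
  class(cfg) <- "analysis_config"
  cfg
}

#' @rdname analysis_config
#' @param path YAML config file; keys mirror the arguments.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$hbond)) y$hbond <- do.call(hbond_criterion, y$hbond)
  do.call(analysis_config, y)
}

config_echo <- function(cfg) {
  list(mode = cfg$mode, contact_cutoff = cfg$contact_cutoff,
       rotamer_threshold = cfg$rotamer_threshold,
       stability_threshold = cfg$stability_threshold,
       energy_cutoff = cfg$energy_cutoff,
       hbond_dist_cutoff = cfg$hbond$dist_cutoff,
       hbond_angle_cutoff = cfg$hbond$angle_cutoff,
       min_fraction = cfg$min_fraction,
       tracked_bw = cfg$tracked_bw,
       backbone_atoms = cfg$backbone_atoms,
       version = as.character(utils::packageVersion("rotadimer")))
}

resolve_inputs <- function(cfg) {
  traj <- cfg$trajectory
  if (is.character(traj)) traj <- read_pdb(traj, dt = cfg$dt)
  bw <- cfg$bw
  if (is.character(bw)) bw <- load_bw_map(bw)
  list(traj = traj, bw = bw)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Run the monomer (ligand-bound receptor) analysis
#'
#' Computes the TMD backbone RMSD trace (vs frame 1), the ligand
#' RMSD-to-final trace in the receptor frame, the pose stability window,
#' the contact fingerprint over the stable window, and chi1 cis/trans
#' occupancies of the tracked residues over both the stable window and
#' the full run.
#'
#' @param config an [analysis_config()] in monomer mode.
#' @return list of class `run_report`.
#' @export
run_monomer <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  if (config$mode != "monomer") abort("config mode must be 'monomer'")
  if (is.null(config$ligand_chain)) {
    abort("monomer mode needs `ligand_chain` (none configured)")
  }
  inp <- stage("inputs", resolve_inputs(config))
  traj <- inp$traj; bw <- inp$bw
  at <- atoms(traj)
  if (!config$ligand_chain %in% at$chainId) {
    abort(paste0("ligand chain '", config$ligand_chain, "' absent from trajectory"))
  }
  tmd_sel <- paste0("segment ", paste(paste0("tm", 1:7), collapse = " "),
                    " and name ", paste(config$backbone_atoms, collapse = " "))
  lig_sel <- paste0("chain ", config$ligand_chain)
  backbone_rmsd <- stage("backbone rmsd",
    rmsd_trace(traj, tmd_sel, reference = "first", bw = bw))
  ligand_rmsd <- stage("ligand rmsd",
    rmsd_trace(traj, lig_sel, reference = "final", fit_sel = tmd_sel, bw = bw))
  stability <- stage("stability window",
    stability_onset(ligand_rmsd, threshold = config$stability_threshold))
  window <- c(stability$onset, max(traj$times))
  freqs <- stage("contact frequency",
    contact_frequency(traj, lig_sel, "protein", window = window,
                      cutoff = config$contact_cutoff, bw = bw))
  pocket <- stage("frequent contacts", frequent_contacts(freqs, config$min_fraction))
  occ <- stage("occupancy", {
    rows <- lapply(config$tracked_bw, function(lbl) {
      tr <- chi1_trace(traj, bw = bw, bw_id = lbl)
      st <- rotamer_states(tr, threshold = config$rotamer_threshold)
      dplyr::bind_rows(
        dplyr::mutate(state_occupancy(st, window), basis = "stable window"),
        dplyr::mutate(state_occupancy(st), basis = "full run"))
    })
    dplyr::bind_rows(rows)
  })
  report <- list(provenance = c(config_echo(config),
                                list(window = window,
                                     ligand_chain = config$ligand_chain)),
                 backbone_rmsd = backbone_rmsd,
                 ligand_rmsd = ligand_rmsd,
                 stability = stability,
                 contact_frequency = freqs,
                 pocket = pocket,
                 occupancy = occ)
  class(report) <- "run_report"
  report
}

#' Run the homodimer interface analysis
#'
#' Interface distance traces between the TM5+TM6 selections of the two
#' protomers, the cross-protomer minimum distance of the tracked
#' residue pair, Tyr-Tyr (5.48) hydrogen-bond occupancy in symmetric
#' mode, the interface energy mean +/- SD, and an alanine scan of the
#' tracked residues on both protomers.
#'
#' @param config an [analysis_config()] in dimer mode.
#' @return list of class `run_report`.
#' @export
run_dimer <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  if (config$mode != "dimer") abort("config mode must be 'dimer'")
  inp <- stage("inputs", resolve_inputs(config))
  traj <- inp$traj; bw <- inp$bw
  chains <- unique(atoms(traj)$chainId[!atoms(traj)$het])
  if (length(chains) < 2) abort("dimer mode needs a two-chain trajectory")
  chains <- chains[1:2]
  helix_sel <- function(ch) paste0("chain ", ch, " and segment tm5 tm6")
  distances <- stage("interface distances",
    interface_distance_trace(traj, helix_sel(chains[1]), helix_sel(chains[2]),
                             bw = bw))
  tracked_sel <- function(ch) {
    rs <- vapply(config$tracked_bw, function(l)
      bw_resolve(bw, l, chain = ch)$resSeq, 1L)
    paste0("chain ", ch, " and resid ", paste(rs, collapse = " "))
  }
  pair_dist <- stage("residue pair distance",
    residue_pair_min_distance(traj, tracked_sel(chains[1]),
                              tracked_sel(chains[2]), bw = bw))
  tyr_oh <- function(ch) {
    rs <- bw_resolve(bw, config$tracked_bw[1], chain = ch)$resSeq
    paste0("chain ", ch, " and resid ", rs, " and name OH")
  }
  hb <- stage("hbond occupancy",
    hbond_occupancy(traj, tyr_oh(chains[1]), tyr_oh(chains[2]),
                    criterion = config$hbond, symmetric = TRUE, bw = bw))
  params <- energy_params(cutoff = config$energy_cutoff)
  energy <- stage("interface energy", interface_energy(traj, params, chains))
  mut <- dplyr::bind_rows(lapply(chains, function(ch) {
    tibble::tibble(chainId = ch,
                   resSeq = vapply(config$tracked_bw, function(l)
                     bw_resolve(bw, l, chain = ch)$resSeq, 1L))
  }))
  alascan <- stage("alanine scan", alanine_scan(traj, mut, params, chains))
  report <- list(provenance = c(config_echo(config), list(chains = chains)),
                 interface_distances = distances,
                 residue_pair_distance = pair_dist,
                 hbond = hb,
                 energy = energy,
                 alascan = alascan)
  class(report) <- "run_report"
  report
}

#' Partition contact fingerprints across ligands
#'
#' @param config an [analysis_config()] in partition mode whose
#'   `fingerprints` is a named list (>= 2) of contact sets, residue-key
#'   character vectors, or fingerprint TSV paths with a `residue`
#'   column.
#' @return list of class `run_report` with the partition tibble and its
#'   rendered two-column table.
#' @export
run_partition <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  if (config$mode != "partition") abort("config mode must be 'partition'")
  fps <- config$fingerprints
  if (is.null(fps) || length(fps) < 2) abort("partition mode needs >= 2 fingerprints")
  fps <- lapply(fps, function(f) {
    if (is.character(f) && length(f) == 1 && file.exists(f)) {
      tab <- utils::read.delim(f, stringsAsFactors = FALSE)
      if (!"residue" %in% names(tab)) abort("fingerprint TSV needs a 'residue' column")
      tab$residue
    } else f
  })
  part <- stage("partition", partition_contacts(fps))
  report <- list(provenance = c(config_echo(config),
                                list(ligands = names(fps))),
                 partition = part,
                 table = format_partition(part))
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>", x$provenance$mode, "analysis\n")
  cat("  components:", paste(setdiff(names(x), "provenance"), collapse = ", "), "\n")
  invisible(x)
}

#' Write a run report to a directory
#'
#' Tabular components become TSV, the provenance and scalar summaries
#' JSON, the partition table plain text. Numeric formatting is fixed
#' (3 decimals; 1 for percentages) so reruns on identical inputs are
#' byte-identical. On error any partially written files are removed.
#'
#' @param report a `run_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    abort(paste0("report write failed (partial outputs removed): ",
                 conditionMessage(e)))
  }
  tryCatch({
    emit_tsv <- function(tab, name) {
      p <- file.path(dir, name)
      tab <- as.data.frame(tab)
      num <- vapply(tab, is.numeric, TRUE)
      tab[num] <- lapply(tab[num], function(v)
        ifelse(v == round(v), sprintf("%d", as.integer(round(v))),
               sprintf("%.3f", v)))
      utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
      written <<- c(written, p)
    }
    pj <- file.path(dir, "provenance.json")
    jsonlite::write_json(report$provenance, pj, auto_unbox = TRUE, digits = NA)
    written <- c(written, pj)
    for (nm in setdiff(names(report), c("provenance", "table"))) {
      obj <- report[[nm]]
      if (is.data.frame(obj)) {
        emit_tsv(obj, paste0(nm, ".tsv"))
      } else if (inherits(obj, "interface_energy_report")) {
        emit_tsv(obj$energies, paste0(nm, "_per_frame.tsv"))
        sj <- file.path(dir, paste0(nm, ".json"))
        jsonlite::write_json(list(mean = round(obj$mean, 3), sd = round(obj$sd, 3),
                                  model = obj$model),
                             sj, auto_unbox = TRUE, digits = NA)
        written <- c(written, sj)
      } else if (inherits(obj, "ala_scan_result")) {
        sj <- file.path(dir, paste0(nm, ".json"))
        jsonlite::write_json(list(residues = as.data.frame(obj$residues),
                                  E_wt = round(obj$E_wt, 3),
                                  E_mut = round(obj$E_mut, 3),
                                  contribution = round(obj$contribution, 3)),
                             sj, auto_unbox = TRUE, digits = NA)
        written <- c(written, sj)
      }
    }
    if (!is.null(report$table)) {
      tp <- file.path(dir, "partition_table.txt")
      writeLines(report$table, tp)
      written <- c(written, tp)
    }
  }, error = on_fail)
  invisible(dir)
}
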