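# Protein-ligand close-contact fingerprints and the common/unique
# partition of contact sets across ligands.

#' Residues in close contact with a ligand (single frame)
#'
#' A receptor residue is in contact when any of its heavy atoms lies
#' strictly closer than `cutoff` to any ligand heavy atom.
#'
#' @param x a `md_structure`, or a `md_trajectory` with `frame`.
#' @param ligand_sel,receptor_sel atom selections; must be disjoint and
#'   non-empty.
#' @param cutoff Angstrom, strict `<` (default 3.5).
#' @param frame frame index for trajectories.
#' @param bw optional [bw_map()]; adds generic/loop labels to the report.
#' @return tibble of class `contact_set`: `chainId`, `resSeq`, `resName`,
#'   `label`, `min_dist`; the basis (frame, cutoff) is attached as
#'   attributes.
#' @export
close_contacts <- function(x, ligand_sel, receptor_sel, cutoff = 3.5,
                           frame = 1L, bw = NULL) {
  il <- select_atoms(x, ligand_sel, bw)
  ir <- select_atoms(x, receptor_sel, bw)
  if (length(intersect(il, ir)) > 0) {
    abort("ligand and receptor selections overlap")
  }
  at <- atoms(x)
  el <- toupper(at$element)
  il <- il[el[il] != "H"]; ir <- ir[el[ir] != "H"]
  if (length(il) == 0 || length(ir) == 0) abort("empty heavy-atom selection")
  m <- coords_matrix(x, frame)
  d2 <- cross_dist2(m[ir, , drop = FALSE], m[il, , drop = FALSE])
  dmin <- sqrt(apply(d2, 1, min))
  rec <- tibble::tibble(chainId = at$chainId[ir], resSeq = at$resSeq[ir],
                        resName = at$resName[ir], dmin = dmin)
  out <- rec |>
    dplyr::group_by(.data$chainId, .data$resSeq, .data$resName) |>
    dplyr::summarise(min_dist = min(.data$dmin), .groups = "drop") |>
    dplyr::filter(.data$min_dist < cutoff) |>
    dplyr::arrange(.data$chainId, .data$resSeq)
  out$label <- bw_label_safe(bw, out$chainId, out$resSeq)
  out <- out[, c("chainId", "resSeq", "resName", "label", "min_dist")]
  attr(out, "basis") <- list(mode = "single frame", frame = frame, cutoff = cutoff)
  class(out) <- c("contact_set", class(out))
  out
}

#' Per-residue contact frequency over a trajectory window
#'
#' Fraction of window frames in which each residue is in close contact
#' (strict `< cutoff` on heavy-atom pairs) with the ligand. Residues that
#' never contact the ligand are absent from the report.
#'
#' @inheritParams close_contacts
#' @param traj a `md_trajectory`.
#' @param window `c(t_start, t_end)` ns, or NULL for the full run.
#' @return tibble of class `contact_frequency`: residue columns plus
#'   `n_frames`, `n_contact`, `fraction`.
#' @export
contact_frequency <- function(traj, ligand_sel, receptor_sel, window = NULL,
                              cutoff = 3.5, bw = NULL) {
  stopifnot(inherits(traj, "md_trajectory"))
  il <- select_atoms(traj, ligand_sel, bw)
  ir <- select_atoms(traj, receptor_sel, bw)
  if (length(intersect(il, ir)) > 0) abort("ligand and receptor selections overlap")
  at <- atoms(traj)
  el <- toupper(at$element)
  il <- il[el[il] != "H"]; ir <- ir[el[ir] != "H"]
  if (length(il) == 0 || length(ir) == 0) abort("empty heavy-atom selection")
  keep <- frames_in_window(traj$times, window)
  if (length(keep) == 0) abort("window overlaps no frames")
  rkey <- paste(at$chainId[ir], at$resSeq[ir])
  counts <- new.env(parent = emptyenv())
  for (f in keep) {
    m <- coords_matrix(traj, f)
    d2 <- cross_dist2(m[ir, , drop = FALSE], m[il, , drop = FALSE])
    hit <- unique(rkey[apply(d2, 1, min) < cutoff^2])
    for (k in hit) assign(k, (counts[[k]] %||% 0L) + 1L, envir = counts)
  }
  keys <- ls(counts)
  if (length(keys) == 0) {
    out <- tibble::tibble(chainId = character(), resSeq = integer(),
                          resName = character(), label = character(),
                          n_frames = integer(), n_contact = integer(),
                          fraction = numeric())
  } else {
    parts <- strsplit(keys, " ", fixed = TRUE)
    ch <- vapply(parts, `[`, "", 1)
    rs <- as.integer(vapply(parts, `[`, "", 2))
    rn <- at$resName[ir][match(keys, rkey)]
    nc <- unname(vapply(keys, function(k) counts[[k]], 1L))
    out <- tibble::tibble(chainId = ch, resSeq = rs, resName = rn,
                          label = bw_label_safe(bw, ch, rs),
                          n_frames = length(keep),
                          n_contact = nc,
                          fraction = nc / length(keep)) |>
      dplyr::arrange(.data$chainId, .data$resSeq)
  }
  attr(out, "basis") <- list(mode = "frequency", window = window, cutoff = cutoff)
  class(out) <- c("contact_frequency", class(out))
  out
}

#' Filter a contact-frequency table to frequent contacts
#'
#' @param freqs a [contact_frequency()] result.
#' @param min_fraction retain residues contacted in at least this
#'   fraction of frames (default 0.5). Zero degenerates to the set of
#'   ever-contacting residues.
#' @return a `contact_set` tibble with the frequency basis recorded.
#' @export
frequent_contacts <- function(freqs, min_fraction = 0.5) {
  stopifnot(inherits(freqs, "contact_frequency"))
  out <- freqs[freqs$fraction >= min_fraction,
               c("chainId", "resSeq", "resName", "label")]
  out$min_dist <- NA_real_
  basis <- attr(freqs, "basis")
  basis$mode <- "frequency"
  basis$min_fraction <- min_fraction
  attr(out, "basis") <- basis
  class(out) <- c("contact_set", class(out))
  out
}

#' Partition named contact sets into common and unique categories
#'
#' Given named per-ligand residue sets, residues are grouped by the exact
#' combination of ligands contacting them. With three sets (the
#' risperidone/clozapine/spiperone convention) the categories are tagged:
#' (I) common to all three; (II) first+second only; (III) first+third
#' only; (IV) second+third only; "unique" otherwise. The categories are
#' pairwise disjoint and their union per ligand reproduces that ligand's
#' input set.
#'
#' @param sets named list (>= 2, unique names) of `contact_set` tibbles
#'   or character vectors of residue identifiers.
#' @return tibble of class `contact_partition`: one row per
#'   (ligand, residue) with `category` and `shared_with`.
#' @export
partition_contacts <- function(sets) {
  if (!is.list(sets) || length(sets) < 2) abort("need at least 2 named contact sets")
  nms <- names(sets)
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms)) {
    abort("contact sets must have unique non-empty names")
  }
  as_keys <- function(s) {
    if (is.character(s)) return(unique(s))
    if (is.data.frame(s)) {
      lab <- if ("label" %in% names(s)) s$label else NA
      key <- ifelse(!is.na(lab), paste0(s$resName, s$resSeq, "^", lab),
                    paste0(s$resName, s$resSeq))
      return(unique(key))
    }
    abort("each set must be a contact_set or character vector")
  }
  keys <- lapply(sets, as_keys)
  all_res <- unique(unlist(keys))
  membership <- vapply(keys, function(k) all_res %in% k, logical(length(all_res)))
  if (length(all_res) == 1) membership <- matrix(membership, nrow = 1)
  combo_tag <- function(memb) {
    who <- nms[memb]
    if (length(who) == length(nms)) return("I")
    if (length(who) == 1) return("unique")
    if (length(nms) == 3 && length(who) == 2) {
      if (setequal(who, nms[c(1, 2)])) return("II")
      if (setequal(who, nms[c(1, 3)])) return("III")
      return("IV")
    }
    "common"   # >3 ligand generalization: shared but not universal
  }
  rows <- lapply(seq_along(all_res), function(i) {
    memb <- membership[i, ]
    tibble::tibble(ligand = nms[memb], residue = all_res[i],
                   category = combo_tag(memb),
                   shared_with = paste(nms[memb], collapse = "+"))
  })
  out <- dplyr::bind_rows(rows) |> dplyr::arrange(.data$ligand, .data$category)
  class(out) <- c("contact_partition", class(out))
  out
}

#' Render a partition as a two-column text table
#'
#' One block per ligand with its unique interactions alongside its tagged
#' common interactions, mirroring the usual published layout.
#'
#' @param partition a [partition_contacts()] result.
#' @return character vector of report lines.
#' @export
format_partition <- function(partition) {
  stopifnot(inherits(partition, "contact_partition"))
  lines <- c(sprintf("%-14s%-24s%s", "Ligand", "Unique Interactions",
                     "Common Interactions"))
  for (lg in unique(partition$ligand)) {
    p <- partition[partition$ligand == lg, ]
    uni <- p$residue[p$category == "unique"]
    com <- p[p$category != "unique", ]
    com <- com[order(com$category, com$residue), ]
    nrows <- max(length(uni), nrow(com), 1)
    for (i in seq_len(nrows)) {
      lines <- c(lines, sprintf("%-14s%-24s%s",
        if (i == 1) lg else "",
        if (i <= length(uni)) uni[i] else "",
        if (i <= nrow(com)) paste0(com$residue[i], "  (", com$category[i], ")") else ""))
    }
  }
  lines
}
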