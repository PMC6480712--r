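# chi1 extraction, cis/trans pseudo-state classification and occupancy,
# ligand-pose stability windows, trace summaries.
#
# "cis" and "trans" here are the pseudo-states of the chi1 torsion
# N-CA-CB-CG centered near 300 and 180 degrees respectively, split at a
# 240-degree threshold with the tie (exactly 240) assigned to trans:
# cis iff chi1 > threshold.

#' Default chi1 cis/trans split, degrees
#' @export
ROTAMER_THRESHOLD <- 240

#' chi1 torsion trace of one residue
#'
#' chi1 is the N-CA-CB-CG dihedral, reported on [0, 360).
#'
#' @param traj a `md_trajectory`.
#' @param chain,resSeq residue identity; alternatively pass `bw_id` with a
#'   map.
#' @param bw optional [bw_map()]; used both to resolve `bw_id` and to
#'   annotate the result.
#' @param bw_id generic label (e.g. "5.48") instead of chain/resSeq.
#' @return tibble of class `chi1_trace`: `frame`, `time`, `chi1`
#'   (degrees); residue descriptors in attributes.
#' @export
chi1_trace <- function(traj, chain = NULL, resSeq = NULL, bw = NULL, bw_id = NULL) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (!is.null(bw_id)) {
    hit <- bw_resolve(bw, bw_id, chain = chain)
    chain <- hit$chainId; resSeq <- hit$resSeq
  }
  if (is.null(chain) || is.null(resSeq)) abort("give chain+resSeq or bw_id")
  at <- atoms(traj)
  res <- which(at$chainId == chain & at$resSeq == resSeq)
  if (length(res) == 0) abort(sprintf("residue %s:%d not in topology", chain, resSeq))
  idx <- integer(4)
  need <- c("N", "CA", "CB", "CG")
  for (i in seq_along(need)) {
    hit <- res[toupper(at$name[res]) == need[i]]
    if (length(hit) == 0) {
      abort(sprintf("residue %s:%d lacks atom %s (chi1 undefined)",
                    chain, resSeq, need[i]))
    }
    idx[i] <- hit[1]
  }
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    m <- coords_matrix(traj, f, idx)
    dihedral_angle(m[1, ], m[2, ], m[3, ], m[4, ])
  }, numeric(1))
  out <- tibble::tibble(frame = seq_len(n_frames(traj)), time = traj$times,
                        chi1 = vals)
  attr(out, "residue") <- list(chainId = chain, resSeq = resSeq,
                               resName = at$resName[idx[1]],
                               bw = bw_label_safe(bw, chain, resSeq))
  class(out) <- c("chi1_trace", class(out))
  out
}

#' Classify chi1 angles into cis/trans pseudo-states
#'
#' cis if angle > threshold, trans otherwise (the tie at exactly the
#' threshold is trans). Angles must already be wrapped to [0, 360);
#' use `wrap_angle()` first if needed.
#'
#' @param angle numeric vector of angles, degrees in [0, 360).
#' @param threshold split point, degrees (default 240).
#' @return character vector of "cis"/"trans".
#' @export
classify_rotamer <- function(angle, threshold = ROTAMER_THRESHOLD) {
  if (any(!is.finite(angle)) || any(angle < 0 | angle >= 360)) {
    abort("angles must lie in [0, 360); wrap them first")
  }
  ifelse(angle > threshold, "cis", "trans")
}

#' @rdname classify_rotamer
#' @param x numeric angles in degrees (any range).
#' @export
wrap_angle <- function(x) x %% 360

#' Per-frame rotamer states of a chi1 trace
#'
#' @param trace a [chi1_trace()].
#' @inheritParams classify_rotamer
#' @return the trace tibble with a `state` column, class `rotamer_states`;
#'   the threshold is recorded as an attribute.
#' @export
rotamer_states <- function(trace, threshold = ROTAMER_THRESHOLD) {
  stopifnot(inherits(trace, "chi1_trace") || all(c("time", "chi1") %in% names(trace)))
  out <- tibble::as_tibble(trace)
  out$state <- classify_rotamer(out$chi1, threshold)
  attr(out, "residue") <- attr(trace, "residue")
  attr(out, "threshold") <- threshold
  class(out) <- c("rotamer_states", class(out))
  out
}

# frames with time inside [window[1], window[2]] (inclusive)
frames_in_window <- function(times, window = NULL) {
  if (is.null(window)) return(seq_along(times))
  stopifnot(length(window) == 2)
  which(times >= window[1] & times <= window[2])
}

#' Cis/trans occupancy over a time window
#'
#' Fractions are frame counts in the window divided by the total frame
#' count, so `fraction_cis + fraction_trans == 1` exactly.
#'
#' @param states a [rotamer_states()] tibble.
#' @param window `c(t_start, t_end)` in ns, or NULL for the full trace.
#' @return one-row tibble: residue descriptors, window bounds,
#'   `n_frames`, `n_cis`, `n_trans`, `fraction_cis`, `fraction_trans`.
#' @export
state_occupancy <- function(states, window = NULL) {
  stopifnot(inherits(states, "rotamer_states"))
  keep <- frames_in_window(states$time, window)
  if (length(keep) == 0) abort("window overlaps no frames")
  st <- states$state[keep]
  res <- attr(states, "residue")
  n_cis <- sum(st == "cis")
  tibble::tibble(
    chainId = res$chainId %||% NA_character_,
    resSeq = res$resSeq %||% NA_integer_,
    resName = res$resName %||% NA_character_,
    bw = res$bw %||% NA_character_,
    t_start = states$time[keep[1]],
    t_end = states$time[keep[length(keep)]],
    n_frames = length(st),
    n_cis = n_cis,
    n_trans = length(st) - n_cis,
    fraction_cis = n_cis / length(st),
    fraction_trans = (length(st) - n_cis) / length(st))
}

#' Ligand-pose stability window
#'
#' Given an RMSD-to-final-conformation trace, the onset is the time of
#' the earliest frame from which every later frame (itself included)
#' stays strictly below the threshold. The final frame always qualifies,
#' so an onset always exists.
#'
#' @param trace an [rmsd_trace()] computed against the final frame.
#' @param threshold Angstrom (default 3.0).
#' @return one-row tibble of class `stability_window`: `onset` (ns),
#'   `onset_frame`, `t_end`, `threshold`, `n_stable` frames.
#' @export
stability_onset <- function(trace, threshold = 3.0) {
  stopifnot(all(c("time", "rmsd") %in% names(trace)), nrow(trace) > 0)
  viol <- which(trace$rmsd >= threshold)
  k <- if (length(viol) == 0) 1L else max(viol) + 1L
  if (k > nrow(trace)) k <- nrow(trace)   # final frame qualifies by definition
  out <- tibble::tibble(onset = trace$time[k], onset_frame = k,
                        t_end = trace$time[nrow(trace)],
                        threshold = threshold,
                        n_stable = nrow(trace) - k + 1L)
  class(out) <- c("stability_window", class(out))
  out
}

#' Mean and population SD of a trace over a window
#'
#' For angular traces use `circular = TRUE`: the mean is the circular
#' mean mapped to [0, 360) and the SD the circular standard deviation
#' (both in degrees), which behave correctly across the 0/360 seam.
#'
#' @param x an `rmsd_trace`/`chi1_trace` tibble or a numeric vector.
#' @param window `c(t_start, t_end)` ns (traces only).
#' @param circular treat values as angles in degrees.
#' @return one-row tibble: `mean`, `sd`, `n`.
#' @export
summarize_trace <- function(x, window = NULL, circular = FALSE) {
  if (is.data.frame(x)) {
    col <- intersect(c("rmsd", "chi1", "value", "dist", "energy"), names(x))[1]
    if (is.na(col)) abort("no numeric trace column found")
    keep <- frames_in_window(x$time, window)
    v <- x[[col]][keep]
  } else {
    v <- as.numeric(x)
  }
  if (length(v) < 2) abort("need at least 2 frames to summarize")
  if (circular) {
    rad <- v * pi / 180
    s <- mean(sin(rad)); c <- mean(cos(rad))
    mu <- (atan2(s, c) * 180 / pi) %% 360
    if (mu >= 360 - 1e-9) mu <- 0
    rbar <- min(1, sqrt(s^2 + c^2))
    sdv <- sqrt(-2 * log(max(rbar, .Machine$double.xmin))) * 180 / pi
    tibble::tibble(mean = mu, sd = sdv, n = length(v))
  } else {
    tibble::tibble(mean = mean(v),
                   sd = sqrt(mean((v - mean(v))^2)),  # population SD
                   n = length(v))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
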