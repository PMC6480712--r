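#' @importFrom rlang .data abort
#' @import tibble
NULL

#' Molecular structure and trajectory containers
#'
#' A `md_structure` holds an atoms tibble (one row per atom) with columns
#' `serial`, `name`, `element`, `resName`, `resSeq`, `chainId`, `het`,
#' `x`, `y`, `z` (coordinates in Angstrom). A `md_trajectory` holds a
#' `md_structure` topology plus a `T x N x 3` coordinate array and a
#' strictly increasing time vector in nanoseconds.
#'
#' @param atoms a data frame of atom records (see Details).
#' @return `md_structure()` returns a validated object of class
#'   `md_structure`.
#' @details Invariants enforced at construction: non-empty element symbols,
#'   finite coordinates, and uniqueness of `(chainId, resSeq, name)` so a
#'   residue never carries two atoms of the same name.
#' @examples
#' s <- md_structure(tibble::tibble(
#'   serial = 1:2, name = c("CA", "CB"), element = "C",
#'   resName = "ALA", resSeq = 1L, chainId = "A", het = FALSE,
#'   x = c(0, 1.5), y = 0, z = 0))
#' n_atoms(s)
#' @export
md_structure <- function(atoms) {
  atoms <- tibble::as_tibble(atoms)
  req <- c("serial", "name", "element", "resName", "resSeq", "chainId", "x", "y", "z")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atoms table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!"het" %in% names(atoms)) atoms$het <- FALSE
  atoms$serial <- as.integer(atoms$serial)
  atoms$resSeq <- as.integer(atoms$resSeq)
  if (nrow(atoms) > 0) {
    if (any(is.na(atoms$element) | atoms$element == "")) {
      abort("every atom needs a non-empty element symbol")
    }
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    if (!all(is.finite(xyz))) abort("non-finite coordinates in atoms table")
    key <- paste(atoms$chainId, atoms$resSeq, toupper(atoms$name))
    if (anyDuplicated(key)) {
      abort(paste0("duplicate atom within a residue: ", key[duplicated(key)][1]))
    }
  }
  structure(list(atoms = atoms), class = "md_structure")
}

#' @rdname md_structure
#' @param topology a `md_structure` giving atom metadata.
#' @param coords numeric array `T x N x 3`, Angstrom.
#' @param times numeric vector of frame times, ns, strictly increasing.
#' @export
md_trajectory <- function(topology, coords, times) {
  stopifnot(inherits(topology, "md_structure"))
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3) {
    abort("coords must be a T x N x 3 array")
  }
  n <- n_atoms(topology)
  if (dim(coords)[2] != n) {
    abort(sprintf("coords has %d atoms per frame but topology has %d",
                  dim(coords)[2], n))
  }
  if (length(times) != dim(coords)[1]) abort("times length must equal frame count")
  if (length(times) > 1 && any(diff(times) <= 0)) {
    abort("frame times must be strictly increasing")
  }
  if (!all(is.finite(coords))) abort("non-finite coordinates in trajectory")
  structure(list(topology = topology, coords = coords, times = as.numeric(times)),
            class = "md_trajectory")
}

#' @rdname md_structure
#' @param x a structure or trajectory.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "md_trajectory")) return(nrow(x$topology$atoms))
  nrow(x$atoms)
}

#' @rdname md_structure
#' @export
n_frames <- function(x) {
  if (inherits(x, "md_trajectory")) return(dim(x$coords)[1])
  1L
}

#' Extract coordinates as a numeric matrix
#'
#' @param x a `md_structure` or `md_trajectory`.
#' @param frame frame index (1-based) for trajectories; ignored for
#'   structures.
#' @param sel optional integer vector of atom indices.
#' @return an `N x 3` matrix in Angstrom.
#' @export
coords_matrix <- function(x, frame = 1L, sel = NULL) {
  if (inherits(x, "md_trajectory")) {
    if (frame < 1 || frame > n_frames(x)) abort("frame index out of range")
    m <- x$coords[frame, , , drop = FALSE]
    dim(m) <- dim(x$coords)[2:3]
  } else if (inherits(x, "md_structure")) {
    m <- as.matrix(x$atoms[, c("x", "y", "z")])
    dimnames(m) <- NULL
  } else {
    abort("expected a md_structure or md_trajectory")
  }
  if (!is.null(sel)) m <- m[sel, , drop = FALSE]
  m
}

#' @rdname coords_matrix
#' @export
get_frame <- function(x, frame = 1L) {
  if (inherits(x, "md_structure")) return(x)
  m <- coords_matrix(x, frame)
  at <- x$topology$atoms
  at$x <- m[, 1]; at$y <- m[, 2]; at$z <- m[, 3]
  md_structure(at)
}

#' Atom metadata table
#'
#' @param x a structure or trajectory.
#' @return the atoms tibble (topology atoms for a trajectory).
#' @export
atoms <- function(x) {
  if (inherits(x, "md_trajectory")) x$topology$atoms else x$atoms
}

#' @export
print.md_structure <- function(x, ...) {
  cat(sprintf("<md_structure> %d atoms, %d residues, chains: %s\n",
              n_atoms(x),
              nrow(unique(x$atoms[, c("chainId", "resSeq")])),
              paste(unique(x$atoms$chainId), collapse = " ")))
  invisible(x)
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory> %d frames x %d atoms, %.3f-%.3f ns\n",
              n_frames(x), n_atoms(x),
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}
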