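# PDB fixed-column reader/writer. Columns follow the wwPDB v3 convention:
# serial 7-11, name 13-16, resName 18-20, chainId 22, resSeq 23-26,
# x/y/z 31-38/39-46/47-54, element 77-78. MODEL/ENDMDL delimit frames.

#' Read a PDB file as a structure or trajectory
#'
#' Files without `MODEL` records yield a [md_structure()]; multi-MODEL
#' files yield a [md_trajectory()] whose frames are the MODEL blocks in
#' order. Atom metadata is taken from the first model; all models must
#' contain the same number of atoms in the same order.
#'
#' @param path path to a PDB file.
#' @param dt time step between MODEL frames, ns (PDB carries no time
#'   axis; defaults to 1 ns/frame).
#' @return a `md_structure` or `md_trajectory`.
#' @export
read_pdb <- function(path, dt = 1) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- startsWith(rec, "MODEL")
  is_end <- startsWith(rec, "ENDMDL")

  parse_block <- function(idx) {
    ln <- lines[idx]
    num <- function(a, b, what) {
      v <- suppressWarnings(as.numeric(trimws(substr(ln, a, b))))
      bad <- which(!is.finite(v))
      if (length(bad) > 0) {
        abort(sprintf("unparsable %s field at line %d", what, idx[bad[1]]))
      }
      v
    }
    name <- trimws(substr(ln, 13, 16))
    element <- trimws(substr(ln, 77, 78))
    # infer element from the atom name when column 77-78 is blank
    noel <- element == ""
    if (any(noel)) {
      guess <- toupper(sub("^[0-9]*", "", name[noel]))
      element[noel] <- substr(guess, 1, 1)
      two <- substr(guess, 1, 2) %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE")
      element[noel][two] <- substr(guess[two], 1, 2)
    }
    tibble::tibble(
      serial = as.integer(num(7, 11, "serial")),
      name = name,
      element = element,
      resName = trimws(substr(ln, 18, 20)),
      resSeq = as.integer(num(23, 26, "resSeq")),
      chainId = substr(ln, 22, 22),
      het = substr(ln, 1, 6) == "HETATM",
      x = num(31, 38, "x coordinate"),
      y = num(39, 46, "y coordinate"),
      z = num(47, 54, "z coordinate"))
  }

  if (!any(is_model)) {
    return(md_structure(parse_block(which(is_atom))))
  }

  model_starts <- which(is_model)
  model_ends <- which(is_end)
  if (length(model_ends) < length(model_starts)) {
    model_ends <- c(model_ends, length(lines) + 1L)
  }
  blocks <- lapply(seq_along(model_starts), function(i) {
    span <- seq(model_starts[i] + 1L, model_ends[i] - 1L)
    span[is_atom[span]]
  })
  n0 <- length(blocks[[1]])
  for (i in seq_along(blocks)) {
    if (length(blocks[[i]]) != n0) {
      abort(sprintf("MODEL %d has %d atoms; MODEL 1 has %d",
                    i, length(blocks[[i]]), n0))
    }
  }
  topo <- md_structure(parse_block(blocks[[1]]))
  tt <- length(blocks)
  coords <- array(NA_real_, c(tt, n0, 3))
  coords[1, , ] <- coords_matrix(topo)
  if (tt > 1) {
    for (i in 2:tt) {
      b <- parse_block(blocks[[i]])
      coords[i, , ] <- as.matrix(b[, c("x", "y", "z")])
    }
  }
  md_trajectory(topo, coords, times = (seq_len(tt) - 1) * dt)
}

#' Write a structure or trajectory as PDB
#'
#' Trajectories are written as MODEL/ENDMDL blocks. Coordinates must fit
#' the `%8.3f` fixed columns (|x| < 10^4 Angstrom).
#'
#' @param x a `md_structure` or `md_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  fmt_frame <- function(at) {
    xyz <- as.matrix(at[, c("x", "y", "z")])
    if (any(abs(xyz) >= 1e4)) {
      abort("coordinate magnitude >= 10^4 Angstrom cannot be written in PDB columns")
    }
    # 4-char names start in column 13, shorter ones in column 14
    nm <- ifelse(nchar(at$name) >= 4, substr(at$name, 1, 4),
                 sprintf(" %-3s", at$name))
    sprintf("%-6s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            ifelse(at$het, "HETATM", "ATOM"),
            at$serial %% 100000L, nm, at$resName, at$chainId, at$resSeq %% 10000L,
            xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, at$element)
  }
  out <- character(0)
  if (inherits(x, "md_trajectory")) {
    at <- x$topology$atoms
    for (i in seq_len(n_frames(x))) {
      m <- coords_matrix(x, i)
      at$x <- m[, 1]; at$y <- m[, 2]; at$z <- m[, 3]
      out <- c(out, sprintf("MODEL     %4d", i), fmt_frame(at), "ENDMDL")
    }
  } else if (inherits(x, "md_structure")) {
    if (n_atoms(x) > 0) out <- fmt_frame(x$atoms)
  } else {
    abort("expected a md_structure or md_trajectory")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}
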