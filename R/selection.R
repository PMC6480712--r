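# Atom selection mini-language.
#
# Grammar (case-insensitive):
#   selection := clause ("and" clause)*
#   clause    := "chain" id+ | "resid" range+ | "resname" id+ |
#                "name" id+ | "element" id+ | "segment" id+ |
#                "bw" label+ | "backbone" | "sidechain" | "heavy" |
#                "protein" | "hetero" | "all"
#   range     := INT | INT":"INT
# Values within a clause are alternatives (OR); clauses are intersected
# (AND). "backbone" means atoms named N, CA, C, O; "heavy" drops
# hydrogens; "hetero"/"protein" split on the HETATM record flag.
# "bw" and "segment" need a Ballesteros-Weinstein map.

#' Select atoms with a VMD-like selection string
#'
#' @param x a `md_structure` or `md_trajectory`.
#' @param sel selection string (see the grammar in the package vignette),
#'   or an integer/logical vector used as-is.
#' @param bw optional [bw_map()] enabling `bw` and `segment` clauses.
#' @return integer vector of atom indices (1-based, in topology order).
#' @examples
#' s <- build_toy_protomer()
#' length(select_atoms(s$structure, "backbone and segment TM5", bw = s$bw))
#' select_atoms(s$structure, "bw 5.48 and name CA", bw = s$bw)
#' @export
select_atoms <- function(x, sel, bw = NULL) {
  at <- atoms(x)
  if (is.logical(sel)) {
    stopifnot(length(sel) == nrow(at))
    return(which(sel))
  }
  if (is.numeric(sel)) {
    sel <- as.integer(sel)
    if (any(sel < 1 | sel > nrow(at))) abort("atom index out of range")
    return(sel)
  }
  stopifnot(is.character(sel), length(sel) == 1)
  toks <- strsplit(trimws(tolower(sel)), "[[:space:]]+")[[1]]
  if (length(toks) == 0 || toks[1] == "") abort("empty selection string")
  keywords <- c("chain", "resid", "resname", "name", "element", "segment",
                "bw", "backbone", "sidechain", "heavy", "protein", "hetero", "all")
  # split on "and"
  groups <- split(toks, cumsum(toks == "and"))
  mask <- rep(TRUE, nrow(at))
  seg_label <- function() {
    if (is.null(bw)) abort("selection uses 'bw'/'segment' but no bw map given")
    key <- paste(bw$chainId, bw$resSeq)
    match(paste(at$chainId, at$resSeq), key)
  }
  for (g in groups) {
    g <- g[g != "and"]
    if (length(g) == 0) abort("dangling 'and' in selection")
    kw <- g[1]
    vals <- g[-1]
    if (!kw %in% keywords) abort(paste0("unknown selection keyword: ", kw))
    if (kw %in% c("backbone", "sidechain", "heavy", "protein", "hetero", "all") &&
        length(vals) > 0) {
      abort(paste0("'", kw, "' takes no values"))
    }
    m <- switch(kw,
      all = rep(TRUE, nrow(at)),
      chain = tolower(at$chainId) %in% vals,
      resname = tolower(at$resName) %in% vals,
      name = tolower(at$name) %in% vals,
      element = tolower(at$element) %in% vals,
      backbone = toupper(at$name) %in% c("N", "CA", "C", "O"),
      sidechain = !(toupper(at$name) %in% c("N", "CA", "C", "O", "OXT")) & !at$het,
      heavy = toupper(at$element) != "H",
      protein = !at$het,
      hetero = at$het,
      resid = {
        if (length(vals) == 0) abort("'resid' needs at least one value")
        ok <- rep(FALSE, nrow(at))
        for (v in vals) {
          if (grepl(":", v, fixed = TRUE)) {
            ab <- as.integer(strsplit(v, ":", fixed = TRUE)[[1]])
            if (any(is.na(ab)) || length(ab) != 2) abort(paste0("bad resid range: ", v))
            ok <- ok | (at$resSeq >= min(ab) & at$resSeq <= max(ab))
          } else {
            iv <- suppressWarnings(as.integer(v))
            if (is.na(iv)) abort(paste0("bad resid value: ", v))
            ok <- ok | at$resSeq == iv
          }
        }
        ok
      },
      segment = {
        idx <- seg_label()
        tolower(bw$segment)[idx] %in% vals & !is.na(idx)
      },
      bw = {
        idx <- seg_label()
        lab <- tolower(bw$bw)[idx]
        !is.na(lab) & lab %in% vals
      })
    if (kw %in% c("chain", "resname", "name", "element") && length(vals) == 0) {
      abort(paste0("'", kw, "' needs at least one value"))
    }
    mask <- mask & m
  }
  which(mask)
}
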