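# Ballesteros-Weinstein residue numbering support. Class-A GPCR residues
# are referred to by helix.position generic labels (e.g. "5.48" is the
# 48th position of TM5); loop residues carry a segment tag instead.

.bw_segments <- c(paste0("TM", 1:7), paste0("ECL", 1:3), paste0("ICL", 1:3), "other")

#' Build or load a Ballesteros-Weinstein residue map
#'
#' `bw_map()` validates a table with columns `chainId`, `resSeq`, `bw`
#' (generic label such as "5.48", may be `NA` for loop residues) and
#' `segment` (one of TM1..TM7, ECL1..3, ICL1..3, other).
#' `load_bw_map()` reads the same table from a tab-separated file; a
#' header line is detected automatically and `#` lines are skipped.
#'
#' @param x data frame with the four columns above.
#' @return a tibble of class `bw_map`.
#' @examples
#' m <- bw_map(data.frame(chainId = "A", resSeq = c(199L, 390L),
#'                        bw = c("5.48", "6.52"), segment = c("TM5", "TM6")))
#' bw_resolve(m, "5.48")
#' @export
bw_map <- function(x) {
  x <- tibble::as_tibble(x)
  req <- c("chainId", "resSeq", "bw", "segment")
  if (!all(req %in% names(x))) {
    abort(paste0("bw map needs columns: ", paste(req, collapse = ", ")))
  }
  x$resSeq <- as.integer(x$resSeq)
  x$bw <- as.character(x$bw)
  x$bw[x$bw %in% c("", "NA", "-", ".")] <- NA_character_
  bad <- setdiff(unique(x$segment), .bw_segments)
  if (length(bad) > 0) {
    abort(paste0("unknown segment id(s): ", paste(bad, collapse = ", ")))
  }
  lab <- x$bw[!is.na(x$bw)]
  ch <- x$chainId[!is.na(x$bw)]
  if (anyDuplicated(paste(ch, lab))) {
    abort(paste0("duplicate BW label within a chain: ",
                 paste(ch, lab)[duplicated(paste(ch, lab))][1]))
  }
  if (anyDuplicated(paste(x$chainId, x$resSeq))) {
    abort("duplicate residue in bw map")
  }
  class(x) <- c("bw_map", class(x))
  x
}

#' @rdname bw_map
#' @param path tab-separated file: chain, resSeq, BW label, segment.
#' @export
load_bw_map <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(bw_map(tibble::tibble(chainId = character(), resSeq = integer(),
                                 bw = character(), segment = character())))
  }
  fields <- strsplit(lines, "\t")
  first <- fields[[1]]
  has_header <- is.na(suppressWarnings(as.integer(first[2])))
  if (has_header) fields <- fields[-1]
  tab <- tibble::tibble(
    chainId = vapply(fields, `[`, "", 1),
    resSeq = as.integer(vapply(fields, `[`, "", 2)),
    bw = vapply(fields, `[`, "", 3),
    segment = vapply(fields, `[`, "", 4))
  bw_map(tab)
}

#' Resolve a BW label to a residue, or a residue to its label
#'
#' @param map a `bw_map`.
#' @param label generic label, e.g. "5.48".
#' @param chain optional chain restriction.
#' @return `bw_resolve()`: one-row tibble with `chainId` and `resSeq`
#'   (errors if the label is absent or ambiguous across chains);
#'   `bw_label()`: the label string (or the segment tag for unlabeled
#'   loop residues).
#' @export
bw_resolve <- function(map, label, chain = NULL) {
  stopifnot(inherits(map, "bw_map"))
  hit <- map[!is.na(map$bw) & map$bw == label, ]
  if (!is.null(chain)) hit <- hit[hit$chainId %in% chain, ]
  if (nrow(hit) == 0) abort(paste0("BW label not in map: ", label))
  if (is.null(chain) && length(unique(hit$chainId)) > 1) {
    abort(paste0("BW label ", label, " matches several chains; pass `chain`"))
  }
  hit[1, c("chainId", "resSeq")]
}

#' @rdname bw_resolve
#' @param resSeq residue number.
#' @export
bw_label <- function(map, chain, resSeq) {
  stopifnot(inherits(map, "bw_map"))
  hit <- map[map$chainId == chain & map$resSeq == resSeq, ]
  if (nrow(hit) == 0) abort(sprintf("residue %s:%d not in bw map", chain, resSeq))
  if (is.na(hit$bw[1])) hit$segment[1] else hit$bw[1]
}

#' @rdname bw_map
#' @param map a `bw_map` to write.
#' @export
write_bw_map <- function(map, path) {
  stopifnot(inherits(map, "bw_map"))
  header <- "chainId\tresSeq\tbw\tsegment"
  body <- sprintf("%s\t%d\t%s\t%s", map$chainId, map$resSeq,
                  ifelse(is.na(map$bw), "NA", map$bw), map$segment)
  writeLines(c(header, body), path)
  invisible(path)
}

# vectorized label lookup used by report builders; residues outside the
# map come back NA rather than erroring
bw_label_safe <- function(map, chain, resSeq) {
  if (is.null(map)) return(rep(NA_character_, length(resSeq)))
  key <- paste(map$chainId, map$resSeq)
  lab <- ifelse(is.na(map$bw), map$segment, map$bw)
  lab[match(paste(chain, resSeq), key)]
}
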