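#' Atom/residue selection specification
#'
#' Selections name a set of residues (1-based sequence numbers, inclusive
#' ranges) and an atom-name filter, and are resolved lazily against a
#' topology. This mirrors how analysis regions are declared throughout the
#' package: e.g. loop 5 of human kinesin-5 is `sel_spec("116-134")`, the
#' P-loop `sel_spec("105-112")`, the alpha-2 anchor
#' `sel_spec("111-116,135-140", atoms = "backbone")`.
#'
#' @param residues residue numbers as an integer vector, or a compact range
#'   string such as `"111-116,135-140"` (both ends inclusive). `NULL` selects
#'   all residues.
#' @param atoms one of `"CA"` (alpha carbons), `"backbone"` (N, CA, C, O),
#'   `"all"`, or a character vector of PDB atom names.
#' @return an object of class `kin_selection`.
#' @examples
#' sel_spec("105-112")                        # P-loop, CA only
#' sel_spec(111:140, atoms = "backbone")
#' @export
sel_spec <- function(residues = NULL, atoms = "CA") {
  if (is.character(residues) && length(residues) == 1L) {
    residues <- parse_ranges(residues)
  }
  if (!is.null(residues)) {
    residues <- as.integer(residues)
    if (anyNA(residues)) stop("residue numbers must be integers")
  }
  stopifnot(is.character(atoms), length(atoms) >= 1L)
  structure(list(residues = residues, atoms = atoms), class = "kin_selection")
}

#' Parse a compact residue-range string
#'
#' @param txt e.g. `"111-116,135-140"` or `"127"`.
#' @return integer vector of residue numbers.
#' @export
parse_ranges <- function(txt) {
  parts <- strsplit(gsub("\\s", "", txt), ",")[[1]]
  out <- lapply(parts, function(p) {
    if (grepl("-", p)) {
      ab <- as.integer(strsplit(p, "-")[[1]])
      if (length(ab) != 2L || anyNA(ab) || ab[1] > ab[2]) {
        stop("malformed residue range: '", p, "'")
      }
      seq.int(ab[1], ab[2])
    } else {
      v <- as.integer(p)
      if (is.na(v)) stop("malformed residue number: '", p, "'")
      v
    }
  })
  unique(unlist(out))
}

#' @export
print.kin_selection <- function(x, ...) {
  res <- if (is.null(x$residues)) "all residues" else {
    paste0(length(x$residues), " residues")
  }
  cat("<kin_selection> ", res, "; atoms: ",
      paste(x$atoms, collapse = ","), "\n", sep = "")
  invisible(x)
}

backbone_names <- c("N", "CA", "C", "O")

#' Resolve a selection to atom indices of a topology
#'
#' @param top a `kin_structure` topology.
#' @param sel a `kin_selection` (or `NULL` for all atoms).
#' @return sorted, duplicate-free integer atom indices.
#' @details Insertion-coded residues are excluded from residue-range
#'   selections (their numbering is ambiguous against a 1-based range).
#' @export
resolve_selection <- function(top, sel = NULL) {
  stopifnot(inherits(top, "kin_structure"))
  at <- top$atoms
  keep <- rep(TRUE, nrow(at))
  if (is.null(sel)) return(which(keep))
  stopifnot(inherits(sel, "kin_selection"))
  if (!identical(sel$atoms, "all")) {
    names_want <- if (identical(sel$atoms, "CA")) "CA"
      else if (identical(sel$atoms, "backbone")) backbone_names
      else sel$atoms
    keep <- keep & at$elety %in% names_want
  }
  if (!is.null(sel$residues)) {
    keep <- keep & at$resno %in% sel$residues & !at$has_insert
  }
  inds <- which(keep)
  if (length(inds) == 0L) {
    stop("selection resolves to zero atoms (residues: ",
         if (is.null(sel$residues)) "all" else
           paste(range(sel$residues), collapse = "-"),
         "; atoms: ", paste(sel$atoms, collapse = ","), ")")
  }
  inds
}
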