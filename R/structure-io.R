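#' Construct a structure from an atom table
#'
#' Low-level constructor used by the PDB reader and the synthetic generators.
#'
#' @param atoms data frame with columns `elety` (atom name), `elesy` (element
#'   symbol), `resno` (1-based residue number), `resid` (residue name),
#'   `chain` (chain id), `x`, `y`, `z` (Angstrom). Optional: `o` (occupancy),
#'   `het` (logical HETATM flag), `has_insert` (logical).
#' @param source character label recording where the atoms came from.
#' @return object of class `kin_structure`.
#' @export
kin_structure <- function(atoms, source = "constructed") {
  need <- c("elety", "resno", "resid", "chain", "x", "y", "z")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols)) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(atoms$elesy)) atoms$elesy <- substr(atoms$elety, 1, 1)
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$het)) atoms$het <- FALSE
  if (is.null(atoms$has_insert)) atoms$has_insert <- FALSE
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("non-finite coordinates in atom table")
  atoms$eleno <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, source = source), class = "kin_structure")
}

#' @export
print.kin_structure <- function(x, ...) {
  rt <- residue_table(x)
  cat("<kin_structure> ", nrow(x$atoms), " atoms, ", nrow(rt), " residues, ",
      length(unique(x$atoms$chain)), " chain(s) [", x$source, "]\n", sep = "")
  invisible(x)
}

#' Ordered residue table of a structure
#'
#' @param top a `kin_structure`.
#' @return data frame with one row per residue: `chain`, `resno`, `resid`,
#'   `het`, in atom order.
#' @export
residue_table <- function(top) {
  stopifnot(inherits(top, "kin_structure"))
  at <- top$atoms
  key <- paste(at$chain, at$resno, at$resid, sep = "\r")
  first <- !duplicated(key)
  data.frame(chain = at$chain[first], resno = at$resno[first],
             resid = at$resid[first], het = at$het[first],
             stringsAsFactors = FALSE)
}

#' Number of atoms in a structure or trajectory topology
#' @param x a `kin_structure` or `kin_trajectory`.
#' @export
natoms <- function(x) {
  if (inherits(x, "kin_trajectory")) x <- x$top
  nrow(x$atoms)
}

#' Load a structure from a PDB file
#'
#' Reads one model of a PDB file, optionally restricted to one chain.
#' Alternate locations are resolved to the highest-occupancy copy of each
#' atom. Waters and other heteroatoms are retained but flagged in the atom
#' table (`het` column) so that protein-only selections exclude them by atom
#' name.
#'
#' @param path PDB file.
#' @param model model number (1-based) for multi-model files.
#' @param chain chain identifier, or `NULL` for all chains.
#' @return a `kin_structure`.
#' @export
load_structure <- function(path, model = 1L, chain = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  nmodels <- nrow(pdb$xyz)
  if (model < 1L || model > nmodels) {
    stop("model ", model, " not present; file has model(s) ",
         paste(seq_len(nmodels), collapse = ", "))
  }
  at <- pdb$atom
  coords <- xyz2mat(pdb$xyz[model, ])
  at$x <- coords[, 1]; at$y <- coords[, 2]; at$z <- coords[, 3]

  chains <- unique(at$chain)
  if (!is.null(chain)) {
    if (!chain %in% chains) {
      stop("chain '", chain, "' not found; available chains: ",
           paste(chains, collapse = ", "))
    }
    at <- at[at$chain == chain, , drop = FALSE]
  }

  # altloc: keep the highest-occupancy copy of each (chain, resno, insert, name)
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    ins <- at$insert; ins[is.na(ins)] <- ""
    key <- paste(at$chain, at$resno, ins, at$elety, sep = "\r")
    occ <- at$o; occ[is.na(occ)] <- 1
    ord <- order(key, -occ)
    at <- at[ord, , drop = FALSE][!duplicated(sort(key)), , drop = FALSE]
    at <- at[order(at$eleno), , drop = FALSE]
  }

  ins <- at$insert
  has_insert <- !(is.na(ins) | ins == "")
  water_names <- c("HOH", "WAT", "TIP3", "TIP4", "SPC")
  out <- data.frame(
    elety = at$elety, elesy = at$elesy %||% substr(at$elety, 1, 1),
    resno = at$resno, resid = at$resid, chain = at$chain,
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o),
    het = at$type == "HETATM" | at$resid %in% water_names,
    has_insert = has_insert,
    stringsAsFactors = FALSE
  )
  kin_structure(out, source = basename(path))
}

#' Write a structure (or one trajectory frame) to a PDB file
#'
#' @param top a `kin_structure`.
#' @param path output file.
#' @param xyz optional replacement coordinates (flat vector, length 3*natoms),
#'   e.g. a trajectory frame or a cluster centroid.
#' @export
write_structure <- function(top, path, xyz = NULL) {
  stopifnot(inherits(top, "kin_structure"))
  at <- top$atoms
  if (is.null(xyz)) xyz <- mat2xyz(as.matrix(at[, c("x", "y", "z")]))
  stopifnot(length(xyz) == 3L * nrow(at))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = ifelse(at$het, "HETATM", "ATOM"),
                   resno = at$resno, resid = at$resid, eleno = at$eleno,
                   elety = at$elety, chain = at$chain, o = at$o,
                   elesy = at$elesy)
  invisible(path)
}
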