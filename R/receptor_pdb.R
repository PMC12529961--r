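# Receptor container and a minimal PDB reader/writer for C-alpha bead models.
# Only ATOM records of the first model are used; alternate locations other
# than blank/'A' are skipped. Fixed-width output follows PDB v3.3 columns.

#' Receptor bead model
#'
#' One bead per residue at the C-alpha coordinate.
#'
#' @param types character vector of one-letter residue codes.
#' @param coords numeric matrix `n x 3` of coordinates in Angstrom.
#' @param id free-text identifier.
#' @param labels optional free-text per-bead annotation (used by fixtures
#'   to mark pocket core vs rim beads).
#' @return Object of class `receptor`.
#' @export
receptor <- function(types, coords, id = "receptor", labels = NULL) {
  coords <- as.matrix(coords)
  stopifnot(length(types) == nrow(coords), ncol(coords) == 3,
            all(is.finite(coords)))
  structure(list(types = as.character(types), coords = unname(coords),
                 id = id, labels = labels), class = "receptor")
}

#' @export
print.receptor <- function(x, ...) {
  cat("<receptor>", x$id, "-", length(x$types), "C-alpha beads\n")
  invisible(x)
}

aa_three_to_one <- function(code3) {
  alpha <- residue_alphabet()
  m <- setNames(alpha$code, alpha$code3)
  out <- m[toupper(code3)]
  out
}

aa_one_to_three <- function(code1) {
  alpha <- residue_alphabet()
  setNames(alpha$code3, alpha$code)[code1]
}

#' Read a receptor from a PDB file
#'
#' Parses ATOM records of the first model, keeping one CA atom per residue
#' (altloc blank or 'A'). Residues with a three-letter code outside the
#' 20-type alphabet are dropped with a warning.
#'
#' @param path PDB file.
#' @param id identifier; defaults to the file name.
#' @return A [receptor()].
#' @export
read_receptor_pdb <- function(path, id = basename(path)) {
  lines <- readLines(path)
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1)]
  atoms <- lines[startsWith(lines, "ATOM  ")]
  if (!length(atoms)) stop("no ATOM records in ", path)
  name <- trimws(substr(atoms, 13, 16))
  altloc <- substr(atoms, 17, 17)
  keep <- name == "CA" & altloc %in% c(" ", "A")
  atoms <- atoms[keep]
  if (!length(atoms)) stop("no C-alpha atoms in ", path)
  res3 <- trimws(substr(atoms, 18, 20))
  x <- as.numeric(substr(atoms, 31, 38))
  y <- as.numeric(substr(atoms, 39, 46))
  z <- as.numeric(substr(atoms, 47, 54))
  types <- aa_three_to_one(res3)
  bad <- is.na(types)
  if (any(bad)) {
    warning("dropping ", sum(bad), " residues with non-standard codes")
    types <- types[!bad]; x <- x[!bad]; y <- y[!bad]; z <- z[!bad]
  }
  receptor(types, cbind(x, y, z), id = id)
}

#' Write C-alpha beads as a minimal PDB file
#'
#' @param types one-letter residue codes; @param coords `n x 3` matrix;
#' @param path output file; @param chain chain identifier.
#' @return The path, invisibly.
#' @export
write_beads_pdb <- function(types, coords, path, chain = "A") {
  coords <- as.matrix(coords)
  res3 <- aa_one_to_three(types)
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_along(types), res3, chain, seq_along(types),
    coords[, 1], coords[, 2], coords[, 3])
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' @rdname write_beads_pdb
#' @param x a [receptor()].
#' @export
write_receptor_pdb <- function(x, path) {
  write_beads_pdb(x$types, x$coords, path)
}
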