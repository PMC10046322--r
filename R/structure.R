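# Structure container and PDB reading/writing.  Reading is delegated to
# bio3d::read.pdb; a light pre-scan adds line-numbered errors for malformed
# ATOM/HETATM records.  Author (PDB) residue numbering is used throughout.

#' Create a Structure from an atom table
#'
#' The atom table is the single source of truth for geometry and numbering:
#' one row per atom with columns `chain`, `resno` (author numbering),
#' `resname` (3-letter), `name` (atom name), `element`, `het` (HETATM flag),
#' `x`, `y`, `z` (Angstrom) and `b` (B-factor, reused for annotations).
#'
#' @param atoms data.frame as described above.
#' @param title Free-text title.
#' @return An object of class `Structure`.
#' @export
new_structure <- function(atoms, title = "") {
  required <- c("chain", "resno", "resname", "name", "element", "x", "y", "z")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0)
    stop("atom table lacks column(s): ", paste(missing, collapse = ", "))
  if (is.null(atoms$het)) atoms$het <- FALSE
  if (is.null(atoms$b)) atoms$b <- 0
  atoms$resno <- as.integer(atoms$resno)
  if (anyNA(atoms[required]))
    stop("atom table contains NA in a required column")
  if (!all(is.finite(as.matrix(atoms[c("x", "y", "z")]))))
    stop("all coordinates must be finite")
  key <- paste(atoms$chain, atoms$resno, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate (chain, resno, atom name) triple: ",
         key[which(duplicated(key))[1]])
  for (ch in unique(atoms$chain)) {
    r <- atoms$resno[atoms$chain == ch]
    if (is.unsorted(r))
      stop("residue numbers decrease within chain ", ch)
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, title = title), class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  cat("Structure:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), "residues\n")
  if (nzchar(x$title)) cat("  title:", x$title, "\n")
  invisible(x)
}

n_atoms <- function(structure) nrow(structure$atoms)

#' Coordinates of a Structure as an N x 3 matrix
#' @param structure A `Structure`.
#' @return Numeric matrix with one row per atom.
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

`coords<-` <- function(structure, value) {
  stopifnot(nrow(value) == n_atoms(structure))
  structure$atoms$x <- value[, 1]
  structure$atoms$y <- value[, 2]
  structure$atoms$z <- value[, 3]
  structure
}

# Pre-scan PDB text for coordinate fields that do not parse, so errors can
# name the offending line (bio3d reports neither line nor field).
.validate_pdb_lines <- function(lines, path) {
  rec <- substr(lines, 1, 6)
  idx <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(idx) == 0)
    stop("no ATOM/HETATM records found in '", path, "'")
  for (i in idx) {
    ln <- lines[i]
    for (col in list(c(31, 38), c(39, 46), c(47, 54))) {
      field <- substr(ln, col[1], col[2])
      if (is.na(suppressWarnings(as.numeric(field))))
        stop("malformed coordinate field in '", path, "' at line ", i,
             ": '", trimws(field), "'")
    }
  }
  idx
}

# Resolve alternate locations: keep, per (chain, resno, name), the record
# with highest occupancy; ties go to the first listed.
.resolve_altloc <- function(atom) {
  alt <- atom$alt
  alt[is.na(alt)] <- ""
  if (all(alt == "")) return(atom)
  occ <- atom$o
  occ[is.na(occ)] <- 1
  key <- paste(atom$chain, atom$resno, atom$elety)
  ord <- order(key, -occ, seq_len(nrow(atom)))
  keep <- ord[!duplicated(key[ord])]
  atom[sort(keep), , drop = FALSE]
}

.bio3d_atom_to_table <- function(atom) {
  element <- trimws(atom$elesy)
  guess <- toupper(substr(trimws(atom$elety), 1, 1))
  element[is.na(element) | element == ""] <- guess[is.na(element) | element == ""]
  data.frame(chain = ifelse(is.na(atom$chain), "A", atom$chain),
             resno = atom$resno,
             resname = atom$resid,
             name = trimws(atom$elety),
             element = element,
             het = atom$type == "HETATM",
             x = atom$x, y = atom$y, z = atom$z,
             b = ifelse(is.na(atom$b), 0, atom$b),
             stringsAsFactors = FALSE)
}

#' Read a structure from a PDB file
#'
#' Author residue numbering is preserved.  Alternate locations are resolved
#' to the highest-occupancy record (ties: first listed).  Files with
#' insertion codes are rejected to avoid silent misnumbering.  If the file
#' holds several MODELs only the first is returned (see [read_ensemble()]).
#'
#' @param path Path to a PDB file.
#' @return A `Structure`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty file: '", path, "'")
  .validate_pdb_lines(lines, path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  atom <- pdb$atom
  if (any(!is.na(atom$insert) & atom$insert != ""))
    stop("insertion codes are not supported (found in '", path, "')")
  atom <- .resolve_altloc(atom)
  title <- sub("^TITLE\\s+", "", grep("^TITLE", lines, value = TRUE)[1])
  if (is.na(title)) title <- ""
  new_structure(.bio3d_atom_to_table(atom), title = title)
}

.format_atom_lines <- function(atoms, serial = seq_len(nrow(atoms))) {
  rec <- ifelse(atoms$het, "HETATM", "ATOM  ")
  name4 <- ifelse(nchar(atoms$name) < 4 & nchar(atoms$element) == 1,
                  sprintf(" %-3s", atoms$name), sprintf("%-4s", atoms$name))
  sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, name4, atoms$resname, atoms$chain, atoms$resno,
          atoms$x, atoms$y, atoms$z, 1.00, atoms$b, atoms$element)
}

.pdb_header <- function(extra = character()) {
  c(sprintf("REMARK   generated by esterdyn %s",
            as.character(utils::packageVersion("esterdyn"))), extra)
}

#' Write a structure to a PDB file
#'
#' @param structure A `Structure`.
#' @param path Output path.
#' @param b Optional numeric vector (length = atoms) written to the B-factor
#'   column, e.g. a per-residue annotation expanded to atoms.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path, b = NULL) {
  atoms <- structure$atoms
  if (!is.null(b)) {
    stopifnot(length(b) == nrow(atoms))
    atoms$b <- b
  }
  hdr <- .pdb_header(if (nzchar(structure$title))
    sprintf("TITLE     %s", structure$title) else character())
  writeLines(c(hdr, .format_atom_lines(atoms), "END"), path)
  invisible(path)
}
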