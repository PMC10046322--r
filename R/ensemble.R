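# Ensemble container and trajectory IO (multi-model PDB via bio3d, DCD in
# the CHARMM/NAMD dialect: bio3d reads, the writer lives here since bio3d
# has none).  Frames are stored bio3d-style as an F x 3N matrix in Angstrom.

#' Create an Ensemble
#'
#' @param topology A `Structure` shared by all frames.
#' @param xyz F x 3N coordinate matrix (frame-major, atom triplets x,y,z).
#' @param frame_metadata Optional data.frame with one row per frame.
#' @return An `Ensemble`.
#' @export
new_ensemble <- function(topology, xyz, frame_metadata = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * n_atoms(topology))
    stop("frames carry ", ncol(xyz) / 3, " atoms but topology has ",
         n_atoms(topology))
  if (nrow(xyz) < 1L) stop("an ensemble needs at least one frame")
  if (!is.null(frame_metadata) && nrow(frame_metadata) != nrow(xyz))
    stop("frame_metadata rows must match frame count")
  structure(list(topology = topology, xyz = xyz,
                 frame_metadata = frame_metadata),
            class = "Ensemble")
}

#' @export
print.Ensemble <- function(x, ...) {
  cat("Ensemble:", nrow(x$xyz), "frames x", ncol(x$xyz) / 3, "atoms\n")
  invisible(x)
}

n_frames <- function(ensemble) nrow(ensemble$xyz)

# Frame f as an N x 3 matrix.
frame_coords <- function(ensemble, f) {
  matrix(ensemble$xyz[f, ], ncol = 3, byrow = TRUE)
}

# Column indices into the xyz matrix for an atom-index vector.
xyz_columns <- function(atom_indices) {
  as.vector(rbind(3L * atom_indices - 2L, 3L * atom_indices - 1L,
                  3L * atom_indices))
}

mask_indices <- function(mask) {
  if (inherits(mask, "SelectionMask")) mask$indices else as.integer(mask)
}

#' Read a conformational ensemble
#'
#' @param topology_path PDB file defining atoms and numbering.
#' @param traj_path Multi-model PDB or DCD file (by extension, or forced via
#'   `format`); DCD coordinates are interpreted as Angstrom.
#' @param format `"auto"`, `"pdb"` or `"dcd"`.
#' @return An `Ensemble` with frames in file order.
#' @export
read_ensemble <- function(topology_path, traj_path, format = "auto") {
  topo <- read_structure(topology_path)
  if (format == "auto")
    format <- if (grepl("\\.dcd$", traj_path, ignore.case = TRUE)) "dcd" else "pdb"
  xyz <- switch(format,
    dcd = unclass(bio3d::read.dcd(traj_path, verbose = FALSE)),
    pdb = {
      pdb <- bio3d::read.pdb(traj_path, multi = TRUE, verbose = FALSE)
      unclass(pdb$xyz)
    },
    stop("unknown trajectory format '", format, "'"))
  xyz <- matrix(as.numeric(xyz), nrow = nrow(xyz))
  if (ncol(xyz) != 3L * n_atoms(topo))
    stop("trajectory frames have ", ncol(xyz) / 3,
         " atoms but topology has ", n_atoms(topo))
  if (nrow(xyz) == 0) stop("trajectory contains zero frames")
  new_ensemble(topo, xyz)
}

#' Write an ensemble as a multi-model PDB
#'
#' @param ensemble An `Ensemble`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, path) {
  atoms <- ensemble$topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.pdb_header(), con)
  for (f in seq_len(n_frames(ensemble))) {
    fc <- frame_coords(ensemble, f)
    atoms$x <- fc[, 1]; atoms$y <- fc[, 2]; atoms$z <- fc[, 3]
    writeLines(c(sprintf("MODEL     %4d", f),
                 .format_atom_lines(atoms), "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

.write_fortran_record <- function(con, payload_writer) {
  rc <- rawConnection(raw(0), "wb")
  payload_writer(rc)
  payload <- rawConnectionValue(rc)
  close(rc)
  writeBin(length(payload), con, size = 4, endian = "little")
  writeBin(payload, con)
  writeBin(length(payload), con, size = 4, endian = "little")
}

#' Write an ensemble as a DCD trajectory
#'
#' CHARMM/NAMD dialect: little-endian, 4-byte Fortran record markers,
#' single-precision coordinates (round-trips to ~1e-3 Angstrom).  A title
#' record names the writing tool version.
#'
#' @param ensemble An `Ensemble`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ensemble_dcd <- function(ensemble, path) {
  nf <- n_frames(ensemble)
  na <- n_atoms(ensemble$topology)
  con <- file(path, "wb")
  on.exit(close(con))
  .write_fortran_record(con, function(c2) {
    writeChar("CORD", c2, nchars = 4, eos = NULL)
    icntrl <- integer(20)
    icntrl[1] <- nf        # NSET
    icntrl[2] <- 1L        # ISTART
    icntrl[3] <- 1L        # NSAVC
    icntrl[4] <- nf
    icntrl[20] <- 24L      # CHARMM version stamp
    writeBin(icntrl, c2, size = 4, endian = "little")
  })
  .write_fortran_record(con, function(c2) {
    writeBin(1L, c2, size = 4, endian = "little")
    title <- sprintf("generated by esterdyn %s",
                     as.character(utils::packageVersion("esterdyn")))
    writeChar(formatC(title, width = 80, flag = "-"), c2, nchars = 80,
              eos = NULL)
  })
  .write_fortran_record(con, function(c2)
    writeBin(na, c2, size = 4, endian = "little"))
  for (f in seq_len(nf)) {
    fc <- frame_coords(ensemble, f)
    for (k in 1:3) {
      .write_fortran_record(con, function(c2)
        writeBin(as.numeric(fc[, k]), c2, size = 4, endian = "little"))
    }
  }
  invisible(path)
}
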