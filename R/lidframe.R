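# The bespoke geometric statistics: a local coordinate frame anchored on
# three Calpha atoms (origin at the catalytic serine, x toward Q244, y
# toward D284 after Gram-Schmidt, z = x cross y), per-frame lid-centroid
# traces in that frame, catalytic-triad side-chain distance series, and the
# flat-bottom distance-restraint operator with its compliance classifier.

#' Build a local coordinate frame from three anchor residues
#'
#' Origin at the Calpha of `origin_res`; x is the unit vector toward the
#' Calpha of `x_res`; y is the direction toward the Calpha of `y_res`
#' orthogonalized against x (Gram-Schmidt); z = x cross y (right-handed).
#'
#' @param structure A `Structure` (or N x 3 coordinate matrix paired with
#'   `topology`).
#' @param origin_res,x_res,y_res Author residue numbers of the anchors
#'   (defaults 146, 244, 284: the catalytic serine and the two frame
#'   residues).
#' @param chain Chain identifier.
#' @param coordinates Optional N x 3 matrix overriding the structure's
#'   coordinates (for per-frame frames).
#' @return A `LocalFrame` with `origin`, `basis` (rows x, y, z), `anchors`.
#' @export
build_lid_frame <- function(structure, origin_res = 146, x_res = 244,
                            y_res = 284, chain = "A", coordinates = NULL) {
  atoms <- structure$atoms
  xyz <- if (is.null(coordinates)) coords(structure) else as.matrix(coordinates)
  anchor <- function(res) {
    i <- which(atoms$chain == chain & atoms$resno == res & atoms$name == "CA")
    if (length(i) != 1)
      stop("anchor Calpha of residue ", res, " not found")
    xyz[i, ]
  }
  o <- anchor(origin_res)
  ax <- anchor(x_res)
  ay <- anchor(y_res)
  x <- unitv(ax - o)
  v <- ay - o
  y_raw <- v - sum(v * x) * x
  if (vnorm(y_raw) < 1e-8 * vnorm(v))
    stop("frame anchors are collinear")
  y <- unitv(y_raw)
  z <- cross3(x, y)
  structure(list(origin = o, basis = rbind(x = x, y = y, z = z),
                 anchors = c(origin = origin_res, x = x_res, y = y_res)),
            class = "LocalFrame")
}

#' Express points in a local frame
#' @param points N x 3 matrix or 3-vector (lab coordinates, Angstrom).
#' @param frame A `LocalFrame`.
#' @return Coordinates in the frame, same shape.
#' @export
to_frame_coords <- function(points, frame) {
  p <- if (is.null(dim(points))) matrix(points, 1, 3) else as.matrix(points)
  out <- sweep(p, 2, frame$origin) %*% t(frame$basis)
  colnames(out) <- c("x", "y", "z")
  if (is.null(dim(points))) out[1, ] else out
}

#' Per-frame lid-centroid trace in the local frame
#'
#' For every frame the anchor frame is rebuilt (so the trace is invariant
#' under global rigid motion) and the centroid of the lid-subset Calpha
#' atoms is expressed in it.
#'
#' @param ensemble An `Ensemble`.
#' @param lid_subset Residue numbers whose Calpha centroid is tracked
#'   (default 192:196).
#' @param origin_res,x_res,y_res,chain Frame anchors as in
#'   [build_lid_frame()].
#' @return A `LidTrace` data.frame with `frame`, `x`, `y`, `z` (Angstrom).
#' @export
lid_trace <- function(ensemble, lid_subset = 192:196, origin_res = 146,
                      x_res = 244, y_res = 284, chain = "A") {
  topo <- ensemble$topology
  lid_mask <- region_mask(topo, region_definition("lid", lid_subset, chain),
                          atom_level = "ca")
  lid_idx <- lid_mask$indices
  nf <- n_frames(ensemble)
  out <- matrix(NA_real_, nf, 3)
  for (f in seq_len(nf)) {
    fc <- frame_coords(ensemble, f)
    lf <- build_lid_frame(topo, origin_res, x_res, y_res, chain,
                          coordinates = fc)
    centroid <- colMeans(fc[lid_idx, , drop = FALSE])
    out[f, ] <- to_frame_coords(centroid, lf)
  }
  res <- data.frame(frame = seq_len(nf), x = out[, 1], y = out[, 2],
                    z = out[, 3])
  class(res) <- c("LidTrace", "data.frame")
  res
}

#' Two-state classification of a 1D coordinate
#'
#' Deterministic 1D 2-means (centers initialized at the observed minimum and
#' maximum) used to assign open/closed states from a lid-trace coordinate.
#'
#' @param z Numeric vector (e.g. the lid-trace z column).
#' @return list with `state` (0 = low, 1 = high), `occupancy_high`,
#'   `centers`, `threshold`.
#' @export
classify_two_state <- function(z) {
  km <- stats::kmeans(z, centers = matrix(c(min(z), max(z))))
  high <- which.max(km$centers)
  state <- as.integer(km$cluster == high)
  list(state = state, occupancy_high = mean(state),
       centers = sort(as.vector(km$centers)),
       threshold = mean(km$centers))
}

#' Catalytic-triad side-chain distance series
#'
#' Defaults follow the triad hydrogen-bond topology: d1 = Ser146 OG to
#' His270 NE2; d2 = Glu240 carboxylate (minimum over OE1/OE2) to His270
#' ND1.  Coincident atoms yield a distance of 0 (flagged with a warning),
#' not an error.
#'
#' @param ensemble An `Ensemble` carrying side-chain atoms.
#' @param ser,his,glu Residue numbers (defaults 146, 270, 240).
#' @param chain Chain identifier.
#' @param ser_atom,his_d1_atom,his_d2_atom Atom names (defaults OG, NE2,
#'   ND1).
#' @param glu_atoms Candidate carboxylate atoms; the per-frame minimum is
#'   taken (default OE1, OE2).
#' @return A `TriadDistanceSeries` data.frame with `frame`, `d1`, `d2`.
#' @export
triad_distances <- function(ensemble, ser = 146, his = 270, glu = 240,
                            chain = "A", ser_atom = "OG",
                            his_d1_atom = "NE2", his_d2_atom = "ND1",
                            glu_atoms = c("OE1", "OE2")) {
  atoms <- ensemble$topology$atoms
  find <- function(res, name) {
    i <- which(atoms$chain == chain & atoms$resno == res &
                 atoms$name == name)
    if (length(i) != 1)
      stop("side-chain atom ", name, " of residue ", res, " not found")
    i
  }
  i_ser <- find(ser, ser_atom)
  i_ne2 <- find(his, his_d1_atom)
  i_nd1 <- find(his, his_d2_atom)
  i_glu <- vapply(glu_atoms, function(a) find(glu, a), integer(1))
  d1 <- .min_dist_series(ensemble$xyz, i_ser, i_ne2)
  d2 <- .min_dist_series(ensemble$xyz, i_glu, i_nd1)
  if (any(d1 == 0) || any(d2 == 0))
    warning("coincident triad atoms in some frame(s); distance 0 reported")
  out <- data.frame(frame = seq_len(n_frames(ensemble)), d1 = d1, d2 = d2)
  attr(out, "pairs") <- list(
    d1 = sprintf("%s%d:%s - %s%d:%s", "S", ser, ser_atom, "H", his,
                 his_d1_atom),
    d2 = sprintf("%s%d:min(%s) - %s%d:%s", "E", glu,
                 paste(glu_atoms, collapse = ","), "H", his, his_d2_atom))
  class(out) <- c("TriadDistanceSeries", "data.frame")
  out
}

#' Free-energy landscape over a distance pair
#'
#' Delegates to [fes_2d()] on the (d1, d2) columns of a
#' `TriadDistanceSeries`.
#'
#' @param series A `TriadDistanceSeries` (or F x 2 matrix).
#' @param n_bins,temperature As in [fes_2d()].
#' @return An `FESGrid`.
#' @export
distance_fes <- function(series, n_bins = 60, temperature = 300) {
  m <- if (inherits(series, "TriadDistanceSeries"))
    cbind(series$d1, series$d2) else as.matrix(series)
  fes_2d(m, n_bins = n_bins, temperature = temperature)
}

#' Define a set of flat-bottom distance restraints
#'
#' Each restraint is an atom pair, an upper bound and a harmonic force
#' constant; the energy convention is `E = k (d - bound)^2` for `d > bound`
#' and exactly 0 otherwise (note: `k`, not `k/2` -- the AMBER restraint
#' convention).
#'
#' @param pairs List of 2-element integer vectors (atom indices) or a
#'   2-column matrix.
#' @param bound Upper bound(s) in Angstrom (default 5.5).
#' @param k Force constant(s), kcal/mol/A^2 (default 32).
#' @param labels Optional restraint labels.
#' @return A `RestraintSpec` data.frame.
#' @export
restraint_spec <- function(pairs, bound = 5.5, k = 32, labels = NULL) {
  m <- if (is.matrix(pairs)) pairs else do.call(rbind, pairs)
  if (any(bound <= 0)) stop("restraint bounds must be positive")
  if (any(k < 0)) stop("force constants must be non-negative")
  out <- data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]),
                    bound = bound, k = k)
  out$label <- if (is.null(labels)) paste0("r", seq_len(nrow(out))) else labels
  class(out) <- c("RestraintSpec", "data.frame")
  out
}

#' Flat-bottom restraint energies for one frame
#'
#' @param frame_xyz N x 3 coordinate matrix.
#' @param spec A `RestraintSpec`.
#' @return data.frame with `label`, `distance`, `energy` (kcal/mol),
#'   `compliant` (energy == 0); attribute `all_compliant`.
#' @export
restraint_energy <- function(frame_xyz, spec) {
  frame_xyz <- as.matrix(frame_xyz)
  bad <- c(spec$i, spec$j)
  if (any(bad < 1 | bad > nrow(frame_xyz)))
    stop("restraint refers to atoms outside the frame")
  d <- sqrt(rowSums((frame_xyz[spec$i, , drop = FALSE] -
                       frame_xyz[spec$j, , drop = FALSE])^2))
  excess <- pmax(d - spec$bound, 0)
  e <- spec$k * excess^2
  out <- data.frame(label = spec$label, distance = d, energy = e,
                    compliant = e == 0)
  attr(out, "all_compliant") <- all(out$compliant)
  out
}

#' Fraction of frames in the restrained (catalytic) state
#'
#' A frame is catalytic iff every restraint in `spec` has zero flat-bottom
#' energy.
#'
#' @param ensemble An `Ensemble`.
#' @param spec A `RestraintSpec`.
#' @return Fraction in `[0, 1]`.
#' @export
catalytic_state_fraction <- function(ensemble, spec) {
  ok <- vapply(seq_len(n_frames(ensemble)), function(f) {
    attr(restraint_energy(frame_coords(ensemble, f), spec),
         "all_compliant")
  }, logical(1))
  mean(ok)
}
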