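# Synthetic benchmark constructors.  These are first-class generator code,
# not test scaffolding: they define the study conditions under which every
# downstream statistic is validated by parameter recovery.

#' Puckered ring of Calpha nodes
#'
#' A 3D ring (out-of-plane pucker keeps the elastic network in generic
#' position, avoiding planar zero modes) used as the small closed-form ENM
#' benchmark.
#'
#' @param n Number of nodes (default 20).
#' @param radius Ring radius in Angstrom (default 12; adjacent nodes then
#'   sit ~3.8 A apart, the Calpha virtual bond).
#' @param pucker Out-of-plane amplitude in Angstrom (default 2).
#' @return A `Structure` of Calpha pseudo-atoms, residues 1..n.
#' @export
ring_structure <- function(n = 20, radius = 12, pucker = 2) {
  th <- 2 * pi * (0:(n - 1)) / n
  new_structure(data.frame(chain = "A", resno = seq_len(n),
                           resname = "ALA", name = "CA", element = "C",
                           het = FALSE,
                           x = radius * cos(th), y = radius * sin(th),
                           z = pucker * sin(3 * th), b = 0),
                title = sprintf("synthetic %d-node ring benchmark", n))
}

#' Three-lobe synthetic benchmark protein
#'
#' A compact 297-residue Calpha chain built by a seeded self-avoiding walk
#' confined to three overlapping spheres, giving the modular contact
#' topology (three lobes joined by linkers) that the community analysis is
#' validated on, with a surface-exposed lid (residues 182-199) and the
#' frame-anchor residues (146, 244, 284) in distinct lobes.  Coordinates
#' are inverted at build time if needed so the mean-structure lid-frame z
#' axis points along the outward lid direction ("open" is +z).
#'
#' @param seed Integer seed for the walk.
#' @param n_res Chain length (default 297).
#' @return A `Structure` of Calpha pseudo-atoms.
#' @export
benchmark_structure <- function(seed = 42, n_res = 297) {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  centers <- rbind(c(0, 0, 0), c(24, 0, 0), c(12, 21, 0))
  lobe_of <- function(r) 1 + (r > 99) + (r > 198)
  pts <- matrix(NA_real_, n_res, 3)
  pts[1, ] <- centers[1, ] + c(-8, 0, 0)
  for (i in 2:n_res) {
    ctr <- centers[lobe_of(i), ]
    best <- NULL; best_pen <- Inf
    for (try in 1:300) {
      pull <- ctr - pts[i - 1, ]
      dirv <- unitv(stats::rnorm(3) + 0.22 * pull)
      cand <- pts[i - 1, ] + 3.8 * dirv
      clash <- if (i > 2)
        min(sqrt(rowSums(sweep(pts[1:(i - 2), , drop = FALSE], 2,
                               cand)^2))) else Inf
      pen <- max(0, 3.4 - clash) * 10 + max(0, vnorm(cand - ctr) - 13)
      if (pen == 0) { best <- cand; break }
      if (pen < best_pen) { best_pen <- pen; best <- cand }
    }
    pts[i, ] <- best
  }
  mk <- function(p) new_structure(
    data.frame(chain = "A", resno = seq_len(n_res), resname = "ALA",
               name = "CA", element = "C", het = FALSE,
               x = p[, 1], y = p[, 2], z = p[, 3], b = 0),
    title = "synthetic three-lobe benchmark protein")
  s <- mk(pts)
  lf <- build_lid_frame(s)
  lid_idx <- region_mask(s, region_definition("lid", 182:199), "ca")$indices
  outward <- unitv(colMeans(pts[lid_idx, , drop = FALSE]) - colMeans(pts))
  if (sum(lf$basis["z", ] * outward) < 0) s <- mk(-pts)
  s
}

#' Two-residue ideal-cystine fixture
#'
#' Builds, by analytic internal-to-Cartesian construction, a pair of
#' residues whose backbones admit a disulfide with exactly the requested
#' chi3 torsion, ideal Calpha-Cbeta-Sgamma angles (114.6 deg), Cbeta-Sgamma
#' bonds of 1.81 A and an S-S distance of 2.04 A, with both chi1 values on
#' the default 5-degree scan grid.  `spacer_residues` optionally appends
#' far-away residues (with full backbones) so that pair scans see exactly
#' one viable pair.
#'
#' @param chi3 Target Cbeta-Sgamma-Sgamma'-Cbeta' torsion in degrees
#'   (default -87).
#' @param chi1_i,chi1_j N-CA-CB-SG torsions, degrees (defaults -60, -65;
#'   keep on the scan grid for exact recovery).
#' @param res_i,res_j Residue numbers (defaults 10, 20).
#' @param spacer_residues Number of distant residues to append (default 0).
#' @return A `Structure` with backbone N, CA, C and CB atoms.
#' @export
ideal_cystine_fixture <- function(chi3 = -87, chi1_i = -60, chi1_j = -65,
                                  res_i = 10, res_j = 20,
                                  spacer_residues = 0) {
  ss_angle <- 104.2  # CB-SG-SG' bond angle of cystine
  ca_i <- c(0, 0, 0)
  n_i <- c(1.458, 0, 0)
  c_i <- 1.525 * c(cos(111.2 * pi / 180), sin(111.2 * pi / 180), 0)
  cb_i <- ideal_cbeta(n_i, ca_i, c_i)
  sg_i <- place_atom(n_i, ca_i, cb_i, 1.81, 114.6, chi1_i)
  sg_j <- place_atom(ca_i, cb_i, sg_i, 2.04, ss_angle, -75)
  cb_j <- place_atom(cb_i, sg_i, sg_j, 1.81, ss_angle, chi3)
  ca_j <- place_atom(sg_i, sg_j, cb_j, 1.53, 114.6, 160)
  n_j <- place_atom(sg_j, cb_j, ca_j, 1.458, 110.5, chi1_j)
  # choose the carbonyl-carbon branch that keeps residue j in the same
  # chirality convention as ideal_cbeta (so Gly reconstruction round-trips)
  c_cands <- lapply(c(118, -118), function(off)
    place_atom(sg_j, cb_j, ca_j, 1.525, 110.5, chi1_j + off))
  errs <- vapply(c_cands, function(cc)
    vnorm(ideal_cbeta(n_j, ca_j, cc) - cb_j), numeric(1))
  c_j <- c_cands[[which.min(errs)]]
  res <- function(resno, n, ca, c, cb) {
    data.frame(chain = "A", resno = resno,
               resname = "ALA",
               name = c("N", "CA", "C", "CB"),
               element = c("N", "C", "C", "C"), het = FALSE,
               x = c(n[1], ca[1], c[1], cb[1]),
               y = c(n[2], ca[2], c[2], cb[2]),
               z = c(n[3], ca[3], c[3], cb[3]), b = 0)
  }
  atoms <- rbind(res(res_i, n_i, ca_i, c_i, cb_i),
                 res(res_j, n_j, ca_j, c_j, cb_j))
  if (spacer_residues > 0) {
    for (k in seq_len(spacer_residues)) {
      shift <- c(40 + 25 * k, 0, 0)
      atoms <- rbind(atoms,
                     res(res_j + 10 * k, n_i + shift, ca_i + shift,
                         c_i + shift, cb_i + shift))
    }
  }
  new_structure(atoms, title = "synthetic ideal-cystine fixture")
}
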