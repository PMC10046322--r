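# Rigid-body superposition (Kabsch) and the first-line ensemble statistics:
# RMSD series, iteratively-referenced RMSF, radius of gyration, and
# average-linkage clustering on the all-pairs best-fit RMSD matrix.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation (det = +1; reflections excluded) and
#' translation minimizing the RMSD of the masked atoms, so that
#' `x_fitted = x %*% t(rotation) + translation` maps `mobile` onto
#' `reference`.
#'
#' @param mobile,reference N x 3 coordinate matrices over the same atoms.
#' @param mask Optional `SelectionMask` or index vector of atoms to fit on
#'   (default: all).
#' @return A `SuperpositionResult` with `rotation`, `translation`, `rmsd`.
#' @export
kabsch <- function(mobile, reference, mask = NULL) {
  if (!is.null(mask)) {
    idx <- mask_indices(mask)
    p <- mobile[idx, , drop = FALSE]
    q <- reference[idx, , drop = FALSE]
  } else {
    p <- mobile; q <- reference
  }
  if (nrow(p) < 3) stop("superposition needs at least 3 masked atoms")
  cm <- colMeans(p); cr <- colMeans(q)
  pc <- sweep(p, 2, cm); qc <- sweep(q, 2, cr)
  sp <- svd(pc); sq <- svd(qc)
  if (sp$d[2] < 1e-8 * max(sp$d[1], 1e-12) ||
      sq$d[2] < 1e-8 * max(sq$d[1], 1e-12))
    stop("masked atoms are collinear; superposition is degenerate")
  h <- crossprod(pc, qc)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- pc %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - qc)^2)))
  structure(list(rotation = rot,
                 translation = as.vector(cr - rot %*% cm),
                 rmsd = rmsd),
            class = "SuperpositionResult")
}

#' Apply a superposition to coordinates
#' @param xyz N x 3 matrix.
#' @param sp A `SuperpositionResult`.
#' @return Transformed N x 3 matrix.
#' @export
apply_superposition <- function(xyz, sp) {
  sweep(xyz %*% t(sp$rotation), 2, sp$translation, "+")
}

# Proper rotation mapping centered p onto centered q (no degeneracy checks;
# callers validate the reference once).
.rot_fit <- function(pc, qc) {
  sv <- svd(crossprod(pc, qc))
  d <- sign(det(sv$v %*% t(sv$u)))
  sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
}

# Fit every frame of an F x 3N matrix onto reference coords, on the mask.
.fit_frames <- function(xyz, ref_n3, atom_idx) {
  qm <- ref_n3[atom_idx, , drop = FALSE]
  if (nrow(qm) < 3) stop("superposition needs at least 3 masked atoms")
  cr <- colMeans(qm)
  qc <- sweep(qm, 2, cr)
  if (svd(qc)$d[2] < 1e-8 * max(svd(qc)$d[1], 1e-12))
    stop("masked reference atoms are collinear; superposition is degenerate")
  for (f in seq_len(nrow(xyz))) {
    fc <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    pm <- fc[atom_idx, , drop = FALSE]
    cm <- colMeans(pm)
    rot <- .rot_fit(sweep(pm, 2, cm), qc)
    xyz[f, ] <- as.vector(t(sweep(sweep(fc, 2, cm) %*% t(rot), 2, cr, "+")))
  }
  xyz
}

# Iterative average-structure reference: fit to the running mean until the
# mean moves < tol (max 10 iterations), removing first-frame bias.
iterative_mean_fit <- function(ensemble, mask = NULL, tol = 1e-6,
                               max_iter = 10) {
  atom_idx <- if (is.null(mask)) seq_len(n_atoms(ensemble$topology))
              else mask_indices(mask)
  xyz <- ensemble$xyz
  ref <- matrix(xyz[1, ], ncol = 3, byrow = TRUE)
  for (it in seq_len(max_iter)) {
    xyz <- .fit_frames(xyz, ref, atom_idx)
    new_ref <- matrix(colMeans(xyz), ncol = 3, byrow = TRUE)
    shift <- max(abs(new_ref[atom_idx, ] - ref[atom_idx, ]))
    ref <- new_ref
    if (shift < tol) break
  }
  list(xyz = xyz, mean = as.vector(t(ref)), iterations = it)
}

#' Per-frame RMSD series against a reference structure
#'
#' Each frame is superposed onto the reference on `fit_mask`, then the RMSD
#' of `measure_mask` atoms is reported.
#'
#' @param ensemble An `Ensemble`.
#' @param reference A `Structure` (default: the ensemble topology).
#' @param fit_mask,measure_mask `SelectionMask`s (default: all atoms; the
#'   measure mask defaults to the fit mask).
#' @return Numeric vector of per-frame RMSDs in Angstrom.
#' @export
rmsd_series <- function(ensemble, reference = NULL, fit_mask = NULL,
                        measure_mask = NULL) {
  ref <- if (is.null(reference)) coords(ensemble$topology)
         else coords(reference)
  fit_idx <- if (is.null(fit_mask)) seq_len(nrow(ref))
             else mask_indices(fit_mask)
  meas_idx <- if (is.null(measure_mask)) fit_idx
              else mask_indices(measure_mask)
  vapply(seq_len(n_frames(ensemble)), function(f) {
    fc <- frame_coords(ensemble, f)
    sp <- kabsch(fc, ref, mask = fit_idx)
    fitted <- apply_superposition(fc, sp)
    sqrt(mean(rowSums((fitted[meas_idx, , drop = FALSE] -
                         ref[meas_idx, , drop = FALSE])^2)))
  }, numeric(1))
}

#' Per-residue RMSF about the iterative average structure
#'
#' Frames are superposed on `mask` onto the iteratively converged average
#' structure; per-atom fluctuation is the root-mean-square displacement from
#' that average.
#'
#' @param ensemble An `Ensemble` with at least 2 frames.
#' @param mask `SelectionMask` (default: Calpha atoms).
#' @param fit If `FALSE`, skip superposition (for ensembles sampled without
#'   rigid motion).
#' @return An `RMSFProfile` data.frame with `chain`, `resno`, `name`, `rmsf`.
#' @export
rmsf_profile <- function(ensemble, mask = NULL, fit = TRUE) {
  if (n_frames(ensemble) < 2) stop("RMSF needs at least 2 frames")
  if (is.null(mask)) mask <- select_atoms(ensemble$topology, "ca")
  idx <- mask_indices(mask)
  if (fit) {
    fitres <- iterative_mean_fit(ensemble, mask)
    xyz <- fitres$xyz; mean_xyz <- fitres$mean
  } else {
    xyz <- ensemble$xyz; mean_xyz <- colMeans(xyz)
  }
  cols <- xyz_columns(idx)
  delta <- sweep(xyz[, cols, drop = FALSE], 2, mean_xyz[cols])
  msf_per_coord <- colMeans(delta^2)
  rmsf <- sqrt(colSums(matrix(msf_per_coord, nrow = 3)))
  atoms <- ensemble$topology$atoms[idx, , drop = FALSE]
  out <- data.frame(chain = atoms$chain, resno = atoms$resno,
                    name = atoms$name, rmsf = rmsf)
  attr(out, "mask_provenance") <- if (inherits(mask, "SelectionMask"))
    mask$provenance else "indices"
  attr(out, "reference") <- if (fit) "iterative average structure"
                            else "raw ensemble mean"
  class(out) <- c("RMSFProfile", "data.frame")
  out
}

#' Per-residue RMSF difference, optionally written to a B-factor column
#'
#' @param profile_a,profile_b `RMSFProfile`s over the same residues.
#' @param structure Optional `Structure` to annotate.
#' @param path Optional output PDB path (requires `structure`); the delta is
#'   written into the B-factor column of every atom of each residue.
#' @return data.frame with `resno` and `delta` (= a - b), in Angstrom.
#' @export
rmsf_difference <- function(profile_a, profile_b, structure = NULL,
                            path = NULL) {
  if (!identical(profile_a$resno, profile_b$resno) ||
      !identical(profile_a$chain, profile_b$chain))
    stop("RMSF profiles cover different residues; cannot subtract")
  out <- data.frame(chain = profile_a$chain, resno = profile_a$resno,
                    delta = profile_a$rmsf - profile_b$rmsf)
  if (!is.null(path)) {
    if (is.null(structure)) stop("annotated output needs a structure")
    b <- rep(0, n_atoms(structure))
    key <- paste(structure$atoms$chain, structure$atoms$resno)
    lut <- stats::setNames(out$delta, paste(out$chain, out$resno))
    hit <- key %in% names(lut)
    b[hit] <- lut[key[hit]]
    write_structure(structure, path, b = b)
  }
  out
}

# Element masses from bio3d's periodic-table dataset (memoized).
.mass_env <- new.env(parent = emptyenv())
.element_mass <- function(symbols) {
  if (is.null(.mass_env$table)) {
    e <- new.env()
    utils::data("elements", package = "bio3d", envir = e)
    .mass_env$table <- stats::setNames(e$elements$mass,
                                       toupper(e$elements$symb))
  }
  m <- .mass_env$table[toupper(symbols)]
  if (anyNA(m))
    stop("unknown element symbol(s): ",
         paste(unique(symbols[is.na(m)]), collapse = ","))
  unname(m)
}

#' Per-frame radius of gyration
#'
#' Mass-weighted, with element masses from `bio3d::atom2mass` (a
#' Calpha-only mask therefore uses the carbon mass).
#'
#' @param ensemble An `Ensemble`.
#' @param mask Optional `SelectionMask` (default: all atoms).
#' @return Numeric vector of per-frame Rg in Angstrom.
#' @export
radius_of_gyration <- function(ensemble, mask = NULL) {
  idx <- if (is.null(mask)) seq_len(n_atoms(ensemble$topology))
         else mask_indices(mask)
  if (length(idx) == 0) stop("empty mask")
  m <- .element_mass(ensemble$topology$atoms$element[idx])
  mtot <- sum(m)
  cols <- xyz_columns(idx)
  rg2 <- numeric(n_frames(ensemble))
  comp <- lapply(0:2, function(k)
    ensemble$xyz[, cols[seq(1 + k, length(cols), by = 3)], drop = FALSE])
  for (k in 1:3) {
    x <- comp[[k]]
    com <- as.vector(x %*% m) / mtot
    rg2 <- rg2 + as.vector(sweep(x, 1, com)^2 %*% m) / mtot
  }
  sqrt(rg2)
}

# --- all-pairs best-fit RMSD, closed form ---------------------------------
# rmsd(a,b)^2 = (Ga + Gb - 2 D_ab)/N with D the sum of signed singular
# values of the 3x3 cross-covariance; computed for all pairs at once from
# nine F x F component products and a vectorized symmetric-3x3 eigensolver.

.sym3_eigenvalues <- function(S11, S22, S33, S12, S13, S23) {
  q <- (S11 + S22 + S33) / 3
  p2 <- (S11 - q)^2 + (S22 - q)^2 + (S33 - q)^2 +
    2 * (S12^2 + S13^2 + S23^2)
  p <- sqrt(pmax(p2, 0) / 6)
  safe <- p > 1e-30
  pin <- ifelse(safe, p, 1)
  B11 <- (S11 - q) / pin; B22 <- (S22 - q) / pin; B33 <- (S33 - q) / pin
  B12 <- S12 / pin; B13 <- S13 / pin; B23 <- S23 / pin
  detB <- B11 * (B22 * B33 - B23^2) - B12 * (B12 * B33 - B23 * B13) +
    B13 * (B12 * B23 - B22 * B13)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  e1[!safe] <- q[!safe]; e2[!safe] <- q[!safe]; e3[!safe] <- q[!safe]
  list(e1 = e1, e2 = e2, e3 = e3)
}

#' All-pairs best-fit RMSD matrix
#'
#' Vectorized closed-form Kabsch RMSD between every pair of frames over the
#' masked atoms (each pair is optimally superposed; reflections excluded).
#' Working memory scales as roughly 16 F^2 doubles, so the matrix is meant
#' for the hundreds-of-frames regime of clustering, not for raw
#' multi-thousand-frame trajectories (subsample first).
#'
#' @param ensemble An `Ensemble`.
#' @param mask Optional `SelectionMask` (default: Calpha atoms).
#' @return F x F symmetric matrix of RMSDs in Angstrom.
#' @export
pairwise_rmsd <- function(ensemble, mask = NULL) {
  if (is.null(mask)) mask <- select_atoms(ensemble$topology, "ca")
  idx <- mask_indices(mask)
  cols <- xyz_columns(idx)
  nf <- n_frames(ensemble)
  natm <- length(idx)
  comp <- lapply(0:2, function(k) {
    x <- ensemble$xyz[, cols[seq(1 + k, length(cols), by = 3)], drop = FALSE]
    x - rowMeans(x)
  })
  g <- Reduce(`+`, lapply(comp, function(x) rowSums(x^2)))
  M <- vector("list", 9)
  dim(M) <- c(3, 3)
  for (k in 1:3) for (l in 1:3)
    M[[k, l]] <- comp[[k]] %*% t(comp[[l]])
  detM <- M[[1, 1]] * (M[[2, 2]] * M[[3, 3]] - M[[2, 3]] * M[[3, 2]]) -
    M[[1, 2]] * (M[[2, 1]] * M[[3, 3]] - M[[2, 3]] * M[[3, 1]]) +
    M[[1, 3]] * (M[[2, 1]] * M[[3, 2]] - M[[2, 2]] * M[[3, 1]])
  S <- function(k, l) M[[1, k]] * M[[1, l]] + M[[2, k]] * M[[2, l]] +
    M[[3, k]] * M[[3, l]]
  ev <- .sym3_eigenvalues(S(1, 1), S(2, 2), S(3, 3), S(1, 2), S(1, 3),
                          S(2, 3))
  dsum <- sqrt(pmax(ev$e1, 0)) + sqrt(pmax(ev$e2, 0)) +
    sign(detM) * sqrt(pmax(ev$e3, 0))
  r2 <- (outer(g, g, "+") - 2 * dsum) / natm
  r <- sqrt(pmax(r2, 0))
  diag(r) <- 0
  (r + t(r)) / 2
}

#' Cluster frames by pairwise best-fit RMSD
#'
#' Average-linkage hierarchical clustering on the all-pairs best-fit RMSD
#' matrix, cut at `k` clusters.  Clusters are relabelled by decreasing
#' population (ties: lowest member frame index); medoids minimize the mean
#' intra-cluster RMSD (ties: lowest frame index).
#'
#' @param ensemble An `Ensemble`.
#' @param mask Optional `SelectionMask` (default: Calpha atoms).
#' @param k Number of clusters (default 2).
#' @return A `ClusterAssignment` with `labels`, `fractions`, `medoids`.
#' @export
cluster_frames <- function(ensemble, mask = NULL, k = 2) {
  nf <- n_frames(ensemble)
  if (k > nf) stop("k = ", k, " exceeds frame count ", nf)
  dmat <- pairwise_rmsd(ensemble, mask)
  hc <- stats::hclust(stats::as.dist(dmat), method = "average")
  raw <- stats::cutree(hc, k = k)
  sizes <- tabulate(raw, nbins = k)
  first <- vapply(seq_len(k), function(c) min(which(raw == c)), integer(1))
  ord <- order(-sizes, first)
  labels <- match(raw, ord)
  fractions <- sizes[ord] / nf
  medoids <- vapply(seq_len(k), function(c) {
    members <- which(labels == c)
    if (length(members) == 1) return(members)
    within <- rowMeans(dmat[members, members, drop = FALSE])
    members[which.min(within)]
  }, integer(1))
  structure(list(labels = labels, fractions = fractions, medoids = medoids,
                 k = k),
            class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat("ClusterAssignment:", x$k, "clusters; fractions",
      paste(sprintf("%.3f", x$fractions), collapse = "/"),
      "; medoid frames", paste(x$medoids, collapse = ","), "\n")
  invisible(x)
}
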