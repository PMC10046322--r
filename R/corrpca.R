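# Correlation and collective-motion layer: dynamic cross-correlation
# matrices, Calpha PCA, and free-energy surfaces over low-dimensional
# projections.

#' Dynamic cross-correlation matrix (DCCM)
#'
#' After iterative mean-structure superposition on the mask, computes
#' `C_ij = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>)` with displacements taken
#' from the average structure (scalar-product / trace-of-cross-covariance
#' convention, values in `[-1, 1]`).
#'
#' @param ensemble An `Ensemble` with >= 2 frames.
#' @param mask Optional Calpha `SelectionMask` (default: all Calpha).
#' @param fit Superpose first (default `TRUE`).
#' @return A `CorrelationMatrix`: N x N matrix with residue-number dimnames
#'   and a `mask_provenance` attribute.
#' @export
dccm <- function(ensemble, mask = NULL, fit = TRUE) {
  if (n_frames(ensemble) < 2) stop("DCCM needs at least 2 frames")
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
  n <- length(idx)
  num <- matrix(0, n, n)
  for (k in 0:2) {
    x <- delta[, seq(1 + k, ncol(delta), by = 3), drop = FALSE]
    num <- num + crossprod(x)
  }
  num <- num / nrow(delta)
  v <- diag(num)
  zero <- which(v < 1e-12)
  if (length(zero) > 0)
    stop("zero-variance atom(s) in DCCM: residue ",
         paste(ensemble$topology$atoms$resno[idx[zero]], collapse = ","))
  cmat <- num / sqrt(outer(v, v))
  cmat <- (cmat + t(cmat)) / 2
  diag(cmat) <- 1
  resno <- ensemble$topology$atoms$resno[idx]
  dimnames(cmat) <- list(resno, resno)
  attr(cmat, "mask_provenance") <- if (inherits(mask, "SelectionMask"))
    mask$provenance else "indices"
  class(cmat) <- c("CorrelationMatrix", "matrix")
  cmat
}

#' Principal component analysis of an ensemble
#'
#' Eigendecomposition of the 3N x 3N covariance (denominator F - 1) of the
#' superposed masked coordinates.  Eigenvector signs are fixed by making the
#' largest-magnitude coordinate positive, so results are reproducible across
#' runs and platforms.
#'
#' @param ensemble An `Ensemble` with >= 2 frames.
#' @param mask Optional `SelectionMask` (default: Calpha).
#' @param n_components Number of components to project on (default 2).
#' @param fit Superpose first (default `TRUE`).
#' @return A `PCAResult`: `values` (all eigenvalues, descending, A^2),
#'   `vectors` (3N x n_components, orthonormal), `mean` (3N), `projections`
#'   (F x n_components, mean-centred), `resno`.
#' @export
pca_ensemble <- function(ensemble, mask = NULL, n_components = 2,
                         fit = TRUE) {
  if (n_frames(ensemble) < 2) stop("PCA needs at least 2 frames")
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
  covmat <- crossprod(delta) / (nrow(delta) - 1)
  eig <- eigen(covmat, symmetric = TRUE)
  values <- pmax(eig$values, 0)
  rank <- sum(values > 1e-12 * max(values, 1e-300))
  if (n_components > rank)
    stop("n_components = ", n_components, " exceeds covariance rank ", rank)
  vectors <- eig$vectors[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(ncol(vectors))) {
    imax <- which.max(abs(vectors[, j]))
    if (vectors[imax, j] < 0) vectors[, j] <- -vectors[, j]
  }
  structure(list(values = values,
                 vectors = vectors,
                 mean = mean_xyz[cols],
                 projections = delta %*% vectors,
                 resno = ensemble$topology$atoms$resno[idx],
                 n_components = n_components),
            class = "PCAResult")
}

#' @export
print.PCAResult <- function(x, ...) {
  tot <- sum(x$values)
  cat("PCAResult:", length(x$values), "modes;",
      "PC1", sprintf("%.1f%%", 100 * x$values[1] / tot),
      "PC2", sprintf("%.1f%%", 100 * x$values[2] / tot), "of variance\n")
  invisible(x)
}

#' 2D free-energy surface over two projections
#'
#' `F(bin) = -kT ln(P(bin) / P_max)` from a normalized 2D histogram;
#' empty bins are `NA` and the minimum over occupied bins is exactly 0.
#'
#' @param projections F x 2 matrix (e.g. PC1/PC2 or a distance pair).
#' @param n_bins Bins per axis (default 60).
#' @param temperature Kelvin (default 300).
#' @param breaks_x,breaks_y Optional explicit bin edges.
#' @return An `FESGrid`: `energy` (n_bins x n_bins, kcal/mol), `xmids`,
#'   `ymids`, `xbreaks`, `ybreaks`, `counts`, `temperature`.
#' @export
fes_2d <- function(projections, n_bins = 60, temperature = 300,
                   breaks_x = NULL, breaks_y = NULL) {
  projections <- as.matrix(projections)
  if (ncol(projections) != 2) stop("projections must have two columns")
  pad <- function(r) {
    if (diff(r) < 1e-12) r + c(-0.5, 0.5) else r + diff(r) * 1e-9 * c(-1, 1)
  }
  if (is.null(breaks_x))
    breaks_x <- seq(pad(range(projections[, 1]))[1],
                    pad(range(projections[, 1]))[2], length.out = n_bins + 1)
  if (is.null(breaks_y))
    breaks_y <- seq(pad(range(projections[, 2]))[1],
                    pad(range(projections[, 2]))[2], length.out = n_bins + 1)
  ix <- findInterval(projections[, 1], breaks_x, rightmost.closed = TRUE)
  iy <- findInterval(projections[, 2], breaks_y, rightmost.closed = TRUE)
  keep <- ix >= 1 & ix <= length(breaks_x) - 1 &
    iy >= 1 & iy <= length(breaks_y) - 1
  counts <- matrix(0L, length(breaks_x) - 1, length(breaks_y) - 1)
  tab <- table(factor(ix[keep], levels = seq_len(nrow(counts))),
               factor(iy[keep], levels = seq_len(ncol(counts))))
  counts[] <- as.integer(tab)
  kT <- KB_KCAL * temperature
  energy <- matrix(NA_real_, nrow(counts), ncol(counts))
  occ <- counts > 0
  energy[occ] <- -kT * log(counts[occ] / max(counts))
  structure(list(energy = energy, counts = counts,
                 xmids = (breaks_x[-1] + breaks_x[-length(breaks_x)]) / 2,
                 ymids = (breaks_y[-1] + breaks_y[-length(breaks_y)]) / 2,
                 xbreaks = breaks_x, ybreaks = breaks_y,
                 temperature = temperature),
            class = "FESGrid")
}

#' @export
print.FESGrid <- function(x, ...) {
  cat("FESGrid:", nrow(x$energy), "x", ncol(x$energy), "bins;",
      sum(!is.na(x$energy)), "occupied; max",
      sprintf("%.2f", max(x$energy, na.rm = TRUE)), "kcal/mol\n")
  invisible(x)
}

#' Location of the FES global minimum
#' @param fes An `FESGrid`.
#' @return c(x, y) bin centers of the zero-energy bin.
#' @export
fes_minimum <- function(fes) {
  ij <- which(fes$energy == 0, arr.ind = TRUE)[1, ]
  c(x = fes$xmids[ij[1]], y = fes$ymids[ij[2]])
}

#' Radial free-energy profile of an FES
#'
#' Averages occupied-bin free energies over concentric radial shells about
#' `center` (shell width = one bin diagonal), the standard reduction for
#' checking a quadratic well against its closed form.
#'
#' @param fes An `FESGrid`.
#' @param center c(x, y) of the well (default: the global minimum bin).
#' @return data.frame with shell mid-radius `r` and mean free energy `f`.
#' @export
fes_radial_profile <- function(fes, center = NULL) {
  if (is.null(center)) center <- fes_minimum(fes)
  grid <- expand.grid(x = fes$xmids, y = fes$ymids)
  r <- sqrt((grid$x - center[1])^2 + (grid$y - center[2])^2)
  f <- as.vector(fes$energy)
  keep <- !is.na(f)
  width <- sqrt(diff(fes$xbreaks[1:2])^2 + diff(fes$ybreaks[1:2])^2)
  shell <- floor(r[keep] / width)
  agg <- tapply(f[keep], shell, mean)
  data.frame(r = (as.numeric(names(agg)) + 0.5) * width,
             f = as.numeric(agg))
}

#' Per-residue displacement magnitude along a principal component
#'
#' The Euclidean norm of each residue's 3-vector in the eigenvector, scaled
#' by sqrt(eigenvalue) so the value is an RMS displacement in Angstrom.
#'
#' @param pca A `PCAResult`.
#' @param component Component index (<= n_components).
#' @param structure Optional `Structure` to annotate (B-factor column).
#' @param path Optional output PDB path.
#' @return data.frame with `resno` and `displacement` (Angstrom).
#' @export
mode_displacement_map <- function(pca, component = 1, structure = NULL,
                                  path = NULL) {
  if (component > pca$n_components)
    stop("component ", component, " was not retained")
  v <- pca$vectors[, component]
  mag <- sqrt(colSums(matrix(v^2, nrow = 3))) * sqrt(pca$values[component])
  out <- data.frame(resno = pca$resno, displacement = mag)
  if (!is.null(path)) {
    if (is.null(structure)) stop("annotated output needs a structure")
    b <- rep(0, n_atoms(structure))
    lut <- stats::setNames(mag, pca$resno)
    key <- as.character(structure$atoms$resno)
    hit <- key %in% names(lut)
    b[hit] <- lut[key[hit]]
    write_structure(structure, path, b = b)
  }
  out
}
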