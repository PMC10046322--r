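# Anisotropic elastic-network model (ANM) and the seeded ensemble sampler.
# The ANM's pseudo-inverse Hessian gives a closed-form fluctuation
# covariance, which is what makes these ensembles usable as parameter-
# recovery oracles for every downstream statistic.

#' Boltzmann constant in kcal/mol/K
#' @export
KB_KCAL <- 0.0019872041

#' Build an anisotropic elastic-network model from Calpha positions
#'
#' Nodes are the Calpha atoms of `structure`; every pair within `cutoff`
#' receives a Hookean spring of stiffness `gamma`.  The 3N x 3N Hessian is
#' assembled from the standard ANM super-elements; thermal fluctuation
#' covariance is kT times the pseudo-inverse over the non-rigid modes
#' (eigenvalue > 1e-8 x largest, which drops the 6 rigid-body modes of any
#' connected graph and any additional small-N degeneracies).
#'
#' @param structure A `Structure` (Calpha atoms are used as nodes).
#' @param cutoff Contact cutoff in Angstrom (default 10).
#' @param gamma Uniform spring constant, kcal/mol/Angstrom^2 (default 1).
#' @param temperature Temperature in Kelvin (default 300).
#' @return An `ENMModel`.
#' @export
build_enm <- function(structure, cutoff = 10, gamma = 1, temperature = 300) {
  ca <- select_atoms(structure, "ca")
  node_atoms <- if (length(ca$indices) >= 3) ca$indices
                else seq_len(n_atoms(structure))
  xyz <- coords(structure)[node_atoms, , drop = FALSE]
  n <- nrow(xyz)
  if (n < 2) stop("an elastic network needs at least 2 nodes")
  d <- as.matrix(stats::dist(xyz))
  contact <- d <= cutoff & upper.tri(d)
  pairs <- which(contact, arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  if (igraph::vcount(g) < n)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  comp <- igraph::components(g)
  if (comp$no > 1)
    stop("contact graph is disconnected at cutoff ", cutoff, " (",
         comp$no, " components; sizes ",
         paste(comp$csize, collapse = ","), ")")
  hessian <- matrix(0, 3 * n, 3 * n)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    dv <- xyz[j, ] - xyz[i, ]
    block <- -gamma * tcrossprod(dv) / sum(dv * dv)
    bi <- (3 * i - 2):(3 * i); bj <- (3 * j - 2):(3 * j)
    hessian[bi, bj] <- block
    hessian[bj, bi] <- block
    hessian[bi, bi] <- hessian[bi, bi] - block
    hessian[bj, bj] <- hessian[bj, bj] - block
  }
  eig <- eigen(hessian, symmetric = TRUE)
  keep <- eig$values > 1e-8 * max(eig$values)
  structure(list(structure = structure, node_atoms = node_atoms,
                 coords = xyz, cutoff = cutoff, gamma = gamma,
                 temperature = temperature, hessian = hessian,
                 mode_values = eig$values[keep],
                 mode_vectors = eig$vectors[, keep, drop = FALSE],
                 n_nodes = n),
            class = "ENMModel")
}

#' @export
print.ENMModel <- function(x, ...) {
  cat("ENMModel:", x$n_nodes, "nodes, cutoff", x$cutoff, "A, gamma",
      x$gamma, "kcal/mol/A^2,", length(x$mode_values),
      "vibrational modes\n")
  invisible(x)
}

#' Rescale springs between two node sets
#'
#' Multiplies the Hessian super-elements of every spring with one endpoint
#' in `nodes_a` and the other in `nodes_b` by `factor`, then rediagonalizes.
#' Used to plant stronger (factor > 1) or weaker inter-domain coupling in
#' synthetic benchmarks.
#'
#' @param model An `ENMModel`.
#' @param nodes_a,nodes_b Node index vectors (1-based, into the model nodes).
#' @param factor Positive multiplier for the affected spring constants.
#' @return A new `ENMModel`.
#' @export
scale_springs <- function(model, nodes_a, nodes_b, factor) {
  stopifnot(factor > 0)
  xyz <- model$coords
  d <- as.matrix(stats::dist(xyz))
  hessian <- model$hessian
  for (i in nodes_a) for (j in nodes_b) {
    if (i == j || d[i, j] > model$cutoff) next
    dv <- xyz[j, ] - xyz[i, ]
    delta <- -(factor - 1) * model$gamma * tcrossprod(dv) / sum(dv * dv)
    bi <- (3 * i - 2):(3 * i); bj <- (3 * j - 2):(3 * j)
    hessian[bi, bj] <- hessian[bi, bj] + delta
    hessian[bj, bi] <- hessian[bj, bi] + delta
    hessian[bi, bi] <- hessian[bi, bi] - delta
    hessian[bj, bj] <- hessian[bj, bj] - delta
  }
  eig <- eigen(hessian, symmetric = TRUE)
  keep <- eig$values > 1e-8 * max(eig$values)
  model$hessian <- hessian
  model$mode_values <- eig$values[keep]
  model$mode_vectors <- eig$vectors[, keep, drop = FALSE]
  model
}

#' Closed-form ENM fluctuation covariance (3N x 3N)
#' @param model An `ENMModel`.
#' @return kT-weighted pseudo-inverse of the Hessian, Angstrom^2.
#' @export
enm_covariance <- function(model) {
  kT <- KB_KCAL * model$temperature
  v <- model$mode_vectors
  v %*% (t(v) * (kT / model$mode_values))
}

#' Closed-form per-node RMSF predicted by an ENM
#' @param model An `ENMModel`.
#' @return Numeric vector, sqrt of the trace of each node's 3x3 block.
#' @export
enm_rmsf <- function(model) {
  kT <- KB_KCAL * model$temperature
  w <- kT / model$mode_values
  per_coord <- (model$mode_vectors^2) %*% w
  sqrt(colSums(matrix(per_coord, nrow = 3)))
}

#' Closed-form ENM cross-correlation matrix
#'
#' C_ij = tr(Sigma_ij) / sqrt(tr(Sigma_ii) tr(Sigma_jj)) on the model
#' covariance; the analytic counterpart of [dccm()].
#'
#' @param model An `ENMModel`.
#' @return N x N matrix in `[-1, 1]`.
#' @export
enm_correlation <- function(model) {
  sigma <- enm_covariance(model)
  n <- model$n_nodes
  tr <- matrix(0, n, n)
  for (k in 0:2) {
    idx <- seq(1, 3 * n, by = 3) + k
    tr <- tr + sigma[idx, idx]
  }
  dvec <- sqrt(diag(tr))
  tr / outer(dvec, dvec)
}

#' Plant a Gaussian collective mode
#'
#' @param vector Length-3N displacement direction (normalized internally).
#' @param sigma Gaussian amplitude standard deviation in Angstrom.
#' @param label Free-text label.
#' @return A `PlantedMode`.
#' @export
plant_gaussian_mode <- function(vector, sigma, label = "planted") {
  structure(list(vector = vector / vnorm(vector), type = "gaussian",
                 sigma = sigma, label = label),
            class = "PlantedMode")
}

#' Plant a two-state lid-opening mode
#'
#' The mode vector is nonzero only on the lid nodes and points outward along
#' the protein-centroid-to-lid-centroid axis; its amplitude takes two values
#' {0, displacement} (closed/open) so that the open state moves the lid
#' centroid by exactly `displacement` Angstrom outward.
#'
#' @param model An `ENMModel`.
#' @param lid_mask `SelectionMask` (atom indices into the model's structure)
#'   or an integer vector of node indices.
#' @param open_occupancy Fraction of frames in the open state, in (0, 1).
#' @param displacement Open-state lid-centroid displacement in Angstrom.
#' @return A `PlantedMode` with per-frame two-state amplitudes.
#' @export
plant_two_state_lid <- function(model, lid_mask, open_occupancy,
                                displacement) {
  if (!(open_occupancy > 0 && open_occupancy < 1))
    stop("open_occupancy must lie strictly between 0 and 1")
  idx <- mask_indices(lid_mask)
  nodes <- match(idx, model$node_atoms)
  nodes <- nodes[!is.na(nodes)]
  if (length(nodes) == 0) stop("lid mask matches no network node")
  lid_centroid <- colMeans(model$coords[nodes, , drop = FALSE])
  protein_centroid <- colMeans(model$coords)
  direction <- unitv(lid_centroid - protein_centroid)
  vec <- numeric(3 * model$n_nodes)
  for (nd in nodes) vec[(3 * nd - 2):(3 * nd)] <- direction
  vec <- vec / vnorm(vec)
  structure(list(vector = vec, type = "two_state",
                 open_occupancy = open_occupancy,
                 displacement = displacement,
                 # unit-vector amplitude that moves the lid centroid by
                 # `displacement`: each lid node carries 1/sqrt(n_lid)
                 open_amplitude = displacement * sqrt(length(nodes)),
                 lid_nodes = nodes, label = "lid-opening"),
            class = "PlantedMode")
}

#' Sample a synthetic conformational ensemble from an ENM
#'
#' Frames are i.i.d. Gaussian samples in the model's vibrational-mode
#' subspace (per-mode variance kT/lambda), plus an optional planted
#' collective mode, plus optional rigid-body frame noise (uniform random
#' axis/bounded angle rotation about the centroid and a uniform translation).
#' Identical `(seed, arguments)` give bit-identical ensembles; the RNG is
#' R's Mersenne-Twister with inversion normals.
#'
#' @param model An `ENMModel`.
#' @param n_frames Number of frames (>= 1).
#' @param seed Integer seed (required).
#' @param planted Optional `PlantedMode`.
#' @param rigid_noise Optional `list(max_rotation_deg=, max_translation=)`.
#' @return An `Ensemble` whose topology is the model's node structure; the
#'   generation truth (model parameters, seed, planted state labels) is
#'   attached as attribute `"truth"` and, for two-state modes, as
#'   `frame_metadata$state`.
#' @export
sample_ensemble <- function(model, n_frames, seed, planted = NULL,
                            rigid_noise = NULL) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  n <- model$n_nodes
  kT <- KB_KCAL * model$temperature
  m <- length(model$mode_values)
  z <- matrix(stats::rnorm(n_frames * m), n_frames, m)
  disp <- z %*% (t(model$mode_vectors) * sqrt(kT / model$mode_values))
  state <- NULL
  if (!is.null(planted)) {
    if (planted$type == "gaussian") {
      amp <- stats::rnorm(n_frames, 0, planted$sigma)
    } else {
      state <- stats::rbinom(n_frames, 1, planted$open_occupancy)
      amp <- state * planted$open_amplitude
    }
    disp <- disp + outer(amp, planted$vector)
  }
  mean_xyz <- as.vector(t(model$coords))
  xyz <- sweep(disp, 2, mean_xyz, "+")
  if (!is.null(rigid_noise)) {
    max_rot <- rigid_noise$max_rotation_deg * pi / 180
    max_trans <- rigid_noise$max_translation
    for (f in seq_len(n_frames)) {
      axis <- stats::rnorm(3)
      theta <- stats::runif(1, 0, max_rot)
      shift <- stats::runif(3, -max_trans, max_trans)
      rot <- rotation_about_axis(axis, theta)
      fc <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
      ctr <- colMeans(fc)
      fc <- sweep(sweep(fc, 2, ctr) %*% t(rot), 2, ctr + shift, "+")
      xyz[f, ] <- as.vector(t(fc))
    }
  }
  topo <- model$structure
  if (length(model$node_atoms) != n_atoms(topo)) {
    topo <- new_structure(topo$atoms[model$node_atoms, , drop = FALSE],
                          title = topo$title)
  }
  meta <- if (!is.null(state)) data.frame(state = state) else NULL
  ens <- new_ensemble(topo, xyz, frame_metadata = meta)
  attr(ens, "truth") <- list(
    seed = seed, cutoff = model$cutoff, gamma = model$gamma,
    temperature = model$temperature, n_frames = n_frames,
    planted = if (is.null(planted)) NULL else
      planted[setdiff(names(planted), "vector")],
    planted_vector = if (is.null(planted)) NULL else planted$vector,
    state = state)
  ens
}

#' Write the generation truth of a sampled ensemble to JSON
#'
#' @param ensemble An ensemble from [sample_ensemble()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(ensemble, path) {
  truth <- attr(ensemble, "truth")
  if (is.null(truth)) stop("ensemble carries no generation truth")
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
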