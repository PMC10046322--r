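# Contact-persistence maps, pocket-residue identification, and the
# correlation-weighted dynamical network / community layer (edges on
# persistent contacts, -log|C| weights, Girvan-Newman communities,
# inter-community flow from edge betweenness).

.residue_atom_map <- function(structure, atom_level = c("heavy", "ca", "all")) {
  atom_level <- match.arg(atom_level)
  atoms <- structure$atoms
  keep <- switch(atom_level,
                 heavy = toupper(atoms$element) != "H",
                 ca = atoms$name == "CA" & !atoms$het,
                 all = rep(TRUE, nrow(atoms)))
  idx <- which(keep)
  split(idx, paste(atoms$chain[idx], atoms$resno[idx], sep = "|"))
}

# Per-frame minimum inter-atom distance between two atom sets, vectorized
# over frames.
.min_dist_series <- function(xyz, atoms_a, atoms_b) {
  best <- rep(Inf, nrow(xyz))
  for (i in atoms_a) {
    ci <- (3 * i - 2):(3 * i)
    for (j in atoms_b) {
      cj <- (3 * j - 2):(3 * j)
      d2 <- (xyz[, ci[1]] - xyz[, cj[1]])^2 +
        (xyz[, ci[2]] - xyz[, cj[2]])^2 +
        (xyz[, ci[3]] - xyz[, cj[3]])^2
      best <- pmin(best, d2)
    }
  }
  sqrt(best)
}

#' Contact persistence between two residue regions
#'
#' A residue pair is in contact in a frame iff the minimum inter-residue
#' atom distance is at most `cutoff`; persistence is the fraction of frames
#' in contact.
#'
#' @param ensemble An `Ensemble`.
#' @param region_a,region_b `RegionDefinition`s.
#' @param cutoff Contact cutoff in Angstrom (default 4.5).
#' @param atom_level `"heavy"` or `"ca"`.
#' @return A `ContactPersistenceMap` data.frame with `resno_a`, `resno_b`,
#'   `persistence`; self-pairs excluded, contact definition in attributes.
#' @export
contact_persistence <- function(ensemble, region_a, region_b, cutoff = 4.5,
                                atom_level = c("heavy", "ca")) {
  atom_level <- match.arg(atom_level)
  if (length(region_a$resno) == 0 || length(region_b$resno) == 0)
    stop("empty region")
  amap <- .residue_atom_map(ensemble$topology, atom_level)
  key_a <- paste(region_a$chain, region_a$resno, sep = "|")
  key_b <- paste(region_b$chain, region_b$resno, sep = "|")
  missing <- c(setdiff(key_a, names(amap)), setdiff(key_b, names(amap)))
  if (length(missing) > 0)
    stop("region residues without ", atom_level, " atoms: ",
         paste(missing, collapse = ", "))
  out <- expand.grid(resno_a = region_a$resno, resno_b = region_b$resno)
  if (identical(region_a$chain, region_b$chain))
    out <- out[out$resno_a != out$resno_b, , drop = FALSE]
  out$persistence <- mapply(function(ra, rb) {
    d <- .min_dist_series(ensemble$xyz,
                          amap[[paste(region_a$chain, ra, sep = "|")]],
                          amap[[paste(region_b$chain, rb, sep = "|")]])
    mean(d <= cutoff)
  }, out$resno_a, out$resno_b)
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  attr(out, "atom_level") <- atom_level
  class(out) <- c("ContactPersistenceMap", "data.frame")
  out
}

#' Pocket residues around a ligand
#'
#' Residues with any heavy atom within `radius` of any ligand heavy atom.
#'
#' @param structure A `Structure` containing the ligand (HETATM records or a
#'   mask you pass explicitly).
#' @param ligand_mask `SelectionMask` of the ligand atoms.
#' @param radius Angstrom (default 5, the usual pocket definition).
#' @return A `RegionDefinition` named `"pocket"`.
#' @export
pocket_residues <- function(structure, ligand_mask, radius = 5.0) {
  lig <- mask_indices(ligand_mask)
  if (length(lig) == 0) stop("ligand mask is empty")
  atoms <- structure$atoms
  heavy <- toupper(atoms$element) != "H"
  lig <- lig[heavy[lig]]
  cand <- setdiff(which(heavy & !seq_len(nrow(atoms)) %in% lig), lig)
  xyz <- coords(structure)
  d2 <- .min_sq_dist_to_set(xyz[cand, , drop = FALSE],
                            xyz[lig, , drop = FALSE])
  hit <- cand[d2 <= radius^2]
  resno <- sort(unique(atoms$resno[hit]))
  chain <- unique(atoms$chain[hit])
  region_definition("pocket", resno, chain = chain[1])
}

# All-pairs residue contact persistence (Calpha fast path; heavy-atom path
# prefilters candidate pairs on the mean structure).
.all_pairs_persistence <- function(ensemble, resno, amap, cutoff,
                                   atom_level) {
  n <- length(resno)
  nf <- n_frames(ensemble)
  single <- all(lengths(amap) == 1)
  counts <- matrix(0, n, n)
  if (single) {
    idx <- unlist(amap)
    cols <- xyz_columns(idx)
    for (f in seq_len(nf)) {
      fc <- matrix(ensemble$xyz[f, cols], ncol = 3, byrow = TRUE)
      counts <- counts + (as.matrix(stats::dist(fc)) <= cutoff)
    }
    return(counts / nf)
  }
  mean_fc <- matrix(colMeans(ensemble$xyz), ncol = 3, byrow = TRUE)
  cent <- t(vapply(amap, function(a)
    colMeans(mean_fc[a, , drop = FALSE]), numeric(3)))
  reach <- max(vapply(seq_along(amap), function(i) {
    max(sqrt(rowSums(sweep(mean_fc[amap[[i]], , drop = FALSE], 2,
                           cent[i, ])^2)))
  }, numeric(1)))
  cd <- as.matrix(stats::dist(cent))
  cand <- which(cd <= cutoff + 2 * reach + 5 & upper.tri(cd), arr.ind = TRUE)
  for (p in seq_len(nrow(cand))) {
    i <- cand[p, 1]; j <- cand[p, 2]
    d <- .min_dist_series(ensemble$xyz, amap[[i]], amap[[j]])
    counts[i, j] <- counts[j, i] <- sum(d <= cutoff)
  }
  counts / nf
}

#' Build a dynamical residue network
#'
#' Nodes are residues (one per Calpha); an edge joins two non-covalent
#' neighbours (|i - j| > 1) that are in contact in at least
#' `persistence_cutoff` of frames, with distance weight `-log|C_ij|`
#' (|C| clamped to [1e-6, 1 - 1e-6]) and affinity |C_ij| kept for
#' modularity.
#'
#' @param ensemble An `Ensemble`.
#' @param correlation A `CorrelationMatrix` from [dccm()] on the same
#'   residue set.
#' @param persistence_cutoff Fraction of frames (default 0.75).
#' @param distance_cutoff Contact cutoff in Angstrom (default 4.5).
#' @param atom_level `"heavy"` or `"ca"` (use `"ca"` with a wider cutoff for
#'   Calpha-only models).
#' @return A `DynamicalNetwork`: an igraph graph (vertex name = resno, edge
#'   attributes `weight`, `affinity`, `cij`, `persistence`) plus parameters.
#' @export
build_network <- function(ensemble, correlation, persistence_cutoff = 0.75,
                          distance_cutoff = 4.5,
                          atom_level = c("heavy", "ca")) {
  atom_level <- match.arg(atom_level)
  ca <- select_atoms(ensemble$topology, "ca")
  resno <- ensemble$topology$atoms$resno[ca$indices]
  if (!identical(as.character(resno), rownames(correlation)))
    stop("correlation matrix residue set does not match the ensemble")
  atoms <- ensemble$topology$atoms
  amap_all <- .residue_atom_map(ensemble$topology, atom_level)
  key <- paste(atoms$chain[ca$indices], resno, sep = "|")
  amap <- amap_all[key]
  pers <- .all_pairs_persistence(ensemble, resno, amap, distance_cutoff,
                                 atom_level)
  n <- length(resno)
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  adj <- pers >= persistence_cutoff & sep > 1
  pairs <- which(adj & upper.tri(adj), arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(resno))
  if (nrow(pairs) > 0) {
    cij <- correlation[pairs]
    cabs <- pmin(pmax(abs(cij), 1e-6), 1 - 1e-6)
    g <- igraph::add_edges(g, t(pairs))
    g <- igraph::set_edge_attr(g, "cij", value = cij)
    g <- igraph::set_edge_attr(g, "affinity", value = cabs)
    g <- igraph::set_edge_attr(g, "weight", value = -log(cabs))
    g <- igraph::set_edge_attr(g, "persistence", value = pers[pairs])
  }
  structure(list(graph = g, resno = resno,
                 params = list(persistence_cutoff = persistence_cutoff,
                               distance_cutoff = distance_cutoff,
                               atom_level = atom_level)),
            class = "DynamicalNetwork")
}

#' @export
print.DynamicalNetwork <- function(x, ...) {
  cat("DynamicalNetwork:", igraph::vcount(x$graph), "residues,",
      igraph::ecount(x$graph), "edges (contact >=",
      x$params$persistence_cutoff, "of frames at",
      x$params$distance_cutoff, "A)\n")
  invisible(x)
}

.as_network_graph <- function(x) {
  g <- if (inherits(x, "DynamicalNetwork")) x$graph else x
  if (!igraph::is_igraph(g)) stop("need a DynamicalNetwork or igraph graph")
  if (is.null(igraph::edge_attr(g, "weight")))
    g <- igraph::set_edge_attr(g, "weight", value = rep(1, igraph::ecount(g)))
  if (is.null(igraph::edge_attr(g, "affinity")))
    g <- igraph::set_edge_attr(g, "affinity",
                               value = exp(-igraph::E(g)$weight))
  if (is.null(igraph::vertex_attr(g, "name")))
    g <- igraph::set_vertex_attr(g, "name",
                                 value = as.character(seq_len(igraph::vcount(g))))
  g
}

# Deterministic choice of the maximum-betweenness edge: ties broken by the
# lexicographically smallest (numeric) endpoint pair.
.max_betweenness_edge <- function(g) {
  eb <- igraph::edge_betweenness(g, directed = FALSE,
                                 weights = igraph::E(g)$weight)
  ends <- igraph::ends(g, igraph::E(g), names = TRUE)
  a <- suppressWarnings(as.numeric(ends[, 1]))
  b <- suppressWarnings(as.numeric(ends[, 2]))
  if (anyNA(a) || anyNA(b)) { a <- ends[, 1]; b <- ends[, 2] }
  lo <- pmin(a, b); hi <- pmax(a, b)
  cand <- which(eb >= max(eb) - 1e-12 * max(max(eb), 1))
  cand[order(lo[cand], hi[cand])][1]
}

#' Girvan-Newman community detection
#'
#' Iteratively removes the edge of maximal weighted (shortest-path) edge
#' betweenness, using edge weights as distances; ties are broken on the
#' lexicographically smallest endpoint pair.  The returned partition either
#' maximizes Newman weighted modularity -- evaluated on the original graph
#' with *affinity* weights (|C| for a [build_network()] graph), since the
#' -log|C| distance weights are not strengths -- or is the first partition
#' with `k` components.
#'
#' @param network A `DynamicalNetwork` or igraph graph (edge attribute
#'   `weight` = distance; optional `affinity` = strength, default
#'   `exp(-weight)`).
#' @param k Optional target community count; default: maximize modularity.
#' @return A `CommunityPartition`: `membership` (named by residue),
#'   `n_communities`, `modularity`.
#' @export
girvan_newman_communities <- function(network, k = NULL) {
  g0 <- .as_network_graph(network)
  if (igraph::vcount(g0) == 0) stop("empty graph")
  aff <- igraph::E(g0)$affinity
  best <- NULL
  g <- g0
  repeat {
    comp <- igraph::components(g)
    membership <- comp$membership
    q <- igraph::modularity(g0, membership, weights = aff)
    if (!is.null(k)) {
      if (comp$no >= k) {
        best <- list(membership = membership, modularity = q)
        break
      }
    } else if (is.null(best) || q > best$modularity + 1e-12) {
      best <- list(membership = membership, modularity = q)
    }
    if (igraph::ecount(g) == 0) break
    g <- igraph::delete_edges(g, .max_betweenness_edge(g))
  }
  memb <- best$membership
  names(memb) <- igraph::V(g0)$name
  # relabel communities by order of first appearance for determinism
  memb <- match(memb, unique(memb))
  names(memb) <- igraph::V(g0)$name
  structure(list(membership = memb,
                 n_communities = length(unique(memb)),
                 modularity = best$modularity),
            class = "CommunityPartition")
}

#' @export
print.CommunityPartition <- function(x, ...) {
  cat("CommunityPartition:", x$n_communities, "communities, modularity",
      sprintf("%.3f", x$modularity), "\n")
  invisible(x)
}

#' Inter-community communication flow
#'
#' Edge betweenness is computed once on the full weighted graph (weights as
#' distances); `flow(A, B)` is the sum over edges with one endpoint in A and
#' the other in B.  Diagonal entries hold the intra-community sums, so the
#' table's total equals the total edge betweenness.
#'
#' @param network A `DynamicalNetwork` or igraph graph.
#' @param partition A `CommunityPartition` (or membership vector).
#' @return Symmetric k x k matrix of betweenness flow.
#' @export
intercommunity_flow <- function(network, partition) {
  g <- .as_network_graph(network)
  memb <- if (inherits(partition, "CommunityPartition"))
    partition$membership else partition
  if (length(memb) != igraph::vcount(g))
    stop("partition length does not match the graph")
  eb <- igraph::edge_betweenness(g, directed = FALSE,
                                 weights = igraph::E(g)$weight)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  k <- length(unique(memb))
  flow <- matrix(0, k, k)
  for (e in seq_along(eb)) {
    a <- memb[ends[e, 1]]; b <- memb[ends[e, 2]]
    if (a == b) flow[a, a] <- flow[a, a] + eb[e]
    else {
      flow[a, b] <- flow[a, b] + eb[e]
      flow[b, a] <- flow[b, a] + eb[e]
    }
  }
  dimnames(flow) <- list(seq_len(k), seq_len(k))
  flow
}

#' Seeded planted-partition benchmark graph
#'
#' k blocks of `n_per_block` nodes; within-block edges with probability
#' `p_in`, between-block with `p_out`; unit weights and affinities.  The
#' planted block labels are stored in the vertex attribute `block`.
#'
#' @param n_per_block,k Block size and count.
#' @param p_in,p_out Edge probabilities.
#' @param seed Integer seed.
#' @return An igraph graph.
#' @export
sample_planted_partition_graph <- function(n_per_block = 12, k = 3,
                                           p_in = 0.9, p_out = 0.05,
                                           seed = 1) {
  set.seed(seed, kind = "Mersenne-Twister")
  n <- n_per_block * k
  block <- rep(seq_len(k), each = n_per_block)
  pairs <- t(utils::combn(n, 2))
  p <- ifelse(block[pairs[, 1]] == block[pairs[, 2]], p_in, p_out)
  keep <- stats::runif(nrow(pairs)) < p
  g <- igraph::graph_from_edgelist(pairs[keep, , drop = FALSE],
                                   directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  g <- igraph::set_vertex_attr(g, "name", value = as.character(seq_len(n)))
  g <- igraph::set_vertex_attr(g, "block", value = block)
  g <- igraph::set_edge_attr(g, "weight", value = rep(1, igraph::ecount(g)))
  g <- igraph::set_edge_attr(g, "affinity", value = rep(1, igraph::ecount(g)))
  g
}
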