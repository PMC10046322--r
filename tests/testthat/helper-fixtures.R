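# Shared fixtures and independent oracles, all built in code.

# Minimal one-glycine PDB text (3 atoms).
toy_gly_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       2.009   1.420   0.000  1.00  0.00           C",
    "END"), path)
  path
}

# A small Calpha-only structure with arbitrary residue numbers.
ca_structure <- function(xyz, resno = seq_len(nrow(xyz)), chain = "A",
                         resname = "ALA") {
  new_structure(data.frame(chain = chain, resno = resno, resname = resname,
                           name = "CA", element = "C", het = FALSE,
                           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], b = 0))
}

# Ensemble from a list of N x 3 coordinate matrices over one topology.
ensemble_from_frames <- function(topology, frames) {
  new_ensemble(topology, do.call(rbind, lapply(frames, function(f)
    as.vector(t(f)))))
}

random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# EstJ6-like Calpha topology used when author numbering matters.
estj6_like <- function() benchmark_structure(seed = 42)

# Brute-force all-pairs shortest-path edge betweenness: Floyd-Warshall
# distances, then exhaustive enumeration of every shortest path with equal
# splitting among ties.  Independent of igraph's Brandes implementation.
brute_force_edge_betweenness <- function(g) {
  n <- igraph::vcount(g)
  W <- matrix(Inf, n, n)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, nrow(ends))
  for (e in seq_len(nrow(ends))) {
    W[ends[e, 1], ends[e, 2]] <- w[e]
    W[ends[e, 2], ends[e, 1]] <- w[e]
  }
  D <- W; diag(D) <- 0
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], "+"))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  emap <- stats::setNames(seq_len(nrow(ends)), key(ends[, 1], ends[, 2]))
  adj <- lapply(seq_len(n), function(i) which(is.finite(W[i, ])))
  eb <- numeric(nrow(ends))
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t])) next
    paths <- list()
    rec <- function(v, path) {
      if (v == t) { paths[[length(paths) + 1]] <<- path; return(invisible()) }
      for (u in adj[[v]])
        if (abs(W[v, u] + D[u, t] - D[v, t]) < 1e-9) rec(u, c(path, u))
    }
    rec(s, s)
    np <- length(paths)
    for (p in paths) for (i in seq_len(length(p) - 1))
      eb[emap[[key(p[i], p[i + 1])]]] <-
        eb[emap[[key(p[i], p[i + 1])]]] + 1 / np
  }
  eb
}

# Two q-cliques joined by a single bridge edge, unit weights.
two_clique_graph <- function(q = 6) {
  el <- rbind(t(utils::combn(1:q, 2)), t(utils::combn((q + 1):(2 * q), 2)),
              c(q, q + 1))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name",
                               value = as.character(seq_len(2 * q)))
  g <- igraph::set_edge_attr(g, "weight", value = rep(1, nrow(el)))
  igraph::set_edge_attr(g, "affinity", value = rep(1, nrow(el)))
}

# All-atom mini active site: SER146 (OG), GLU240 (OE1/OE2), HIS270
# (ND1/NE2), with controllable key coordinates.
triad_structure <- function(og = c(0, 0, 0), ne2 = c(0, 0, 4.96),
                            nd1 = c(3, 0, 5), oe1 = c(9, 0, 5),
                            oe2 = c(8, 0, 5)) {
  row <- function(resno, resname, name, element, p)
    data.frame(chain = "A", resno = resno, resname = resname, name = name,
               element = element, het = FALSE,
               x = p[1], y = p[2], z = p[3], b = 0)
  new_structure(rbind(
    row(146, "SER", "CA", "C", og + c(-1.5, 0, 0)),
    row(146, "SER", "OG", "O", og),
    row(240, "GLU", "CA", "C", oe1 + c(1.5, 0, 0)),
    row(240, "GLU", "OE1", "O", oe1),
    row(240, "GLU", "OE2", "O", oe2),
    row(270, "HIS", "CA", "C", ne2 + c(0, 1.5, 0)),
    row(270, "HIS", "ND1", "N", nd1),
    row(270, "HIS", "NE2", "N", ne2)))
}
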