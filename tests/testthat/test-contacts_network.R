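test_that("contact persistence counts frames below the cutoff exactly", {
  topo <- ca_structure(rbind(c(0, 0, 0), c(3, 0, 0)), resno = c(1, 50))
  stay <- ensemble_from_frames(topo, replicate(5, coords(topo),
                                               simplify = FALSE))
  ra <- region_definition("a", 1)
  rb <- region_definition("b", 50)
  expect_equal(contact_persistence(stay, ra, rb, cutoff = 4.5,
                                   atom_level = "ca")$persistence, 1.0)
  # 7 of 10 frames in contact: separations 3,3,3,3,3,3,3,6,6,6
  seps <- c(rep(3, 7), rep(6, 3))
  frames <- lapply(seps, function(d) rbind(c(0, 0, 0), c(d, 0, 0)))
  ens <- ensemble_from_frames(topo, frames)
  expect_equal(contact_persistence(ens, ra, rb, cutoff = 4.5,
                                   atom_level = "ca")$persistence, 0.7)
  expect_equal(contact_persistence(ens, ra, rb, cutoff = 1.0,
                                   atom_level = "ca")$persistence, 0.0)
  # frame-order invariance and symmetry
  ens_rev <- ensemble_from_frames(topo, rev(frames))
  expect_equal(contact_persistence(ens_rev, ra, rb, cutoff = 4.5,
                                   atom_level = "ca")$persistence, 0.7)
  expect_equal(contact_persistence(ens, rb, ra, cutoff = 4.5,
                                   atom_level = "ca")$persistence, 0.7)
})

test_that("pocket residues honor the 5 A boundary", {
  at <- rbind(
    data.frame(chain = "A", resno = 1, resname = "DBP", name = "C1",
               element = "C", het = TRUE, x = 0, y = 0, z = 0, b = 0),
    data.frame(chain = "A", resno = 10, resname = "ALA", name = "CA",
               element = "C", het = FALSE, x = 4.9, y = 0, z = 0, b = 0),
    data.frame(chain = "A", resno = 11, resname = "ALA", name = "CA",
               element = "C", het = FALSE, x = 5.1, y = 0, z = 0, b = 0),
    data.frame(chain = "A", resno = 12, resname = "ALA", name = "CA",
               element = "C", het = FALSE, x = 0, y = 3, z = 0, b = 0))
  s <- new_structure(at)
  pocket <- pocket_residues(s, select_atoms(s, "ligand"), radius = 5)
  expect_setequal(pocket$resno, c(10, 12))
})

test_that("network edges carry -log|C| weights with clamping", {
  s <- ring_structure(8, radius = 5)
  m <- build_enm(s)
  ens <- sample_ensemble(m, 200, seed = 20)
  cm <- dccm(ens)
  net <- build_network(ens, cm, persistence_cutoff = 0.5,
                       distance_cutoff = 6, atom_level = "ca")
  g <- net$graph
  expect_gt(igraph::ecount(g), 0)
  expect_true(all(igraph::E(g)$weight > 0))
  expect_equal(igraph::E(g)$weight,
               -log(pmin(pmax(abs(igraph::E(g)$cij), 1e-6), 1 - 1e-6)))
  # covalent neighbours excluded
  ends <- igraph::ends(g, igraph::E(g))
  expect_true(all(abs(as.integer(ends[, 1]) - as.integer(ends[, 2])) > 1))
  # weights decrease monotonically as |C| grows
  ord <- order(abs(igraph::E(g)$cij))
  expect_true(all(diff(igraph::E(g)$weight[ord]) <= 1e-12))
})

test_that("module betweenness equals the brute-force oracle exactly", {
  set.seed(21)
  for (case in 1:3) {
    g <- sample_planted_partition_graph(n_per_block = 5, k = 3,
                                        p_in = 0.8, p_out = 0.15,
                                        seed = 100 + case)
    w <- runif(igraph::ecount(g), 0.5, 2)
    g <- igraph::set_edge_attr(g, "weight", value = w)
    eb <- igraph::edge_betweenness(g, directed = FALSE,
                                   weights = igraph::E(g)$weight)
    expect_equal(eb, brute_force_edge_betweenness(g), tolerance = 1e-9)
  }
})

test_that("the bridge between two cliques is severed first", {
  g <- two_clique_graph(6)
  eb <- igraph::edge_betweenness(g, directed = FALSE,
                                 weights = igraph::E(g)$weight)
  ends <- igraph::ends(g, igraph::E(g))
  bridge <- which((ends[, 1] == "6" & ends[, 2] == "7") |
                    (ends[, 1] == "7" & ends[, 2] == "6"))
  expect_equal(which.max(eb), bridge)
  part <- girvan_newman_communities(g)
  expect_equal(part$n_communities, 2)
  expect_equal(unname(part$membership[as.character(1:6)]), rep(1, 6))
  expect_equal(unname(part$membership[as.character(7:12)]), rep(2, 6))
})

test_that("a complete graph stays one community at maximal modularity", {
  n <- 8
  el <- t(utils::combn(n, 2))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = rep(1, nrow(el)))
  g <- igraph::set_edge_attr(g, "affinity", value = rep(1, nrow(el)))
  part <- girvan_newman_communities(g)
  expect_equal(part$n_communities, 1)
  expect_equal(part$modularity, 0, tolerance = 1e-12)
})

test_that("Girvan-Newman recovers a seeded planted partition exactly", {
  skip_if_not_installed("mclust")
  g <- sample_planted_partition_graph(n_per_block = 12, k = 3,
                                      p_in = 0.9, p_out = 0.05, seed = 7)
  part <- girvan_newman_communities(g)
  ari <- mclust::adjustedRandIndex(part$membership,
                                   igraph::V(g)$block)
  expect_equal(ari, 1.0)
  expect_equal(part$n_communities, 3)
})

test_that("inter-community flow equals cross-edge betweenness and conserves", {
  g <- two_clique_graph(6)
  part <- girvan_newman_communities(g)
  flow <- intercommunity_flow(g, part)
  eb <- igraph::edge_betweenness(g, directed = FALSE,
                                 weights = igraph::E(g)$weight)
  ends <- igraph::ends(g, igraph::E(g))
  bridge <- which((ends[, 1] == "6" & ends[, 2] == "7") |
                    (ends[, 1] == "7" & ends[, 2] == "6"))
  expect_equal(flow[1, 2], eb[bridge])
  expect_equal(flow[1, 2], flow[2, 1])
  expect_equal(sum(diag(flow)) + flow[1, 2], sum(eb))
  # merging the two communities conserves the total
  merged <- intercommunity_flow(g, rep(1, igraph::vcount(g)))
  expect_equal(sum(merged), sum(eb))
})

test_that("strengthening coupling merges communities (count falls)", {
  # same topology (two blocks densely inter-wired), planted cross-block
  # correlation strength varied: weak coupling splits, strong merges
  gw <- sample_planted_partition_graph(n_per_block = 10, k = 2,
                                       p_in = 1.0, p_out = 0.6, seed = 5)
  ends <- igraph::ends(gw, igraph::E(gw), names = FALSE)
  block <- igraph::V(gw)$block
  cross <- block[ends[, 1]] != block[ends[, 2]]
  reweight <- function(g, aff_cross) {
    aff <- ifelse(cross, aff_cross, 0.9)
    g <- igraph::set_edge_attr(g, "affinity", value = aff)
    igraph::set_edge_attr(g, "weight", value = -log(aff))
  }
  n_weak <- girvan_newman_communities(reweight(gw, 0.02))$n_communities
  n_strong <- girvan_newman_communities(reweight(gw, 0.9))$n_communities
  expect_gt(n_weak, n_strong)
})
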