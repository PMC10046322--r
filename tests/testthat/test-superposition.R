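test_that("kabsch recovers exact rigid motions and refuses degeneracy", {
  set.seed(1)
  p <- matrix(rnorm(30), 10, 3)
  sp0 <- kabsch(p, p)
  expect_equal(sp0$rotation, diag(3), tolerance = 1e-10)
  expect_equal(sp0$rmsd, 0, tolerance = 1e-10)
  rot90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)  # 90 deg about z
  q <- sweep(p %*% t(rot90), 2, c(1, 0, 0), "+")
  sp <- kabsch(p, q)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(apply_superposition(p, sp), q, tolerance = 1e-10)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-10)
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch(line, line), "collinear")
  expect_error(kabsch(p[1:2, ], p[1:2, ]), "at least 3")
})

test_that("kabsch beats a brute-force random-rotation search", {
  set.seed(2)
  p <- matrix(rnorm(30), 10, 3)
  q <- p + matrix(rnorm(30, sd = 0.3), 10, 3)
  best <- Inf
  qc <- sweep(q, 2, colMeans(q))
  pc <- sweep(p, 2, colMeans(p))
  for (i in 1:2000) {
    r <- random_rotation()
    best <- min(best, sqrt(mean(rowSums((pc %*% t(r) - qc)^2))))
  }
  expect_lte(kabsch(p, q)$rmsd, best + 1e-12)
})

test_that("kabsch agrees with the bio3d fitting oracle", {
  set.seed(3)
  p <- matrix(rnorm(45), 15, 3)
  q <- p + matrix(rnorm(45, sd = 0.5), 15, 3)
  mine <- kabsch(p, q)$rmsd
  oracle <- bio3d::rmsd(as.vector(t(q)), as.vector(t(p)), fit = TRUE)
  expect_lt(abs(mine - oracle), 6e-4)  # bio3d rounds to 3 decimals
})

test_that("rmsd_series is zero for copies and rigid transforms of the reference", {
  topo <- ca_structure(matrix(rnorm(36), 12, 3) * 4)
  ref <- coords(topo)
  rot <- random_rotation()
  frames <- list(ref, sweep(ref %*% t(rot), 2, c(5, 0, 0), "+"), ref + 5)
  ens <- ensemble_from_frames(topo, frames)
  expect_equal(rmsd_series(ens), rep(0, 3), tolerance = 1e-8)
})

test_that("rmsd_series matches hand arithmetic on a 4-atom fixture", {
  topo <- ca_structure(rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0),
                             c(0, 0, 4)))
  ref <- coords(topo)
  moved <- ref; moved[4, 3] <- 5  # one atom displaced 1 A
  ens <- ensemble_from_frames(topo, list(moved))
  fit3 <- structure(
    list(indices = 1:3, provenance = "first three", frame = "n/a"),
    class = "SelectionMask")
  # fitting on the 3 undisplaced atoms leaves them imperfect only through
  # centroid/rotation coupling of the measure set; measuring all 4 after a
  # fit on atoms 1-3 must equal the explicit per-atom formula
  val <- rmsd_series(ens, fit_mask = fit3,
                     measure_mask = structure(
                       list(indices = 1:4, provenance = "all",
                            frame = "n/a"), class = "SelectionMask"))
  direct <- {
    sp <- kabsch(moved, ref, mask = 1:3)
    fitted <- apply_superposition(moved, sp)
    sqrt(mean(rowSums((fitted - ref)^2)))
  }
  expect_equal(val, direct, tolerance = 1e-12)
  # and the unfitted displacement is exactly sqrt(1/4)
  expect_equal(sqrt(mean(rowSums((moved - ref)^2))), sqrt(1 / 4))
})

test_that("RMSF is zero for a static ensemble and order-independent", {
  topo <- ca_structure(matrix(rnorm(30), 10, 3) * 5)
  static <- ensemble_from_frames(topo, replicate(4, coords(topo),
                                                 simplify = FALSE))
  expect_equal(rmsf_profile(static)$rmsf, rep(0, 10), tolerance = 1e-10)
  expect_error(rmsf_profile(ensemble_from_frames(topo, list(coords(topo)))),
               "at least 2")
  set.seed(4)
  frames <- replicate(30, coords(topo) + matrix(rnorm(30, sd = 0.4), 10, 3),
                      simplify = FALSE)
  ens <- ensemble_from_frames(topo, frames)
  ens_perm <- ensemble_from_frames(topo, frames[sample(30)])
  expect_equal(rmsf_profile(ens)$rmsf, rmsf_profile(ens_perm)$rmsf,
               tolerance = 1e-8)
})

test_that("planted lid residues dominate the RMSF profile", {
  s <- benchmark_structure()
  m <- build_enm(s)
  lid <- select_atoms(s, "ca and resid 182-199")
  pm <- plant_two_state_lid(m, lid, 0.5, 6)
  ens <- sample_ensemble(m, 400, seed = 9, planted = pm)
  prof <- rmsf_profile(ens)
  in_lid <- prof$resno %in% 182:199
  expect_gt(min(prof$rmsf[in_lid]), max(prof$rmsf[!in_lid]))
})

test_that("RMSF differences annotate the B-factor column at format precision", {
  topo <- ca_structure(matrix(rnorm(24), 8, 3) * 5)
  set.seed(5)
  mk <- function(sd) ensemble_from_frames(topo, replicate(25,
    coords(topo) + matrix(rnorm(24, sd = sd), 8, 3), simplify = FALSE))
  pa <- rmsf_profile(mk(0.8)); pb <- rmsf_profile(mk(0.3))
  expect_equal(rmsf_difference(pa, pa)$delta, rep(0, 8))
  tf <- withr::local_tempfile(fileext = ".pdb")
  d <- rmsf_difference(pa, pb, structure = topo, path = tf)
  back <- read_structure(tf)
  expect_equal(back$atoms$b, round(d$delta, 2), tolerance = 1e-9)
})

test_that("radius of gyration matches closed forms and a direct-sum oracle", {
  single <- ensemble_from_frames(ca_structure(rbind(c(1, 2, 3))),
                                 list(rbind(c(1, 2, 3))))
  expect_equal(radius_of_gyration(single), 0)
  pair <- ca_structure(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(radius_of_gyration(ensemble_from_frames(pair,
                                                       list(coords(pair)))),
               1.0)
  ringens <- ensemble_from_frames(ring_structure(),
                                  list(coords(ring_structure())))
  xyz <- coords(ring_structure())
  com <- colMeans(xyz)  # equal carbon masses cancel
  oracle <- sqrt(mean(rowSums(sweep(xyz, 2, com)^2)))
  expect_equal(radius_of_gyration(ringens), oracle, tolerance = 1e-10)
})

test_that("vectorized pairwise RMSD equals the looped Kabsch computation", {
  s <- ring_structure(10)
  m <- build_enm(s)
  ens <- sample_ensemble(m, 15, seed = 12)
  dmat <- pairwise_rmsd(ens)
  for (a in c(1, 4, 9)) for (b in c(2, 7, 15)) {
    fa <- matrix(ens$xyz[a, ], ncol = 3, byrow = TRUE)
    fb <- matrix(ens$xyz[b, ], ncol = 3, byrow = TRUE)
    expect_equal(dmat[a, b], kabsch(fa, fb)$rmsd, tolerance = 1e-8)
  }
  expect_equal(dmat, t(dmat))
})

test_that("clustering recovers planted two-state populations", {
  s <- benchmark_structure()
  m <- build_enm(s)
  lid <- select_atoms(s, "ca and resid 182-199")
  pm <- plant_two_state_lid(m, lid, 2 / 3, 4)
  ens <- sample_ensemble(m, 600, seed = 43, planted = pm)
  cl <- cluster_frames(ens, k = 2)
  expect_equal(cl$fractions[1], 2 / 3, tolerance = 0.03)
  expect_equal(cl$fractions[2], 1 / 3, tolerance = 0.03)
  truth <- attr(ens, "truth")$state
  agree <- max(mean((cl$labels == 1) == (truth == 1)),
               mean((cl$labels == 2) == (truth == 1)))
  expect_gt(agree, 0.97)
  expect_true(all(cl$labels[cl$medoids] == seq_len(cl$k)))
})

test_that("degenerate clustering inputs are handled deterministically", {
  topo <- ca_structure(matrix(rnorm(15), 5, 3) * 4)
  dup <- ensemble_from_frames(topo, replicate(6, coords(topo),
                                              simplify = FALSE))
  cl1 <- cluster_frames(dup, k = 1)
  expect_equal(cl1$fractions, 1.0)
  cl2a <- cluster_frames(dup, k = 2)
  cl2b <- cluster_frames(dup, k = 2)
  expect_identical(cl2a$labels, cl2b$labels)
  expect_error(cluster_frames(dup, k = 7), "exceeds")
})
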