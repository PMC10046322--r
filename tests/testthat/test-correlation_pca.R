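test_that("perfectly correlated and anti-correlated motions give +1 / -1", {
  topo <- ca_structure(rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0),
                             c(0, 10, 0), c(20, 10, 0)))
  base <- coords(topo)
  set.seed(6)
  amps <- rnorm(40)
  frames <- lapply(amps, function(a) {
    f <- base
    f[1, ] <- f[1, ] + a * c(1, 0, 0)   # atoms 1,2 move together
    f[2, ] <- f[2, ] + a * c(1, 0, 0)
    f[3, ] <- f[3, ] - a * c(1, 0, 0)   # atom 3 moves opposite
    f[4, ] <- f[4, ] + rnorm(1) * c(0, 1, 0)
    f[5, ] <- f[5, ] + rnorm(1) * c(0, 0, 1)
    f
  })
  cm <- dccm(ensemble_from_frames(topo, frames), fit = FALSE)
  expect_equal(cm[1, 2], 1, tolerance = 1e-10)
  expect_equal(cm[1, 3], -1, tolerance = 1e-10)
  expect_true(all(diag(unclass(cm)) == 1))
  expect_true(all(abs(cm) <= 1 + 1e-12))
})

test_that("a zero-variance atom is reported by residue", {
  topo <- ca_structure(rbind(c(0, 0, 0), c(8, 0, 0), c(16, 0, 0)),
                       resno = c(5, 6, 7))
  base <- coords(topo)
  frames <- lapply(1:10, function(i) {
    f <- base; f[1, 1] <- f[1, 1] + rnorm(1); f[2, 2] <- f[2, 2] + rnorm(1)
    f  # atom 3 (residue 7) never moves
  })
  expect_error(dccm(ensemble_from_frames(topo, frames), fit = FALSE), "7")
})

test_that("sampled DCCM matches the analytic ENM correlation", {
  s <- ring_structure()
  m <- build_enm(s)
  ens <- sample_ensemble(m, 5000, seed = 7)
  cm <- dccm(ens)
  expect_lt(max(abs(unclass(cm) - enm_correlation(m))), 0.1)
})

test_that("DCCM agrees with the bio3d oracle on the same fitted coordinates", {
  s <- ring_structure()
  m <- build_enm(s)
  ens <- sample_ensemble(m, 300, seed = 8)
  mine <- dccm(ens, fit = FALSE)
  oracle <- bio3d::dccm.xyz(ens$xyz)
  expect_equal(unclass(mine), unclass(oracle), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("DCCM entries are reproducible across replicate splits", {
  s <- ring_structure()
  m <- build_enm(s)
  ens <- sample_ensemble(m, 4000, seed = 13)
  half1 <- new_ensemble(ens$topology, ens$xyz[1:2000, ])
  half2 <- new_ensemble(ens$topology, ens$xyz[2001:4000, ])
  expect_lt(max(abs(unclass(dccm(half1)) - unclass(dccm(half2)))), 0.15)
})

test_that("PCA recovers a planted dominant mode in the vibrational subspace", {
  s <- ring_structure()
  m <- build_enm(s)
  set.seed(3)
  v <- rnorm(3 * 20)
  v <- m$mode_vectors %*% crossprod(m$mode_vectors, v)  # strip rigid part
  v <- as.vector(v / sqrt(sum(v^2)))
  kT <- KB_KCAL * m$temperature
  sigma <- sqrt(200 * kT / min(m$mode_values))  # 200x the softest mode
  ens <- sample_ensemble(m, 2000, seed = 11,
                         planted = plant_gaussian_mode(v, sigma))
  pc <- pca_ensemble(ens, n_components = 3, fit = FALSE)
  expect_gt(abs(sum(pc$vectors[, 1] * v)), 0.99)
  expect_gt(pc$values[1] / pc$values[2], 100)
})

test_that("isotropic displacements give a flat spectrum and exact variance sum", {
  topo <- ca_structure(matrix(rnorm(60), 20, 3) * 10)
  set.seed(10)
  # n chosen so the Marchenko-Pastur spread (1 +/- sqrt(60/n))^2 of sample
  # eigenvalues keeps the max/min ratio clearly under 1.5
  frames <- replicate(12000, coords(topo) + matrix(rnorm(60), 20, 3),
                      simplify = FALSE)
  ens <- ensemble_from_frames(topo, frames)
  pc <- pca_ensemble(ens, n_components = 5, fit = FALSE)
  expect_lt(max(pc$values) / min(pc$values[pc$values > 1e-12]), 1.5)
  delta <- sweep(ens$xyz, 2, colMeans(ens$xyz))
  total_var <- sum(delta^2) / (nrow(delta) - 1)
  expect_equal(sum(pc$values), total_var, tolerance = 1e-8)
  # orthonormality
  expect_equal(crossprod(pc$vectors), diag(5), tolerance = 1e-8)
  # the mean structure projects to the origin
  expect_equal(colMeans(pc$projections), rep(0, 5), tolerance = 1e-10)
})

test_that("PCA agrees with the prcomp oracle on unfitted coordinates", {
  s <- ring_structure(10)
  m <- build_enm(s)
  ens <- sample_ensemble(m, 200, seed = 16)
  pc <- pca_ensemble(ens, n_components = 4, fit = FALSE)
  oracle <- stats::prcomp(ens$xyz, center = TRUE, scale. = FALSE)
  expect_equal(pc$values[1:4], oracle$sdev[1:4]^2, tolerance = 1e-9)
  for (j in 1:4)
    expect_equal(abs(sum(pc$vectors[, j] * oracle$rotation[, j])), 1,
                 tolerance = 1e-8)
})

test_that("free-energy surfaces obey their defining identities", {
  proj <- cbind(rep(0.5, 100), rep(0.5, 100))
  fes <- fes_2d(proj, n_bins = 10)
  expect_equal(sum(fes$energy == 0, na.rm = TRUE), 1)
  expect_equal(sum(!is.na(fes$energy)), 1)
  set.seed(11)
  p2 <- cbind(rnorm(20000), rnorm(20000))
  f1 <- fes_2d(p2, n_bins = 40)
  expect_equal(min(f1$energy, na.rm = TRUE), 0)
  # translation invariance with aligned edges
  f2 <- fes_2d(p2 + 5, n_bins = 40,
               breaks_x = f1$xbreaks + 5, breaks_y = f1$ybreaks + 5)
  expect_equal(f1$energy, f2$energy, tolerance = 1e-12)
})

test_that("a 2D Gaussian yields a quadratic radial free-energy profile", {
  set.seed(5)
  sd0 <- 2
  proj <- cbind(rnorm(50000, sd = sd0), rnorm(50000, sd = sd0))
  fes <- fes_2d(proj, n_bins = 60, temperature = 300)
  prof <- fes_radial_profile(fes, center = c(0, 0))
  # fit only radii resolvable without empty-bin censoring
  kT <- KB_KCAL * 300
  pred <- 0.5 * kT * prof$r^2 / sd0^2
  keep <- prof$r < 2.5 * sd0
  fit <- summary(stats::lm(prof$f[keep] ~ pred[keep]))
  expect_gt(fit$r.squared, 0.95)
  expect_equal(unname(fit$coefficients[2, 1]), 1, tolerance = 0.1)
})

test_that("doubling the bin count keeps the FES minimum in place", {
  set.seed(12)
  proj <- cbind(rnorm(20000, mean = 1.5), rnorm(20000, mean = -2))
  f1 <- fes_2d(proj, n_bins = 30)
  f2 <- fes_2d(proj, n_bins = 60)
  coarse_w <- diff(f1$xbreaks[1:2])
  expect_lt(max(abs(fes_minimum(f1) - fes_minimum(f2))), coarse_w + 1e-12)
})

test_that("mode displacement maps are normalized and localize planted motion", {
  s <- benchmark_structure()
  m <- build_enm(s)
  lid <- select_atoms(s, "ca and resid 182-199")
  pm <- plant_two_state_lid(m, lid, 0.5, 10)
  ens <- sample_ensemble(m, 500, seed = 14, planted = pm)
  pc <- pca_ensemble(ens, n_components = 2)
  disp <- mode_displacement_map(pc, 1)
  expect_true(all(disp$displacement >= 0))
  # unscaled eigenvector magnitudes are unit-normalized
  raw <- sqrt(colSums(matrix(pc$vectors[, 1]^2, nrow = 3)))
  expect_equal(sum(raw^2), 1, tolerance = 1e-10)
  in_lid <- disp$resno %in% 182:199
  # variance share: the planted lid mode carries almost all of PC1
  expect_gt(sum(disp$displacement[in_lid]^2) / sum(disp$displacement^2),
            0.9)
})

test_that("DCCM is stable under global rigid motion of every frame", {
  s <- ring_structure()
  m <- build_enm(s)
  ens <- sample_ensemble(m, 800, seed = 15)
  rot <- random_rotation()
  moved <- t(apply(ens$xyz, 1, function(row) {
    fc <- matrix(row, ncol = 3, byrow = TRUE)
    as.vector(t(sweep(fc %*% t(rot), 2, c(30, -5, 12), "+")))
  }))
  ens2 <- new_ensemble(ens$topology, moved)
  expect_lt(max(abs(unclass(dccm(ens)) - unclass(dccm(ens2)))), 0.01)
})
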