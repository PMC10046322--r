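test_that("the ideal cystine fixture is recovered within grid precision", {
  f <- ideal_cystine_fixture(chi3 = -87, chi1_i = -60, chi1_j = -65)
  cd <- model_cystine(f, 10, 20)
  expect_equal(cd$chi3, -87, tolerance = 1)
  expect_equal(cd$angle_i, 114.6, tolerance = 1)
  expect_equal(cd$angle_j, 114.6, tolerance = 1)
  expect_equal(cd$ss_distance, 2.04, tolerance = 0.01)
  expect_true(apply_criteria(cd)$pass)
})

test_that("the screen is symmetric in residue order", {
  f <- ideal_cystine_fixture()
  a <- model_cystine(f, 10, 20)
  b <- model_cystine(f, 20, 10)
  expect_equal(a$chi3, b$chi3, tolerance = 1e-9)
  expect_equal(a$ss_distance, b$ss_distance, tolerance = 1e-9)
  expect_equal(a$angle_i, b$angle_j, tolerance = 1e-9)
})

test_that("distant residues fail feasibility without erroring", {
  f <- ideal_cystine_fixture()
  at <- f$atoms
  at[at$resno == 20, c("x")] <- at[at$resno == 20, "x"] + 40
  cd <- model_cystine(new_structure(at), 10, 20)
  expect_false(cd$ss_feasible)
  expect_gt(cd$ss_distance, 5)
  expect_false(apply_criteria(cd)$pass)
  expect_true("ss_distance" %in% apply_criteria(cd)$reasons)
})

test_that("glycine Cbeta reconstruction matches an independent construction", {
  f <- ideal_cystine_fixture()
  at <- f$atoms
  keep <- !(at$resno == 20 & at$name == "CB")
  at$resname[at$resno == 20] <- "GLY"
  gly <- new_structure(at[keep, , drop = FALSE])
  cd_gly <- model_cystine(gly, 10, 20)
  cd_ref <- model_cystine(f, 10, 20)
  # oracle: NeRF internal-to-Cartesian placement with the same ideal values
  bb <- at[at$resno == 20, ]
  getp <- function(nm) as.numeric(bb[bb$name == nm, c("x", "y", "z")])
  n <- getp("N"); ca <- getp("CA"); cc <- getp("C")
  solve_tor <- function() {
    for (tor in seq(-180, 180, by = 0.05)) {
      cb <- place_atom(cc, n, ca, 1.53, 110.5, tor)
      if (abs(angle_deg(cc, ca, cb) - 110.5) < 0.02 &&
          abs(angle_deg(n, ca, cb) - 110.5) < 0.02) return(cb)
    }
    NULL
  }
  oracle_cbs <- solve_tor()
  mine_cb <- esterdyn:::ideal_cbeta(n, ca, cc)
  expect_equal(sqrt(sum((mine_cb - ca)^2)), 1.53, tolerance = 1e-9)
  expect_equal(angle_deg(n, ca, mine_cb), 110.5, tolerance = 1e-6)
  expect_equal(angle_deg(cc, ca, mine_cb), 110.5, tolerance = 1e-6)
  # NeRF finds a Cbeta with the same internal coordinates (either branch)
  expect_false(is.null(oracle_cbs))
  # reconstructed-CB candidate still models a near-ideal disulfide
  expect_equal(cd_gly$ss_distance, cd_ref$ss_distance, tolerance = 0.2)
})

test_that("chi3 windows use circular arithmetic around both centers", {
  base <- ideal_cystine_fixture()
  cd <- model_cystine(base, 10, 20)
  tweak <- function(cd, field, value) { cd[[field]] <- value; cd }
  expect_true(apply_criteria(tweak(cd, "chi3", 97))$pass)
  expect_true(apply_criteria(tweak(cd, "chi3", 126))$pass)   # 97 + 29
  expect_true(apply_criteria(tweak(cd, "chi3", -116))$pass)  # -87 - 29
  expect_false(apply_criteria(tweak(cd, "chi3", 0))$pass)
  expect_false(apply_criteria(tweak(cd, "chi3", 180))$pass)  # 83 deg off +97
  # wrap-around: -170 is 93 deg from -87 but wraps to 93 from +97 too
  expect_false(apply_criteria(tweak(cd, "chi3", -170))$pass)
  expect_true(apply_criteria(tweak(cd, "chi3", 110))$pass)
})

test_that("each criterion flips to fail exactly past its window", {
  cd <- model_cystine(ideal_cystine_fixture(), 10, 20)
  tweak <- function(field, value) {
    x <- cd; x[[field]] <- value; apply_criteria(x)
  }
  # 1 degree beyond the +/-30 deg chi3 window
  expect_false(tweak("chi3", -87 - 31)$pass)
  expect_true(tweak("chi3", -87 - 29)$pass)
  # 1 degree beyond the 114.6 +/- 10 deg angle window
  r <- tweak("angle_i", 114.6 + 11)
  expect_false(r$pass)
  expect_true("angle_i" %in% r$reasons)
  expect_true(tweak("angle_i", 114.6 + 9)$pass)
  r2 <- tweak("angle_j", 130)
  expect_false(r2$pass)
  expect_true("angle_j" %in% r2$reasons)
  # relaxing a halfwidth can only grow the pass set
  wide <- apply_criteria({ x <- cd; x$chi3 <- -87 - 31; x },
                         chi3_halfwidth = 40)
  expect_true(wide$pass)
})

test_that("site filters reject by triad radius, region radius and blacklist", {
  # linear arrangement: triad CA at origin; candidate residues at 8 / 12 A
  row <- function(resno, name, element, x)
    data.frame(chain = "A", resno = resno, resname = "ALA", name = name,
               element = element, het = FALSE, x = x, y = 0, z = 0, b = 0)
  s <- new_structure(rbind(
    row(30, "CA", "C", 8), row(31, "CA", "C", 8.5),
    row(53, "CA", "C", 40), row(60, "CA", "C", 12),
    row(61, "CA", "C", 12.5), row(90, "CA", "C", 45),
    row(146, "CA", "C", 0)))
  filt <- functional_site_filter(triad_resno = 146, triad_radius = 10,
                                 blacklist = 53)
  near <- list(res_i = 30, res_j = 31, chain = "A")
  far <- list(res_i = 60, res_j = 61, chain = "A")
  black <- list(res_i = 53, res_j = 90, chain = "A")
  out <- apply_site_filters(list(near, far, black), s, filt)
  expect_false(out$retained[1])
  expect_match(out$reasons[1], "triad")
  expect_true(out$retained[2])
  expect_equal(out$reasons[2], "")
  expect_false(out$retained[3])
  expect_match(out$reasons[3], "conserved:53")
  # region filter at 5 A
  filt2 <- functional_site_filter(
    triad_resno = integer(), triad_radius = 10,
    regions = list(lid = region_definition("lid", 90)), region_radius = 5)
  s2 <- new_structure(rbind(
    row(30, "CA", "C", 4), row(31, "CA", "C", 4.5),
    row(60, "CA", "C", 6), row(61, "CA", "C", 6.5),
    row(90, "CA", "C", 0)))
  out2 <- apply_site_filters(list(near, far), s2, filt2)
  expect_false(out2$retained[1])
  expect_match(out2$reasons[1], "lid")
  expect_true(out2$retained[2])
})

test_that("pair scans find the single engineered pair, deterministically", {
  f <- ideal_cystine_fixture(spacer_residues = 3)
  rep1 <- scan_all_pairs(f)
  rep2 <- scan_all_pairs(f)
  expect_identical(rep1, rep2)
  passing <- rep1[rep1$criteria_pass, ]
  expect_equal(nrow(passing), 1)
  expect_equal(sort(c(passing$res_i, passing$res_j)), c(10, 20))
  # with every residue inside the triad shell, nothing survives but the
  # rejections are all logged
  filt <- functional_site_filter(triad_resno = 10, triad_radius = 1000)
  rep3 <- scan_all_pairs(f, filter = filt)
  expect_true(all(!rep3$retained))
  expect_true(all(nzchar(rep3$filter_reasons)))
})

test_that("the mutant writer emits CYS residues with SG atoms", {
  f <- ideal_cystine_fixture()
  cd <- model_cystine(f, 10, 20)
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_cystine_mutant(f, cd, tf)
  s <- read_structure(tf)
  cys <- s$atoms[s$atoms$resno %in% c(10, 20), ]
  expect_setequal(unique(cys$resname), "CYS")
  sg <- cys[cys$name == "SG", ]
  expect_equal(nrow(sg), 2)
  d <- sqrt(sum((as.numeric(sg[1, c("x", "y", "z")]) -
                   as.numeric(sg[2, c("x", "y", "z")]))^2))
  expect_equal(d, 2.04, tolerance = 0.01)
})
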