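# Geometric disulfide-bond design screen: model a hypothetical cystine on a
# residue pair from backbone geometry, test the chi3/angle windows
# (-87/+97 +/- 30 deg; 114.6 +/- 10 deg), then apply functional-site
# exclusion filters (10 A of the triad, 5 A of important regions, a
# conservation blacklist).
#
# Note on the angle criterion: the geometrically meaningful bond angle for
# a cystine is Calpha-Cbeta-Sgamma (cysteine has no Cgamma); that is what is
# screened and recorded here.

.IDEAL_CB_SG <- 1.81    # Cbeta-Sgamma bond, Angstrom
.IDEAL_SS <- 2.04       # Sgamma-Sgamma' bond, Angstrom
.IDEAL_CA_CB_SG <- 114.6

# Ideal Cbeta for glycine (or as a replacement), from backbone N, CA, C:
# tetrahedral geometry, bond 1.53 A, angles N-CA-CB = C-CA-CB = 110.5 deg.
ideal_cbeta <- function(n, ca, c) {
  b1 <- unitv(n - ca)
  b2 <- unitv(c - ca)
  bisector <- unitv(b1 + b2)
  perp <- unitv(cross3(b1, b2))
  half <- acos(sum(b1 * b2)) / 2
  theta <- 110.5 * pi / 180
  # direction at angle theta from both b1 and b2: in the plane spanned by
  # -bisector and perp; cos(theta) = cos(alpha) cos(half)
  ca_dir <- cos(theta) / cos(half)
  ca_dir <- max(-1, min(1, ca_dir))
  alpha <- acos(ca_dir)
  dirv <- unitv(cos(alpha) * bisector + sin(alpha) * perp)
  # choose the branch giving L-chirality (CB on the opposite side of the
  # N,CA,C plane from the N->C cross product convention)
  dirv2 <- unitv(cos(alpha) * bisector - sin(alpha) * perp)
  pick <- if (sum(dirv * cross3(b2, b1)) > sum(dirv2 * cross3(b2, b1)))
    dirv else dirv2
  ca + 1.53 * pick
}

.backbone_of <- function(structure, res, chain) {
  atoms <- structure$atoms
  get <- function(name) {
    i <- which(atoms$chain == chain & atoms$resno == res &
                 atoms$name == name)
    if (length(i) != 1) return(NULL)
    as.numeric(atoms[i, c("x", "y", "z")])
  }
  n <- get("N"); ca <- get("CA"); c <- get("C")
  if (is.null(n) || is.null(ca) || is.null(c))
    stop("residue ", res, " lacks backbone N/CA/C atoms")
  cb <- get("CB")
  if (is.null(cb)) cb <- ideal_cbeta(n, ca, c)
  list(n = n, ca = ca, c = c, cb = cb)
}

# Sgamma candidate positions on a chi1 grid (dihedral N-CA-CB-SG).
.sg_grid <- function(bb, step = 5) {
  chi1 <- seq(-180 + step, 180, by = step)
  t(vapply(chi1, function(x1)
    place_atom(bb$n, bb$ca, bb$cb, .IDEAL_CB_SG, .IDEAL_CA_CB_SG, x1),
    numeric(3)))
}

#' Model a hypothetical cystine on a residue pair
#'
#' Sgamma is placed on each residue at the ideal Cbeta-Sgamma bond length
#' (1.81 A) and Calpha-Cbeta-Sgamma angle, scanning the chi1 dihedral on a
#' 5-degree grid; the chi1 pair minimizing |d(Sgamma-Sgamma') - 2.04 A| is
#' retained.  Glycines get an ideal reconstructed Cbeta.  Geometric
#' impossibility (e.g. distant residues) is recorded in the feasibility
#' flag, never raised as an error.
#'
#' @param structure A `Structure` with backbone atoms.
#' @param res_i,res_j Author residue numbers.
#' @param chain Chain identifier.
#' @param chi1_step Grid step in degrees (default 5).
#' @return A `DisulfideCandidate`: residue pair, modeled `sg_i`/`sg_j`,
#'   `chi3` (Cbeta-Sgamma-Sgamma'-Cbeta', degrees), `angle_i`/`angle_j`
#'   (Calpha-Cbeta-Sgamma, degrees), `ss_distance` (A), `ss_feasible`.
#' @export
model_cystine <- function(structure, res_i, res_j, chain = "A",
                          chi1_step = 5) {
  bb_i <- .backbone_of(structure, res_i, chain)
  bb_j <- .backbone_of(structure, res_j, chain)
  gi <- .sg_grid(bb_i, chi1_step)
  gj <- .sg_grid(bb_j, chi1_step)
  d2 <- outer(rowSums(gi^2), rowSums(gj^2), "+") - 2 * gi %*% t(gj)
  d <- sqrt(pmax(d2, 0))
  best <- which(abs(d - .IDEAL_SS) == min(abs(d - .IDEAL_SS)),
                arr.ind = TRUE)[1, ]
  sg_i <- gi[best[1], ]; sg_j <- gj[best[2], ]
  ss <- d[best[1], best[2]]
  structure(list(res_i = res_i, res_j = res_j, chain = chain,
                 sg_i = sg_i, sg_j = sg_j,
                 chi3 = dihedral_deg(bb_i$cb, sg_i, sg_j, bb_j$cb),
                 angle_i = angle_deg(bb_i$ca, bb_i$cb, sg_i),
                 angle_j = angle_deg(bb_j$ca, bb_j$cb, sg_j),
                 ss_distance = ss,
                 ss_feasible = abs(ss - .IDEAL_SS) <= 0.5),
            class = "DisulfideCandidate")
}

#' @export
print.DisulfideCandidate <- function(x, ...) {
  cat(sprintf(
    "DisulfideCandidate %d-%d: chi3 %.1f deg, angles %.1f/%.1f deg, S-S %.2f A\n",
    x$res_i, x$res_j, x$chi3, x$angle_i, x$angle_j, x$ss_distance))
  invisible(x)
}

#' Apply the geometric disulfide criteria
#'
#' Pass iff chi3 lies within `chi3_halfwidth` (circular) of either center
#' (-87 or +97 degrees) AND both Calpha-Cbeta-Sgamma angles lie within
#' `angle_center +/- angle_halfwidth`, AND the modeled S-S distance is
#' geometrically feasible.
#'
#' @param candidate A `DisulfideCandidate`.
#' @param chi3_center_minus,chi3_center_plus Window centers, degrees.
#' @param chi3_halfwidth,angle_halfwidth Half-widths, degrees.
#' @param angle_center Degrees.
#' @return list with `pass` and character vector `reasons` (empty if pass).
#' @export
apply_criteria <- function(candidate, chi3_center_minus = -87,
                           chi3_center_plus = 97, chi3_halfwidth = 30,
                           angle_center = 114.6, angle_halfwidth = 10) {
  reasons <- character()
  chi_dev <- min(circular_diff_deg(candidate$chi3, chi3_center_minus),
                 circular_diff_deg(candidate$chi3, chi3_center_plus))
  if (chi_dev > chi3_halfwidth) reasons <- c(reasons, "chi3")
  if (abs(candidate$angle_i - angle_center) > angle_halfwidth)
    reasons <- c(reasons, "angle_i")
  if (abs(candidate$angle_j - angle_center) > angle_halfwidth)
    reasons <- c(reasons, "angle_j")
  if (!candidate$ss_feasible) reasons <- c(reasons, "ss_distance")
  list(pass = length(reasons) == 0, reasons = reasons,
       chi3_deviation = chi_dev)
}

#' Define functional-site exclusion filters
#'
#' @param triad_resno Catalytic-triad residue numbers (default 146, 240,
#'   270).
#' @param triad_radius Exclusion radius around the triad, A (default 10).
#' @param regions List of `RegionDefinition`s (lid, pocket, ...).
#' @param region_radius Exclusion radius around the regions, A (default 5).
#' @param blacklist Conserved residue numbers to reject outright.
#' @return A `FunctionalSiteFilter`.
#' @export
functional_site_filter <- function(triad_resno = c(146, 240, 270),
                                   triad_radius = 10, regions = list(),
                                   region_radius = 5,
                                   blacklist = integer()) {
  if (triad_radius <= 0 || region_radius <= 0)
    stop("exclusion radii must be positive")
  structure(list(triad_resno = triad_resno, triad_radius = triad_radius,
                 regions = regions, region_radius = region_radius,
                 blacklist = as.integer(blacklist)),
            class = "FunctionalSiteFilter")
}

# Minimum distance from any atom of a residue to a reference atom set.
.residue_min_dist <- function(structure, res, chain, ref_idx) {
  atoms <- structure$atoms
  idx <- which(atoms$chain == chain & atoms$resno == res)
  xyz <- coords(structure)
  sqrt(min(.min_sq_dist_to_set(xyz[idx, , drop = FALSE],
                               xyz[ref_idx, , drop = FALSE])))
}

#' Apply functional-site filters to disulfide candidates
#'
#' A candidate is rejected -- with recorded reasons, nothing silently
#' dropped -- if either residue has any atom within `triad_radius` of any
#' triad-residue atom, within `region_radius` of any important-region atom,
#' or appears on the conservation blacklist.
#'
#' @param candidates List of `DisulfideCandidate`s.
#' @param structure The `Structure` the candidates refer to.
#' @param filter A `FunctionalSiteFilter`.
#' @return data.frame with one row per candidate: `res_i`, `res_j`,
#'   `retained`, `reasons` (';'-joined, empty if retained).
#' @export
apply_site_filters <- function(candidates, structure, filter) {
  atoms <- structure$atoms
  triad_idx <- which(atoms$resno %in% filter$triad_resno & !atoms$het)
  if (length(triad_idx) == 0 && length(filter$triad_resno) > 0)
    stop("triad residues not found in structure")
  region_idx <- lapply(filter$regions, function(rg) {
    idx <- which(atoms$chain == rg$chain & atoms$resno %in% rg$resno)
    if (length(idx) == 0)
      stop("filter region '", rg$name, "' not found in structure")
    idx
  })
  rows <- lapply(candidates, function(cd) {
    reasons <- character()
    for (res in c(cd$res_i, cd$res_j)) {
      if (res %in% filter$blacklist)
        reasons <- c(reasons, sprintf("conserved:%d", res))
      if (length(triad_idx) > 0 &&
          .residue_min_dist(structure, res, cd$chain, triad_idx) <=
            filter$triad_radius)
        reasons <- c(reasons, sprintf("triad_%gA:%d", filter$triad_radius,
                                      res))
      for (nm in names(region_idx)) {
        if (.residue_min_dist(structure, res, cd$chain, region_idx[[nm]]) <=
              filter$region_radius)
          reasons <- c(reasons,
                       sprintf("%s_%gA:%d", filter$regions[[nm]]$name,
                               filter$region_radius, res))
      }
    }
    reasons <- unique(reasons)
    data.frame(res_i = cd$res_i, res_j = cd$res_j,
               retained = length(reasons) == 0,
               reasons = paste(reasons, collapse = ";"))
  })
  do.call(rbind, rows)
}

#' Screen all residue pairs for disulfide candidates
#'
#' Unordered residue pairs with Cbeta-Cbeta distance <= `cb_prefilter` (a
#' generous upper bound for any disulfide) and sequence separation >= 2 are
#' modeled with [model_cystine()], screened with [apply_criteria()], then
#' passed through [apply_site_filters()] if a filter is given.  Output is
#' sorted by |S-S - 2.04| then chi3 deviation, and is fully deterministic.
#'
#' @param structure A `Structure` with backbone atoms.
#' @param filter Optional `FunctionalSiteFilter`.
#' @param chain Chain identifier.
#' @param cb_prefilter Cbeta-Cbeta prefilter distance, A (default 8).
#' @param chi1_step chi1 grid step, degrees.
#' @param ... Criterion overrides passed to [apply_criteria()].
#' @return data.frame report: pair, geometry, `criteria_pass`,
#'   `criteria_reasons`, `retained`, `filter_reasons`.
#' @export
scan_all_pairs <- function(structure, filter = NULL, chain = "A",
                           cb_prefilter = 8, chi1_step = 5, ...) {
  atoms <- structure$atoms
  resno <- sort(unique(atoms$resno[atoms$chain == chain & !atoms$het]))
  cb <- t(vapply(resno, function(r) .backbone_of(structure, r, chain)$cb,
                 numeric(3)))
  dcb <- as.matrix(stats::dist(cb))
  pairs <- which(dcb <= cb_prefilter & upper.tri(dcb), arr.ind = TRUE)
  pairs <- pairs[abs(resno[pairs[, 1]] - resno[pairs[, 2]]) >= 2, ,
                 drop = FALSE]
  if (nrow(pairs) == 0)
    return(data.frame(res_i = integer(), res_j = integer()))
  cands <- lapply(seq_len(nrow(pairs)), function(p)
    model_cystine(structure, resno[pairs[p, 1]], resno[pairs[p, 2]],
                  chain = chain, chi1_step = chi1_step))
  crit <- lapply(cands, apply_criteria, ...)
  rep <- data.frame(
    res_i = vapply(cands, `[[`, numeric(1), "res_i"),
    res_j = vapply(cands, `[[`, numeric(1), "res_j"),
    chi3 = vapply(cands, `[[`, numeric(1), "chi3"),
    angle_i = vapply(cands, `[[`, numeric(1), "angle_i"),
    angle_j = vapply(cands, `[[`, numeric(1), "angle_j"),
    ss_distance = vapply(cands, `[[`, numeric(1), "ss_distance"),
    criteria_pass = vapply(crit, `[[`, logical(1), "pass"),
    criteria_reasons = vapply(crit, function(x)
      paste(x$reasons, collapse = ";"), character(1)),
    chi3_deviation = vapply(crit, `[[`, numeric(1), "chi3_deviation"))
  if (!is.null(filter)) {
    fres <- apply_site_filters(cands, structure, filter)
    rep$retained <- rep$criteria_pass & fres$retained
    rep$filter_reasons <- fres$reasons
  } else {
    rep$retained <- rep$criteria_pass
    rep$filter_reasons <- ""
  }
  ord <- order(abs(rep$ss_distance - .IDEAL_SS), rep$chi3_deviation,
               rep$res_i, rep$res_j)
  rep <- rep[ord, , drop = FALSE]
  rownames(rep) <- NULL
  rep
}

#' Write a double-cysteine mutant with the modeled Sgamma atoms
#'
#' @param structure A `Structure`.
#' @param candidate A `DisulfideCandidate`.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_cystine_mutant <- function(structure, candidate, path) {
  atoms <- structure$atoms
  for (side in c("i", "j")) {
    res <- candidate[[paste0("res_", side)]]
    sg <- candidate[[paste0("sg_", side)]]
    sel <- atoms$chain == candidate$chain & atoms$resno == res
    atoms$resname[sel] <- "CYS"
    keep <- !(sel & !(atoms$name %in% c("N", "CA", "C", "O", "CB")))
    atoms <- atoms[keep, , drop = FALSE]
    anchor <- max(which(atoms$chain == candidate$chain &
                          atoms$resno == res))
    row <- atoms[anchor, , drop = FALSE]
    row$name <- "SG"; row$element <- "S"
    row$x <- sg[1]; row$y <- sg[2]; row$z <- sg[3]
    atoms <- rbind(atoms[seq_len(anchor), , drop = FALSE], row,
                   atoms[-seq_len(anchor), , drop = FALSE])
  }
  write_structure(new_structure(atoms, title = structure$title), path)
}
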