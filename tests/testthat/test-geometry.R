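test_that("closest H-H distance is the minimum over hydrogen pairs", {
  a <- synthetic_trp(extra = data.frame(name = "HE1", x = 0, y = 0, z = 0))
  b <- synthetic_trp(extra = data.frame(name = "HE1", x = 0, y = 0, z = 3.1))
  expect_equal(closest_hh_distance(trp_pair(a, b)), 3.1)
  # a designed 2.75 A closest contact among several hydrogens
  a2 <- synthetic_trp(extra = data.frame(name = c("HE1", "HZ2"),
                                         x = c(0, 5), y = 0, z = c(0, 0)))
  b2 <- synthetic_trp(extra = data.frame(name = c("HD1", "HH2"),
                                         x = c(0, 9), y = 0, z = c(2.75, 4)))
  expect_equal(closest_hh_distance(trp_pair(a2, b2)), 2.75)
  no_h <- synthetic_trp()
  expect_error(closest_hh_distance(trp_pair(no_h, b)), "hydrogen")
})

test_that("inter-plane angle recovers constructed rotations, folded to [0, 90]", {
  flat <- synthetic_trp()
  expect_equal(interplane_angle(trp_pair(flat, flat)), 0, tolerance = 1e-8)
  expect_equal(interplane_angle(
    trp_pair(flat, synthetic_trp(transform = rotate_x(90)))), 90,
    tolerance = 1e-8)
  expect_equal(interplane_angle(
    trp_pair(flat, synthetic_trp(transform = rotate_x(80)))), 80,
    tolerance = 1e-8)
  # 130 degrees folds to 50
  expect_equal(interplane_angle(
    trp_pair(flat, synthetic_trp(transform = rotate_x(130)))), 50,
    tolerance = 1e-8)
})

test_that("ring overlap area handles identity, displacement and disjointness", {
  flat <- synthetic_trp()
  lifted <- synthetic_trp(transform = function(m) sweep(m, 2, c(0, 0, -3.4)))
  pair <- trp_pair(flat, lifted)
  ring <- as.matrix(flat[, c("x", "y")])
  hull <- ring[rev(grDevices::chull(ring)), ]
  full_area <- hbnet:::shoelace_area(hull)
  expect_equal(ring_overlap_area(pair), full_area, tolerance = 1e-8)
  far <- synthetic_trp(transform = function(m) sweep(m, 2, c(-30, 0, -3.4)))
  expect_equal(ring_overlap_area(trp_pair(flat, far)), 0)
  part <- synthetic_trp(transform = function(m) sweep(m, 2, c(-1.5, 0, -3.4)))
  expect_lt(ring_overlap_area(trp_pair(flat, part)), full_area)
  expect_gt(ring_overlap_area(trp_pair(flat, part)), 0)
})

test_that("convex clipping matches a Monte-Carlo area oracle", {
  # two unit squares overlapping by half
  sq <- function(x0) rbind(c(x0, 0), c(x0 + 1, 0), c(x0 + 1, 1), c(x0, 1))
  inter <- hbnet:::clip_convex(sq(0), sq(0.5))
  expect_equal(hbnet:::shoelace_area(inter), 0.5, tolerance = 1e-12)
  # rejection-sampling oracle on a rotated pair of quadrilaterals
  set.seed(99)
  rot <- function(p, th) p %*% rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  A <- sq(0); B <- rot(sq(0.3), 0.4)
  area_cc <- hbnet:::shoelace_area(hbnet:::clip_convex(A, B))
  inside_all <- function(pts, poly) {
    n <- nrow(poly); j <- c(2:n, 1)
    ok <- rep(TRUE, nrow(pts))
    for (i in seq_len(n)) {
      cross <- (poly[j[i], 1] - poly[i, 1]) * (pts[, 2] - poly[i, 2]) -
        (poly[j[i], 2] - poly[i, 2]) * (pts[, 1] - poly[i, 1])
      ok <- ok & cross >= 0
    }
    ok
  }
  n_pts <- 4e5
  pts <- cbind(runif(n_pts, -1, 2), runif(n_pts, -1, 2))
  hits <- mean(inside_all(pts, A) & inside_all(pts, B))
  expect_equal(hits * 9, area_cc, tolerance = 0.01)
})

test_that("all three statistics are rigid-motion invariant", {
  a <- synthetic_trp(extra = data.frame(name = "HE1", x = 1, y = 2, z = 0.5))
  b <- synthetic_trp(extra = data.frame(name = "HZ3", x = 0, y = 1, z = 3),
                     transform = rotate_x(65))
  pair <- trp_pair(a, b)
  moved <- apply_to_pair(pair, rigid_motion(deg_z = 25, shift = c(3, -2, 7)))
  expect_equal(closest_hh_distance(moved), closest_hh_distance(pair),
               tolerance = 1e-10)
  expect_equal(interplane_angle(moved), interplane_angle(pair),
               tolerance = 1e-8)
  expect_equal(ring_overlap_area(moved), ring_overlap_area(pair),
               tolerance = 1e-8)
})

test_that("overlap never exceeds the smaller projected outline", {
  for (deg in c(10, 40, 70)) {
    pair <- trp_pair(synthetic_trp(),
                     synthetic_trp(transform = function(m)
                       rotate_x(deg)(sweep(m, 2, c(-1, -0.5, -3.4)))))
    ra <- hbnet:::ring_coords(pair$atoms_a)
    rb <- hbnet:::ring_coords(pair$atoms_b)
    pl <- hbnet:::fit_plane(ra)
    proj <- function(m) sweep(m, 2, pl$centroid) %*% pl$basis
    areas <- c(hbnet:::shoelace_area(hbnet:::ccw_hull(proj(ra))),
               hbnet:::shoelace_area(hbnet:::ccw_hull(proj(rb))))
    expect_lte(ring_overlap_area(pair), min(areas) + 1e-9)
  }
})

test_that("PDB round-trip via bio3d recovers constructed geometry", {
  a <- synthetic_trp(extra = data.frame(name = "HE1", x = 0, y = 0, z = 0))
  b <- synthetic_trp(extra = data.frame(name = "HE1", x = 0, y = 0, z = 2.75))
  path <- withr::local_tempfile(fileext = ".pdb")
  lines <- character(0)
  serial <- 0
  for (res in list(list(at = a, no = 306), list(at = b, no = 359))) {
    for (i in seq_len(nrow(res$at))) {
      serial <- serial + 1
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        serial, res$at$name[i], "TRP", "A", res$no,
        res$at$x[i], res$at$y[i], res$at$z[i]))
    }
  }
  writeLines(c(lines, "END"), path)
  pair <- read_trp_pair_pdb(path, 306, 359, chain_a = "A", chain_b = "A")
  expect_equal(closest_hh_distance(pair), 2.75, tolerance = 1e-3)
  expect_equal(interplane_angle(pair), 0, tolerance = 1e-6)
  expect_error(read_trp_pair_pdb(path, 306, 999), "999")
})
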