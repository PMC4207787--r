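# Grid-probe cavity detection and druggability descriptors

# hand-made single-cell pocket with a trivial grid context
single_cell_pocket <- function(atom_element = "C") {
  dims <- c(5L, 5L, 5L)
  origin <- c(0, 0, 0)
  center_lin <- 3L + 5L * (2L + 5L * 2L)  # cell (3,3,3), 1-based
  grid <- list(origin = origin, dims = dims, spacing = 1,
               protein = logical(prod(dims)),
               counts = integer(prod(dims)), burial_threshold = 1L,
               atoms = data.frame(element = atom_element, chain = "A",
                                  resno = 1, stringsAsFactors = FALSE),
               atom_centers = matrix(c(10, 10, 10), 1))
  structure(list(cells = center_lin,
                 cell_centers = matrix(c(2, 2, 2), 1),
                 spacing = 1, volume = 1, grid = grid),
            class = "Pocket")
}

test_that("a compact atom cluster with no cavity yields no pockets", {
  s <- quick_structure(c(0, 1.5, 0, 1.5, 0.7), c(0, 0, 1.5, 1.5, 0.7),
                       rep(0, 5))
  expect_equal(length(detect_pockets(s)), 0)
  expect_error(detect_pockets(s, spacing = 2), "spacing")
})

test_that("an analytic cubic void is recovered at its known volume", {
  s <- box_structure(10)
  pk <- detect_pockets(s, spacing = 1.0)
  expect_equal(length(pk), 1)
  expect_lt(abs(pk[[1]]$volume - 1000) / 1000, 0.15)
  expect_lte(pk[[1]]$lipo_surface, pk[[1]]$surface)
})

test_that("two carved cavities give exactly two disjoint pockets", {
  s1 <- box_structure(10)
  s2 <- box_structure(7, shift = c(30, 0, 0))
  atoms <- rbind(s1$atoms, s2$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  atoms$resno <- seq_len(nrow(atoms))
  s <- new_structure(atoms, "twoboxes")
  pk <- detect_pockets(s, spacing = 1.0)
  expect_equal(length(pk), 2)
  expect_equal(length(intersect(pk[[1]]$cells, pk[[2]]$cells)), 0)
  expect_gt(pk[[1]]$volume, pk[[2]]$volume)  # sorted by volume
})

test_that("a single fully exposed cavity cell has a 6 A^2 cube surface", {
  p <- pocket_descriptors(single_cell_pocket(), s = NULL)
  expect_equal(p$surface, 6)
  expect_equal(p$depth, 0)
})

test_that("apolar lining raises the lipophilic surface, polar zeroes it", {
  carbon <- pocket_descriptors(single_cell_pocket("C"), s = NULL)
  oxygen <- pocket_descriptors(single_cell_pocket("O"), s = NULL)
  expect_equal(carbon$lipo_surface, carbon$surface)
  expect_equal(oxygen$lipo_surface, 0)
  expect_gt(carbon$lipo_surface, oxygen$lipo_surface)
  # the same contrast on a full detection: carbon-walled vs oxygen-walled box
  pc <- detect_pockets(box_structure(8, element = "C"), spacing = 1.0)[[1]]
  po <- detect_pockets(box_structure(8, element = "O"), spacing = 1.0)[[1]]
  expect_gt(pc$lipo_surface, po$lipo_surface)
  expect_lte(po$lipo_surface, po$surface)
})

test_that("the druggability score is bounded, monotone and separates cases", {
  mk <- function(volume, surface, lipo, depth) {
    structure(list(volume = volume, surface = surface, lipo_surface = lipo,
                   depth = depth, cells = 1L,
                   cell_centers = matrix(0, 1, 3), spacing = 1),
              class = "Pocket")
  }
  zero <- druggability_score(mk(0, 1, 0, 0))
  expect_equal(zero, stats::plogis(-6))
  expect_gt(zero, 0); expect_lt(zero, 1)
  # componentwise dominance never lowers the score
  a <- mk(200, 100, 40, 2)
  b <- mk(400, 100, 60, 4)
  expect_lte(druggability_score(a), druggability_score(b))
  # a deep lipophilic 1500 A^3 pocket clears 0.8; a shallow dimple stays
  # under 0.3
  expect_gt(druggability_score(mk(1500, 500, 450, 10)), 0.8)
  expect_lt(druggability_score(mk(50, 80, 40, 1)), 0.3)
  expect_error(druggability_score(mk(10, 0, 0, 1)), "zero surface")
  # the detected cubic void itself scores as druggable
  pk <- detect_pockets(box_structure(10), spacing = 1.0)
  expect_gt(pk[[1]]$druggability, 0.8)
})

test_that("proximity triage keeps lining pockets and drops remote ones", {
  s1 <- box_structure(10)
  s2 <- box_structure(7, shift = c(40, 0, 0))
  atoms <- rbind(s1$atoms, s2$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  atoms$resno <- seq_len(nrow(atoms))
  s <- new_structure(atoms, "twoboxes")
  pk <- detect_pockets(s, spacing = 1.0)
  # a residue lining the first box
  lining_res <- pk[[1]]$lining_residues$resno[1]
  near <- pockets_near_residue(pk, s, "A", lining_res, max_dist = 10)
  expect_equal(names(near), "P0")
  expect_lte(near$P0$site_distance, 4)
  # the second cavity is ~40 A away from that residue
  expect_equal(length(pockets_near_residue(pk["P1"], s, "A", lining_res,
                                           max_dist = 10)), 0)
  expect_equal(length(pockets_near_residue(list(), s, "A", lining_res)), 0)
  expect_error(pockets_near_residue(pk, s, "Q", 1), "not present")
})

test_that("volume responds monotonically to burial and converges in spacing", {
  s <- box_structure(10)
  v_loose <- detect_pockets(s, spacing = 1.0, burial_threshold = 14,
                            descriptors = FALSE)
  v_strict <- detect_pockets(s, spacing = 1.0, burial_threshold = 22,
                             descriptors = FALSE)
  vol <- function(pk) if (length(pk) == 0) 0 else pk[[1]]$volume
  expect_lte(vol(v_strict), vol(v_loose))
  v1 <- vol(detect_pockets(s, spacing = 1.0, descriptors = FALSE))
  v05 <- vol(detect_pockets(s, spacing = 0.5, descriptors = FALSE))
  expect_lt(abs(v05 - v1) / v1, 0.10)
})

test_that("pocket ranking is invariant to lattice-compatible rigid motion", {
  s1 <- box_structure(10)
  s2 <- box_structure(6, shift = c(28, 0, 0))
  atoms <- rbind(s1$atoms, s2$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  atoms$resno <- seq_len(nrow(atoms))
  s <- new_structure(atoms, "twoboxes")
  pk <- detect_pockets(s, spacing = 1.0)
  # translation by whole cells: identical volumes and scores
  st <- set_coords(s, sweep(get_coords(s), 2, c(3, -2, 5), "+"))
  pkt <- detect_pockets(st, spacing = 1.0)
  expect_equal(pocket_table(pkt)$volume, pocket_table(pk)$volume)
  expect_equal(pocket_table(pkt)$druggability, pocket_table(pk)$druggability,
               tolerance = 1e-9)
  # 90-degree rotation about z maps the lattice onto itself
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  sr <- set_coords(s, get_coords(s) %*% Rz)
  pkr <- detect_pockets(sr, spacing = 1.0)
  expect_equal(pocket_table(pkr)$volume, pocket_table(pk)$volume)
  expect_equal(order(-pocket_table(pkr)$druggability),
               order(-pocket_table(pk)$druggability))
})
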