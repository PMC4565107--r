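# face-area lookup: summed area of faces of cell i against neighbor j
face_area_of <- function(tess, i, j) {
  f <- tess$faces
  sum(f$area[f$site == i & !is.na(f$neighbor) & f$neighbor == j])
}

box_volume <- function(box) prod(box[c(2, 4, 6)] - box[c(1, 3, 5)])

test_that("a single site fills its box with one boundary-only cell", {
  s <- data.frame(x = 0.5, y = 0.5, z = 0.5, weight = 1, reskey = "X:1", atom = "C")
  tess <- build_tessellation(s, box = c(0, 1, 0, 1, 0, 1))
  expect_equal(tess$volumes, 1)
  expect_equal(nrow(tess$faces), 6)
  expect_true(all(is.na(tess$faces$neighbor)))
  expect_equal(sum(tess$faces$area), 6)
})

test_that("radical plane sits at the closed-form position (d^2 + w1 - w2) / 2d", {
  # centers 3 A apart on x, weights 4 and 1 -> plane at x = 2 from the first
  s <- data.frame(x = c(0, 3), y = 0, z = 0, weight = c(4, 1),
                  reskey = c("X:1", "X:2"), atom = "C")
  tess <- build_tessellation(s, box = c(-2, 5, -2, 2, -2, 2))
  # cell 1 spans x in [-2, 2] of a 4 x 4 cross-section
  expect_equal(tess$volumes, c(4 * 16, 3 * 16))
  expect_equal(face_area_of(tess, 1, 2), 16)
  expect_equal(face_area_of(tess, 2, 1), 16)

  # equal weights at (+-1, 0, 0): symmetric split
  s2 <- data.frame(x = c(-1, 1), y = 0, z = 0, weight = 1,
                   reskey = c("X:1", "X:2"), atom = "C")
  t2 <- build_tessellation(s2, box = c(-3, 3, -2, 2, -2, 2))
  expect_equal(t2$volumes[1], t2$volumes[2])
})

test_that("power diagram is invariant to a uniform weight shift and scales correctly", {
  sites <- make_lattice_atoms(12, spacing = 3, jitter = 1.0, seed = 5)
  box <- c(-4, 10, -4, 10, -4, 10)
  base <- build_tessellation(sites, box = box)

  # adding a constant to every weight leaves the diagram unchanged;
  # with equal weights this is the equal-weight/ordinary-Voronoi degeneracy
  shifted <- sites
  shifted$weight <- sites$weight + 7.5
  t2 <- build_tessellation(shifted, box = box)
  expect_equal(t2$volumes, base$volumes, tolerance = 1e-9)
  expect_equal(t2$faces$area, base$faces$area, tolerance = 1e-9)

  unit <- sites
  unit$weight <- rep(2.5, nrow(sites))
  shifted_unit <- sites
  shifted_unit$weight <- rep(4.0, nrow(sites))
  expect_equal(build_tessellation(unit, box = box)$volumes,
               build_tessellation(shifted_unit, box = box)$volumes,
               tolerance = 1e-9)

  # scaling coordinates by s scales areas by s^2 and volumes by s^3
  sc <- 2.5
  scaled <- sites
  scaled$x <- sites$x * sc; scaled$y <- sites$y * sc; scaled$z <- sites$z * sc
  scaled$weight <- sites$weight * sc^2
  t3 <- build_tessellation(scaled, box = box * sc)
  expect_equal(t3$volumes, base$volumes * sc^3, tolerance = 1e-8)
  expect_equal(sort(t3$faces$area), sort(base$faces$area * sc^2), tolerance = 1e-8)
})

test_that("cells tile the box and faces are symmetric on random fixtures", {
  for (seed in 1:20) {
    n <- 5 + (seed * 7) %% 30
    sites <- make_lattice_atoms(n, spacing = 3, jitter = 1.2, seed = seed)
    tess <- build_tessellation(sites, padding = 4)
    vb <- box_volume(tess$box)
    expect_lt(abs(sum(tess$volumes) - vb) / vb, 1e-3)
    f <- tess$faces[!is.na(tess$faces$neighbor), ]
    for (r in seq_len(nrow(f))) {
      expect_lt(abs(f$area[r] - face_area_of(tess, f$neighbor[r], f$site[r])), 1e-6)
    }
  }
})

test_that("degenerate and invalid inputs are rejected", {
  dup <- data.frame(x = c(0, 0), y = c(0, 0), z = c(0, 0), weight = 1,
                    reskey = c("X:1", "X:2"), atom = "C")
  expect_error(build_tessellation(dup), "duplicate")
  bad_w <- data.frame(x = c(0, 1), y = 0, z = 0, weight = c(1, 0),
                      reskey = c("X:1", "X:2"), atom = "C")
  expect_error(build_tessellation(bad_w), "positive")
  # exactly degenerate cosphericity (unjittered lattice) still tiles the box
  grid <- make_lattice_atoms(8, spacing = 3, jitter = 0, seed = 1)
  tg <- build_tessellation(grid, padding = 3)
  expect_equal(sum(tg$volumes), box_volume(tg$box), tolerance = 1e-6)
})

test_that("residue areas satisfy the surface + contact = total identity", {
  # single-residue structure: no contacts, surface equals total
  one <- data.frame(x = 0, y = 0, z = 0, weight = 2.89, reskey = "A:1", atom = "C")
  a1 <- residue_areas(build_tessellation(one, padding = 3))
  expect_equal(nrow(a1$contacts), 0)
  expect_equal(a1$residues$surface, a1$residues$total)

  # two single-atom residues share one face, counted equally for both
  two <- data.frame(x = c(0, 3), y = 0, z = 0, weight = c(4, 1),
                    reskey = c("A:1", "A:2"), atom = "C")
  a2 <- residue_areas(build_tessellation(two, box = c(-2, 5, -2, 2, -2, 2)))
  expect_equal(area_neighbors(a2, "A:1")$area, 16)
  expect_equal(area_neighbors(a2, "A:2")$area, 16)

  for (seed in 1:10) {
    sites <- make_lattice_atoms(24, spacing = 3, jitter = 1.2, seed = seed)
    sites$reskey <- paste0("A:", rep(1:8, each = 3))  # 3-atom residues
    ar <- residue_areas(build_tessellation(sites, padding = 4))
    r <- ar$residues
    csum <- vapply(r$reskey, function(k) sum(area_neighbors(ar, k)$area), numeric(1))
    expect_lt(max(abs(r$surface + csum - r$total)), 1e-6)
    # contact symmetry
    ct <- ar$contacts
    for (i in seq_len(nrow(ct))) {
      back <- ct$area[ct$res_a == ct$res_b[i] & ct$res_b == ct$res_a[i]]
      expect_equal(ct$area[i], back, tolerance = 1e-6)
    }
    expect_true(all(r$total >= 0) && all(r$surface >= 0) && all(ct$area >= 0))
  }
})

test_that("intra-residue faces are excluded from residue totals", {
  # two atoms of one residue plus one atom of another, collinear
  sites <- data.frame(x = c(0, 2, 6), y = 0, z = 0, weight = 1,
                      reskey = c("A:1", "A:1", "A:2"), atom = "C")
  tess <- build_tessellation(sites, box = c(-2, 8, -2, 2, -2, 2))
  ar <- residue_areas(tess)
  # the atom1-atom2 face (at x = 1) must not appear in A:1's total
  r1 <- ar$residues[ar$residues$reskey == "A:1", ]
  expect_equal(r1$total, r1$surface + sum(area_neighbors(ar, "A:1")$area),
               tolerance = 1e-9)
  inner_face <- 16  # 4 x 4 cross-section between the two A:1 atoms
  all_faces <- sum(tess$faces$area[tess$faces$site %in% c(1, 2)])
  expect_equal(all_faces - 2 * inner_face, r1$total, tolerance = 1e-6)
})

test_that("the Monte-Carlo oracle reproduces analytic volumes and face areas", {
  # two-atom case: analytic cross-section of the box at the radical plane
  s <- data.frame(x = c(0, 3), y = 0, z = 0, weight = c(4, 1),
                  reskey = c("X:1", "X:2"), atom = "C")
  box <- c(-2, 5, -2, 2, -2, 2)
  mc <- mc_area_oracle(s, box, n_samples = 4e5, seed = 3)
  expect_equal(mc$volumes[1], 64, tolerance = 3 * mc$volume_se[1] / 64)
  f <- mc$faces[mc$faces$site_i == 1 & mc$faces$site_j == 2, ]
  expect_lt(abs(f$area - 16), 3 * f$se)

  # symmetric two-atom split: 50/50 within 3 SE
  s2 <- data.frame(x = c(-1, 1), y = 0, z = 0, weight = 1,
                   reskey = c("X:1", "X:2"), atom = "C")
  mc2 <- mc_area_oracle(s2, c(-3, 3, -2, 2, -2, 2), n_samples = 4e5, seed = 4)
  expect_lt(abs(mc2$volumes[1] - mc2$volumes[2]), 3 * sqrt(2) * mc2$volume_se[1])

  # single cell: volume is the box volume exactly
  mc1 <- mc_area_oracle(s[1, ], box, n_samples = 1e5, seed = 5)
  expect_equal(mc1$volumes, box_volume(box))

  # multi-site fixture: every analytic cell volume within 3 SE
  sites <- make_lattice_atoms(6, spacing = 3, jitter = 1.2, seed = 9)
  tess <- build_tessellation(sites, padding = 4)
  mc3 <- mc_area_oracle(sites, tess$box, n_samples = 6e5, seed = 9)
  expect_true(all(abs(tess$volumes - mc3$volumes) <= 3 * mc3$volume_se))
})
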