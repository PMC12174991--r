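test_that("supercell replication meets the minimum extent", {
  s25 <- crystal(diag(3) * 25, matrix(0.5, 1, 3), "C")
  cl <- periodic_point_cloud(s25, 20)
  expect_identical(cl$rep, c(1L, 1L, 1L))
  expect_equal(nrow(cl$points), 1)

  fx <- make_crystal(1, "triatomic", cell = c(6, 6, 6), seed = 1)
  cl6 <- periodic_point_cloud(fx$p1, 20)
  expect_identical(cl6$rep, c(4L, 4L, 4L))           # ceil(20/6)
  expect_equal(nrow(cl6$points), 64 * n_atoms(fx$p1))

  # non-orthogonal cell: extent via perpendicular widths; oracle through the
  # reciprocal lattice (width_i = 1 / |row i of inverse lattice|)
  lat <- rbind(c(6, 0, 0), c(-3, 5.196, 0), c(0, 0, 8))
  s <- crystal(lat, matrix(0.3, 1, 3), "C")
  w_oracle <- 1 / sqrt(rowSums(t(solve(lat))^2))
  cl2 <- periodic_point_cloud(s, 20)
  expect_identical(cl2$rep, as.integer(ceiling(20 / w_oracle)))
})

test_that("tiny clouds give the expected diagrams", {
  expect_error(persistence_diagrams(matrix(numeric(0), 0, 3)),
               "at least one point")
  one <- persistence_diagrams(matrix(c(0, 0, 0), 1, 3))
  expect_equal(nrow(one$dim1), 0)
  expect_equal(nrow(one$dim2), 0)

  # 8 corners of a 3 A cube enclose a void: birth at the face circumradius,
  # death at the half space-diagonal
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * 3
  d2 <- persistence_diagrams(cube)$dim2
  expect_equal(nrow(d2), 1)
  expect_equal(d2$birth, 3 * sqrt(2) / 2, tolerance = 1e-3)
  expect_equal(d2$birth + d2$persistence, 3 * sqrt(3) / 2, tolerance = 1e-3)
})

test_that("ring channels grow monotonically in persistence with radius", {
  th <- 2 * pi * (0:11) / 12
  pers <- vapply(c(2, 3, 4), function(r) {
    ring <- cbind(r * cos(th), r * sin(th), 0)
    d1 <- persistence_diagrams(ring)$dim1
    max(d1$persistence)
  }, numeric(1))
  expect_true(all(diff(pers) > 0))
  # the dominant loop dies when the disc is covered: death ~ ring radius
  ring3 <- cbind(3 * cos(th), 3 * sin(th), 0)
  d1 <- persistence_diagrams(ring3)$dim1
  k <- which.max(d1$persistence)
  expect_equal(d1$birth[k] + d1$persistence[k], 3, tolerance = 0.01)
})

test_that("alpha diagrams match the brute-force Cech oracle", {
  set.seed(421)
  for (n in c(8, 12, 16)) {
    pts <- matrix(rnorm(3 * n, sd = 2), n, 3)
    mine <- persistence_diagrams(pts, jitter = 0)
    oracle <- cech_persistence(pts)
    for (dd in c("dim1", "dim2")) {
      a <- mine[[dd]][order(mine[[dd]]$birth, mine[[dd]]$persistence), ]
      b <- oracle[[dd]]
      expect_equal(nrow(a), nrow(b), info = paste(dd, "n =", n))
      if (nrow(a)) {
        expect_equal(a$birth, b$birth, tolerance = 1e-6)
        expect_equal(a$persistence, b$persistence, tolerance = 1e-6)
      }
    }
  }
})

test_that("diagrams are invariant under rigid motion", {
  set.seed(99)
  pts <- matrix(rnorm(45, sd = 2), 15, 3)
  rot <- crysformer:::rotation_matrix(c(0.4, 1.1, 2.2))
  pts2 <- pts %*% t(rot) + matrix(c(5, -3, 2), 15, 3, byrow = TRUE)
  a <- persistence_diagrams(pts, jitter = 0)
  b <- persistence_diagrams(pts2, jitter = 0)
  for (dd in c("dim1", "dim2")) {
    oa <- a[[dd]][order(a[[dd]]$birth), ]
    ob <- b[[dd]][order(b[[dd]]$birth), ]
    expect_equal(oa$birth, ob$birth, tolerance = 1e-6)
    expect_equal(oa$persistence, ob$persistence, tolerance = 1e-6)
  }
})

test_that("persistence images have unit mass per point and scaled maxima", {
  empty <- persistence_image(data.frame(birth = numeric(0),
                                        persistence = numeric(0)))
  expect_equal(sum(empty$image), 0)
  expect_equal(empty$max_persistence, 0)
  expect_equal(empty$max_birth, 0)
  expect_equal(dim(empty$image), c(50, 50))

  # one point is scaled to the (1,1) corner of the unit square; about a
  # quarter of its Gaussian mass falls outside the grid there
  one <- persistence_image(data.frame(birth = 0.5, persistence = 0.3),
                           resolution = 50, spread = 0.15)
  expect_equal(one$max_birth, 0.5)
  expect_equal(one$max_persistence, 0.3)
  corner <- which(one$image == max(one$image), arr.ind = TRUE)
  expect_gte(corner[1, 1], 45)
  expect_gte(corner[1, 2], 45)
  expect_equal(sum(one$image), 0.25, tolerance = 0.05)

  # interior points carry mass ~ 1 each (within boundary truncation)
  dg <- data.frame(birth = c(0.2, 0.5, 1.0), persistence = c(0.5, 1.0, 0.4))
  img <- persistence_image(dg)
  expect_equal(sum(img$image), nrow(dg), tolerance = 0.05 * nrow(dg) + 0.8)
  expect_true(all(img$image >= 0))
})

test_that("patchify is exact, row-major and invertible", {
  img <- matrix(seq_len(2500) / 2500, 50, 50)
  p <- patchify(img, 5)
  expect_equal(dim(p), c(100, 25))
  expect_identical(unpatchify(p, 50), img)
  # first patch is the top-left 5x5 block flattened row-major
  expect_identical(p[1, ], as.numeric(t(img[1:5, 1:5])))
  const <- patchify(matrix(1, 50, 50), 5)
  expect_true(all(apply(const, 1, function(r) all(r == const[1, ]))))
  expect_error(patchify(img, 7), "divide")
})

test_that("representative cycles fold back to the original cell atoms", {
  th <- 2 * pi * (0:11) / 12
  ring <- cbind(3 * cos(th), 3 * sin(th), 0)
  dg <- persistence_diagrams(ring, with_cycles = TRUE)
  k <- which.max(dg$dim1$persistence)
  atoms <- map_cycle_to_atoms(dg$dim1, k, 12)
  expect_true(all(atoms >= 0 & atoms < 12))
  expect_gte(length(atoms), 3)

  # folding across a supercell: all indices must land inside the cell
  ps <- make_pore_series(2.5, seed = 3)[[1]]
  cl <- periodic_point_cloud(ps, 12)
  dgs <- persistence_diagrams(cl, with_cycles = TRUE)
  k2 <- which.max(dgs$dim1$persistence)
  folded <- map_cycle_to_atoms(dgs$dim1, k2, cl$n_cell)
  expect_true(all(folded >= 0 & folded < cl$n_cell))

  nocyc <- persistence_diagrams(ring)
  expect_error(map_cycle_to_atoms(nocyc$dim1, 1, 12), "without")
  empty <- persistence_diagrams(matrix(c(0, 0, 0), 1, 3),
                                with_cycles = TRUE)
  expect_error(map_cycle_to_atoms(empty$dim1, 1, 1), "empty")
})

test_that("pore-series channel radii drive the max 1-D persistence", {
  ps <- make_pore_series(c(2, 3, 4), seed = 1)
  mp <- vapply(ps, function(s) {
    persistence_features(s)$max_persistence_1d
  }, numeric(1))
  expect_true(all(diff(mp) > 0))
})
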