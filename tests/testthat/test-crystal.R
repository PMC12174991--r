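test_that("density matches the hand-computed value and its invariances", {
  s <- crystal(diag(3) * 10, matrix(c(0.1, 0.1, 0.1), 1), "C")
  # 12.011 u / (6.02214e23 * 1e-21 cm^3)
  expect_equal(density(s), 0.0199447, tolerance = 1e-5)
  # doubling the cell with doubled contents leaves density unchanged
  s2 <- supercell(s, c(2, 1, 1))
  expect_equal(density(s2), density(s), tolerance = 1e-12)
  expect_error(crystal(diag(3), matrix(numeric(0), 0, 3), character(0)),
               "at least one atom")
  expect_error(crystal(diag(3) * 5, matrix(0.5, 1, 3), "Xx"),
               "unknown element")
})

test_that("P1 expansion is density-preserving and multiplies the formula", {
  fx <- make_crystal(4, "triatomic", jitter_sigma = 0, seed = 3)
  expect_equal(fx$asym$space_group, 4L)
  p1 <- to_p1(fx$asym)
  expect_equal(p1$space_group, 1L)
  expect_equal(n_atoms(p1), 2 * n_atoms(fx$asym))   # two general positions
  # density counts all symmetry copies, so it is invariant under expansion
  expect_equal(density(p1), density(fx$asym), tolerance = 1e-10)
  # P1 input round-trips unchanged
  expect_identical(to_p1(p1), p1)

  fx19 <- make_crystal(19, "triatomic", jitter_sigma = 0, seed = 5)
  p119 <- to_p1(fx19$asym)
  expect_equal(n_atoms(p119), 4 * n_atoms(fx19$asym))
})

test_that("expanded fixtures retain the generating symmetry", {
  for (g in c(2L, 4L, 19L)) {
    fx <- make_crystal(g, "triatomic", jitter_sigma = 0, seed = 7)
    p1 <- to_p1(fx$asym)
    expect_true(all(symmetry_holds(p1, g)), info = paste("group", g))
  }
  # a screw-only crystal must not satisfy inversion
  fx4 <- make_crystal(4, "triatomic", jitter_sigma = 0, seed = 7)
  expect_false(all(symmetry_holds(to_p1(fx4$asym), 2)))
})

test_that("molecule assignment uses periodic connected components", {
  # two N2 units 5 A apart in a large cell
  lat <- diag(3) * 12
  fc <- rbind(c(0.1, 0.1, 0.1), c(0.1 + 1.1 / 12, 0.1, 0.1),
              c(0.1, 0.1, 0.1 + 5 / 12), c(0.1 + 1.1 / 12, 0.1, 0.1 + 5 / 12))
  s <- assign_molecules(crystal(lat, fc, rep("N", 4)))
  expect_identical(sort(unique(s$molecule_ids)), c(0L, 1L))
  expect_identical(s$molecule_ids[1], s$molecule_ids[2])
  expect_false(s$molecule_ids[1] == s$molecule_ids[3])

  # one molecule crossing the cell boundary is merged through the image
  fcw <- rbind(c(0.98, 0.5, 0.5), c(0.02, 0.5, 0.5))
  sw <- assign_molecules(crystal(diag(3) * 3, fcw, c("N", "N")))
  expect_identical(sw$molecule_ids, c(0L, 0L))

  # P1-expanded two-molecule fixture
  fx <- make_crystal(4, "ring6", seed = 2)
  expect_identical(sort(unique(fx$p1$molecule_ids)), c(0L, 1L))

  # label permutation invariance (up to relabelling)
  p <- sample(n_atoms(fx$p1))
  sp <- crystal(fx$p1$lattice, fx$p1$frac_coords[p, ], fx$p1$elements[p])
  sp <- assign_molecules(sp)
  grp_a <- split(seq_along(p), fx$p1$molecule_ids[p])
  grp_b <- split(seq_along(p), sp$molecule_ids)
  expect_true(setequal(lapply(grp_a, sort), lapply(grp_b, sort)))

  # fully disconnected structure: one molecule per atom
  iso <- assign_molecules(crystal(diag(3) * 20,
                                  rbind(c(.1, .1, .1), c(.5, .5, .5),
                                        c(.9, .2, .7)), rep("C", 3)))
  expect_identical(sort(iso$molecule_ids), 0:2)
})

test_that("perturbation is seeded, bounded and disabled at sigma zero", {
  fx <- make_crystal(19, "ring6", seed = 4)
  s <- fx$p1
  expect_identical(perturb(s, 0, 1), s)
  expect_equal(perturb(s, 0.1, 42)$frac_coords,
               perturb(s, 0.1, 42)$frac_coords)
  expect_false(isTRUE(all.equal(perturb(s, 0.1, 1)$frac_coords,
                                perturb(s, 0.1, 2)$frac_coords)))
  expect_error(perturb(s, -0.1, 1), "sigma")
  # RMS displacement of sigma * sqrt(3) for a large atom count
  big <- crystal(diag(3) * 200, matrix(runif(3e4), 1e4, 3), rep("C", 1e4))
  pb <- perturb(big, 0.05, 7)
  disp <- cart_coords(pb) - cart_coords(big)
  disp <- disp - round(disp / 200) * 200   # unwrap
  rms <- sqrt(mean(rowSums(disp^2)))
  expect_equal(rms, 0.05 * sqrt(3), tolerance = 0.05)
})
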