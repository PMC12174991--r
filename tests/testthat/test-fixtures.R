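test_that("fixtures carry self-consistent ground truth", {
  fx <- make_crystal(1, "ring6", seed = 3)
  expect_equal(fx$truth$n_molecules, 1)
  expect_equal(unname(unlist(fx$truth[crysformer:::.sep_bit_names])),
               c(1L, 0L, 0L, 0L, 0L, 0L, 0L))
  expect_equal(fx$truth$density, density(fx$p1))

  fx19 <- make_crystal(19, "diatomic", seed = 2)
  expect_equal(n_atoms(fx19$p1), 8)
  expect_equal(fx19$truth$n_molecules, 4)
  expect_equal(length(unique(fx19$p1$molecule_ids)), 4)
  expect_equal(unname(unlist(fx19$truth[crysformer:::.sep_bit_names])),
               c(0L, 0L, 0L, 0L, 1L, 0L, 0L))
  expect_error(make_crystal(5, "ring6"), "space_group")
})

test_that("fixture generation is byte-deterministic in the seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  make_dataset(6, seed = 9, dir = d1)
  make_dataset(6, seed = 9, dir = d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("datasets round-trip through CIF with labels preserved", {
  dir <- withr::local_tempdir()
  ds <- make_dataset(8, seed = 4, target = "density", dir = dir)
  tab <- utils::read.csv(file.path(dir, "properties.csv"),
                         stringsAsFactors = FALSE)
  expect_equal(nrow(tab), 8)
  expect_identical(tab$family, ds$table$family)
  # labels equal densities recomputed from the stored structures
  expect_equal(tab$label, vapply(ds$structures, density, numeric(1)),
               tolerance = 1e-8)
  # CIFs re-read and re-expanded match the in-memory P1 structures
  for (i in c(1, 5, 8)) {
    f <- file.path(dir, "structures", paste0(tab$structure_id[i], ".cif"))
    r <- read_cif(f)
    expect_equal(r$space_group, ds$truth$space_group[i])
    p1 <- assign_molecules(to_p1(r))
    expect_equal(n_atoms(p1), ds$truth$n_atoms[i])
    expect_equal(density(p1), ds$truth$density[i], tolerance = 1e-4)
    expect_equal(max(p1$molecule_ids) + 1L, ds$truth$n_molecules[i])
  }
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$seed, 4)
  expect_equal(man$target, "density")
})

test_that("two templates produce two family tags", {
  ds <- make_dataset(20, seed = 10, templates = c("diatomic", "ring6"))
  expect_setequal(unique(ds$table$family), c("diatomic", "ring6"))
})

test_that("pore fixtures put the declared channel radius into the geometry", {
  radii <- c(2, 3.5)
  ps <- make_pore_series(radii, seed = 2)
  for (k in seq_along(ps)) {
    s <- ps[[k]]
    expect_s3_class(s, "crystal")
    expect_equal(attr(s, "channel_radius"), radii[k])
    # geometric radius: distance from the channel axis (cell centre) to the
    # nearest atom
    cart <- cart_coords(s)
    centre <- colMeans(cart)
    dxy <- sqrt((cart[, 1] - centre[1])^2 + (cart[, 2] - centre[2])^2)
    expect_lt(abs(min(dxy) - radii[k]), 0.2)
  }
  expect_error(make_pore_series(1.2), ">= 1.5")
})
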