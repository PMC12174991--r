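test_that("space-group closure reproduces the tabulated operation counts", {
  for (n in c(1, 2, 4, 14, 19, 47, 63, 141, 166, 194, 221, 225, 230)) {
    ops <- sg_operations(n)
    expect_length(ops, crysformer:::.sg_table[[n]]$nops)
    # closed under composition
    if (length(ops) > 1) {
      k1 <- crysformer:::op_key(crysformer:::compose_ops(ops[[2]],
                                                         ops[[length(ops)]]))
      keys <- vapply(ops, crysformer:::op_key, character(1))
      expect_true(k1 %in% keys)
    }
  }
  expect_error(sg_operations(0), "1..230")
  expect_error(sg_operations(231), "1..230")
})

test_that("symmetry-element labels are valid for all 230 groups", {
  for (n in 1:230) {
    b <- unclass(symmetry_elements(n))
    expect_length(b, 7)
    expect_true(all(b %in% c(0L, 1L)))
    expect_gte(sum(b), 1)
    # bit 0 set iff all others are 0
    expect_identical(b[["no_element"]] == 1L, sum(b[-1]) == 0L)
  }
})

test_that("labels agree with the brute-force fixed-point oracle (all 230)", {
  for (n in 1:230) {
    expect_identical(unclass(symmetry_elements(n)),
                     symmetry_elements_oracle(n),
                     info = paste("space group", n))
  }
})

test_that("the discussed groups carry the expected labels", {
  b1 <- unclass(symmetry_elements(1))
  expect_identical(unname(b1), c(1L, 0L, 0L, 0L, 0L, 0L, 0L))
  b2 <- unclass(symmetry_elements(2))
  expect_identical(unname(b2), c(0L, 1L, 0L, 0L, 0L, 0L, 0L))
  for (n in c(4, 19)) {
    b <- unclass(symmetry_elements(n))
    expect_identical(unname(b), c(0L, 0L, 0L, 0L, 1L, 0L, 0L),
                     info = paste("space group", n))
  }
})

test_that("group 2 is exactly {identity, inversion}", {
  ops <- sg_operations(2)
  kinds <- sort(vapply(ops, crysformer:::classify_op, character(1)))
  expect_identical(kinds, c("identity", "inversion"))
})

test_that("inverse-frequency weights behave as specified", {
  expect_equal(element_weights(rep(5, 7)), rep(1, 7))
  # two-class check at epsilon = 1: w proportional to 1/p, mean-normalised
  expect_equal(element_weights(c(900, 100), epsilon = 1), c(0.2, 1.8))
  # flattening limit
  expect_equal(element_weights(c(1, 10, 100, 5, 7, 2, 40), epsilon = 1e6),
               rep(1, 7), tolerance = 1e-3)
  expect_error(element_weights(c(1, 2), epsilon = 0.5), "epsilon")
  # permutation equivariance
  f <- c(3, 50, 7, 120, 9, 14, 1)
  p <- sample(7)
  expect_equal(element_weights(f)[p], element_weights(f[p]))
  # monotone toward uniformity in epsilon
  spread_at <- function(eps) diff(range(element_weights(f, eps)))
  eps_grid <- c(1, 1.5, 2.5, 5, 20)
  expect_true(all(diff(vapply(eps_grid, spread_at, numeric(1))) < 0))
  # strictly decreasing in frequency
  w <- element_weights(f)
  expect_true(all(diff(w[order(f)]) < 0))
  # zero counts are smoothed, not fatal
  expect_true(all(is.finite(element_weights(c(0, 5, 10, 0, 3, 2, 1)))))
})

test_that("exact-match scoring thresholds at 0.5 over all seven bits", {
  lab <- symmetry_elements(19)
  expect_true(sep_exact_match(as.numeric(unclass(lab)), lab))
  flipped <- as.numeric(unclass(lab)); flipped[2] <- 1 - flipped[2]
  expect_false(sep_exact_match(flipped, lab))
  pred <- c(0.2, 0.1, 0.1, 0.1, 0.6, 0.4, 0.49)
  expect_true(sep_exact_match(pred, lab))
  expect_error(sep_exact_match(c(pred[-1], 1.2), lab), "probabilities")
})

test_that("the 230-group label table exports and regenerates identically", {
  tab <- sg_label_table()
  expect_equal(nrow(tab), 230)
  expect_identical(tab, sg_label_table())
  path <- withr::local_tempfile(fileext = ".json")
  export_sg_labels(path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$number, tab$number)
  expect_equal(back$screw, tab$screw)
})
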