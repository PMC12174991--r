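tiny_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- crysformer_model(tiny_config(), c("C", "N", "O", "H"),
                                 seed = 7)
    }
    cache
  }
})

test_that("the multi-modal token layout follows the fixed order", {
  cfg <- model_config(L = 1L, H = 32L, A = 4L, H_graph = 32L,
                      resolution = 50L, patch = 5L, min_extent = 6)
  model <- crysformer_model(cfg, c("C", "N", "O", "H"), seed = 2)
  fx <- make_crystal(2, "triatomic", seed = 21)
  expect_equal(n_atoms(fx$p1), 6)
  feats <- prepare_structure(fx$p1, model)
  ag_reset()
  seq <- build_sequence(model, feats, pos_seed = 1)
  n <- 6
  types <- seq$types
  expect_equal(sum(types == 2), n)                 # ATOM tokens
  expect_equal(sum(types == 4) + sum(types == 5), 200)  # patches
  expect_equal(sum(types == 6), 4)                 # SCL tokens
  expect_equal(length(types), n + 207)
  expect_identical(types[1], unname(crysformer:::.token_types["CLS"]))
  # order: CLS, atoms, SEP, 100 x 1D patches, 2 SCL, SEP, 100 x 2D, 2 SCL
  expect_identical(types[2:(n + 1)], rep(2L, n))
  expect_identical(types[n + 2], 3L)
  expect_identical(types[(n + 3):(n + 102)], rep(4L, 100))
  expect_identical(types[(n + 103):(n + 104)], c(6L, 6L))
  expect_identical(types[n + 105], 3L)
  expect_identical(types[(n + 106):(n + 205)], rep(5L, 100))
  expect_identical(types[(n + 206):(n + 207)], c(6L, 6L))
  # every ATOM token maps back to exactly one atom
  expect_identical(seq$atom_pos, 2:(n + 1))
  expect_equal(nrow(seq$x$val), n + 207)
})

test_that("disabling images truncates the sequence after the first SEP", {
  model <- tiny_model()
  fx <- make_crystal(1, "triatomic", seed = 5)
  feats <- prepare_structure(fx$p1, model)
  ag_reset()
  seq <- build_sequence(model, feats, pos_seed = 1)
  expect_identical(seq$types, c(1L, rep(2L, feats$n), 3L))
  expect_length(seq$patch1_pos, 0)
  expect_length(seq$scl2_pos, 0)
})

test_that("structures beyond max_atoms are rejected explicitly", {
  cfg <- tiny_config(max_atoms = 4L)
  model <- crysformer_model(cfg, c("C", "N", "O", "H"), seed = 1)
  fx <- make_crystal(19, "triatomic", seed = 5)   # 12 atoms
  expect_error(prepare_structure(fx$p1, model), "max_atoms")
})

test_that("unknown elements at inference are an error", {
  model <- tiny_model()
  s <- crystal(diag(3) * 8, matrix(0.5, 1, 3), "Fe")
  expect_error(prepare_structure(s, model), "vocabulary")
})

test_that("encoding is deterministic and attention is row-stochastic", {
  model <- tiny_model()
  fx <- make_crystal(4, "triatomic", seed = 9)
  feats <- prepare_structure(fx$p1, model)
  ag_reset()
  seq <- build_sequence(model, feats, pos_seed = 3)
  enc <- encode(model, seq, keep_attention = TRUE)
  expect_equal(ncol(enc$reps$val), model$cfg$H)
  expect_length(enc$attn, model$cfg$L)
  expect_length(enc$attn[[1]], model$cfg$A)
  for (a in enc$attn[[1]]) {
    expect_equal(rowSums(a), rep(1, nrow(a)), tolerance = 1e-5)
  }
  ag_reset()
  seq2 <- build_sequence(model, feats, pos_seed = 3)
  enc2 <- encode(model, seq2)
  expect_identical(enc2$reps$val, enc$reps$val)
})

test_that("masking selects round(0.15 n) atoms with floor one", {
  ids20 <- rep(1:4, 5)
  m <- mask_atoms(ids20, 4, rate = 0.15, seed = 1)
  expect_length(m$selected, 3)                 # round(3) = 3
  expect_identical(m$labels, ids20[m$selected])
  m1 <- mask_atoms(c(1L, 2L), 4, rate = 0.15, seed = 1)
  expect_length(m1$selected, 1)                # floor of one atom
  # masked ids actually differ where mode is MASK
  expect_true(all(m$mask_ids[m$selected[m$modes == 1L]] == 5L))
  # unchanged mode keeps the true identity
  keep <- m$selected[m$modes == 3L]
  expect_identical(m$mask_ids[keep], ids20[keep])
})

test_that("masking fraction and corruption modes hit the stated rates", {
  n <- 600
  ids <- rep(1:4, 150)
  fracs <- vapply(1:200, function(sd) {
    length(mask_atoms(ids, 4, seed = sd)$selected) / n
  }, numeric(1))
  expect_equal(mean(fracs), 0.15, tolerance = 1e-3)

  modes <- unlist(lapply(1:120, function(sd) {
    mask_atoms(ids, 4, seed = 1000 + sd)$modes
  }))
  n_draws <- length(modes)
  expect_gte(n_draws, 1e4)
  p <- c(0.8, 0.1, 0.1)
  for (k in 1:3) {
    tol <- 3 * sqrt(p[k] * (1 - p[k]) / n_draws)
    expect_lt(abs(mean(modes == k) - p[k]), tol)
  }
})

test_that("random-atom replacement never draws the true element", {
  ids <- rep(1:4, 50)
  for (sd in 1:30) {
    m <- mask_atoms(ids, 4, seed = sd)
    rnd <- m$selected[m$modes == 2L]
    if (length(rnd)) {
      expect_true(all(m$mask_ids[rnd] != ids[rnd]))
      expect_true(all(m$mask_ids[rnd] <= 4L))
    }
  }
})

test_that("pair sampling is balanced, seeded, and sentinel-disabled", {
  mol <- rep(0:1, each = 10)
  p <- sample_pairs(mol, 200, seed = 3)
  expect_equal(nrow(p), 200)
  expect_equal(sum(p$same == 1), 100)
  expect_equal(sum(p$same == 0), 100)
  expect_true(all(p$i != p$j))
  expect_identical(sample_pairs(mol, 200, seed = 3), p)
  same_truth <- mol[p$i] == mol[p$j]
  expect_identical(as.integer(same_truth), p$same)
  expect_null(sample_pairs(rep(0L, 8), 200, seed = 1))
  expect_null(sample_pairs(0:7, 200, seed = 1))   # no intra pairs possible
  expect_error(sample_pairs(mol, 201, seed = 1), "even")
})

test_that("the pair head is exactly symmetric, including after training", {
  model <- tiny_model()
  set.seed(4)
  a <- ag_const(matrix(rnorm(32), 1))
  b <- ag_const(matrix(rnorm(32), 1))
  ag_reset()
  expect_identical(apc_head(model, a, b)$val, apc_head(model, b, a)$val)
  # h_i == h_j collapses to twice the single-order head
  g1 <- model$modules$apc_g1; g2 <- model$modules$apc_g2
  gval <- nn_apply_linear(g2, ag_gelu(nn_apply_linear(
    g1, ag_cbind(a, a))))$val
  expect_equal(apc_head(model, a, a)$val, 2 * gval, tolerance = 1e-12)
  # symmetry survives parameter updates
  params <- c(crysformer:::nn_params(g1), crysformer:::nn_params(g2))
  opt <- adamw(params, lr = 1e-2)
  for (step in 1:5) {
    ag_zero_grad(params)
    ag_reset()
    loss <- ag_bce(apc_head(model, a, b), matrix(1, 1, 1))
    ag_backward(loss)
    adamw_step(opt)
  }
  ag_reset()
  expect_identical(apc_head(model, a, b)$val, apc_head(model, b, a)$val)
})

test_that("the density head is a single affine map", {
  model <- tiny_model()
  head <- model$modules$cdp_head
  old_w <- head$W$val; old_b <- head$b$val
  on.exit({ head$W$val <- old_w; head$b$val <- old_b })
  head$W$val[] <- 0
  head$b$val[] <- 1.5
  ag_reset()
  x <- ag_const(matrix(rnorm(32), 1))
  expect_equal(cdp_head(model, x)$val[1, 1], 1.5)
  head$W$val[] <- old_w; head$b$val[] <- 0
  ag_reset()
  p1 <- cdp_head(model, ag_const(matrix(1, 1, 32) * 2))$val
  p2 <- cdp_head(model, ag_const(matrix(1, 1, 32)))$val
  expect_equal(p1, 2 * p2, tolerance = 1e-12)
})

test_that("the weighted symmetry loss reduces to plain BCE at unit weights", {
  set.seed(8)
  logits <- matrix(rnorm(7), 1)
  y <- matrix(c(0, 0, 0, 0, 1, 0, 0), 1)
  ag_reset()
  lw <- ag_bce(ag_const(logits), y, rep(1, 7))
  lp <- ag_bce(ag_const(logits), y)
  expect_equal(lw$val, lp$val, tolerance = 1e-12)
  # perfect logits drive the loss to ~0 and exact match to true
  strong <- y * 20 - 10
  ag_reset()
  expect_lt(ag_bce(ag_const(strong), y)$val, 1e-3)
  expect_true(sep_exact_match(1 / (1 + exp(-strong[1, ])), as.integer(y)))
  # doubling one weight doubles that logit's gradient at fixed prediction
  w <- rep(1, 7)
  grad_k <- function(wk) {
    w[5] <- wk
    ag_reset()
    node <- ag_const(logits)
    loss <- ag_bce(node, y, w)
    ag_backward(loss)
    node$grad[1, 5]
  }
  expect_equal(grad_k(2), 2 * grad_k(1), tolerance = 1e-10)
})

test_that("the pre-training loss is the unit-weighted sum of task losses", {
  model <- tiny_model()
  fx <- make_crystal(4, "triatomic", seed = 31)
  feats <- prepare_structure(fx$p1, model)
  lab <- unclass(symmetry_elements(4))
  ag_reset()
  fw <- crysformer:::pretrain_forward(model, feats, lab, epoch_seed = 11L)
  expect_equal(fw$loss$val[1, 1], sum(fw$parts), tolerance = 1e-10)
  expect_named(fw$parts, c("map", "apc", "cdp", "sep"))
  # single-molecule structure: APC sentinel contributes exactly zero
  fx1 <- make_crystal(1, "ring6", seed = 13)
  feats1 <- prepare_structure(fx1$p1, model)
  ag_reset()
  fw1 <- crysformer:::pretrain_forward(model, feats1,
                                       unclass(symmetry_elements(1)),
                                       epoch_seed = 12L)
  expect_equal(unname(fw1$parts["apc"]), 0)
  expect_equal(fw1$loss$val[1, 1], sum(fw1$parts), tolerance = 1e-10)
})

test_that("checkpoints round-trip and refuse featurization mismatches", {
  model <- tiny_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path, expect_hash = model$feat_hash)
  p1 <- crysformer:::model_params(model)
  p2 <- crysformer:::model_params(back)
  expect_equal(length(p1), length(p2))
  for (k in seq_along(p1)) expect_identical(p1[[k]]$val, p2[[k]]$val)
  expect_error(load_checkpoint(path, expect_hash = "different"),
               "hash mismatch")
})
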