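test_that("rollout of identity attention returns the [CLS] one-hot", {
  for (L in c(1, 3, 5)) {
    attn <- lapply(seq_len(L), function(l) list(diag(6), diag(6)))
    for (alpha in c(0, 0.5, 0.9)) {
      r <- attention_rollout(attn, residual_alpha = alpha)
      expect_equal(r, c(1, rep(0, 5)))
    }
  }
})

test_that("two layers of uniform attention mix completely", {
  u <- matrix(0.5, 2, 2)
  r <- attention_rollout(list(list(u), list(u)), residual_alpha = 0)
  expect_equal(r, c(0.5, 0.5))
})

test_that("rollout rows stay stochastic and non-stochastic input errors", {
  set.seed(12)
  attn <- lapply(1:3, function(l) lapply(1:2, function(h) {
    random_stochastic(5)
  }))
  r <- attention_rollout(attn)
  expect_equal(sum(r), 1, tolerance = 1e-10)
  expect_true(all(r >= 0))
  bad <- attn
  bad[[2]][[1]][1, ] <- bad[[2]][[1]][1, ] * 1.2
  expect_error(attention_rollout(bad), "row-stochastic")
})

test_that("rollout equals the brute-force matrix product oracle", {
  set.seed(33)
  for (rep in 1:5) {
    t_len <- sample(3:8, 1)
    L <- sample(1:4, 1)
    A <- sample(1:3, 1)
    attn <- lapply(seq_len(L), function(l) {
      lapply(seq_len(A), function(h) random_stochastic(t_len))
    })
    alpha <- runif(1)
    expect_equal(attention_rollout(attn, alpha),
                 rollout_oracle(attn, alpha), tolerance = 1e-10)
  }
})

multimodal_attr_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- model_config(L = 2L, H = 32L, A = 4L, H_graph = 32L,
                          min_extent = 8)
      model <- crysformer_model(cfg, c("C", "N", "O", "H"), seed = 5)
      fx <- make_crystal(2, "triatomic", seed = 17)
      cache <<- list(model = model, s = fx$p1)
    }
    cache
  }
})

test_that("attribution covers atoms, patches and scale tokens and sums to 1", {
  fx <- multimodal_attr_fixture()
  res <- attribute(fx$model, fx$s, pos_seed = 2)
  n <- n_atoms(fx$s)
  expect_length(res$atom_scores, n)
  expect_length(res$patch_scores_1d, 100)
  expect_length(res$patch_scores_2d, 100)
  expect_length(res$scl_scores, 4)
  total <- sum(res$atom_scores, res$patch_scores_1d, res$patch_scores_2d,
               res$scl_scores)
  expect_equal(total, 1, tolerance = 1e-6)
  expect_true(all(res$atom_scores >= 0))
  # top-10 patch lists are sorted by descending score
  expect_length(res$top10_1d, 10)
  expect_true(all(diff(res$patch_scores_1d[res$top10_1d]) <= 1e-12))
  # clipping zeroes only sub-threshold entries, leaving others unchanged
  cl <- clip_scores(res)
  keep <- res$atom_scores >= res$clip_threshold
  expect_identical(cl[keep], res$atom_scores[keep])
  expect_true(all(cl[!keep] == 0))
})

test_that("a pore-size model keeps reading the image modality", {
  # channel-radius target over an engineered pore series: after fine-tuning,
  # the attribution must stay deterministic, the image modality must retain
  # a substantial share of the rolled-out attention, and the [SCL] scale
  # tokens (which carry the pore radius directly through the maximum
  # persistence) must stay enriched above the uniform per-token share
  radii <- seq(1.8, 4.4, length.out = 12)
  pores <- make_pore_series(radii, seed = 8, jitter_sigma = 0.05)
  ids <- sprintf("pore%02d", seq_along(pores))
  structures <- stats::setNames(pores, ids)
  for (i in seq_along(structures)) structures[[i]]$structure_id <- ids[i]
  tab <- data.frame(structure_id = ids, label = radii,
                    split = factor(c(rep("train", 8), "val", "val",
                                     "test", "test"),
                                   levels = c("train", "val", "test")))
  cfg <- model_config(L = 2L, H = 32L, A = 4L, H_graph = 32L, lr = 1e-3,
                      min_extent = 12)
  model <- crysformer_model(cfg, "C", seed = 6)
  ft <- finetune(model, structures, tab, epochs = 8, batch_size = 2,
                 seed = 2)
  res <- attribute(ft, structures[[1]], pos_seed = 3)
  res2 <- attribute(ft, structures[[1]], pos_seed = 3)
  expect_identical(res$atom_scores, res2$atom_scores)
  n_tok <- length(res$atom_scores) + 204
  image_mass <- sum(res$patch_scores_1d, res$patch_scores_2d,
                    res$scl_scores)
  expect_gt(image_mass / (204 / n_tok), 0.5)
  expect_gt(mean(res$scl_scores) * n_tok, 1)
})

test_that("attribution exports round-trip through disk", {
  fx <- multimodal_attr_fixture()
  res <- attribute(fx$model, fx$s, pos_seed = 2)
  dir <- withr::local_tempdir()
  paths <- export_attribution(res, fx$s, dir)
  expect_true(all(file.exists(paths)))
  back <- read_extxyz(paths[["xyz"]])
  expect_equal(back$extra$attention, res$atom_scores, tolerance = 1e-5)
  js <- jsonlite::read_json(paths[["json"]], simplifyVector = TRUE)
  expect_equal(js$clip_threshold, 0.005)
  expect_equal(js$top10_1d, res$top10_1d)
  grid <- as.matrix(utils::read.csv(paths[["patches_1d"]]))
  expect_equal(as.numeric(t(grid)), res$patch_scores_1d, tolerance = 1e-12,
               ignore_attr = TRUE)
})
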