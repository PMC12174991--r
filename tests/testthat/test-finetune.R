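test_that("split assignment is reproducible and order-invariant", {
  tab <- data.frame(structure_id = sprintf("s%03d", 1:200),
                    label = rnorm(200))
  a <- assign_split(tab, seed = 5)
  b <- assign_split(tab, seed = 5)
  expect_identical(a$split, b$split)
  shuf <- tab[sample(nrow(tab)), ]
  c2 <- assign_split(shuf, seed = 5)
  m <- match(tab$structure_id, shuf$structure_id)
  expect_identical(as.character(c2$split[m]), as.character(a$split))
  expect_false(identical(a$split, assign_split(tab, seed = 6)$split))
  # proportions are near 80/10/10 and splits are disjoint by construction
  expect_equal(mean(a$split == "train"), 0.8, tolerance = 0.1)
  expect_identical(attr(a, "split_seed"), 5)
  expect_error(assign_split(tab, split = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("r2 matches hand arithmetic and guards its preconditions", {
  expect_equal(r2(c(1, 2, 3), c(1, 2, 3)), 1)
  y <- c(4, 8, 6)
  expect_equal(r2(rep(mean(y), 3), y), 0)
  expect_equal(r2(c(0, 1, 1), c(0, 1, 2)), 0.5)   # 1 - 1/2
  expect_error(r2(c(1, 2), c(3, 3)), "zero variance")
  expect_error(r2(1, 1), "two records")
})

test_that("top-n overlap counts the intersection with stable ties", {
  x <- c(3, 1, 4, 1.5, 2)
  expect_equal(top_n_overlap(x, x, 3, "lowest"), 3)
  y <- c(10, 20, 30, 40)
  expect_equal(top_n_overlap(-y, y, 2, "lowest"), 0)
  expect_equal(top_n_overlap(c(1, 2, 3, 4), c(1, 3, 2, 4), 2, "lowest"), 1)
  expect_equal(top_n_overlap(c(1, 2, 3, 4), c(1, 3, 2, 4), 2, "highest"), 1)
  # ties broken by record order: identical values pick earlier records
  expect_equal(top_n_overlap(c(1, 1, 1, 2), c(1, 1, 1, 2), 2, "lowest"), 2)
  expect_error(top_n_overlap(1:3, 1:3, 5), "exceeds")
})

make_ft_fixture <- function(n = 24, seed = 31) {
  ds <- make_dataset(n, seed = seed, target = "density")
  structures <- ds$structures
  names(structures) <- ds$table$structure_id
  model <- crysformer_model(tiny_config(lr = 1e-3),
                            c("C", "N", "O", "H"), seed = 2)
  list(ds = ds, structures = structures, model = model)
}

test_that("fine-tuning runs, selects on validation and reports on test", {
  fx <- make_ft_fixture()
  tab <- assign_split(fx$ds$table, seed = 1)
  ft <- finetune(fx$model, fx$structures, tab, epochs = 3, batch_size = 8,
                 seed = 1, top_n = 3)
  expect_s3_class(ft, "crysformer_finetuned")
  expect_true(is.finite(ft$report$mae))
  expect_true(is.na(ft$report$r2) || ft$report$r2 <= 1)
  expect_gte(ft$report$top_n_overlap, 0)
  expect_lte(ft$report$top_n_overlap, ft$report$top_n)
  expect_equal(nrow(ft$report$predictions), sum(tab$split == "test"))
  # the base model is untouched by fine-tuning
  expect_identical(crysformer:::model_params(fx$model)[[1]]$val,
                   crysformer_model(tiny_config(lr = 1e-3),
                                    c("C", "N", "O", "H"),
                                    seed = 2)$modules$ge$embed$val)
  preds <- predict(ft, fx$structures[1:3])
  expect_equal(nrow(preds), 3)
  expect_true(all(is.finite(preds$prediction)))
})

test_that("fine-tuned bundles round-trip through disk", {
  fx <- make_ft_fixture(n = 12, seed = 41)
  tab <- assign_split(fx$ds$table, seed = 2)
  ft <- finetune(fx$model, fx$structures, tab, epochs = 2, batch_size = 6,
                 seed = 1, top_n = 2)
  path <- withr::local_tempfile(fileext = ".rds")
  save_finetuned(ft, path)
  back <- load_finetuned(path)
  p1 <- predict(ft, fx$structures[1:2])
  p2 <- predict(back, fx$structures[1:2])
  expect_equal(p1$prediction, p2$prediction, tolerance = 1e-10)
})

test_that("degenerate and invalid splits are rejected; 1-record train runs", {
  fx <- make_ft_fixture(n = 8, seed = 51)
  tab <- fx$ds$table
  tab$split <- factor(c("train", rep("val", 3), rep("test", 4)),
                      levels = c("train", "val", "test"))
  ft <- finetune(fx$model, fx$structures, tab, epochs = 2, batch_size = 2,
                 seed = 1, top_n = 2)
  expect_true(is.finite(ft$report$mae))
  tab2 <- tab
  tab2$split[tab2$split == "val"] <- "train"
  expect_error(finetune(fx$model, fx$structures, tab2, epochs = 1),
               "empty val split")
  expect_error(finetune(fx$model, fx$structures, fx$ds$table, epochs = 1),
               "split column")
})

test_that("the few-shot protocol holds out a family and shrinks its test", {
  ds <- make_dataset(30, seed = 61, target = "density",
                     templates = c("diatomic", "ring6"))
  structures <- ds$structures
  names(structures) <- ds$table$structure_id
  model <- crysformer_model(tiny_config(lr = 1e-3), c("C", "N", "O", "H"),
                            seed = 3)
  hold_n <- sum(ds$table$family == "ring6")
  expect_gte(hold_n, 6)
  fs <- few_shot_protocol(model, structures, ds$table,
                          holdout_tag = "ring6", k_list = c(0L, 4L),
                          seed = 1, stage1_epochs = 2, stage2_epochs = 2)
  expect_equal(fs$k, c(0L, 4L))
  expect_equal(fs$test_n, c(hold_n, hold_n - 4L))
  expect_true(all(is.finite(fs$mae)))
  reports <- attr(fs, "reports")
  expect_named(reports, c("0", "4"))
  # k = 0 is exactly the stage-1 model evaluated on the full holdout
  expect_equal(fs$mae[1], reports[["0"]]$mae)
  expect_error(few_shot_protocol(model, structures, ds$table,
                                 holdout_tag = "ring6",
                                 k_list = c(0L, hold_n), seed = 1,
                                 stage1_epochs = 1),
               "smaller than the holdout")
  tab_nofam <- ds$table[, c("structure_id", "label")]
  expect_error(few_shot_protocol(model, structures, tab_nofam, "x", 0L),
               "family")
})
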