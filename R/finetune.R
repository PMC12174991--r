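# Fine-tuning on scalar property tables: a fresh affine head on [CLS], full
# model fine-tuned; random 80/10/10 splits; MAE / R^2 / top-n overlap
# reporting; the few-shot transfer protocol over molecule families.

#' Attach a reproducible train/validation/test split to a property table
#'
#' Assignment is uniform at random in the stated proportions, reproducible
#' from the stored seed, and invariant to the order of the records (records
#' are ranked by `structure_id` before drawing).
#'
#' @param table data frame with columns `structure_id`, `label` (and
#'   optionally `family`).
#' @param seed split seed (stored in the result).
#' @param split train/val/test proportions.
#' @return the table with a `split` factor column; attribute `split_seed`.
#' @export
assign_split <- function(table, seed = 1L, split = c(0.8, 0.1, 0.1)) {
  if (abs(sum(split) - 1) > 1e-8) stop("split proportions must sum to 1")
  if (anyDuplicated(table$structure_id)) stop("duplicate structure_id")
  ord <- order(table$structure_id)
  n <- nrow(table)
  lab <- with_seed(seed, sample(c("train", "val", "test"), n, replace = TRUE,
                                prob = split))
  out <- table
  out$split <- factor(NA, levels = c("train", "val", "test"))
  out$split[ord] <- lab
  attr(out, "split_seed") <- seed
  out
}

#' Coefficient of determination
#'
#' @param pred,true equal-length numeric vectors; `true` must have nonzero
#'   variance and at least two records.
#' @return `1 - SS_res / SS_tot`.
#' @export
r2 <- function(pred, true) {
  if (length(true) < 2) stop("need at least two records")
  sst <- sum((true - mean(true))^2)
  if (sst <= 0) stop("true values have zero variance")
  1 - sum((true - pred)^2) / sst
}

#' Overlap between the predicted and actual top-n records
#'
#' Counts how many of the `n` best records by predicted value are among the
#' `n` best by actual value. Ties are broken by stable record order.
#'
#' @param pred,true equal-length numeric vectors.
#' @param n size of the head to compare.
#' @param direction `"lowest"` (e.g. energies) or `"highest"` (capacities).
#' @return integer in `0..n`.
#' @export
top_n_overlap <- function(pred, true, n = 10L, direction = c("lowest",
                                                             "highest")) {
  direction <- match.arg(direction)
  if (length(pred) != length(true)) stop("length mismatch")
  if (n > length(pred)) stop("n exceeds the number of records")
  pick <- function(v) {
    o <- if (direction == "lowest") order(v, seq_along(v)) else
      order(-v, seq_along(v))
    o[seq_len(n)]
  }
  length(intersect(pick(pred), pick(true)))
}

eval_report <- function(pred, true, ids, top_n = 10L,
                        direction = "lowest") {
  top_n <- min(top_n, length(pred))
  r2v <- if (length(true) >= 2 && stats::sd(true) > 0) r2(pred, true) else
    NA_real_
  list(mae = mean(abs(pred - true)),
       r2 = r2v,
       top_n = top_n,
       top_n_overlap = top_n_overlap(pred, true, top_n, direction),
       predictions = data.frame(structure_id = ids, label = true,
                                prediction = pred))
}

regression_forward <- function(model, head, feats, z, pos_seed) {
  seq <- build_sequence(model, feats, pos_seed = pos_seed)
  enc <- encode(model, seq)
  cls <- ag_gather(enc$reps, 1L)
  pred <- nn_apply_linear(head, cls)
  list(loss = ag_mse(pred, matrix(z, 1, 1)), pred = pred$val[1, 1])
}

predict_scalar <- function(model, head, feats_list, norm, pos_seed = 1L) {
  vapply(seq_along(feats_list), function(i) {
    ag_reset()
    seq <- build_sequence(model, feats_list[[i]], pos_seed = pos_seed + i)
    enc <- encode(model, seq)
    pred <- nn_apply_linear(head, ag_gather(enc$reps, 1L))
    pred$val[1, 1] * norm$sd + norm$mean
  }, numeric(1))
}

#' Fine-tune a model on a scalar property table
#'
#' Initialises a fresh affine head on the `[CLS]` token and fine-tunes all
#' model weights with AdamW (squared-error loss on standardised labels,
#' linear warm-up then decay). The epoch with the best validation MAE is
#' kept and evaluated on the test split.
#'
#' @param model a (typically pre-trained) `crysformer_model`; left
#'   unmodified — fine-tuning operates on a clone.
#' @param structures named list of P1 `crystal`s keyed by `structure_id`.
#' @param dataset property table with a `split` column ([assign_split()]).
#' @param epochs,batch_size overrides of the config fine-tuning values.
#' @param seed training seed.
#' @param top_n,direction reporting options for the top-n overlap.
#' @param verbose print per-epoch validation MAE.
#' @return object of class `crysformer_finetuned`: the tuned model, head,
#'   label normalisation and an `EvalReport`-style list `report`.
#' @export
finetune <- function(model, structures, dataset, epochs = NULL,
                     batch_size = NULL, seed = 1L, top_n = 10L,
                     direction = "lowest", verbose = FALSE) {
  cfg <- model$cfg
  if (is.null(epochs)) epochs <- cfg$finetune_epochs
  if (is.null(batch_size)) batch_size <- cfg$finetune_batch
  if (is.null(dataset$split)) stop("dataset needs a split column")
  for (sp in c("train", "val", "test")) {
    if (!any(dataset$split == sp)) stop("empty ", sp, " split")
  }
  missing <- setdiff(dataset$structure_id, names(structures))
  if (length(missing)) stop("structures missing for: ",
                            paste(utils::head(missing, 3), collapse = ", "))
  work <- clone_model(model)
  head <- with_seed(seed, nn_linear(cfg$H, 1L))
  tr <- dataset[dataset$split == "train", ]
  va <- dataset[dataset$split == "val", ]
  te <- dataset[dataset$split == "test", ]
  sd0 <- stats::sd(tr$label)
  norm <- list(mean = mean(tr$label),
               sd = if (is.finite(sd0) && sd0 > 1e-6) sd0 else 1)
  feats <- lapply(structures[dataset$structure_id], prepare_structure,
                  model = work)
  names(feats) <- dataset$structure_id
  z <- (dataset$label - norm$mean) / norm$sd
  names(z) <- dataset$structure_id
  params <- c(model_params(work), nn_params(head))
  opt <- adamw(params, lr = cfg$lr, weight_decay = cfg$weight_decay)
  ntr <- nrow(tr)
  total_steps <- epochs * ceiling(ntr / batch_size)
  step <- 0L
  best <- list(mae = Inf, values = NULL)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(seed + 31L * ep, sample(tr$structure_id))
    for (bstart in seq(1, ntr, by = batch_size)) {
      batch <- ord[bstart:min(bstart + batch_size - 1L, ntr)]
      ag_zero_grad(params)
      for (id in batch) {
        ag_reset()
        fw <- regression_forward(work, head, feats[[id]], z[[id]],
                                 pos_seed = seed + 613L * ep +
                                   match(id, dataset$structure_id))
        ag_backward(fw$loss)
      }
      for (p in params) if (!is.null(p$grad)) p$grad <- p$grad / length(batch)
      step <- step + 1L
      adamw_step(opt, lr_schedule(step, total_steps, cfg$warmup_frac))
    }
    vp <- predict_scalar(work, head, feats[va$structure_id], norm,
                         pos_seed = seed + 7L)
    vmae <- mean(abs(vp - va$label))
    if (verbose) message(sprintf("epoch %3d | val MAE %.4f", ep, vmae))
    if (vmae < best$mae) {
      best$mae <- vmae
      best$values <- lapply(params, function(p) p$val)
    }
  }
  if (!is.null(best$values)) {
    for (k in seq_along(params)) params[[k]]$val <- best$values[[k]]
  }
  tp <- predict_scalar(work, head, feats[te$structure_id], norm,
                       pos_seed = seed + 11L)
  out <- list(model = work, head = head, norm = norm,
              val_mae = best$mae,
              report = eval_report(tp, te$label, te$structure_id, top_n,
                                   direction))
  class(out) <- "crysformer_finetuned"
  out
}

#' @export
print.crysformer_finetuned <- function(x, ...) {
  cat(sprintf(
    "<crysformer_finetuned> test MAE %.4f, R^2 %.3f, top-%d overlap %d\n",
    x$report$mae, x$report$r2, x$report$top_n, x$report$top_n_overlap))
  invisible(x)
}

#' Predict a property for new structures with a fine-tuned model
#'
#' @param object a `crysformer_finetuned`.
#' @param structures named list of P1 `crystal`s.
#' @param ... unused.
#' @return data frame with `structure_id` and `prediction`.
#' @export
predict.crysformer_finetuned <- function(object, structures, ...) {
  feats <- lapply(structures, prepare_structure, model = object$model)
  data.frame(structure_id = names(structures),
             prediction = predict_scalar(object$model, object$head, feats,
                                         object$norm))
}

#' Serialise a fine-tuned model (base weights, head, label scaling)
#'
#' @param ft a `crysformer_finetuned`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_finetuned <- function(ft, path) {
  tmp <- tempfile(fileext = ".rds")
  save_checkpoint(ft$model, tmp)
  saveRDS(list(base = readRDS(tmp),
               head = lapply(nn_params(ft$head), function(p) p$val),
               norm = ft$norm, report = ft$report),
          path)
  unlink(tmp)
  invisible(path)
}

#' Load a fine-tuned model written by [save_finetuned()]
#'
#' @param path bundle file.
#' @return a `crysformer_finetuned`.
#' @export
load_finetuned <- function(path) {
  bd <- readRDS(path)
  tmp <- tempfile(fileext = ".rds")
  saveRDS(bd$base, tmp)
  model <- load_checkpoint(tmp)
  unlink(tmp)
  head <- nn_linear(model$cfg$H, 1L)
  hp <- nn_params(head)
  for (k in seq_along(hp)) hp[[k]]$val <- bd$head[[k]]
  out <- list(model = model, head = head, norm = bd$norm,
              val_mae = NA_real_, report = bd$report)
  class(out) <- "crysformer_finetuned"
  out
}

#' Few-shot transfer protocol over molecule families
#'
#' Stage 1 fine-tunes the pre-trained model on all records whose `family`
#' differs from `holdout_tag` (90/10 train/validation). Stage 2, for each
#' `k`, fine-tunes a copy of the stage-1 model further on `k` randomly
#' sampled holdout records (a 10\% validation carve-out when `k >= 20`) and
#' always evaluates on the untouched holdout remainder. `k = 0` reports the
#' stage-1 model directly.
#'
#' @param model a pre-trained `crysformer_model`.
#' @param structures named list of P1 `crystal`s.
#' @param dataset property table with `structure_id`, `label`, `family`.
#' @param holdout_tag the family held out for transfer.
#' @param k_list vector of sample counts (0 = zero-shot).
#' @param seed master seed.
#' @param stage1_epochs,stage2_epochs epoch overrides.
#' @param direction top-n direction.
#' @return data frame with one row per `k`: `k`, `test_n`, `mae`, `r2`,
#'   `top_n_overlap`; per-k reports in the `reports` attribute.
#' @export
few_shot_protocol <- function(model, structures, dataset, holdout_tag,
                              k_list = c(0L, 20L, 50L), seed = 1L,
                              stage1_epochs = NULL, stage2_epochs = NULL,
                              direction = "lowest") {
  if (is.null(dataset$family)) stop("dataset needs a family column")
  hold <- dataset[dataset$family == holdout_tag, ]
  rest <- dataset[dataset$family != holdout_tag, ]
  if (!nrow(hold)) stop("no records carry the holdout tag")
  if (any(k_list >= nrow(hold))) {
    stop("k must be smaller than the holdout size")
  }
  # stage 1: train/val on the other families; the holdout family is the test
  rest <- assign_split(rest, seed = seed, split = c(0.9, 0.1, 0))
  # assign_split may produce an empty test level; recode for finetune()
  stage1_tab <- rbind(
    rest[, c("structure_id", "label", "split")],
    data.frame(structure_id = hold$structure_id, label = hold$label,
               split = "test")
  )
  stage1_tab$split <- factor(stage1_tab$split,
                             levels = c("train", "val", "test"))
  ft1 <- finetune(model, structures, stage1_tab, epochs = stage1_epochs,
                  seed = seed, direction = direction)
  rows <- list(); reports <- list()
  for (k in sort(unique(as.integer(k_list)))) {
    if (k == 0L) {
      rep0 <- ft1$report
      rows[[length(rows) + 1L]] <- data.frame(
        k = 0L, test_n = nrow(hold), mae = rep0$mae, r2 = rep0$r2,
        top_n_overlap = rep0$top_n_overlap)
      reports[["0"]] <- rep0
      next
    }
    sel <- with_seed(seed + 1000L + k, sample(hold$structure_id, k))
    shots <- hold[hold$structure_id %in% sel, ]
    testset <- hold[!hold$structure_id %in% sel, ]
    if (k >= 20L) {
      nval <- max(1L, round(0.1 * k))
      vsel <- with_seed(seed + 2000L + k, sample(shots$structure_id, nval))
      shot_rows <- data.frame(structure_id = shots$structure_id,
                              label = shots$label,
                              split = ifelse(shots$structure_id %in% vsel,
                                             "val", "train"))
    } else {
      # too few shots for a carve-out: train on all k and let the same
      # records act as the validation probe (model selection only)
      shot_rows <- rbind(
        data.frame(structure_id = shots$structure_id, label = shots$label,
                   split = "train"),
        data.frame(structure_id = shots$structure_id, label = shots$label,
                   split = "val"))
    }
    tab <- rbind(shot_rows,
                 data.frame(structure_id = testset$structure_id,
                            label = testset$label, split = "test"))
    tab$split <- factor(tab$split, levels = c("train", "val", "test"))
    ftk <- finetune(ft1$model, structures, tab, epochs = stage2_epochs,
                    seed = seed + k, direction = direction)
    rows[[length(rows) + 1L]] <- data.frame(
      k = k, test_n = nrow(testset), mae = ftk$report$mae,
      r2 = ftk$report$r2, top_n_overlap = ftk$report$top_n_overlap)
    reports[[as.character(k)]] <- ftk$report
  }
  out <- do.call(rbind, rows)
  attr(out, "reports") <- reports
  out
}
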