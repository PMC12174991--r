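# Multi-modal crystal transformer: token sequence assembly, encoder, the
# four self-supervised pre-training heads (masked atom prediction, atom pair
# classification, crystal density prediction, symmetry element prediction)
# and the pre-training loop.

.token_types <- c(CLS = 1L, ATOM = 2L, SEP = 3L, PATCH1D = 4L,
                  PATCH2D = 5L, SCL = 6L)

#' Model and training configuration
#'
#' Defaults follow the reference training recipe: encoder L = 12, H = 768,
#' A = 12; persistence images 50 x 50 with spread 0.15 and 5 x 5 patches;
#' 15\% atom masking split 80/10/10 between MASK, random element and
#' unchanged; 200 atom pairs per crystal; symmetry-element loss weights with
#' epsilon = 1.1; AdamW (lr 1e-4, weight decay 1e-2) with 5\% linear warm-up
#' then linear decay; pre-training 50 epochs at batch size 512; fine-tuning
#' 50 epochs at batch size 32 with an 80/10/10 split.
#'
#' @param L,H,A encoder layers, hidden width, attention heads.
#' @param max_atoms hard cap on atoms per structure (no silent truncation).
#' @param use_images include the persistence-image modality (`FALSE` is the
#'   image-free ablation).
#' @param positional_mode `"relative"` (perturbation-based, rigid-motion
#'   invariant) or `"absolute"` (binned fractional coordinates; the ablation).
#' @param resolution,patch,spread,min_extent persistence-image featurization.
#' @param H_graph,gnn_layers,cutoff,max_neighbors graph embedder size and
#'   neighbourhood.
#' @param knn_k,pos_sigma relative positional embedding neighbours and
#'   perturbation scale (Angstrom).
#' @param pos_rbf radial basis size of the positional features; fine enough
#'   (width 8 / (pos_rbf - 1) Angstrom) to resolve perturbation-scale
#'   distance differences.
#' @param n_anchors shared random reference atoms in the positional
#'   features (see [relative_positional()]).
#' @param abs_bins bins per axis for absolute positional embeddings.
#' @param n_rbf radial basis size.
#' @param mask_rate,corrupt_split masked-atom fraction and
#'   MASK/random/unchanged proportions.
#' @param n_pairs atom pairs per crystal for pair classification.
#' @param task_weights named multipliers on the four pre-training task
#'   losses (unit by default).
#' @param epsilon symmetry-element weight flattening.
#' @param pretrain_epochs,pretrain_batch,finetune_epochs,finetune_batch
#'   training lengths and batch sizes.
#' @param lr,weight_decay,warmup_frac optimiser settings.
#' @param split train/validation/test proportions.
#' @return a validated `crysformer_config` list.
#' @export
model_config <- function(L = 12L, H = 768L, A = 12L, max_atoms = 512L,
                         use_images = TRUE, positional_mode = "relative",
                         resolution = 50L, patch = 5L, spread = 0.15,
                         min_extent = 20, H_graph = 256L, gnn_layers = 2L,
                         cutoff = 5, max_neighbors = 8L, knn_k = 8L,
                         pos_sigma = 0.05, pos_rbf = 64L, n_anchors = 4L,
                         abs_bins = 100L,
                         n_rbf = 16L,
                         mask_rate = 0.15, corrupt_split = c(0.8, 0.1, 0.1),
                         n_pairs = 200L, epsilon = 1.1,
                         task_weights = c(map = 1, apc = 1, cdp = 1,
                                          sep = 1),
                         pretrain_epochs = 50L, pretrain_batch = 512L,
                         finetune_epochs = 50L, finetune_batch = 32L,
                         lr = 1e-4, weight_decay = 1e-2, warmup_frac = 0.05,
                         split = c(0.8, 0.1, 0.1)) {
  cfg <- list(L = as.integer(L), H = as.integer(H), A = as.integer(A),
              max_atoms = as.integer(max_atoms), use_images = use_images,
              positional_mode = match.arg(positional_mode,
                                          c("relative", "absolute")),
              resolution = as.integer(resolution), patch = as.integer(patch),
              spread = spread, min_extent = min_extent,
              H_graph = as.integer(H_graph),
              gnn_layers = as.integer(gnn_layers), cutoff = cutoff,
              max_neighbors = as.integer(max_neighbors),
              knn_k = as.integer(knn_k), pos_sigma = pos_sigma,
              pos_rbf = as.integer(pos_rbf),
              n_anchors = as.integer(n_anchors),
              abs_bins = as.integer(abs_bins), n_rbf = as.integer(n_rbf),
              mask_rate = mask_rate, corrupt_split = corrupt_split,
              n_pairs = as.integer(n_pairs), epsilon = epsilon,
              task_weights = task_weights,
              pretrain_epochs = as.integer(pretrain_epochs),
              pretrain_batch = as.integer(pretrain_batch),
              finetune_epochs = as.integer(finetune_epochs),
              finetune_batch = as.integer(finetune_batch),
              lr = lr, weight_decay = weight_decay,
              warmup_frac = warmup_frac, split = split)
  if (cfg$H %% cfg$A != 0) stop("H must be divisible by A")
  if (cfg$resolution %% cfg$patch != 0) {
    stop("patch size must divide the image resolution")
  }
  if (abs(sum(cfg$corrupt_split) - 1) > 1e-8) {
    stop("corrupt_split must sum to 1")
  }
  if (abs(sum(cfg$split) - 1) > 1e-8) stop("split must sum to 1")
  if (length(cfg$task_weights) != 4 || any(cfg$task_weights < 0)) {
    stop("task_weights must be four non-negative numbers")
  }
  class(cfg) <- "crysformer_config"
  cfg
}

# hash of the featurization-relevant fields; checkpoints refuse to mix with
# feature caches computed under a different featurization
featurization_hash <- function(cfg) {
  paste(cfg$resolution, cfg$patch, cfg$spread, cfg$min_extent, cfg$cutoff,
        cfg$max_neighbors, cfg$knn_k, cfg$n_rbf, cfg$pos_rbf,
        cfg$n_anchors, sep = "|")
}

#' Create a crystal transformer model
#'
#' @param cfg a [model_config()].
#' @param elements character vector of element symbols the model can see
#'   (the masked-atom vocabulary; a reserved MASK identity is appended).
#' @param seed initialisation seed.
#' @return a `crysformer_model`.
#' @export
crysformer_model <- function(cfg, elements, seed = 1L) {
  elements <- unique(as.character(elements))
  vocab <- c(elements, "MASK")
  m <- with_seed(seed, {
    rng <- stats::rnorm
    list(
      ge = graph_embedder(length(vocab), cfg$H_graph, cfg$gnn_layers,
                          cfg$n_rbf, rng),
      pos_proj = nn_linear((cfg$knn_k + cfg$n_anchors) * cfg$pos_rbf,
                           cfg$H_graph, rng),
      abs_tables = lapply(1:3, function(i) {
        ag_param(matrix(rng(cfg$abs_bins * cfg$H_graph) * 0.1,
                        cfg$abs_bins, cfg$H_graph))
      }),
      atom_proj = nn_linear(cfg$H_graph, cfg$H, rng),
      patch_proj = nn_linear(cfg$patch^2, cfg$H, rng),
      scl_proj = nn_linear(1L, cfg$H, rng),
      type_embed = ag_param(matrix(rng(6 * cfg$H) * 0.1, 6, cfg$H)),
      encoder = nn_encoder(cfg$L, cfg$H, cfg$A, rng),
      map_head = nn_linear(cfg$H, length(elements), rng),
      apc_g1 = nn_linear(2L * cfg$H, cfg$H, rng),
      apc_g2 = nn_linear(cfg$H, 1L, rng),
      cdp_head = nn_linear(cfg$H, 1L, rng),
      sep_head = nn_linear(cfg$H, 7L, rng)
    )
  })
  obj <- list(cfg = cfg, elements = elements, vocab = vocab, modules = m,
              sep_bits = .sep_bit_names,
              label_norm = list(mean = 0, sd = 1),
              sep_weights = rep(1, 7),
              feat_hash = featurization_hash(cfg))
  class(obj) <- "crysformer_model"
  obj
}

#' @export
print.crysformer_model <- function(x, ...) {
  np <- sum(vapply(nn_params(x$modules), function(p) length(p$val),
                   numeric(1)))
  cat(sprintf("<crysformer_model> L=%d H=%d A=%d, %s images, %s positions\n",
              x$cfg$L, x$cfg$H, x$cfg$A,
              if (x$cfg$use_images) "with" else "without",
              x$cfg$positional_mode))
  cat(sprintf("  vocabulary: %s; %.2fM parameters\n",
              paste(x$vocab, collapse = " "), np / 1e6))
  invisible(x)
}

model_params <- function(model) nn_params(model$modules)

#' Precompute the static features of one structure
#'
#' Neighbour graph, element ids, persistence-image patches and scale
#' scalars; everything except the per-epoch positional perturbation.
#'
#' @param s a P1 `crystal` with molecules assigned.
#' @param model a `crysformer_model` (for vocabulary and featurization
#'   settings).
#' @return a feature list consumed by [build_sequence()].
#' @export
prepare_structure <- function(s, model) {
  cfg <- model$cfg
  n <- n_atoms(s)
  if (n > cfg$max_atoms) {
    stop(sprintf("structure has %d atoms, exceeding max_atoms = %d", n,
                 cfg$max_atoms))
  }
  ids <- match(s$elements, model$vocab)
  if (anyNA(ids)) {
    stop("element(s) outside the model vocabulary: ",
         paste(unique(s$elements[is.na(ids)]), collapse = ", "))
  }
  feats <- list(
    structure_id = s$structure_id, n = n, elem_ids = ids,
    molecule_ids = s$molecule_ids, density = density(s), structure = s,
    graph = neighbor_graph(s, cfg$cutoff, cfg$max_neighbors)
  )
  if (cfg$use_images) {
    pf <- persistence_features(s, cfg$min_extent, cfg$resolution, cfg$spread)
    feats$patches_1d <- patchify(pf$image_1d, cfg$patch)
    feats$patches_2d <- patchify(pf$image_2d, cfg$patch)
    feats$scl <- c(pf$max_persistence_1d, pf$max_birth_1d,
                   pf$max_persistence_2d, pf$max_birth_2d)
  }
  feats
}

#' Assemble the multi-modal token sequence of a structure
#'
#' Layout: `[CLS]`, one token per atom, `[SEP]`, 1-D image patches, two
#' `[SCL]` scale tokens, `[SEP]`, 2-D image patches, two `[SCL]` tokens.
#' With `use_images = FALSE` the sequence ends after the first `[SEP]`.
#' Atom tokens are graph embedding + positional embedding, summed and
#' projected to H; patch tokens are linear projections of their pixels; SCL
#' tokens project the image's max-persistence / max-birth scalars. Token-type
#' embeddings are added to every position.
#'
#' @param model a `crysformer_model`.
#' @param feats output of [prepare_structure()].
#' @param pos_seed seed of the per-epoch positional perturbation.
#' @param mask_ids optional corrupted element ids (from [mask_atoms()]).
#' @return list with `x` (ag_node, T x H), `types`, and the token maps
#'   (`atom_pos`, `patch1_pos`, `patch2_pos`, `scl_pos`).
#' @export
build_sequence <- function(model, feats, pos_seed = 1L, mask_ids = NULL) {
  cfg <- model$cfg
  mod <- model$modules
  n <- feats$n
  if (is.null(mask_ids)) mask_ids <- feats$elem_ids
  h_atoms <- graph_embed(mod$ge, feats$graph, feats$elem_ids, mask_ids)
  pos <- if (cfg$positional_mode == "relative") {
    pf <- relative_positional(feats$structure, cfg$pos_sigma, cfg$knn_k,
                              pos_seed, cfg$pos_rbf, cfg$n_anchors)
    nn_apply_linear(mod$pos_proj, ag_const(pf))
  } else {
    absolute_positional(mod$abs_tables, feats$structure, cfg$abs_bins)
  }
  atoms <- nn_apply_linear(mod$atom_proj, ag_add(h_atoms, pos))
  zero <- ag_const(matrix(0, 1, cfg$H))
  if (cfg$use_images) {
    p1 <- nn_apply_linear(mod$patch_proj, ag_const(feats$patches_1d))
    p2 <- nn_apply_linear(mod$patch_proj, ag_const(feats$patches_2d))
    scl <- nn_apply_linear(mod$scl_proj, ag_const(matrix(feats$scl, 4, 1)))
    npatch <- (cfg$resolution / cfg$patch)^2
    content <- ag_rbind(zero, atoms, zero, p1, ag_gather(scl, 1:2),
                        zero, p2, ag_gather(scl, 3:4))
    types <- c(.token_types["CLS"], rep(.token_types["ATOM"], n),
               .token_types["SEP"], rep(.token_types["PATCH1D"], npatch),
               rep(.token_types["SCL"], 2), .token_types["SEP"],
               rep(.token_types["PATCH2D"], npatch),
               rep(.token_types["SCL"], 2))
    maps <- list(atom_pos = 2:(n + 1),
                 patch1_pos = (n + 3):(n + 2 + npatch),
                 scl1_pos = (n + 3 + npatch):(n + 4 + npatch),
                 patch2_pos = (n + 6 + npatch):(n + 5 + 2 * npatch),
                 scl2_pos = (n + 6 + 2 * npatch):(n + 7 + 2 * npatch))
  } else {
    content <- ag_rbind(zero, atoms, zero)
    types <- c(.token_types["CLS"], rep(.token_types["ATOM"], n),
               .token_types["SEP"])
    maps <- list(atom_pos = 2:(n + 1), patch1_pos = integer(0),
                 scl1_pos = integer(0), patch2_pos = integer(0),
                 scl2_pos = integer(0))
  }
  x <- ag_add(content, ag_gather(mod$type_embed, unname(types)))
  c(list(x = x, types = unname(types)), maps)
}

#' Run the transformer encoder over a token sequence
#'
#' @param model a `crysformer_model`.
#' @param seq output of [build_sequence()].
#' @param keep_attention retain per-layer, per-head attention matrices.
#' @return list with `reps` (ag_node, T x H) and `attn`
#'   (list of L lists of A TxT row-stochastic matrices) when requested.
#' @export
encode <- function(model, seq, keep_attention = FALSE) {
  r <- nn_apply_encoder(model$modules$encoder, seq$x, keep_attention)
  list(reps = r$out, attn = r$attn)
}

round_half_up <- function(x) floor(x + 0.5)

#' Select and corrupt atoms for masked atom prediction
#'
#' `max(1, round(rate * n))` atoms are drawn uniformly without replacement;
#' each is corrupted independently: with probability 0.8 its identity becomes
#' the reserved MASK token, with 0.1 a different random vocabulary element,
#' and with 0.1 it is left unchanged. The corrupted identities feed both the
#' token sequence and the graph embedder, so neighbours cannot leak the
#' masked element.
#'
#' @param elem_ids true element ids (1-based into the model vocabulary).
#' @param n_elements size of the real (non-MASK) vocabulary.
#' @param rate masking fraction.
#' @param seed sampling seed.
#' @return list with `mask_ids`, `selected` (indices), `labels` (true ids at
#'   the selected positions) and `modes` (1 = MASK, 2 = random, 3 = kept).
#' @export
mask_atoms <- function(elem_ids, n_elements, rate = 0.15, seed = 1L) {
  n <- length(elem_ids)
  if (n < 1) stop("need at least one atom token")
  m <- max(1L, round_half_up(rate * n))
  with_seed(seed, {
    sel <- sample.int(n, m)
    u <- stats::runif(m)
    modes <- ifelse(u < 0.8, 1L, ifelse(u < 0.9, 2L, 3L))
    out <- elem_ids
    mask_id <- n_elements + 1L
    for (k in seq_len(m)) {
      if (modes[k] == 1L) {
        out[sel[k]] <- mask_id
      } else if (modes[k] == 2L) {
        others <- setdiff(seq_len(n_elements), elem_ids[sel[k]])
        out[sel[k]] <- if (length(others)) others[sample.int(length(others),
                                                             1)] else
          elem_ids[sel[k]]
      }
    }
    list(mask_ids = as.integer(out), selected = sel,
         labels = as.integer(elem_ids[sel]), modes = modes)
  })
}

#' Sample balanced atom pairs for same-molecule classification
#'
#' Exactly half the pairs are drawn (with replacement) from the population of
#' intra-molecular pairs and half from the inter-molecular pairs. A structure
#' whose cell contains a single molecule (or no valid intra pair) cannot
#' support the task and returns `NULL`, the task-disabled sentinel.
#'
#' @param molecule_ids per-atom molecule labels (0-based).
#' @param n_pairs total number of pairs (even).
#' @param seed sampling seed.
#' @return data frame with columns `i`, `j` (1-based atom indices) and
#'   `same` (0/1), or `NULL`.
#' @export
sample_pairs <- function(molecule_ids, n_pairs = 200L, seed = 1L) {
  n <- length(molecule_ids)
  if (n < 2) stop("need at least two atoms")
  if (n_pairs %% 2L != 0L) stop("n_pairs must be even")
  cmb <- t(utils::combn(n, 2))
  same <- molecule_ids[cmb[, 1]] == molecule_ids[cmb[, 2]]
  if (!any(same) || all(same)) return(NULL)
  with_seed(seed, {
    half <- n_pairs / 2L
    ii <- which(same)[sample.int(sum(same), half, replace = TRUE)]
    jj <- which(!same)[sample.int(sum(!same), half, replace = TRUE)]
    pick <- c(ii, jj)
    data.frame(i = cmb[pick, 1], j = cmb[pick, 2],
               same = rep(c(1L, 0L), each = half))
  })
}

#' Order-symmetric same-molecule logit
#'
#' The two representations are concatenated in both orders, passed through
#' the same two-layer head, and the outputs summed, making the logit exactly
#' symmetric in its arguments.
#'
#' @param model a `crysformer_model`.
#' @param hi,hj ag_nodes of paired row representations (P x H each).
#' @return ag_node of P x 1 logits.
#' @export
apc_head <- function(model, hi, hj) {
  g <- function(x) {
    nn_apply_linear(model$modules$apc_g2,
                    ag_gelu(nn_apply_linear(model$modules$apc_g1, x)))
  }
  ag_add(g(ag_cbind(hi, hj)), g(ag_cbind(hj, hi)))
}

#' Density prediction from the `[CLS]` representation
#'
#' A single affine head on the standardised density scale; predictions are
#' de-standardised with the statistics stored in the model.
#'
#' @param model a `crysformer_model`.
#' @param cls ag_node 1 x H `[CLS]` representation.
#' @return ag_node 1 x 1 standardised prediction.
#' @export
cdp_head <- function(model, cls) nn_apply_linear(model$modules$cdp_head, cls)

#' Symmetry-element logits from the `[CLS]` representation
#' @param model a `crysformer_model`.
#' @param cls ag_node 1 x H.
#' @return ag_node 1 x 7 logits.
#' @export
sep_head <- function(model, cls) nn_apply_linear(model$modules$sep_head, cls)

# forward pass + all pre-training losses for one structure
pretrain_forward <- function(model, feats, sep_label, epoch_seed) {
  cfg <- model$cfg
  msk <- mask_atoms(feats$elem_ids, length(model$elements), cfg$mask_rate,
                    seed = epoch_seed)
  seq <- build_sequence(model, feats, pos_seed = epoch_seed + 1L,
                        mask_ids = msk$mask_ids)
  enc <- encode(model, seq)
  reps <- enc$reps
  cls <- ag_gather(reps, 1L)
  # MAP
  map_logits <- nn_apply_linear(model$modules$map_head,
                                ag_gather(reps, seq$atom_pos[msk$selected]))
  l_map <- ag_xent(map_logits, msk$labels)
  map_acc <- mean(apply(map_logits$val, 1, which.max) == msk$labels)
  # APC
  pairs <- sample_pairs(feats$molecule_ids, cfg$n_pairs,
                        seed = epoch_seed + 2L)
  if (!is.null(pairs)) {
    hi <- ag_gather(reps, seq$atom_pos[pairs$i])
    hj <- ag_gather(reps, seq$atom_pos[pairs$j])
    logit <- apc_head(model, hi, hj)
    l_apc <- ag_bce(logit, matrix(pairs$same, ncol = 1))
    apc_acc <- mean((logit$val[, 1] > 0) == (pairs$same == 1L))
  } else {
    l_apc <- ag_const(matrix(0, 1, 1))
    apc_acc <- NA_real_
  }
  # CDP (standardised squared error)
  z <- (feats$density - model$label_norm$mean) / model$label_norm$sd
  pred <- cdp_head(model, cls)
  l_cdp <- ag_mse(pred, matrix(z, 1, 1))
  cdp_err <- abs(pred$val[1, 1] * model$label_norm$sd +
                   model$label_norm$mean - feats$density)
  # SEP (weighted multi-label BCE)
  logits7 <- sep_head(model, cls)
  l_sep <- ag_bce(logits7, matrix(as.numeric(sep_label), 1, 7),
                  model$sep_weights)
  p7 <- 1 / (1 + exp(-logits7$val[1, ]))
  sep_ok <- sep_exact_match(p7, sep_label)
  tw <- unname(cfg$task_weights)
  loss <- ag_sum_scalars(list(ag_scale(l_map, tw[1]), ag_scale(l_apc, tw[2]),
                              ag_scale(l_cdp, tw[3]), ag_scale(l_sep, tw[4])))
  list(loss = loss,
       parts = c(map = l_map$val[1, 1], apc = l_apc$val[1, 1],
                 cdp = l_cdp$val[1, 1], sep = l_sep$val[1, 1]),
       metrics = c(map_acc = map_acc, apc_acc = apc_acc, cdp_mae = cdp_err,
                   sep_exact = as.numeric(sep_ok)))
}

#' Pre-train a crystal transformer with the four self-supervised tasks
#'
#' The total loss is the unit-weighted sum of the four task losses; per-task
#' values are logged every epoch. Positional embeddings and masking are
#' redrawn each epoch. Symmetry labels are taken from the declared space
#' group of each training record; densities are recomputed from the
#' structures.
#'
#' @param model a `crysformer_model`.
#' @param structures list of P1 `crystal`s with molecules assigned.
#' @param space_groups integer vector of their space-group numbers.
#' @param epochs,batch_size override the config values (useful for reduced
#'   runs).
#' @param seed master seed.
#' @param verbose print per-epoch task losses.
#' @return the model (parameters updated in place share state), with a
#'   `history` data frame of per-epoch mean task losses attached.
#' @export
pretrain <- function(model, structures, space_groups,
                     epochs = NULL, batch_size = NULL, seed = 1L,
                     verbose = FALSE) {
  cfg <- model$cfg
  if (is.null(epochs)) epochs <- cfg$pretrain_epochs
  if (is.null(batch_size)) batch_size <- cfg$pretrain_batch
  n <- length(structures)
  stopifnot(length(space_groups) == n)
  feats <- lapply(structures, prepare_structure, model = model)
  labels7 <- lapply(space_groups, function(g) unclass(symmetry_elements(g)))
  # CDP standardisation and SEP class weights from the training set
  dens <- vapply(feats, function(f) f$density, numeric(1))
  model$label_norm <- list(mean = mean(dens), sd = max(stats::sd(dens), 1e-6))
  freq <- Reduce("+", labels7)
  # inverse-frequency weights over the observed element classes; classes that
  # never occur in the training set carry no signal (their targets are always
  # zero) and take the mean weight instead of an inflated "ultra-rare" one
  w <- rep(1, 7)
  if (any(freq > 0) && any(freq == 0)) {
    w[freq > 0] <- element_weights(freq[freq > 0], cfg$epsilon)
  } else {
    w <- element_weights(freq, cfg$epsilon)
  }
  model$sep_weights <- w
  params <- model_params(model)
  opt <- adamw(params, lr = cfg$lr, weight_decay = cfg$weight_decay)
  total_steps <- epochs * ceiling(n / batch_size)
  step <- 0L
  hist <- matrix(0, epochs, 4,
                 dimnames = list(NULL, c("map", "apc", "cdp", "sep")))
  for (ep in seq_len(epochs)) {
    ord <- with_seed(seed + 7919L * ep, sample.int(n))
    acc <- c(map = 0, apc = 0, cdp = 0, sep = 0)
    done <- 0L
    for (bstart in seq(1, n, by = batch_size)) {
      batch <- ord[bstart:min(bstart + batch_size - 1L, n)]
      ag_zero_grad(params)
      for (i in batch) {
        ag_reset()
        fw <- pretrain_forward(model, feats[[i]], labels7[[i]],
                               epoch_seed = seed + 104729L * ep + i)
        ag_backward(fw$loss)
        acc <- acc + fw$parts
        done <- done + 1L
      }
      # mean gradient over the batch
      for (p in params) if (!is.null(p$grad)) p$grad <- p$grad / length(batch)
      step <- step + 1L
      adamw_step(opt, lr_schedule(step, total_steps, cfg$warmup_frac))
    }
    hist[ep, ] <- acc / done
    if (verbose) {
      message(sprintf("epoch %3d | map %.4f apc %.4f cdp %.4f sep %.4f",
                      ep, hist[ep, 1], hist[ep, 2], hist[ep, 3], hist[ep, 4]))
    }
  }
  model$history <- as.data.frame(hist)
  model
}

#' Evaluate the pre-training tasks on held-out structures
#'
#' @param model a pre-trained `crysformer_model`.
#' @param structures list of P1 `crystal`s.
#' @param space_groups their space-group numbers.
#' @param seed evaluation seed (controls masking/pair draws).
#' @return named numeric vector: `map_acc`, `apc_acc`, `sep_exact`,
#'   `cdp_mae` (g cm^-3).
#' @export
evaluate_pretrain <- function(model, structures, space_groups, seed = 99L) {
  feats <- lapply(structures, prepare_structure, model = model)
  labels7 <- lapply(space_groups, function(g) unclass(symmetry_elements(g)))
  ms <- t(vapply(seq_along(feats), function(i) {
    ag_reset()
    fw <- pretrain_forward(model, feats[[i]], labels7[[i]],
                           epoch_seed = seed + i)
    fw$metrics
  }, numeric(4)))
  c(map_acc = mean(ms[, "map_acc"]),
    apc_acc = mean(ms[, "apc_acc"], na.rm = TRUE),
    cdp_mae = mean(ms[, "cdp_mae"]),
    sep_exact = mean(ms[, "sep_exact"]))
}

# ---- checkpoints -----------------------------------------------------------

#' Serialise a model to a checkpoint file
#'
#' Stores parameter values, configuration, element vocabulary, the symmetry
#' bit order and the featurization hash. Loading refuses a checkpoint whose
#' featurization hash disagrees with the requested configuration.
#'
#' @param model a `crysformer_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  params <- model_params(model)
  saveRDS(list(values = lapply(params, function(p) p$val),
               cfg = model$cfg, elements = model$elements,
               sep_bits = model$sep_bits, label_norm = model$label_norm,
               sep_weights = model$sep_weights,
               feat_hash = model$feat_hash,
               history = model$history),
          path)
  invisible(path)
}

#' Load a model from a checkpoint file
#'
#' @param path checkpoint file written by [save_checkpoint()].
#' @param expect_hash optional featurization hash that must match.
#' @return a `crysformer_model`.
#' @export
load_checkpoint <- function(path, expect_hash = NULL) {
  ck <- readRDS(path)
  if (!is.null(expect_hash) && !identical(expect_hash, ck$feat_hash)) {
    stop("checkpoint featurization hash mismatch: refusing to load")
  }
  model <- crysformer_model(ck$cfg, ck$elements, seed = 1L)
  if (!identical(model$sep_bits, ck$sep_bits)) {
    stop("checkpoint symmetry bit order disagrees with this build")
  }
  params <- model_params(model)
  stopifnot(length(params) == length(ck$values))
  for (k in seq_along(params)) {
    stopifnot(all(dim(params[[k]]$val) == dim(ck$values[[k]])))
    params[[k]]$val <- ck$values[[k]]
  }
  model$label_norm <- ck$label_norm
  model$sep_weights <- ck$sep_weights
  model$history <- ck$history
  model
}

#' Clone a model (deep copy of parameters)
#' @param model a `crysformer_model`.
#' @return an independent copy.
#' @export
clone_model <- function(model) {
  src <- model_params(model)
  out <- crysformer_model(model$cfg, model$elements, seed = 1L)
  dst <- model_params(out)
  for (k in seq_along(src)) dst[[k]]$val <- src[[k]]$val
  out$label_norm <- model$label_norm
  out$sep_weights <- model$sep_weights
  out$history <- model$history
  out
}
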