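# Attention-rollout attribution: cumulative [CLS] attention across layers,
# mapped back to atoms and persistence-image patches.

#' Attention rollout across encoder layers
#'
#' Heads are averaged per layer, the residual connection is mixed in as
#' `residual_alpha * I + (1 - residual_alpha) * A` with rows renormalised,
#' and the modified matrices are multiplied recursively across layers. The
#' `[CLS]` row of the product gives each token's cumulative contribution.
#'
#' @param attentions list (length L) of lists (length A) of TxT
#'   row-stochastic attention matrices, as returned by [encode()] with
#'   `keep_attention = TRUE`.
#' @param residual_alpha residual mixing weight in `[0, 1]`.
#' @return numeric vector of length T: the rolled-out `[CLS]` row (sums
#'   to 1).
#' @export
attention_rollout <- function(attentions, residual_alpha = 0.5) {
  if (!length(attentions)) stop("no attention matrices supplied")
  t_len <- nrow(attentions[[1]][[1]])
  roll <- diag(t_len)
  for (layer in attentions) {
    a <- Reduce("+", layer) / length(layer)
    if (max(abs(rowSums(a) - 1)) > 1e-3) {
      stop("attention rows do not sum to 1: not row-stochastic")
    }
    a <- residual_alpha * diag(t_len) + (1 - residual_alpha) * a
    a <- a / rowSums(a)
    roll <- a %*% roll
  }
  roll[1, ]
}

#' Attribute a model's output to atoms and image patches
#'
#' Runs the encoder with attention retained, rolls the attention out, and
#' gathers the `[CLS]` row by token type. Scores are renormalised over the
#' non-special tokens (atoms, patches, scale tokens; `[CLS]`/`[SEP]`
#' excluded) so the modality shares are comparable. The display clip
#' threshold (default 0.005) is carried in the result; clipping is applied
#' at export/visualisation time only.
#'
#' @param model a `crysformer_model` or `crysformer_finetuned`.
#' @param s a P1 `crystal` (or a prepared feature list).
#' @param pos_seed positional embedding seed.
#' @param residual_alpha rollout residual mixing.
#' @param clip_threshold display floor carried in the result.
#' @return object of class `attribution` with `atom_scores`,
#'   `patch_scores_1d`, `patch_scores_2d`, `scl_scores`, `top10_1d`,
#'   `top10_2d`.
#' @export
attribute <- function(model, s, pos_seed = 1L, residual_alpha = 0.5,
                      clip_threshold = 0.005) {
  if (inherits(model, "crysformer_finetuned")) model <- model$model
  feats <- if (inherits(s, "crystal")) prepare_structure(s, model) else s
  ag_reset()
  seq <- build_sequence(model, feats, pos_seed = pos_seed)
  enc <- encode(model, seq, keep_attention = TRUE)
  scores <- attention_rollout(enc$attn, residual_alpha)
  keep <- c(seq$atom_pos, seq$patch1_pos, seq$scl1_pos, seq$patch2_pos,
            seq$scl2_pos)
  norm <- scores[keep] / sum(scores[keep])
  names(norm) <- NULL
  n <- feats$n
  npatch <- length(seq$patch1_pos)
  atom_scores <- norm[seq_len(n)]
  at <- n
  patch1 <- norm[at + seq_len(npatch)]; at <- at + npatch
  scl1 <- norm[at + seq_len(length(seq$scl1_pos))]
  at <- at + length(seq$scl1_pos)
  patch2 <- norm[at + seq_len(npatch)]; at <- at + npatch
  scl2 <- norm[at + seq_len(length(seq$scl2_pos))]
  top10 <- function(v) if (length(v)) order(-v)[seq_len(min(10, length(v)))]
    else integer(0)
  structure(list(
    structure_id = feats$structure_id,
    atom_scores = atom_scores,
    patch_scores_1d = patch1, patch_scores_2d = patch2,
    scl_scores = c(scl1, scl2),
    top10_1d = top10(patch1), top10_2d = top10(patch2),
    clip_threshold = clip_threshold,
    rollout = scores, token_types = seq$types
  ), class = "attribution")
}

#' @export
print.attribution <- function(x, ...) {
  cat(sprintf("<attribution '%s'> %d atoms (share %.3f)", x$structure_id,
              length(x$atom_scores), sum(x$atom_scores)))
  if (length(x$patch_scores_1d)) {
    cat(sprintf(", images share %.3f",
                sum(x$patch_scores_1d, x$patch_scores_2d, x$scl_scores)))
  }
  cat("\n")
  invisible(x)
}

#' Clip an attribution's atom scores for display
#'
#' Scores below the stored threshold are set to zero; others are unchanged.
#'
#' @param result an `attribution`.
#' @return numeric vector of clipped atom scores.
#' @export
clip_scores <- function(result) {
  s <- result$atom_scores
  s[s < result$clip_threshold] <- 0
  s
}

#' Export attribution results for visualisation
#'
#' Writes (a) an extended-XYZ file with a per-atom score column, (b) the
#' patch-score overlay grids as CSV, and (c) a JSON summary with the top-10
#' patches per image and the scale-token scores.
#'
#' @param result an `attribution`.
#' @param s the `crystal` the attribution belongs to.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
export_attribution <- function(result, s, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stopifnot(length(result$atom_scores) == n_atoms(s))
  xyz <- file.path(dir, paste0(result$structure_id, "_scores.extxyz"))
  write_extxyz(s, xyz, extra = list(attention = result$atom_scores))
  paths <- c(xyz = xyz)
  grid_of <- function(v) {
    g <- as.integer(sqrt(length(v)))
    matrix(v, g, g, byrow = TRUE)   # row-major patch order
  }
  if (length(result$patch_scores_1d)) {
    p1 <- file.path(dir, paste0(result$structure_id, "_patches_1d.csv"))
    p2 <- file.path(dir, paste0(result$structure_id, "_patches_2d.csv"))
    utils::write.csv(grid_of(result$patch_scores_1d), p1, row.names = FALSE)
    utils::write.csv(grid_of(result$patch_scores_2d), p2, row.names = FALSE)
    paths <- c(paths, patches_1d = p1, patches_2d = p2)
  }
  js <- file.path(dir, paste0(result$structure_id, "_attribution.json"))
  jsonlite::write_json(list(
    structure_id = result$structure_id,
    clip_threshold = result$clip_threshold,
    atom_scores = result$atom_scores,
    scl_scores = result$scl_scores,
    top10_1d = result$top10_1d, top10_2d = result$top10_2d
  ), js, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, json = js)
  invisible(paths)
}
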