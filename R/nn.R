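# Neural building blocks on the autograd engine: linear / layer-norm /
# multi-head self-attention / transformer encoder, plus the atom graph
# embedder (edge-gated message passing on the periodic bond graph
# interleaved with line-graph angle updates).

nn_init <- function(nin, nout, rng) {
  matrix(rng(nin * nout) * sqrt(2 / (nin + nout)), nin, nout)
}

nn_linear <- function(nin, nout, rng = stats::rnorm) {
  list(W = ag_param(nn_init(nin, nout, rng)),
       b = ag_param(matrix(0, 1, nout)))
}

nn_apply_linear <- function(lin, x) ag_add(ag_mm(x, lin$W), lin$b)

nn_layernorm_params <- function(width) {
  list(gamma = ag_param(matrix(1, 1, width)),
       beta = ag_param(matrix(0, 1, width)))
}

nn_apply_ln <- function(ln, x) ag_layernorm(x, ln$gamma, ln$beta)

nn_mha <- function(H, A, rng = stats::rnorm) {
  # the output projection starts at zero so each residual block is the
  # identity at initialisation; input features then reach the heads intact
  # and the attention pathway grows in as training demands it
  o <- nn_linear(H, H, rng)
  o$W$val[] <- 0
  list(H = H, A = A,
       q = nn_linear(H, H, rng), k = nn_linear(H, H, rng),
       v = nn_linear(H, H, rng), o = o)
}

# returns list(out = ag_node TxH, attn = list of A TxT matrices (values))
nn_apply_mha <- function(mha, x, keep_attention = FALSE) {
  H <- mha$H; A <- mha$A
  dk <- H / A
  q <- nn_apply_linear(mha$q, x)
  k <- nn_apply_linear(mha$k, x)
  v <- nn_apply_linear(mha$v, x)
  heads <- vector("list", A)
  attn <- if (keep_attention) vector("list", A) else NULL
  for (h in seq_len(A)) {
    j0 <- (h - 1L) * dk + 1L; j1 <- h * dk
    qh <- ag_cols(q, j0, j1); kh <- ag_cols(k, j0, j1)
    vh <- ag_cols(v, j0, j1)
    scores <- ag_scale(ag_tcross(qh, kh), 1 / sqrt(dk))
    p <- ag_softmax(scores)
    if (keep_attention) attn[[h]] <- p$val
    heads[[h]] <- ag_mm(p, vh)
  }
  out <- nn_apply_linear(mha$o, do.call(ag_cbind, heads))
  list(out = out, attn = attn)
}

nn_encoder_layer <- function(H, A, rng = stats::rnorm) {
  ff2 <- nn_linear(4 * H, H, rng)
  ff2$W$val[] <- 0                   # identity residual at initialisation
  list(ln1 = nn_layernorm_params(H), mha = nn_mha(H, A, rng),
       ln2 = nn_layernorm_params(H),
       ff1 = nn_linear(H, 4 * H, rng), ff2 = ff2)
}

nn_apply_encoder_layer <- function(layer, x, keep_attention = FALSE) {
  # pre-norm residual blocks
  a <- nn_apply_mha(layer$mha, nn_apply_ln(layer$ln1, x), keep_attention)
  x <- ag_add(x, a$out)
  f <- nn_apply_linear(layer$ff2,
                       ag_gelu(nn_apply_linear(layer$ff1,
                                               nn_apply_ln(layer$ln2, x))))
  list(out = ag_add(x, f), attn = a$attn)
}

nn_encoder <- function(L, H, A, rng = stats::rnorm) {
  list(layers = lapply(seq_len(L), function(i) nn_encoder_layer(H, A, rng)),
       ln_out = nn_layernorm_params(H))
}

nn_apply_encoder <- function(enc, x, keep_attention = FALSE) {
  attn <- if (keep_attention) vector("list", length(enc$layers)) else NULL
  for (l in seq_along(enc$layers)) {
    r <- nn_apply_encoder_layer(enc$layers[[l]], x, keep_attention)
    x <- r$out
    if (keep_attention) attn[[l]] <- r$attn
  }
  list(out = nn_apply_ln(enc$ln_out, x), attn = attn)
}

# collect all ag_param nodes from a nested module list
nn_params <- function(module) {
  out <- list()
  walk <- function(m) {
    if (inherits(m, "ag_node")) {
      if (isTRUE(m$is_param)) out[[length(out) + 1L]] <<- m
    } else if (is.list(m)) {
      for (x in m) walk(x)
    }
  }
  walk(module)
  out
}

# ---- periodic graph construction ------------------------------------------

# radial basis expansion: ncent Gaussians, centres lo..hi
rbf_expand <- function(x, lo, hi, ncent) {
  centres <- seq(lo, hi, length.out = ncent)
  width <- (hi - lo) / (ncent - 1)
  exp(-outer(x, centres, "-")^2 / (2 * width^2))
}

#' Periodic neighbour graph of a structure
#'
#' Directed edges to the `max_neighbors` nearest periodic images within
#' `cutoff`, with displacement vectors, distances and the angle triplets
#' (pairs of edges sharing a central atom) used by the line-graph updates.
#'
#' @param s a P1 `crystal`.
#' @param cutoff neighbour cutoff in Angstrom.
#' @param max_neighbors cap on neighbours per atom.
#' @return list with `src`, `dst`, `dist`, `vec` (edge displacement,
#'   Cartesian), and triplet indices `t_e1`, `t_e2`, `t_cos`.
#' @export
neighbor_graph <- function(s, cutoff = 5, max_neighbors = 8) {
  n <- n_atoms(s)
  shell <- pmax(1L, ceiling(cutoff / perp_widths(s$lattice)))
  offs <- as.matrix(expand.grid(a = -shell[1]:shell[1], b = -shell[2]:shell[2],
                                c = -shell[3]:shell[3]))
  cart <- cart_coords(s)
  src <- integer(0); dst <- integer(0); dist <- numeric(0)
  vec <- matrix(0, 0, 3)
  for (k in seq_len(nrow(offs))) {
    shiftc <- (s$frac_coords + matrix(as.numeric(offs[k, ]), n, 3,
                                      byrow = TRUE)) %*% s$lattice
    for (i in seq_len(n)) {
      dv <- shiftc - matrix(cart[i, ], n, 3, byrow = TRUE)
      dd <- sqrt(rowSums(dv^2))
      sel <- which(dd > 1e-8 & dd <= cutoff)
      if (length(sel)) {
        src <- c(src, rep(i, length(sel)))
        dst <- c(dst, sel)
        dist <- c(dist, dd[sel])
        vec <- rbind(vec, dv[sel, , drop = FALSE])
      }
    }
  }
  # keep the max_neighbors nearest per source atom
  keep <- unlist(lapply(seq_len(n), function(i) {
    w <- which(src == i)
    w[order(dist[w])][seq_len(min(length(w), max_neighbors))]
  }))
  keep <- sort(keep)
  src <- src[keep]; dst <- dst[keep]; dist <- dist[keep]
  vec <- vec[keep, , drop = FALSE]
  # angle triplets: all ordered pairs of distinct edges sharing their source
  # atom (both orders, so the line-graph update is permutation-equivariant)
  t_e1 <- integer(0); t_e2 <- integer(0); t_cos <- numeric(0)
  for (i in seq_len(n)) {
    ed <- which(src == i)
    if (length(ed) < 2) next
    pr <- expand.grid(a = ed, b = ed)
    pr <- pr[pr$a != pr$b, , drop = FALSE]
    cosv <- rowSums(vec[pr$a, , drop = FALSE] * vec[pr$b, , drop = FALSE]) /
      (dist[pr$a] * dist[pr$b])
    t_e1 <- c(t_e1, pr$a); t_e2 <- c(t_e2, pr$b)
    t_cos <- c(t_cos, pmin(pmax(cosv, -1), 1))
  }
  list(src = src, dst = dst, dist = dist, vec = vec,
       t_e1 = t_e1, t_e2 = t_e2, t_cos = t_cos, n = n)
}

# ---- atom graph embedder ---------------------------------------------------

graph_embedder <- function(vocab_size, H_graph = 256, n_layers = 2,
                           n_rbf = 16, rng = stats::rnorm) {
  list(
    H_graph = H_graph, n_layers = n_layers, n_rbf = n_rbf,
    embed = ag_param(matrix(rng(vocab_size * H_graph) * 0.1,
                            vocab_size, H_graph)),
    edge_in = nn_linear(n_rbf, H_graph, rng),
    angle_in = nn_linear(n_rbf, H_graph, rng),
    layers = lapply(seq_len(n_layers), function(i) list(
      # bond-graph conv: gated message from source node and edge feature
      gate = nn_linear(2 * H_graph, H_graph, rng),
      msg = nn_linear(2 * H_graph, H_graph, rng),
      upd = nn_linear(2 * H_graph, H_graph, rng),
      # line-graph conv: edge update from the two edges and their angle
      ang_msg = nn_linear(3 * H_graph, H_graph, rng),
      edge_upd = nn_linear(2 * H_graph, H_graph, rng)
    ))
  )
}

#' Per-atom graph embeddings by message passing on bond and line graphs
#'
#' Runs edge-gated message passing on the periodic neighbour graph,
#' interleaved with a line-graph pass that refines edge features from bond
#' angles. Atoms flagged in `mask_flags` enter with the reserved MASK element
#' identity, so their chemical identity is invisible to the network (their
#' own and their neighbours' messages see only MASK).
#'
#' @param ge a graph-embedder module.
#' @param graph output of [neighbor_graph()].
#' @param elem_ids 1-based indices into the element vocabulary.
#' @param mask_ids as `elem_ids` but with masked/corrupted entries replaced.
#' @return ag_node of N x H_graph embeddings.
#' @export
graph_embed <- function(ge, graph, elem_ids, mask_ids = elem_ids) {
  n <- graph$n
  h <- ag_gather(ge$embed, mask_ids)
  e <- nn_apply_linear(ge$edge_in,
                       ag_const(rbf_expand(graph$dist, 0, 8, ge$n_rbf)))
  a <- if (length(graph$t_e1)) {
    nn_apply_linear(ge$angle_in,
                    ag_const(rbf_expand(graph$t_cos, -1, 1, ge$n_rbf)))
  }
  for (ly in ge$layers) {
    if (length(graph$t_e1)) {
      # line-graph update: angle-conditioned message refines both edges
      pair <- ag_cbind(ag_gather(e, graph$t_e1), ag_gather(e, graph$t_e2))
      am <- ag_gelu(nn_apply_linear(ly$ang_msg, ag_cbind(pair, a)))
      # triplets carry both edge orders; each edge receives as t_e1
      agg_e <- ag_scatter(am, graph$t_e1, length(graph$dist))
      e <- ag_add(e, ag_gelu(nn_apply_linear(ly$edge_upd,
                                             ag_cbind(e, agg_e))))
    }
    # bond-graph update: gated messages from neighbours
    hs <- ag_gather(h, graph$src)
    gate <- ag_sigmoid(nn_apply_linear(ly$gate, ag_cbind(hs, e)))
    msg <- ag_mul(gate, ag_gelu(nn_apply_linear(ly$msg, ag_cbind(hs, e))))
    agg <- ag_scatter(msg, graph$dst, n)
    h <- ag_add(h, ag_gelu(nn_apply_linear(ly$upd, ag_cbind(h, agg))))
  }
  h
}

# ---- positional embeddings -------------------------------------------------

#' Relative positional features from a randomly perturbed structure
#'
#' The structure is perturbed with i.i.d. Gaussian noise (`sigma`) and each
#' atom receives two distance-only descriptors, each expanded in a fixed
#' radial basis: (a) its sorted periodic distances to its `k` nearest
#' neighbours (local geometry) and (b) its periodic distances to
#' `n_anchors` randomly selected reference atoms shared by all atoms of the
#' structure (relational geometry: atoms of the same molecule are close, so
#' their anchor distances agree to within the molecular diameter). Both the
#' perturbation and the anchor choice are refreshed with a new seed every
#' epoch, which also breaks any dependence on atom ordering. Built from
#' internal distances only, the features are invariant under rigid rotation
#' and translation of the structure.
#'
#' @param s a P1 `crystal`.
#' @param sigma perturbation scale in Angstrom.
#' @param k number of nearest neighbours.
#' @param seed perturbation / anchor seed.
#' @param n_rbf radial basis size per distance.
#' @param n_anchors number of shared reference atoms.
#' @return N x ((k + n_anchors) * n_rbf) numeric matrix.
#' @export
relative_positional <- function(s, sigma = 0.05, k = 8, seed = 1L,
                                n_rbf = 16, n_anchors = 4L) {
  if (k < 1) stop("k must be >= 1")
  sp <- perturb(s, sigma, seed)
  n <- n_atoms(sp)
  # enumerate enough periodic images that every atom has >= k neighbours
  shell <- max(1L, ceiling(8 / min(perp_widths(sp$lattice))))
  repeat {
    offs <- as.matrix(expand.grid(a = -shell:shell, b = -shell:shell,
                                  c = -shell:shell))
    if ((2 * shell + 1)^3 * n > k) break
    shell <- shell + 1L
  }
  cart <- cart_coords(sp)
  img <- (offs[rep(seq_len(nrow(offs)), each = n), ] +
            sp$frac_coords[rep(seq_len(n), nrow(offs)), ]) %*% sp$lattice
  d2 <- outer(rowSums(cart^2), rowSums(img^2), "+") - 2 * cart %*% t(img)
  d2[d2 < 1e-10] <- Inf      # drop self images (incl. cancellation error)
  dd <- sqrt(t(apply(d2, 1, sort.int, method = "quick")[seq_len(k), ,
                                                        drop = FALSE]))
  feats <- matrix(0, n, (k + n_anchors) * n_rbf)
  for (j in seq_len(k)) {
    feats[, ((j - 1) * n_rbf + 1):(j * n_rbf)] <-
      rbf_expand(dd[, j], 0, 8, n_rbf)
  }
  if (n_anchors > 0) {
    anchors <- with_seed(seed + 1299709L,
                         sample.int(n, n_anchors, replace = n < n_anchors))
    da <- crysformer_min_anchor_dist(sp, anchors)
    for (j in seq_len(n_anchors)) {
      feats[, ((k + j - 1) * n_rbf + 1):((k + j) * n_rbf)] <-
        rbf_expand(da[, j], 0, 12, n_rbf)
    }
  }
  feats
}

# periodic minimum-image distances from every atom to the anchor atoms
crysformer_min_anchor_dist <- function(sp, anchors) {
  d <- min_image_dist(sp$lattice, sp$frac_coords,
                      sp$frac_coords[anchors, , drop = FALSE],
                      shell = 1L)
  d
}

#' Absolute positional embeddings from binned fractional coordinates
#'
#' Each fractional coordinate is discretised into `bins` and looked up in a
#' per-axis embedding table; the three vectors are summed. Deliberately not
#' invariant under rigid motions (the ablation variant).
#'
#' @param tables list of three bins x width parameter nodes.
#' @param s a P1 `crystal`.
#' @param bins number of bins per axis.
#' @return ag_node of N x width embeddings.
#' @export
absolute_positional <- function(tables, s, bins = 100) {
  if (bins < 2) stop("bins must be >= 2")
  idx <- pmin(floor(s$frac_coords * bins), bins - 1) + 1L
  ag_add(ag_add(ag_gather(tables[[1]], idx[, 1]),
                ag_gather(tables[[2]], idx[, 2])),
         ag_gather(tables[[3]], idx[, 3]))
}
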