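# Independent oracles used by the tests. These deliberately take different
# routes from the package implementation:
#  - cech_persistence(): full Cech filtration (min-enclosing-ball radii over
#    every simplex) reduced in plain R; Cech and alpha-complex filtrations
#    have identical persistence diagrams, so this cross-checks the
#    Delaunay/alpha path on small generic clouds.
#  - classify_op_oracle(): symmetry-operation classification via the
#    (det, trace) lookup plus a fixed-point solvability test, instead of the
#    intrinsic-translation projection used by the package.
#  - rollout_oracle(): literal matrix-product attention rollout.

# ---- minimum enclosing ball -----------------------------------------------

meb2 <- function(p) {
  c(r = sqrt(sum((p[1, ] - p[2, ])^2)) / 2)
}

circumcenter_tri <- function(p) {
  u <- p[2, ] - p[1, ]; v <- p[3, ] - p[1, ]
  uu <- sum(u * u); vv <- sum(v * v); uv <- sum(u * v)
  det <- uu * vv - uv^2
  if (abs(det) < 1e-14) return(NULL)
  s <- (0.5 * uu * vv - 0.5 * vv * uv) / det
  t <- (0.5 * vv * uu - 0.5 * uu * uv) / det
  p[1, ] + s * u + t * v
}

circumcenter_tet <- function(p) {
  m <- 2 * (p[2:4, , drop = FALSE] -
              matrix(p[1, ], 3, 3, byrow = TRUE))
  rhs <- rowSums(p[2:4, , drop = FALSE]^2) - sum(p[1, ]^2)
  ctr <- tryCatch(solve(m, rhs), error = function(e) NULL)
  ctr
}

# min enclosing ball radius of 2..4 points (rows of p)
meb_radius <- function(p) {
  n <- nrow(p)
  if (n == 1) return(0)
  best <- Inf
  contains <- function(ctr, r) all(sqrt(colSums((t(p) - ctr)^2)) <= r + 1e-9)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      ctr <- (p[i, ] + p[j, ]) / 2
      r <- sqrt(sum((p[i, ] - p[j, ])^2)) / 2
      if (contains(ctr, r)) best <- min(best, r)
    }
  }
  if (n >= 3) {
    for (tri in utils::combn(n, 3, simplify = FALSE)) {
      ctr <- circumcenter_tri(p[tri, , drop = FALSE])
      if (is.null(ctr)) next
      r <- sqrt(sum((ctr - p[tri[1], ])^2))
      if (contains(ctr, r)) best <- min(best, r)
    }
  }
  if (n == 4) {
    ctr <- circumcenter_tet(p)
    if (!is.null(ctr)) {
      r <- sqrt(sum((ctr - p[1, ])^2))
      if (contains(ctr, r)) best <- min(best, r)
    }
  }
  best
}

# ---- brute-force Cech persistence -----------------------------------------

cech_persistence <- function(points, min_persistence = 1e-6) {
  points <- as.matrix(points)
  n <- nrow(points)
  stopifnot(n <= 30)
  simp <- list()
  for (d in 0:min(3, n - 1)) {
    for (v in utils::combn(n, d + 1, simplify = FALSE)) {
      simp[[length(simp) + 1L]] <- list(
        v = v, dim = d, filt = meb_radius(points[v, , drop = FALSE]))
    }
  }
  ord <- order(vapply(simp, `[[`, numeric(1), "filt"),
               vapply(simp, `[[`, integer(1), "dim"))
  simp <- simp[ord]
  key <- vapply(simp, function(s) paste(s$v, collapse = ","), character(1))
  pos <- seq_along(simp); names(pos) <- key
  m <- length(simp)
  cols <- vector("list", m)
  for (j in seq_len(m)) {
    s <- simp[[j]]
    if (s$dim == 0) { cols[[j]] <- integer(0); next }
    faces <- utils::combn(s$v, s$dim, simplify = FALSE)
    cols[[j]] <- sort(unname(pos[vapply(faces, paste, character(1),
                                        collapse = ",")]))
  }
  low_of <- integer(m)
  pairs <- list()
  for (j in seq_len(m)) {
    col <- cols[[j]]
    while (length(col)) {
      low <- col[length(col)]
      other <- low_of[low]
      if (other == 0L) break
      col <- sort(c(setdiff(col, cols[[other]]),
                    setdiff(cols[[other]], col)))
    }
    cols[[j]] <- col
    if (length(col)) {
      low_of[col[length(col)]] <- j
      pairs[[length(pairs) + 1L]] <- c(col[length(col)], j)
    }
  }
  out <- list()
  for (dd in 1:2) {
    birth <- numeric(0); pers <- numeric(0)
    for (pr in pairs) {
      sb <- simp[[pr[1]]]; sd <- simp[[pr[2]]]
      if (sb$dim != dd || sd$dim != dd + 1) next
      p <- sd$filt - sb$filt
      if (p > min_persistence) {
        birth <- c(birth, sb$filt); pers <- c(pers, p)
      }
    }
    o <- order(birth, pers)
    out[[paste0("dim", dd)]] <- data.frame(birth = birth[o],
                                           persistence = pers[o])
  }
  out
}

# ---- symmetry operation oracle --------------------------------------------

# has the affine operation a fixed point modulo lattice translations?
has_fixed_point <- function(R, t) {
  A <- R - diag(3)
  for (la in -1:1) for (lb in -1:1) for (lc in -1:1) {
    b <- c(la, lb, lc) - t
    x <- qr.coef(qr(A), b)
    x[is.na(x)] <- 0
    if (max(abs(A %*% x - b)) < 1e-8) return(TRUE)
  }
  FALSE
}

classify_op_oracle <- function(op) {
  R <- op$R; t <- op$t
  dt <- round(det(R)); tr <- round(sum(diag(R)))
  if (dt == 1) {
    if (tr == 3) {
      if (all(abs(t - round(t)) < 1e-8)) "identity" else "translation"
    } else {
      if (has_fixed_point(R, t)) "rotation" else "screw"
    }
  } else {
    if (tr == -3) "inversion"
    else if (tr == 1) { if (has_fixed_point(R, t)) "mirror" else "glide" }
    else "rotoinversion"           # traces 0 (-3), -1 (-4), -2 (-6)
  }
}

symmetry_elements_oracle <- function(number) {
  kinds <- vapply(sg_operations(number), classify_op_oracle, character(1))
  bits <- c(no_element = 0L,
            inversion = as.integer("inversion" %in% kinds),
            mirror = as.integer("mirror" %in% kinds),
            rotation = as.integer("rotation" %in% kinds),
            screw = as.integer("screw" %in% kinds),
            rotoinversion = as.integer("rotoinversion" %in% kinds),
            glide = as.integer("glide" %in% kinds))
  if (sum(bits) == 0L) bits["no_element"] <- 1L
  bits
}

# ---- attention rollout oracle ---------------------------------------------

rollout_oracle <- function(attentions, residual_alpha = 0.5) {
  t_len <- nrow(attentions[[1]][[1]])
  mats <- lapply(attentions, function(layer) {
    a <- Reduce("+", layer) / length(layer)
    a <- residual_alpha * diag(t_len) + (1 - residual_alpha) * a
    sweep(a, 1, rowSums(a), "/")
  })
  prod <- diag(t_len)
  for (a in mats) prod <- a %*% prod
  prod[1, ]
}

# ---- misc helpers ----------------------------------------------------------

random_stochastic <- function(t_len) {
  a <- matrix(stats::runif(t_len * t_len), t_len)
  sweep(a, 1, rowSums(a), "/")
}

tiny_config <- function(...) {
  model_config(L = 2L, H = 32L, A = 4L, H_graph = 32L, use_images = FALSE,
               ...)
}

fd_gradient_check <- function(build, params, n_per_param = 4, eps = 1e-5) {
  ag_reset()
  loss <- build()
  ag_backward(loss)
  grads <- lapply(params, function(p) p$grad)
  maxerr <- 0
  for (pi in seq_along(params)) {
    p <- params[[pi]]
    idx <- sample(length(p$val), min(n_per_param, length(p$val)))
    for (k in idx) {
      v0 <- p$val[k]
      p$val[k] <- v0 + eps; ag_reset(); lp <- build()$val[1, 1]
      p$val[k] <- v0 - eps; ag_reset(); lm <- build()$val[1, 1]
      p$val[k] <- v0
      maxerr <- max(maxerr, abs((lp - lm) / (2 * eps) - grads[[pi]][k]))
    }
    p$grad <- NULL
  }
  maxerr
}
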