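# Persistent homology featurization: supercell point cloud -> alpha-complex
# filtration -> 1-D (channels) and 2-D (voids) persistence diagrams ->
# per-image-scaled 50x50 persistence images with max-persistence / max-birth
# scalars -> 5x5 patches for the token sequence.

#' Cartesian point cloud of a replicated supercell
#'
#' Replicates the cell until every supercell edge has perpendicular width at
#' least `min_extent`, so that topological features up to that scale are
#' captured by the finite filtration. Point ordering is deterministic:
#' replica-major, original atom order within each replica, so supercell point
#' index `p` folds back to atom `p %% N`.
#'
#' @param s a P1 `crystal`.
#' @param min_extent minimum supercell extent in Angstrom.
#' @return list with `points` (Mx3 Cartesian matrix), `rep` (replications) and
#'   `n_cell` (atoms per original cell).
#' @export
periodic_point_cloud <- function(s, min_extent = 20) {
  w <- perp_widths(s$lattice)
  if (any(!is.finite(w)) || any(w <= 1e-6)) stop("degenerate cell")
  rep <- pmax(1L, as.integer(ceiling(min_extent / w)))
  n <- n_atoms(s)
  offs <- as.matrix(expand.grid(a = 0:(rep[1] - 1), b = 0:(rep[2] - 1),
                                c = 0:(rep[3] - 1)))
  pts <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k) {
    (s$frac_coords + matrix(as.numeric(offs[k, ]), n, 3,
                            byrow = TRUE)) %*% s$lattice
  }))
  list(points = pts, rep = rep, n_cell = n)
}

#' Persistence diagrams of a point cloud (alpha-complex filtration)
#'
#' Computes 1- and 2-dimensional persistence diagrams of the growing-ball
#' filtration in radius units (Angstrom). Infinite-persistence features are
#' dropped. A tiny deterministic jitter (`1e-7` Angstrom) breaks the exact
#' cospherical degeneracies of crystalline point sets before triangulation.
#'
#' @param points Mx3 Cartesian coordinate matrix, or the list returned by
#'   [periodic_point_cloud()].
#' @param with_cycles record a representative cycle per diagram point.
#' @param min_persistence drop features with persistence below this value.
#' @param max_death drop features dying above this radius; a finite cloud
#'   cannot distinguish features at the scale of its own extent from
#'   open-boundary effects, so [persistence_features()] bounds deaths at half
#'   the supercell's minimum perpendicular width.
#' @param jitter symbolic-perturbation scale in Angstrom (0 disables).
#'   Effectively planar or collinear clouds are automatically jittered at
#'   `1e-3` Angstrom, since their sliver tetrahedra defeat double-precision
#'   predicates at smaller scales.
#' @return list of two data frames (`dim1`, `dim2`) with columns `birth`,
#'   `persistence`, plus a `cycles` list attribute when requested; class
#'   `persistence_diagrams`.
#' @export
persistence_diagrams <- function(points, with_cycles = FALSE,
                                 min_persistence = 1e-6, max_death = Inf,
                                 jitter = 1e-7) {
  cloud <- NULL
  if (is.list(points) && !is.null(points$points)) {
    cloud <- points
    points <- points$points
  }
  points <- as.matrix(points)
  if (nrow(points) < 1) stop("point cloud must contain at least one point")
  if (nrow(points) >= 4 && jitter > 0) {
    ctr <- sweep(points, 2, colMeans(points))
    thickness <- sqrt(min(svd(ctr, nu = 0, nv = 0)$d)^2 / nrow(points))
    if (thickness < 1e-3) jitter <- max(jitter, 1e-3)
  }
  raw <- if (nrow(points) < 2) {
    list(dim1 = list(birth = numeric(0), death = numeric(0), cycles = list()),
         dim2 = list(birth = numeric(0), death = numeric(0), cycles = list()))
  } else {
    # escalate the symbolic jitter if an exactly degenerate configuration
    # still defeats the floating-point predicates
    res <- NULL
    jit <- jitter
    for (attempt in 1:3) {
      p <- points
      if (jit > 0 && nrow(points) >= 4) {
        p <- p + with_seed(20231115 + attempt,
          matrix(stats::runif(length(p), -jit, jit), nrow(p), 3))
      }
      res <- tryCatch(cpp_alpha_persistence(p, with_cycles, min_persistence),
                      error = function(e) NULL)
      if (!is.null(res)) break
      jit <- max(jit, 1e-7) * 100
    }
    if (is.null(res)) stop("persistent degeneracy in the alpha filtration; ",
                           "increase the jitter")
    res
  }
  mk <- function(d, dim) {
    df <- data.frame(birth = d$birth, persistence = d$death - d$birth)
    keep <- d$death <= max_death
    df <- df[keep, , drop = FALSE]
    rownames(df) <- NULL
    attr(df, "homology_dim") <- dim
    attr(df, "birth_simplex") <- lapply(d$birth_simplex[keep], as.integer)
    if (with_cycles) attr(df, "cycles") <- lapply(d$cycles[keep], as.integer)
    df
  }
  structure(list(dim1 = mk(raw$dim1, 1L), dim2 = mk(raw$dim2, 2L),
                 n_points = nrow(points),
                 n_cell = if (is.null(cloud)) nrow(points) else cloud$n_cell),
            class = "persistence_diagrams")
}

#' @export
print.persistence_diagrams <- function(x, ...) {
  cat(sprintf("<persistence_diagrams> %d points; H1: %d features, H2: %d\n",
              x$n_points, nrow(x$dim1), nrow(x$dim2)))
  invisible(x)
}

#' Rasterize a persistence diagram into a per-image-scaled persistence image
#'
#' Each diagram point (birth, persistence) is scaled by the diagram's own
#' maxima onto the unit square and rasterized as an isotropic Gaussian of
#' standard deviation `spread` (in scaled units) with unit mass, accumulated
#' on a `resolution` x `resolution` grid. The per-image maxima are returned
#' alongside and become the two scale tokens of the image.
#'
#' @param diagram one component (`dim1`/`dim2`) of [persistence_diagrams()].
#' @param resolution grid side length.
#' @param spread Gaussian standard deviation in scaled units.
#' @return list with `image` (resolution x resolution matrix),
#'   `max_persistence`, `max_birth`.
#' @export
persistence_image <- function(diagram, resolution = 50, spread = 0.15) {
  if (resolution < 1) stop("resolution must be >= 1")
  img <- matrix(0, resolution, resolution)
  if (nrow(diagram) == 0) {
    return(list(image = img, max_persistence = 0, max_birth = 0))
  }
  mb <- max(diagram$birth)
  mp <- max(diagram$persistence)
  bx <- if (mb > 0) diagram$birth / mb else rep(0, nrow(diagram))
  py <- if (mp > 0) diagram$persistence / mp else rep(0, nrow(diagram))
  centers <- (seq_len(resolution) - 0.5) / resolution
  width <- 1 / resolution
  for (k in seq_len(nrow(diagram))) {
    # separable Gaussian integrated per pixel via the error function
    gx <- stats::pnorm((centers + width / 2 - bx[k]) / spread) -
      stats::pnorm((centers - width / 2 - bx[k]) / spread)
    gy <- stats::pnorm((centers + width / 2 - py[k]) / spread) -
      stats::pnorm((centers - width / 2 - py[k]) / spread)
    img <- img + outer(gx, gy)   # rows: birth axis, cols: persistence axis
  }
  list(image = img, max_persistence = mp, max_birth = mb)
}

#' Full persistence-image feature set of a structure
#'
#' @param s a P1 `crystal`.
#' @param min_extent supercell extent for [periodic_point_cloud()].
#' @param resolution image side length.
#' @param spread Gaussian spread in scaled units.
#' @param with_cycles record representative cycles.
#' @return object of class `persistence_features`: diagrams plus the 1-D and
#'   2-D images and their scale scalars.
#' @export
persistence_features <- function(s, min_extent = 20, resolution = 50,
                                 spread = 0.15, with_cycles = FALSE) {
  cloud <- periodic_point_cloud(s, min_extent)
  super_lat <- diag(cloud$rep) %*% s$lattice
  dg <- persistence_diagrams(cloud, with_cycles = with_cycles)
  # finite-size correction: a feature is only trusted when its birth simplex
  # is at least the feature's death radius away from the open supercell
  # boundary, so truncation of the periodic structure cannot have created or
  # distorted it. Bulk features recur in every replica, so an interior copy
  # survives the filter; open-boundary loops are born at the surface and are
  # removed.
  fsup <- cloud$points %*% solve(super_lat)
  w <- perp_widths(super_lat)
  margin <- apply(pmin(fsup, 1 - fsup) %*% diag(w), 1, min)
  keep_interior <- function(df) {
    if (nrow(df) == 0) return(df)
    bs <- attr(df, "birth_simplex")
    cyc <- attr(df, "cycles")
    ok <- vapply(seq_len(nrow(df)), function(k) {
      min(margin[bs[[k]] + 1L]) >= df$birth[k] + df$persistence[k]
    }, logical(1))
    out <- df[ok, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "homology_dim") <- attr(df, "homology_dim")
    attr(out, "birth_simplex") <- bs[ok]
    if (with_cycles) attr(out, "cycles") <- cyc[ok]
    out
  }
  dg$dim1 <- keep_interior(dg$dim1)
  dg$dim2 <- keep_interior(dg$dim2)
  i1 <- persistence_image(dg$dim1, resolution, spread)
  i2 <- persistence_image(dg$dim2, resolution, spread)
  structure(list(
    diagrams = dg,
    image_1d = i1$image, image_2d = i2$image,
    max_persistence_1d = i1$max_persistence, max_birth_1d = i1$max_birth,
    max_persistence_2d = i2$max_persistence, max_birth_2d = i2$max_birth,
    resolution = resolution, spread = spread, min_extent = min_extent,
    structure_id = s$structure_id
  ), class = "persistence_features")
}

#' Split an image into non-overlapping square patches
#'
#' Row-major patch order; each patch flattened row-major, so
#' [unpatchify()] reassembles the image exactly.
#'
#' @param img RxR matrix.
#' @param patch patch side length P; must divide R.
#' @return (R/P)^2 x P^2 matrix, one flattened patch per row.
#' @export
patchify <- function(img, patch = 5) {
  r <- nrow(img)
  if (ncol(img) != r) stop("image must be square")
  if (r %% patch != 0) stop("patch size must divide the image resolution")
  g <- r / patch
  out <- matrix(0, g * g, patch * patch)
  idx <- 1
  for (pi in seq_len(g)) {
    for (pj in seq_len(g)) {
      block <- img[((pi - 1) * patch + 1):(pi * patch),
                   ((pj - 1) * patch + 1):(pj * patch)]
      out[idx, ] <- as.numeric(t(block))   # row-major flatten
      idx <- idx + 1
    }
  }
  out
}

#' Reassemble an image from its patches
#'
#' @param patches matrix produced by [patchify()].
#' @param resolution image side length R.
#' @return RxR matrix.
#' @export
unpatchify <- function(patches, resolution) {
  patch <- as.integer(sqrt(ncol(patches)))
  g <- resolution / patch
  img <- matrix(0, resolution, resolution)
  idx <- 1
  for (pi in seq_len(g)) {
    for (pj in seq_len(g)) {
      img[((pi - 1) * patch + 1):(pi * patch),
          ((pj - 1) * patch + 1):(pj * patch)] <-
        matrix(patches[idx, ], patch, patch, byrow = TRUE)
      idx <- idx + 1
    }
  }
  img
}

#' Map a diagram point's representative cycle back to original-cell atoms
#'
#' Supercell point indices are folded modulo the replica size, recovering the
#' atom indices (0-based) of the original cell that carry the topological
#' feature.
#'
#' @param diagram a `dim1`/`dim2` component computed with
#'   `with_cycles = TRUE`.
#' @param point_index row index of the diagram point (1-based).
#' @param n_cell atoms per original cell (from [periodic_point_cloud()] or
#'   `persistence_diagrams$n_cell`).
#' @return sorted unique 0-based atom indices.
#' @export
map_cycle_to_atoms <- function(diagram, point_index, n_cell) {
  cyc <- attr(diagram, "cycles")
  if (is.null(cyc)) stop("diagram was computed without representative cycles")
  if (nrow(diagram) == 0) stop("empty diagram has no cycles")
  if (point_index < 1 || point_index > nrow(diagram)) {
    stop("point_index out of range")
  }
  sort(unique(cyc[[point_index]] %% n_cell))
}
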