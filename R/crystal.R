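# CrystalStructure: periodic cell + atoms. Lattice is stored row-wise (each
# row a cell vector, Angstrom); coordinates are fractional, wrapped to [0,1);
# atom indexing is 0-based in all user-facing id columns to match the token
# maps used downstream.

#' Construct a crystal structure
#'
#' @param lattice 3x3 numeric matrix, cell vectors as rows (Angstrom).
#' @param frac_coords Nx3 matrix of fractional coordinates (wrapped to `[0,1)`).
#' @param elements character vector of N element symbols.
#' @param space_group integer space-group number (1-230) of the setting the
#'   coordinates are expressed in.
#' @param molecule_ids optional integer vector of N molecule labels
#'   (0-based; -1 = unassigned).
#' @param structure_id opaque identifier string.
#' @return an object of class `crystal`.
#' @export
crystal <- function(lattice, frac_coords, elements, space_group = 1L,
                    molecule_ids = NULL, structure_id = "crystal") {
  lattice <- matrix(as.numeric(lattice), 3, 3)
  frac_coords <- matrix(as.numeric(frac_coords), ncol = 3)
  n <- nrow(frac_coords)
  if (length(elements) != n) stop("elements length must match atom count")
  if (n == 0) stop("structure must contain at least one atom")
  vol <- det(lattice)
  if (!is.finite(vol) || abs(vol) < 1e-8) stop("degenerate cell: volume ~ 0")
  if (vol < 0) stop("left-handed cell: cell vectors must be right-handed")
  atomic_mass(elements)  # validates symbols
  if (is.null(molecule_ids)) molecule_ids <- rep(-1L, n)
  if (length(molecule_ids) != n) stop("molecule_ids length must match atom count")
  space_group <- as.integer(space_group)
  if (is.na(space_group) || space_group < 1L || space_group > 230L) {
    stop("space_group must be an integer in 1..230")
  }
  structure(list(
    lattice = lattice,
    frac_coords = wrap_frac(frac_coords),
    elements = as.character(elements),
    molecule_ids = as.integer(molecule_ids),
    space_group = space_group,
    structure_id = as.character(structure_id)
  ), class = "crystal")
}

#' @export
print.crystal <- function(x, ...) {
  cat(sprintf("<crystal '%s'>  %d atoms, space group %d\n",
              x$structure_id, nrow(x$frac_coords), x$space_group))
  cat(sprintf("  cell: a=%.3f b=%.3f c=%.3f A, volume %.2f A^3\n",
              sqrt(sum(x$lattice[1, ]^2)), sqrt(sum(x$lattice[2, ]^2)),
              sqrt(sum(x$lattice[3, ]^2)), cell_volume(x)))
  nmol <- length(unique(x$molecule_ids[x$molecule_ids >= 0]))
  cat(sprintf("  elements: %s; molecules assigned: %s\n",
              paste(sort(unique(x$elements)), collapse = " "),
              if (all(x$molecule_ids >= 0)) nmol else "no"))
  invisible(x)
}

#' Number of atoms in a structure
#' @param s a `crystal`.
#' @export
n_atoms <- function(s) nrow(s$frac_coords)

#' Cell volume in cubic Angstrom
#' @param s a `crystal`.
#' @export
cell_volume <- function(s) abs(det(s$lattice))

#' Wrap fractional coordinates into `[0, 1)`
#'
#' @param x numeric matrix or vector of fractional coordinates.
#' @export
wrap_frac <- function(x) {
  w <- x - floor(x)
  # guard against 0.9999999999 -> 1.0 after floating error
  w[w >= 1 - 1e-12] <- 0
  w
}

#' Cartesian coordinates of all atoms
#' @param s a `crystal`.
#' @return Nx3 matrix in Angstrom.
#' @export
cart_coords <- function(s) s$frac_coords %*% s$lattice

# Perpendicular widths of the cell along the three lattice directions:
# w_i = V / area(face spanned by the other two vectors). Used both for
# supercell extent decisions and for picking periodic image search ranges.
perp_widths <- function(lattice) {
  v <- abs(det(lattice))
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  c(v / sqrt(sum(cr(lattice[2, ], lattice[3, ])^2)),
    v / sqrt(sum(cr(lattice[3, ], lattice[1, ])^2)),
    v / sqrt(sum(cr(lattice[1, ], lattice[2, ])^2)))
}

# Periodic minimum-image distance matrix between fractional coordinate sets.
# Searches images in a +-shell range wide enough for cells whose perpendicular
# widths may be small relative to the distances of interest.
min_image_dist <- function(lattice, fa, fb = fa, shell = 1L) {
  offs <- as.matrix(expand.grid(a = -shell:shell, b = -shell:shell,
                                c = -shell:shell))
  na <- nrow(fa); nb <- nrow(fb)
  best <- matrix(Inf, na, nb)
  for (k in seq_len(nrow(offs))) {
    shift <- matrix(offs[k, ], nb, 3, byrow = TRUE)
    cb <- (fb + shift) %*% lattice
    ca <- fa %*% lattice
    d2 <- outer(rowSums(ca^2), rowSums(cb^2), "+") - 2 * ca %*% t(cb)
    best <- pmin(best, d2)
  }
  sqrt(pmax(best, 0))
}

#' Mass density of a crystal
#'
#' Total atomic mass over cell volume.
#'
#' @param s a `crystal`.
#' @return density in g per cubic centimetre.
#' @export
density <- function(s) {
  UseMethod("density")
}

#' @export
density.crystal <- function(s) {
  if (s$space_group != 1L) s <- to_p1(s)   # count all symmetry copies
  amu_g <- 1.66053906892e-24       # unified atomic mass unit in grams
  mass_g <- sum(atomic_mass(s$elements)) * amu_g
  vol_cm3 <- cell_volume(s) * 1e-24
  mass_g / vol_cm3
}

#' @export
density.default <- function(s) stats::density(s)

#' Randomly perturb atomic positions
#'
#' Adds i.i.d. Gaussian displacements (standard deviation `sigma`, Angstrom)
#' to the Cartesian coordinates and rewraps. Used to generate the relative
#' positional embeddings, which are refreshed every epoch.
#'
#' @param s a `crystal`.
#' @param sigma displacement standard deviation in Angstrom (per Cartesian
#'   component).
#' @param seed integer seed; the same seed reproduces the same displacement.
#' @return a perturbed `crystal`.
#' @export
perturb <- function(s, sigma, seed) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(s)
  n <- n_atoms(s)
  disp <- with_seed(seed, matrix(stats::rnorm(3 * n, sd = sigma), n, 3))
  cart <- cart_coords(s) + disp
  s$frac_coords <- wrap_frac(cart %*% solve(s$lattice))
  s
}

# Run expr with a temporary RNG state seeded by `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Build a supercell
#'
#' @param s a `crystal`.
#' @param rep integer vector of length 3, replication along each cell vector.
#' @return a `crystal` with `prod(rep)` times as many atoms.
#' @export
supercell <- function(s, rep) {
  rep <- as.integer(rep)
  if (length(rep) != 3 || any(rep < 1)) stop("rep must be 3 positive integers")
  offs <- as.matrix(expand.grid(a = 0:(rep[1] - 1), b = 0:(rep[2] - 1),
                                c = 0:(rep[3] - 1)))
  # ordering: cell offsets vary fastest over a, then b, then c; atoms within
  # each image keep their original order (deterministic fold-back: replica r,
  # atom i sits at row (r-1)*N + i)
  n <- n_atoms(s)
  fc <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k) {
    sweep(s$frac_coords, 2, as.numeric(offs[k, ]), "+")
  }))
  fc <- fc %*% diag(1 / rep)
  lat <- diag(rep) %*% s$lattice
  crystal(lat, fc, rep(s$elements, nrow(offs)), space_group = 1L,
          molecule_ids = rep(s$molecule_ids, nrow(offs)),
          structure_id = s$structure_id)
}

#' Expand a structure to the P1 setting
#'
#' Applies all symmetry operations of the structure's space group to make
#' every symmetry-equivalent atom explicit. Duplicate images (special
#' positions) are merged.
#'
#' @param s a `crystal` whose `space_group` field names its setting.
#' @param tol fractional-coordinate tolerance for merging duplicate images.
#' @return a `crystal` with `space_group = 1`.
#' @export
to_p1 <- function(s, tol = 1e-4) {
  if (s$space_group == 1L) return(s)
  ops <- sg_operations(s$space_group)
  fc <- s$frac_coords
  out_fc <- NULL
  out_el <- character(0)
  for (op in ops) {
    img <- wrap_frac(fc %*% t(op$R) + matrix(op$t, nrow(fc), 3, byrow = TRUE))
    if (is.null(out_fc)) {
      out_fc <- img
      out_el <- s$elements
    } else {
      for (i in seq_len(nrow(img))) {
        d <- abs(out_fc - matrix(img[i, ], nrow(out_fc), 3, byrow = TRUE))
        d <- pmin(d, 1 - d)          # periodic fractional difference
        if (!any(rowSums(d) < 3 * tol)) {
          out_fc <- rbind(out_fc, img[i, ])
          out_el <- c(out_el, s$elements[i])
        }
      }
    }
  }
  crystal(s$lattice, out_fc, out_el, space_group = 1L,
          structure_id = s$structure_id)
}

#' Assign molecule labels by periodic bond-graph components
#'
#' Two atoms are bonded when their minimum-image distance does not exceed
#' `radius_scale` times the sum of their covalent radii. Connected components
#' of that periodic graph are the molecules, labelled 0..M-1 in order of the
#' lowest atom index they contain.
#'
#' @param s a `crystal` in P1.
#' @param radius_scale bond-detection scale factor on covalent radii.
#' @return the `crystal` with `molecule_ids` set.
#' @export
assign_molecules <- function(s, radius_scale = 1.2) {
  n <- n_atoms(s)
  rad <- covalent_radius(s$elements)
  maxbond <- radius_scale * (2 * max(rad)) + 1e-9
  shell <- max(1L, ceiling(maxbond / min(perp_widths(s$lattice))))
  d <- min_image_dist(s$lattice, s$frac_coords, shell = shell)
  cutoff <- radius_scale * outer(rad, rad, "+")
  adj <- d <= cutoff
  diag(adj) <- FALSE
  # connected components, BFS
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
    cur <- cur + 1L
  }
  s$molecule_ids <- comp
  s
}

#' Check which operations of a space group leave a structure invariant
#'
#' Verification-style symmetry detection for P1-expanded structures: an
#' operation holds when it maps the atom set onto itself (element-preserving
#' permutation within `tol`, allowing an arbitrary origin shift along the
#' operation image). Used in tests to confirm that P1 expansion preserved the
#' generating group.
#'
#' @param s a `crystal` (typically P1-expanded).
#' @param space_group candidate space-group number.
#' @param tol fractional tolerance.
#' @return logical vector, one entry per operation of the group.
#' @export
symmetry_holds <- function(s, space_group, tol = 1e-3) {
  ops <- sg_operations(space_group)
  fc <- s$frac_coords
  vapply(ops, function(op) {
    img <- wrap_frac(fc %*% t(op$R) + matrix(op$t, nrow(fc), 3, byrow = TRUE))
    ok <- TRUE
    for (i in seq_len(nrow(img))) {
      d <- abs(fc - matrix(img[i, ], nrow(fc), 3, byrow = TRUE))
      d <- pmin(d, 1 - d)
      hit <- which(rowSums(d) < 3 * tol & s$elements == s$elements[i])
      if (!length(hit)) { ok <- FALSE; break }
    }
    ok
  }, logical(1))
}
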