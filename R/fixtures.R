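# Synthetic molecular-crystal fixtures with known ground truth. A rigid
# molecular template is placed at a general position of a chosen space group
# (restricted to 1, 2, 4, 19: the no-element, inversion-only and screw-only
# label classes), expanded to P1, and optionally jittered. Density, symmetry
# label, molecule membership and engineered pore radii are all known by
# construction.

.templates <- list(
  # diatomic N2, bond 1.10 A
  diatomic = list(elements = c("N", "N"),
                  xyz = rbind(c(-0.55, 0, 0), c(0.55, 0, 0))),
  # bent triatomic, water-like: O-H 0.96 A, angle 104.5 deg
  triatomic = list(elements = c("O", "H", "H"),
                   xyz = rbind(c(0, 0, 0),
                               c(0.96, 0, 0),
                               c(0.96 * cos(104.5 * pi / 180),
                                 0.96 * sin(104.5 * pi / 180), 0))),
  # planar C6 ring, C-C 1.40 A
  ring6 = local({
    th <- 2 * pi * (0:5) / 6
    list(elements = rep("C", 6), xyz = cbind(1.40 * cos(th), 1.40 * sin(th), 0))
  }),
  # planar C12 "pore ring"; radius set at build time (default 2.5 A)
  ring12 = local({
    th <- 2 * pi * (0:11) / 12
    list(elements = rep("C", 12), xyz = cbind(2.5 * cos(th), 2.5 * sin(th), 0),
         scalable = TRUE)
  })
)

#' Available fixture molecule templates
#' @return character vector of template names.
#' @export
fixture_templates <- function() names(.templates)

template_xyz <- function(template, ring_radius = NULL) {
  tp <- .templates[[template]]
  if (is.null(tp)) stop("unknown template: ", template)
  xyz <- tp$xyz
  if (!is.null(ring_radius)) {
    if (is.null(tp$scalable)) stop("template has a fixed geometry: ", template)
    xyz <- xyz * (ring_radius / 2.5)
  }
  list(elements = tp$elements, xyz = xyz)
}

rotation_matrix <- function(angles) {
  cz <- cos(angles[1]); sz <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cx <- cos(angles[3]); sx <- sin(angles[3])
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Rz %*% Ry %*% Rx
}

.fixture_groups <- c(1L, 2L, 4L, 19L)

#' Generate one synthetic molecular crystal
#'
#' Places a rigid molecular template at a general position of the requested
#' space group, expands to P1, assigns molecules and applies a small Gaussian
#' jitter. Ground-truth labels (density, symmetry-element label, molecule
#' count) are returned alongside.
#'
#' @param space_group one of 1, 2, 4, 19.
#' @param template template name from [fixture_templates()].
#' @param cell length-3 cell edge lengths in Angstrom (orthogonal cell); if
#'   `NULL`, sized from the template with a seeded random margin.
#' @param jitter_sigma Gaussian jitter (Angstrom) applied after expansion.
#' @param seed integer seed controlling placement, orientation and jitter.
#' @param ring_radius ring radius for the scalable `ring12` template.
#' @param structure_id identifier; default derived from the seed.
#' @param min_contact minimum allowed intermolecular contact (Angstrom).
#' @return list with `asym` (asymmetric-unit `crystal` carrying the space
#'   group), `p1` (expanded, jittered, molecule-labelled `crystal`) and
#'   `truth` (one-row data frame of ground-truth labels).
#' @export
make_crystal <- function(space_group = 4L, template = "triatomic",
                         cell = NULL, jitter_sigma = 0.05, seed = 1L,
                         ring_radius = NULL, structure_id = NULL,
                         min_contact = 0.8) {
  space_group <- as.integer(space_group)
  if (!space_group %in% .fixture_groups) {
    stop("fixture space_group must be one of ", paste(.fixture_groups,
                                                      collapse = ", "))
  }
  tp <- template_xyz(template, ring_radius)
  mult <- length(sg_operations(space_group))
  if (is.null(structure_id)) {
    structure_id <- sprintf("fx_sg%d_%s_s%d", space_group, template, seed)
  }
  rmol <- max(sqrt(rowSums(tp$xyz^2)))
  res <- with_seed(seed, {
    # cell sized so symmetry images cannot collide: per-axis room for the
    # molecule plus a random packing margin (drives density variation)
    margin <- stats::runif(3, 1.6, 3.2)
    base <- 2 * rmol + 2.4
    # cell shape follows the packing the symmetry imposes: P2_1 stacks its
    # two molecules along the screw axis b; P-1 packs two molecules around
    # the inversion centre (isotropic volume doubling); P2_12_12_1 has three
    # orthogonal screws and four molecules (volume x4)
    shape <- switch(as.character(space_group),
                    "1" = c(1, 1, 1),
                    "2" = rep(2^(1 / 3), 3),
                    "4" = c(1.05, 2, 1.05),
                    "19" = rep(4^(1 / 3), 3))
    cell_len <- if (is.null(cell)) {
      (base + margin) * shape
    } else as.numeric(cell)
    ang <- stats::runif(3, 0, 2 * pi)
    centre <- c(stats::runif(1, 0.18, 0.32), stats::runif(1, 0.18, 0.32),
                stats::runif(1, 0.18, 0.32))
    list(cell_len = cell_len, ang = ang, centre = centre,
         jit_seed = sample.int(1e6, 1))
  })
  lat <- diag(res$cell_len)
  xyz <- tp$xyz %*% t(rotation_matrix(res$ang))
  fc <- xyz %*% solve(lat) + matrix(res$centre, nrow(xyz), 3, byrow = TRUE)
  asym <- crystal(lat, fc, tp$elements, space_group = space_group,
                  structure_id = structure_id)
  p1 <- to_p1(asym)
  if (n_atoms(p1) != mult * nrow(xyz)) {
    stop("fixture molecule landed on a special position; retry with a ",
         "different seed")
  }
  p1 <- assign_molecules(p1)
  # intermolecular contact check
  if (mult > 1 || TRUE) {
    d <- min_image_dist(p1$lattice, p1$frac_coords)
    inter <- outer(p1$molecule_ids, p1$molecule_ids, "!=")
    mind <- suppressWarnings(min(d[inter]))
    if (is.finite(mind) && mind < min_contact) {
      stop(sprintf("fixture has intermolecular contact %.2f A < %.2f A; ",
                   mind, min_contact), "retry with a different seed")
    }
  }
  if (jitter_sigma > 0) p1 <- perturb(p1, jitter_sigma, res$jit_seed)
  bits <- unclass(symmetry_elements(space_group))
  truth <- data.frame(
    structure_id = structure_id, space_group = space_group,
    template = template, n_atoms = n_atoms(p1),
    n_molecules = mult, density = density(p1),
    t(bits), stringsAsFactors = FALSE
  )
  list(asym = asym, p1 = p1, truth = truth)
}

#' Generate a series of channel (pore) crystals with engineered radii
#'
#' Stacks 12-membered rings coaxially along c so each structure carries a 1-D
#' channel whose radius equals the ring radius by construction. Tubes are
#' close-packed on a hexagonal lattice with a tight wall gap, so the
#' engineered channel is the dominant pore: every other void (interstitial
#' prisms, windows between stacked rings) fills at much smaller radii.
#'
#' @param radii channel radii in Angstrom (each `>= 1.5`).
#' @param seed integer seed for the jitter.
#' @param wall wall separation between neighbouring tubes (Angstrom).
#' @param stack ring stacking distance along the channel (Angstrom).
#' @param jitter_sigma Gaussian jitter in Angstrom.
#' @return list of `crystal` objects with a `channel_radius` attribute each.
#' @export
make_pore_series <- function(radii, seed = 1L, wall = 2.5, stack = 3.4,
                             jitter_sigma = 0.01) {
  if (any(radii < 1.5)) stop("channel radii must be >= 1.5 A")
  lapply(seq_along(radii), function(k) {
    r <- radii[k]
    tp <- template_xyz("ring12", ring_radius = r)
    a <- 2 * r + wall
    lat <- rbind(c(a, 0, 0),
                 c(-a / 2, a * sqrt(3) / 2, 0),
                 c(0, 0, stack))
    fc <- sweep(tp$xyz %*% solve(lat), 2, c(0.5, 0.5, 0.5), "+")
    s <- crystal(lat, fc, tp$elements, space_group = 1L,
                 structure_id = sprintf("pore_r%.2f", r))
    if (jitter_sigma > 0) s <- perturb(s, jitter_sigma, seed + k)
    s <- assign_molecules(s)
    attr(s, "channel_radius") <- r
    s
  })
}

fixture_target <- function(p1, template, target, ring_radius = NULL) {
  switch(target,
    density = density(p1),
    channel_radius = if (is.null(ring_radius)) NA_real_ else ring_radius,
    contact_count = {
      d <- min_image_dist(p1$lattice, p1$frac_coords)
      inter <- outer(p1$molecule_ids, p1$molecule_ids, "!=")
      sum(d < 3.5 & inter) / 2
    },
    stop("unknown synthetic target: ", target)
  )
}

#' Generate a fixture dataset: structures, property table and manifest
#'
#' Draws `n` fixtures over the allowed space groups and templates, computes a
#' deterministic synthetic target per structure, and (optionally) writes CIF
#' files plus a property CSV with family tags (family = molecule template,
#' which enables the few-shot protocol).
#'
#' @param n number of structures.
#' @param seed master seed; the same seed reproduces the dataset byte for
#'   byte.
#' @param target one of `"density"`, `"contact_count"`.
#' @param templates template names to draw from.
#' @param space_groups space groups to draw from (subset of 1, 2, 4, 19).
#' @param jitter_sigma per-structure Gaussian jitter (Angstrom).
#' @param dir if non-`NULL`, directory to write `structures/*.cif`,
#'   `properties.csv` and `manifest.json` into.
#' @return list with `structures` (list of P1 `crystal`s), `table` (data
#'   frame: structure_id, label, family) and `truth` (row-bound ground truth).
#' @export
make_dataset <- function(n, seed = 1L, target = "density",
                         templates = c("diatomic", "triatomic", "ring6"),
                         space_groups = .fixture_groups,
                         jitter_sigma = 0.05, dir = NULL) {
  if (n < 1) stop("n must be >= 1")
  draws <- with_seed(seed, data.frame(
    sg = sample(space_groups, n, replace = TRUE),
    tpl = sample(templates, n, replace = TRUE),
    sub = sample.int(1e6, n)
  ))
  structures <- vector("list", n)
  asyms <- vector("list", n)
  truths <- vector("list", n)
  labels <- numeric(n)
  for (i in seq_len(n)) {
    fx <- NULL
    sub <- draws$sub[i]
    for (try in 1:20) {    # placement may collide; walk the seed forward
      fx <- tryCatch(
        make_crystal(draws$sg[i], draws$tpl[i], jitter_sigma = jitter_sigma,
                     seed = sub + try - 1,
                     structure_id = sprintf("fx%04d", i)),
        error = function(e) NULL)
      if (!is.null(fx)) break
    }
    if (is.null(fx)) stop("could not place fixture ", i, " without overlaps")
    structures[[i]] <- fx$p1
    asyms[[i]] <- fx$asym
    truths[[i]] <- fx$truth
    labels[i] <- fixture_target(fx$p1, draws$tpl[i], target)
  }
  tab <- data.frame(structure_id = sprintf("fx%04d", seq_len(n)),
                    label = labels, family = draws$tpl,
                    stringsAsFactors = FALSE)
  truth <- do.call(rbind, truths)
  if (!is.null(dir)) {
    dir.create(file.path(dir, "structures"), recursive = TRUE,
               showWarnings = FALSE)
    for (i in seq_len(n)) {
      write_cif(asyms[[i]], file.path(dir, "structures",
                                      paste0(tab$structure_id[i], ".cif")))
    }
    utils::write.csv(tab, file.path(dir, "properties.csv"), row.names = FALSE)
    jsonlite::write_json(list(n = n, seed = seed, target = target,
                              templates = templates,
                              space_groups = space_groups,
                              jitter_sigma = jitter_sigma),
                         file.path(dir, "manifest.json"), auto_unbox = TRUE)
  }
  list(structures = structures, asym = asyms, table = tab, truth = truth)
}
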