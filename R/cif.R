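# Minimal CIF reader/writer for fully ordered small-molecule crystals.
# Supports the tags this package writes plus the common aliases found in
# CSD-style files; anything with partial occupancy or disorder is rejected.

strip_su <- function(x) as.numeric(sub("\\(.*\\)$", "", x))

cif_tokens <- function(line) {
  # split on whitespace, honouring single/double quotes
  out <- character(0)
  rest <- trimws(line)
  while (nzchar(rest)) {
    if (startsWith(rest, "'") || startsWith(rest, "\"")) {
      q <- substr(rest, 1, 1)
      end <- regexpr(paste0(q, "([[:space:]]|$)"), substr(rest, 2, nchar(rest)))
      if (end < 0) stop("unterminated quote in CIF line: ", line)
      out <- c(out, substr(rest, 2, end))
      rest <- trimws(substr(rest, end + 2, nchar(rest)))
    } else {
      sp <- regexpr("[[:space:]]", rest)
      if (sp < 0) { out <- c(out, rest); rest <- "" }
      else {
        out <- c(out, substr(rest, 1, sp - 1))
        rest <- trimws(substr(rest, sp, nchar(rest)))
      }
    }
  }
  out
}

#' Read a crystal structure from a CIF file
#'
#' Parses cell parameters, symmetry (explicit operation list and/or the
#' International Tables number) and fractional atom sites. The structure is
#' returned in the file's setting; symmetry operations present in the file
#' are retained in the `symmetry_ops` attribute. Structures with any site
#' occupancy different from 1 are rejected, mirroring the usual pre-filter
#' against disorder.
#'
#' @param path CIF file path.
#' @return a `crystal`.
#' @export
read_cif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^[[:space:]]*#", lines)]
  fields <- list()
  loops <- list()
  i <- 1
  data_name <- "crystal"
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) { i <- i + 1; next }
    if (startsWith(ln, "data_")) {
      data_name <- sub("^data_", "", ln); i <- i + 1; next
    }
    if (identical(tolower(ln), "loop_")) {
      i <- i + 1
      hdr <- character(0)
      while (i <= length(lines) && startsWith(trimws(lines[i]), "_")) {
        hdr <- c(hdr, cif_tokens(lines[i])[1]); i <- i + 1
      }
      rows <- list()
      while (i <= length(lines)) {
        ln2 <- trimws(lines[i])
        if (!nzchar(ln2) || startsWith(ln2, "_") || startsWith(ln2, "loop_") ||
            startsWith(ln2, "data_")) break
        toks <- cif_tokens(ln2)
        if (length(toks) != length(hdr)) {
          stop("CIF loop row does not match header (tag ", hdr[1], "): ", ln2)
        }
        rows[[length(rows) + 1L]] <- toks
        i <- i + 1
      }
      df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
      names(df) <- tolower(hdr)
      loops[[length(loops) + 1L]] <- df
      next
    }
    if (startsWith(ln, "_")) {
      toks <- cif_tokens(ln)
      if (length(toks) < 2) stop("CIF tag without value: ", toks[1])
      fields[[tolower(toks[1])]] <- paste(toks[-1], collapse = " ")
      i <- i + 1
      next
    }
    i <- i + 1
  }
  need <- function(tag) {
    v <- fields[[tag]]
    if (is.null(v)) stop("CIF missing required tag: ", tag)
    v
  }
  a <- strip_su(need("_cell_length_a"))
  b <- strip_su(need("_cell_length_b"))
  cc <- strip_su(need("_cell_length_c"))
  al <- strip_su(need("_cell_angle_alpha")) * pi / 180
  be <- strip_su(need("_cell_angle_beta")) * pi / 180
  ga <- strip_su(need("_cell_angle_gamma")) * pi / 180
  lattice <- lattice_from_params(a, b, cc, al, be, ga)

  site_loop <- NULL
  sym_loop <- NULL
  for (df in loops) {
    if (any(grepl("_atom_site_fract_x", names(df)))) site_loop <- df
    if (any(grepl("equiv_pos_as_xyz", names(df)))) sym_loop <- df
  }
  if (is.null(site_loop)) stop("CIF missing required tag: _atom_site_fract_x")
  getcol <- function(df, pat) {
    j <- grep(pat, names(df))
    if (!length(j)) NULL else df[[j[1]]]
  }
  occ <- getcol(site_loop, "occupancy")
  if (!is.null(occ) && any(abs(strip_su(occ) - 1) > 1e-6)) {
    stop("structure rejected: site occupancy != 1 (disorder is not supported)")
  }
  el <- getcol(site_loop, "type_symbol")
  if (is.null(el)) {
    lab <- getcol(site_loop, "_atom_site_label")
    if (is.null(lab)) stop("CIF missing required tag: _atom_site_type_symbol")
    el <- sub("[0-9].*$", "", lab)
  }
  fc <- cbind(strip_su(getcol(site_loop, "fract_x")),
              strip_su(getcol(site_loop, "fract_y")),
              strip_su(getcol(site_loop, "fract_z")))
  if (anyNA(fc)) stop("CIF atom sites contain non-numeric fractional coordinates")
  sgn <- fields[["_symmetry_int_tables_number"]]
  if (is.null(sgn)) sgn <- fields[["_space_group_it_number"]]
  sgn <- if (is.null(sgn)) 1L else as.integer(strip_su(sgn))
  s <- crystal(lattice, fc, el, space_group = sgn, structure_id = data_name)
  if (!is.null(sym_loop)) {
    attr(s, "symmetry_ops") <- as.character(sym_loop[[grep("as_xyz",
                                                           names(sym_loop))[1]]])
  }
  s
}

lattice_from_params <- function(a, b, c, alpha, beta, gamma) {
  cx <- c * cos(beta)
  cy <- c * (cos(alpha) - cos(beta) * cos(gamma)) / sin(gamma)
  cz <- sqrt(max(c^2 - cx^2 - cy^2, 0))
  rbind(c(a, 0, 0),
        c(b * cos(gamma), b * sin(gamma), 0),
        c(cx, cy, cz))
}

cell_params <- function(lattice) {
  len <- sqrt(rowSums(lattice^2))
  ang <- function(u, v) acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  c(a = len[1], b = len[2], c = len[3],
    alpha = ang(lattice[2, ], lattice[3, ]),
    beta = ang(lattice[1, ], lattice[3, ]),
    gamma = ang(lattice[1, ], lattice[2, ]))
}

#' Write a crystal structure to CIF
#'
#' The symmetry operation list of the structure's space group is written
#' explicitly; P1 structures carry `_symmetry_space_group_name_H-M 'P 1'`.
#'
#' @param s a `crystal`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cif <- function(s, path) {
  p <- cell_params(s$lattice)
  ops <- sg_operations(s$space_group)
  hm <- .sg_table[[s$space_group]]$hm
  lines <- c(
    sprintf("data_%s", gsub("[[:space:]]", "_", s$structure_id)),
    sprintf("_symmetry_space_group_name_H-M '%s'", hm),
    sprintf("_symmetry_Int_Tables_number %d", s$space_group),
    sprintf("_cell_length_a %.6f", p["a"]),
    sprintf("_cell_length_b %.6f", p["b"]),
    sprintf("_cell_length_c %.6f", p["c"]),
    sprintf("_cell_angle_alpha %.6f", p["alpha"]),
    sprintf("_cell_angle_beta %.6f", p["beta"]),
    sprintf("_cell_angle_gamma %.6f", p["gamma"]),
    "loop_",
    "_symmetry_equiv_pos_as_xyz",
    vapply(ops, function(op) sprintf("'%s'", format_triplet(op)), character(1)),
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    "_atom_site_occupancy"
  )
  n <- n_atoms(s)
  lab <- paste0(s$elements, seq_len(n))
  rows <- sprintf("%s %s %.8f %.8f %.8f 1.0", lab, s$elements,
                  s$frac_coords[, 1], s$frac_coords[, 2], s$frac_coords[, 3])
  writeLines(c(lines, rows), path)
  invisible(path)
}

#' Write a structure as extended XYZ
#'
#' Cartesian coordinates with the cell in the `Lattice=` comment field;
#' optional per-atom extra columns (e.g. attribution scores).
#'
#' @param s a `crystal`.
#' @param path output path.
#' @param extra optional named list of per-atom numeric columns.
#' @return `path`, invisibly.
#' @export
write_extxyz <- function(s, path, extra = NULL) {
  cart <- cart_coords(s)
  lat <- paste(sprintf("%.8f", t(s$lattice)), collapse = " ")
  props <- "species:S:1:pos:R:3"
  cols <- NULL
  if (!is.null(extra)) {
    for (nm in names(extra)) {
      stopifnot(length(extra[[nm]]) == n_atoms(s))
      props <- paste0(props, ":", nm, ":R:1")
    }
    cols <- do.call(cbind, extra)
  }
  hdr <- sprintf('Lattice="%s" Properties=%s', lat, props)
  body <- vapply(seq_len(n_atoms(s)), function(i) {
    ln <- sprintf("%s %.8f %.8f %.8f", s$elements[i],
                  cart[i, 1], cart[i, 2], cart[i, 3])
    if (!is.null(cols)) {
      ln <- paste(ln, paste(sprintf("%.8f", cols[i, ]), collapse = " "))
    }
    ln
  }, character(1))
  writeLines(c(as.character(n_atoms(s)), hdr, body), path)
  invisible(path)
}

#' Read an extended XYZ file written by [write_extxyz()]
#'
#' @param path file path.
#' @return list with `crystal` and any extra per-atom columns.
#' @export
read_extxyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(lines[1])
  hdr <- lines[2]
  latm <- regmatches(hdr, regexpr('Lattice="[^"]*"', hdr))
  lat <- matrix(as.numeric(strsplit(sub('Lattice="', "",
                                        sub('"$', "", latm)), " ")[[1]]),
                3, 3, byrow = TRUE)
  props <- sub(".*Properties=([^ ]*).*", "\\1", hdr)
  pp <- strsplit(props, ":")[[1]]
  nm <- pp[seq(1, length(pp), 3)]
  wd <- as.integer(pp[seq(3, length(pp), 3)])
  toks <- strsplit(trimws(lines[3:(2 + n)]), "[[:space:]]+")
  tab <- do.call(rbind, toks)
  col <- 1
  out <- list()
  for (k in seq_along(nm)) {
    vals <- tab[, col:(col + wd[k] - 1), drop = FALSE]
    out[[nm[k]]] <- if (nm[k] == "species") vals[, 1] else
      matrix(as.numeric(vals), nrow = n)
    col <- col + wd[k]
  }
  cart <- out$pos
  fc <- wrap_frac(cart %*% solve(lat))
  s <- crystal(lat, fc, out$species, space_group = 1L,
               structure_id = tools::file_path_sans_ext(basename(path)))
  extras <- out[setdiff(names(out), c("species", "pos"))]
  list(crystal = s, extra = lapply(extras, as.numeric))
}
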