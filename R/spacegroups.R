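# Space-group operations and the 7-bit symmetry-element labelling.
#
# Operations are affine pairs (R, t): x' = R x + t, R an integer 3x3 matrix in
# the standard (conventional) setting, t fractional, taken modulo lattice
# translations. Groups are reconstructed from the stored generator table by
# closure under composition.

.sg_cache <- new.env(parent = emptyenv())

# Parse one xyz triplet ("x,y+1/2,-z") into list(R = 3x3, t = length 3).
parse_triplet <- function(s) {
  parts <- strsplit(gsub("[[:space:]]", "", s), ",")[[1]]
  if (length(parts) != 3) stop("malformed triplet: ", s)
  R <- matrix(0, 3, 3)
  t <- numeric(3)
  for (i in 1:3) {
    expr <- parts[i]
    # tokenize into signed terms
    terms <- regmatches(expr, gregexpr("[+-]?[^+-]+", expr))[[1]]
    for (tm in terms) {
      sign <- if (startsWith(tm, "-")) -1 else 1
      body <- sub("^[+-]", "", tm)
      if (grepl("[xyz]", body)) {
        ax <- match(regmatches(body, regexpr("[xyz]", body)), c("x", "y", "z"))
        coef <- sub("[xyz]", "", body)
        coef <- if (coef == "" || coef == "*") 1 else {
          if (grepl("/", coef)) {
            pq <- as.numeric(strsplit(sub("\\*$", "", coef), "/")[[1]])
            pq[1] / pq[2]
          } else as.numeric(sub("\\*$", "", coef))
        }
        R[i, ax] <- R[i, ax] + sign * coef
      } else {
        val <- if (grepl("/", body)) {
          pq <- as.numeric(strsplit(body, "/")[[1]])
          pq[1] / pq[2]
        } else as.numeric(body)
        t[i] <- t[i] + sign * val
      }
    }
  }
  list(R = R, t = t - floor(t))
}

format_triplet <- function(op) {
  frac_str <- function(v) {
    v <- v - floor(v)
    if (abs(v) < 1e-9) return("")
    den <- c(2, 3, 4, 6, 12)
    for (d in den) {
      num <- round(v * d)
      if (abs(v - num / d) < 1e-9 && num > 0) return(sprintf("+%d/%d", num, d))
    }
    sprintf("%+g", v)
  }
  axes <- c("x", "y", "z")
  comps <- vapply(1:3, function(i) {
    s <- ""
    for (j in 1:3) {
      c_ij <- op$R[i, j]
      if (abs(c_ij) < 1e-9) next
      sgn <- if (c_ij < 0) "-" else if (nzchar(s)) "+" else ""
      mag <- abs(c_ij)
      s <- paste0(s, sgn, if (abs(mag - 1) < 1e-9) "" else format(mag), axes[j])
    }
    paste0(s, frac_str(op$t[i]))
  }, character(1))
  paste(comps, collapse = ",")
}

op_key <- function(op) {
  paste(c(round(op$R), round(op$t * 24) %% 24), collapse = ",")
}

compose_ops <- function(a, b) {
  t <- as.numeric(a$R %*% b$t + a$t)
  list(R = a$R %*% b$R, t = t - floor(t))
}

#' Symmetry operations of a space group
#'
#' Returns the full list of coset representatives (rotation part + fractional
#' translation, modulo lattice translations) for the standard setting of a
#' space group, reconstructed from a stored generator table by closure.
#'
#' @param number space-group number (1-230).
#' @return list of operations, each `list(R = 3x3 integer matrix, t = length-3
#'   fractional translation)`. The identity is included.
#' @export
sg_operations <- function(number) {
  number <- as.integer(number)
  if (is.na(number) || number < 1L || number > 230L) {
    stop("space-group number must be in 1..230")
  }
  key <- as.character(number)
  if (!is.null(.sg_cache[[key]])) return(.sg_cache[[key]])
  entry <- .sg_table[[number]]
  ident <- list(R = diag(3), t = numeric(3))
  have <- list(ident)
  names(have) <- op_key(ident)
  frontier <- lapply(entry$gens, parse_triplet)
  while (length(frontier)) {
    nxt <- list()
    for (a in frontier) {
      for (b in have) {
        for (cand in list(compose_ops(a, b), compose_ops(b, a))) {
          k <- op_key(cand)
          if (is.null(have[[k]])) {
            have[[k]] <- cand
            nxt[[length(nxt) + 1L]] <- cand
          }
        }
      }
    }
    frontier <- nxt
  }
  if (length(have) != entry$nops) {
    stop("space-group closure failed for group ", number)
  }
  ops <- unname(have)
  .sg_cache[[key]] <- ops
  ops
}

# Order of a rotation part (smallest n with R^n = I), n <= 6.
rot_order <- function(R) {
  P <- diag(3)
  for (n in 1:6) {
    P <- P %*% R
    if (all(abs(P - diag(3)) < 1e-9)) return(n)
  }
  stop("rotation part has order > 6: not crystallographic")
}

# Classify a single operation into one of the symmetry-element kinds.
# Intrinsic translation = projection of t onto the operation's invariant
# subspace, reduced modulo the projections of the lattice translations onto
# that subspace (a diagonal "half-translation" that equals a projected
# lattice vector is a shifted mirror/rotation, not a glide/screw).
.lattice_shifts <- as.matrix(expand.grid(a = -2:2, b = -2:2, c = -2:2))

reduce_mod_projected_lattice <- function(w, P) {
  proj <- .lattice_shifts %*% t(P)
  res <- sweep(-proj, 2, w, "+")
  sqrt(min(rowSums(res^2)))
}

classify_op <- function(op, tol = 1e-6) {
  R <- op$R; t <- op$t
  detR <- round(det(R))
  if (detR == 1) {
    n <- rot_order(R)
    if (n == 1) {
      if (all(abs(t - round(t)) < tol)) return("identity")
      return("translation")            # pure (centering) translation
    }
    P <- diag(3)
    acc <- diag(3)
    for (k in 1:(n - 1)) { acc <- acc %*% R; P <- P + acc }
    P <- P / n
    w <- as.numeric(P %*% t)
    if (reduce_mod_projected_lattice(w, P) < 1e-4) "rotation" else "screw"
  } else {
    if (all(abs(R + diag(3)) < 1e-9)) return("inversion")
    n <- rot_order(R)
    if (n == 2) {                       # reflection (possibly glide)
      P <- (diag(3) + R) / 2
      w <- as.numeric(P %*% t)
      if (reduce_mod_projected_lattice(w, P) < 1e-4) "mirror" else "glide"
    } else {
      "rotoinversion"                   # -3, -4, -6
    }
  }
}

.sep_bit_names <- c("no_element", "inversion", "mirror", "rotation",
                    "screw", "rotoinversion", "glide")

#' Symmetry-element label of a space group
#'
#' Classifies every operation of the group (identity and pure translations
#' excluded) into the six symmetry-element types and returns the 7-dimensional
#' multi-hot label used by the symmetry-element prediction task, in fixed bit
#' order: no-element (P1), inversion centre, mirror plane, rotation axis,
#' screw axis, rotoinversion axis, glide plane.
#'
#' @param number space-group number (1-230).
#' @return named integer vector of 7 zeros/ones, class `symmetry_label`.
#' @export
symmetry_elements <- function(number) {
  memo_key <- paste0("label_", number)
  if (!is.null(.sg_cache[[memo_key]])) return(.sg_cache[[memo_key]])
  ops <- sg_operations(number)
  kinds <- vapply(ops, classify_op, character(1))
  bits <- c(
    no_element = 0L,
    inversion = as.integer("inversion" %in% kinds),
    mirror = as.integer("mirror" %in% kinds),
    rotation = as.integer("rotation" %in% kinds),
    screw = as.integer("screw" %in% kinds),
    rotoinversion = as.integer("rotoinversion" %in% kinds),
    glide = as.integer("glide" %in% kinds)
  )
  if (sum(bits) == 0L) bits["no_element"] <- 1L
  out <- structure(bits, class = "symmetry_label")
  .sg_cache[[memo_key]] <- out
  out
}

#' @export
print.symmetry_label <- function(x, ...) {
  on <- .sep_bit_names[which(unclass(x) == 1L)]
  cat("<symmetry_label>", paste(on, collapse = " + "), "\n")
  invisible(x)
}

#' Table of symmetry-element labels for all 230 space groups
#'
#' @return data frame with columns `number`, `hm` (Hermann-Mauguin symbol) and
#'   the seven bit columns.
#' @export
sg_label_table <- function() {
  rows <- lapply(1:230, function(n) {
    b <- unclass(symmetry_elements(n))
    cbind(data.frame(number = n, hm = .sg_table[[n]]$hm,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(b)))
  })
  do.call(rbind, rows)
}

#' Export the space group to symmetry-element label table as JSON
#'
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_sg_labels <- function(path) {
  jsonlite::write_json(sg_label_table(), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Inverse-frequency class weights for the symmetry-element loss
#'
#' Rarer symmetry elements receive larger weights: `w_i` proportional to
#' `p_i^(-1/epsilon)` with `p_i` the relative frequency of element `i`,
#' normalised so the mean weight is 1. `epsilon >= 1` flattens the weights;
#' the default 1.1 avoids extreme values, and `epsilon -> Inf` gives uniform
#' weights. Zero counts are add-one smoothed.
#'
#' @param frequencies per-element occurrence counts (length 7 in the
#'   symmetry-element task, but any length is supported).
#' @param epsilon flattening parameter, `>= 1`.
#' @return numeric weights with mean 1.
#' @export
element_weights <- function(frequencies, epsilon = 1.1) {
  if (epsilon < 1) stop("epsilon must be >= 1")
  x <- as.numeric(frequencies)
  if (any(x < 0)) stop("frequencies must be non-negative")
  x[x == 0] <- x[x == 0] + 1
  p <- x / sum(x)
  w <- p^(-1 / epsilon)
  w / mean(w)
}

#' Exact-match comparison for symmetry-element predictions
#'
#' A prediction counts as correct only when every thresholded probability
#' matches the label bit.
#'
#' @param pred numeric vector of 7 probabilities in `[0,1]`.
#' @param label a `symmetry_label` or 0/1 vector of length 7.
#' @param threshold decision threshold.
#' @return logical scalar.
#' @export
sep_exact_match <- function(pred, label, threshold = 0.5) {
  pred <- as.numeric(pred)
  if (any(pred < 0 | pred > 1)) stop("pred must be probabilities in [0,1]")
  label <- as.integer(unclass(label))
  if (length(pred) != length(label)) stop("length mismatch")
  all(as.integer(pred >= threshold) == label)
}
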