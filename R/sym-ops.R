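#' Symmetry operations
#'
#' A symmetry operation is a pair (R, t): a 3x3 rotation (or rotoinversion)
#' matrix and a translation vector. In the `"fractional"` frame the matrix has
#' integer entries and the translation is expressed in fractions of the unit
#' cell edges; in the `"cartesian"` frame both are in Angstroms. Internally,
#' fractional translations are snapped to multiples of 1/24, which is exact
#' for every crystallographic screw/glide component (1/2, 1/3, 1/4, 1/6, ...).
#'
#' @param rotation 3x3 numeric matrix.
#' @param translation numeric length-3 vector (default zero).
#' @param frame `"fractional"` or `"cartesian"`.
#' @return An object of class `sym_op`.
#' @examples
#' sym_op(diag(3))                       # identity
#' sym_op(diag(c(1, -1, -1)), c(0.5, 0, 0))  # 2_1 screw about x
#' @export
sym_op <- function(rotation, translation = c(0, 0, 0), frame = "fractional") {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3)
  if (any(!is.finite(rotation)) || any(!is.finite(translation)))
    stop("sym_op: non-finite entries")
  frame <- match.arg(frame, c("fractional", "cartesian"))
  if (frame == "fractional") {
    rotation <- round(rotation)
    translation <- round(translation * 24) / 24
    translation <- translation %% 1
  }
  structure(list(rotation = rotation, translation = translation, frame = frame),
            class = "sym_op")
}

#' @export
print.sym_op <- function(x, ...) {
  cat("<sym_op>", x$frame, "frame:", sym_triplet(x), "\n")
  invisible(x)
}

sym_identity <- function(frame = "fractional") sym_op(diag(3), frame = frame)

#' Compose two symmetry operations
#'
#' Returns the operation "first q, then p": rotation `p$rotation %*%
#' q$rotation`, translation `p$rotation %*% q$translation + p$translation`.
#' In the fractional frame the translation is reduced modulo the lattice.
#'
#' @param p,q `sym_op` objects in the same frame.
#' @return A `sym_op`.
#' @export
sym_compose <- function(p, q) {
  stopifnot(inherits(p, "sym_op"), inherits(q, "sym_op"))
  if (!identical(p$frame, q$frame))
    stop("sym_compose: operations are in different frames")
  sym_op(p$rotation %*% q$rotation,
         drop(p$rotation %*% q$translation) + p$translation,
         frame = p$frame)
}

## canonical hashable key; fractional frame only
sym_key <- function(op) {
  paste(c(as.integer(round(op$rotation)),
          as.integer(round(op$translation * 24)) %% 24L), collapse = ",")
}

#' Group closure of a generator set
#'
#' Computes the smallest set of fractional-frame operations containing the
#' identity and the generators and closed under composition modulo lattice
#' translations. Growth past `limit` operations (the largest space-group
#' order is 192) aborts with an error, guarding against a corrupt generator
#' set. The result is returned in a canonical deterministic order (sorted by
#' rotation entries, then translation).
#'
#' @param generators list of fractional `sym_op`s.
#' @param limit maximum group order tolerated before aborting.
#' @return list of `sym_op`s.
#' @export
sym_closure <- function(generators, limit = 192) {
  if (!is.list(generators)) generators <- list(generators)
  if (any(!vapply(generators, inherits, TRUE, "sym_op")))
    stop("sym_closure: generators must be sym_op objects")
  if (any(vapply(generators, function(g) g$frame, "") != "fractional"))
    stop("sym_closure: generators must be in the fractional frame")
  id <- sym_identity()
  ops <- structure(list(id), names = sym_key(id))
  frontier <- list(id)
  while (length(frontier)) {
    fresh <- list()
    for (a in frontier) {
      for (g in generators) {
        cand <- sym_compose(a, g)
        k <- sym_key(cand)
        if (is.null(ops[[k]])) {
          ops[[k]] <- cand
          fresh[[k]] <- cand
          if (length(ops) > limit)
            stop("sym_closure: group order exceeded ", limit,
                 " operations; generator set inconsistent")
        }
      }
    }
    frontier <- fresh
  }
  ops <- unname(ops)
  keys <- vapply(ops, function(o)
    paste(sprintf("%+d", c(round(o$rotation), round(o$translation * 24))),
          collapse = ""), "")
  ops[order(keys)]
}

#' Classify a symmetry operation
#'
#' Determines the geometric type of a fractional-frame operation:
#' `identity`, pure `translation`, proper `rotation`, `screw_rotation`
#' (rotation with a nonzero intrinsic translation along the axis), or
#' `improper` (determinant -1: reflections, inversions, rotoinversions,
#' glides -- the types excluded for chiral molecules such as proteins).
#'
#' The intrinsic translation is the average of `R^k t` over one full turn of
#' the rotation; a screw axis is present iff it is nonzero modulo the lattice.
#'
#' @param op fractional `sym_op`.
#' @return character scalar, one of the five kinds.
#' @export
sym_classify <- function(op) {
  stopifnot(inherits(op, "sym_op"))
  d <- det(op$rotation)
  if (abs(abs(d) - 1) > 1e-6)
    stop("sym_classify: |det| != 1, not a valid crystallographic operation")
  if (d < 0) return("improper")
  R <- round(op$rotation)
  t24 <- as.integer(round(op$translation * 24)) %% 24L
  if (all(R == diag(3))) {
    return(if (all(t24 == 0L)) "identity" else "translation")
  }
  ## order of the rotation part (crystallographic: 2, 3, 4 or 6)
  n <- 1L; P <- R
  while (!all(P == diag(3)) && n <= 6L) { P <- P %*% R; n <- n + 1L }
  if (n > 6L) stop("sym_classify: rotation order exceeds 6")
  ## intrinsic part: sum_{k=0}^{n-1} R^k t, in 1/24 units; screw iff
  ## the sum is not a multiple of 24*n (i.e. intrinsic != 0 mod lattice)
  s <- c(0L, 0L, 0L); P <- diag(3)
  for (k in seq_len(n)) { s <- s + as.integer(round(P %*% t24)); P <- P %*% R }
  if (all(s %% (24L * n) == 0L)) "rotation" else "screw_rotation"
}

#' Render a symmetry operation as a coordinate triplet
#'
#' @param op fractional `sym_op`.
#' @return string such as `"-x,y+1/2,-z"`.
#' @export
sym_triplet <- function(op) {
  ax <- c("x", "y", "z")
  R <- round(op$rotation); t24 <- as.integer(round(op$translation * 24)) %% 24L
  out <- character(3)
  for (i in 1:3) {
    s <- ""
    for (j in 1:3) {
      cf <- R[i, j]
      if (cf == 0) next
      sg <- if (cf < 0) "-" else if (nzchar(s)) "+" else ""
      s <- paste0(s, sg, if (abs(cf) != 1) abs(cf) else "", ax[j])
    }
    if (t24[i] != 0L) {
      g <- gcd2(t24[i], 24L)
      s <- paste0(s, if (nzchar(s)) "+" else "", t24[i] %/% g, "/", 24L %/% g)
    }
    if (!nzchar(s)) s <- "0"
    out[i] <- s
  }
  paste(out, collapse = ",")
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

#' Parse a coordinate triplet into a symmetry operation
#'
#' Accepts Jones-faithful triplets such as `"x+1/2,-y,z"` or `"y-x,x,z+2/3"`.
#'
#' @param text triplet string.
#' @return fractional `sym_op`.
#' @export
parse_triplet <- function(text) {
  parts <- strsplit(gsub(" ", "", text), ",", fixed = TRUE)[[1]]
  if (length(parts) != 3) stop("parse_triplet: expected 3 components in ", text)
  R <- matrix(0, 3, 3); tr <- numeric(3)
  for (i in 1:3) {
    expr <- parts[i]
    toks <- regmatches(expr, gregexpr("[+-]?[^+-]+", expr))[[1]]
    for (tk in toks) {
      sgn <- if (startsWith(tk, "-")) -1 else 1
      body <- sub("^[+-]", "", tk)
      if (grepl("[xyz]", body)) {
        j <- match(sub(".*([xyz]).*", "\\1", body), c("x", "y", "z"))
        coef <- sub("[xyz]", "", body)
        R[i, j] <- R[i, j] + sgn * if (nzchar(coef)) as.numeric(coef) else 1
      } else if (grepl("/", body, fixed = TRUE)) {
        nd <- as.numeric(strsplit(body, "/", fixed = TRUE)[[1]])
        tr[i] <- tr[i] + sgn * nd[1] / nd[2]
      } else {
        tr[i] <- tr[i] + sgn * as.numeric(body)
      }
    }
  }
  sym_op(R, tr)
}

#' Convert a fractional operation to the cartesian frame
#'
#' Conjugates the operation by the orthogonalization matrix `M` of the cell:
#' `R_cart = M R M^{-1}`, `t_cart = M t`.
#'
#' @param op fractional `sym_op`.
#' @param geom `cell_geometry` object.
#' @return cartesian `sym_op`.
#' @export
sym_to_cartesian <- function(op, geom) {
  stopifnot(inherits(op, "sym_op"), inherits(geom, "cell_geometry"))
  if (op$frame != "fractional") return(op)
  M <- geom$orthogonalization
  sym_op(M %*% op$rotation %*% solve(M), drop(M %*% op$translation),
         frame = "cartesian")
}

#' Apply a symmetry operation to coordinates
#'
#' @param op `sym_op` (either frame).
#' @param xyz n x 3 numeric matrix of coordinates in the matching frame.
#' @return transformed n x 3 matrix.
#' @export
sym_apply <- function(op, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  t(op$rotation %*% t(xyz) + op$translation)
}
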