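#' Unit cell geometry from cell parameters
#'
#' Builds the three cell vectors and the fractional-to-cartesian
#' orthogonalization matrix in the standard PDB convention: the a-vector lies
#' along x and the b-vector in the xy-plane. The cell volume is
#' `abc * sqrt(1 - cos^2(alpha) - cos^2(beta) - cos^2(gamma)
#'            + 2 cos(alpha) cos(beta) cos(gamma))`.
#'
#' @param crystal a `crystal_card` (or any list with fields `a, b, c, alpha,
#'   beta, gamma` -- lengths in Angstroms, angles in degrees).
#' @return A `cell_geometry` object: cell vectors (rows of `vectors`), the
#'   `orthogonalization` matrix (columns are the cell vectors) and `volume`
#'   in cubic Angstroms.
#' @examples
#' cell_geometry(crystal_card(10, 10, 10, 90, 90, 90))
#' @export
cell_geometry <- function(crystal) {
  a <- crystal$a; b <- crystal$b; cc <- crystal$c
  al <- crystal$alpha * pi / 180; be <- crystal$beta * pi / 180
  ga <- crystal$gamma * pi / 180
  if (any(c(a, b, cc) <= 0)) stop("cell_geometry: cell edges must be positive")
  if (any(c(crystal$alpha, crystal$beta, crystal$gamma) <= 0) ||
      any(c(crystal$alpha, crystal$beta, crystal$gamma) >= 180))
    stop("cell_geometry: cell angles must lie in (0, 180) degrees")
  ca <- cos(al); cb <- cos(be); cg <- cos(ga); sg <- sin(ga)
  disc <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (disc <= 0)
    stop("cell_geometry: angle combination gives non-positive cell volume")
  v <- sqrt(disc)
  M <- matrix(c(a, b * cg,  cc * cb,
                0, b * sg,  cc * (ca - cb * cg) / sg,
                0, 0,       cc * v / sg),
              nrow = 3, byrow = TRUE)
  structure(list(vectors = t(M),          # rows: a, b, c vectors
                 orthogonalization = M,
                 volume = a * b * cc * v),
            class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat("<cell_geometry> volume", format(x$volume), "A^3\n")
  print(round(x$vectors, 4))
  invisible(x)
}

#' Crystallographic cell description (CRYST1 payload)
#'
#' @param a,b,c cell edges, Angstroms.
#' @param alpha,beta,gamma cell angles, degrees.
#' @param space_group_symbol Hermann-Mauguin symbol, e.g. `"P 21 21 21"`.
#' @param z_value formula units per cell (informational).
#' @return A `crystal_card` list.
#' @export
crystal_card <- function(a, b, c, alpha = 90, beta = 90, gamma = 90,
                         space_group_symbol = "P 1", z_value = 1L) {
  structure(list(a = a, b = b, c = c, alpha = alpha, beta = beta,
                 gamma = gamma, space_group_symbol = space_group_symbol,
                 z_value = as.integer(z_value)),
            class = "crystal_card")
}

#' Fractional/cartesian coordinate conversion
#'
#' @param xyz n x 3 coordinate matrix.
#' @param geom `cell_geometry`.
#' @return n x 3 matrix in the other frame.
#' @export
cart_to_frac <- function(xyz, geom) {
  t(solve(geom$orthogonalization) %*% t(matrix(as.numeric(xyz), ncol = 3)))
}

#' @rdname cart_to_frac
#' @export
frac_to_cart <- function(xyz, geom) {
  t(geom$orthogonalization %*% t(matrix(as.numeric(xyz), ncol = 3)))
}
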