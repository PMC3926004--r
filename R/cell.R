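#' Unit cell
#'
#' Construct a crystallographic unit cell. Lengths are in Angstrom, angles in
#' degrees. The object carries the orthogonalization matrix `orth` (fractional
#' -> Cartesian, PDB convention with `a` along x) and its inverse `frac`, plus
#' the cell volume in cubic Angstrom.
#'
#' @param a,b,c cell edge lengths (Angstrom), must be positive.
#' @param alpha,beta,gamma cell angles (degrees), each in (0, 180).
#' @return an object of class `unit_cell` with fields `a,b,c,alpha,beta,gamma`,
#'   `volume`, `orth` (3x3), `frac` (3x3).
#' @examples
#' cl <- unit_cell(19.677, 39.90, 75.09)
#' cl$volume
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(a > 0, b > 0, c > 0)
  if (any(c(alpha, beta, gamma) <= 0) || any(c(alpha, beta, gamma) >= 180))
    stop("cell angles must lie strictly between 0 and 180 degrees")
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180); cg <- cos(gamma * pi / 180)
  sg <- sin(gamma * pi / 180)
  v <- sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  if (!is.finite(v) || v <= 0) stop("cell angles do not define a positive cell volume")
  orth <- matrix(c(
    a, b * cg, c * cb,
    0, b * sg, c * (ca - cb * cg) / sg,
    0, 0,      c * v / sg), nrow = 3, byrow = TRUE)
  structure(list(a = a, b = b, c = c,
                 alpha = alpha, beta = beta, gamma = gamma,
                 volume = a * b * c * v,
                 orth = orth, frac = solve(orth)),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("Unit cell %.4g x %.4g x %.4g A, angles %.4g %.4g %.4g, V = %.6g A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

#' Convert between fractional and Cartesian coordinates
#'
#' @param cell a [unit_cell()].
#' @param xyz n x 3 matrix of coordinates.
#' @return n x 3 matrix in the other frame (Cartesian in Angstrom).
#' @export
frac_to_cart <- function(cell, xyz) {
  xyz <- as_coord_matrix(xyz)
  xyz %*% t(cell$orth)
}

#' @rdname frac_to_cart
#' @export
cart_to_frac <- function(cell, xyz) {
  xyz <- as_coord_matrix(xyz)
  xyz %*% t(cell$frac)
}

as_coord_matrix <- function(xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  stopifnot(ncol(xyz) == 3)
  xyz
}

#' Wrap fractional coordinates into [0, 1)
#'
#' @param x numeric vector or matrix of fractional coordinates.
#' @return same shape, wrapped to the half-open unit interval.
#' @export
wrap_frac <- function(x) x - floor(x)

#' Resolution of reflections
#'
#' d-spacing (Angstrom) of Miller indices for a given cell.  `s = 1/(2d)` is
#' the sin(theta)/lambda convention used throughout the package.
#'
#' @param cell a [unit_cell()].
#' @param hkl n x 3 matrix (or length-3 vector) of integer Miller indices.
#' @return numeric vector of d-spacings.
#' @export
d_spacing <- function(cell, hkl) {
  1 / sqrt(inv_d2(cell, hkl))
}

# 1/d^2 for hkl rows; works for any cell via the reciprocal metric
inv_d2 <- function(cell, hkl) {
  hkl <- as_coord_matrix(hkl)
  s_vec <- hkl %*% cell$frac        # reciprocal-space vector, Cartesian A^-1
  rowSums(s_vec * s_vec)
}

# Cartesian scattering vectors S (|S| = 1/d), n x 3
scattering_vectors <- function(cell, hkl) {
  as_coord_matrix(hkl) %*% cell$frac
}
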