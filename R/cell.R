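#' Unit cell
#'
#' Construct a validated unit cell from the six lattice parameters.
#'
#' @param a,b,c Axis lengths in Angstrom; must be positive.
#' @param alpha,beta,gamma Inter-axial angles in degrees, each in (0, 180).
#'
#' @details The metric tensor implied by the six parameters must be
#'   positive-definite (equivalently, the cell volume must be real and
#'   positive); degenerate combinations such as `alpha + beta + gamma`
#'   too close to 360 degrees are rejected.
#'
#' @return An object of class `unit_cell`: a named list with fields
#'   `a`, `b`, `c`, `alpha`, `beta`, `gamma`.
#' @examples
#' cell <- unit_cell(78.2, 78.2, 37.1, 90, 90, 90)
#' cell_volume(cell)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  p <- c(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(p))) stop("unit cell parameters must be finite numbers")
  if (any(p[1:3] <= 0)) stop("cell axis lengths must be positive")
  if (any(p[4:6] <= 0) || any(p[4:6] >= 180)) {
    stop("cell angles must lie strictly between 0 and 180 degrees")
  }
  cell <- structure(as.list(p), class = "unit_cell")
  disc <- .cell_discriminant(cell)
  if (disc <= 0) {
    stop("cell angles define a non-positive-definite metric (zero or imaginary volume)")
  }
  cell
}

# 1 - cos^2a - cos^2b - cos^2g + 2 cos a cos b cos g; positive iff the
# metric tensor is positive-definite
.cell_discriminant <- function(cell) {
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
}

#' Unit-cell volume
#'
#' @param cell A [unit_cell()].
#' @return Volume in cubic Angstrom (always positive).
#' @export
cell_volume <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  disc <- .cell_discriminant(cell)
  if (disc <= 0) stop("non-positive-definite cell metric")
  cell$a * cell$b * cell$c * sqrt(disc)
}

#' Orthogonalization matrix (PDB convention)
#'
#' Matrix M mapping fractional to Cartesian coordinates, with the `a` axis
#' along Cartesian x and `b` in the x-y plane. `det(M)` equals the cell
#' volume.
#'
#' @param cell A [unit_cell()].
#' @return A 3x3 numeric matrix.
#' @export
orthogonalization_matrix <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  sg <- sin(cell$gamma * pi / 180)
  v <- sqrt(.cell_discriminant(cell))
  matrix(c(
    cell$a, cell$b * cg, cell$c * cb,
    0,      cell$b * sg, cell$c * (ca - cb * cg) / sg,
    0,      0,           cell$c * v / sg
  ), nrow = 3, byrow = TRUE)
}

#' Fractional to Cartesian coordinates
#'
#' @param frac Numeric length-3 vector or n x 3 matrix of fractional
#'   coordinates.
#' @param cell A [unit_cell()].
#' @return Cartesian coordinates (Angstrom), same shape as `frac`.
#' @export
frac_to_cart <- function(frac, cell) {
  m <- orthogonalization_matrix(cell)
  if (is.matrix(frac)) t(m %*% t(frac)) else as.numeric(m %*% frac)
}

#' Scattering vectors for Miller indices
#'
#' Cartesian reciprocal-lattice vector s = h a* + k b* + l c* in the same
#' frame as [orthogonalization_matrix()]. Its length is 1/d, with d the
#' resolution of the reflection; the direction is the normal of the
#' diffracting plane family.
#'
#' @param hkl Integer length-3 vector or n x 3 matrix of Miller indices;
#'   (0,0,0) is rejected.
#' @param cell A [unit_cell()].
#' @return For a single triple, a length-3 numeric vector (inverse
#'   Angstrom); for a matrix, an n x 3 matrix.
#' @examples
#' s <- scattering_vector(c(1, 0, 0), unit_cell(10, 10, 10))
#' 1 / sqrt(sum(s^2))  # d = 10 Angstrom
#' @export
scattering_vector <- function(hkl, cell) {
  single <- !is.matrix(hkl)
  h <- if (single) matrix(hkl, nrow = 1) else hkl
  if (ncol(h) != 3) stop("hkl must have three columns")
  if (any(rowSums(h != 0) == 0)) stop("(0,0,0) has no scattering vector")
  m <- orthogonalization_matrix(cell)
  # reciprocal basis vectors are the rows of solve(M), so s = solve(M)^T hkl
  s <- h %*% solve(m)
  if (single) as.numeric(s) else s
}

#' Resolution (d-spacing) of reflections
#'
#' @inheritParams scattering_vector
#' @return d-spacings in Angstrom.
#' @export
d_spacing <- function(hkl, cell) {
  s <- scattering_vector(hkl, cell)
  if (!is.matrix(s)) s <- matrix(s, nrow = 1)
  1 / sqrt(rowSums(s^2))
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell  a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f  (V=%.1f A^3)\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, cell_volume(x)))
  invisible(x)
}
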