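#' Unit-cell geometry helpers
#'
#' A unit cell is stored as a numeric vector `c(a, b, c, alpha, beta, gamma)`
#' with lengths in Angstrom and angles in degrees.  Internally all model
#' coordinates are Cartesian (Angstrom); fractional coordinates appear only at
#' the scattering and map boundaries.
#'
#' @param cell numeric length-6 vector `(a, b, c, alpha, beta, gamma)`.
#' @return `cell_orth_matrix()`: the 3x3 orthogonalization matrix `O` mapping
#'   fractional to Cartesian coordinates (standard PDB convention, `a` along
#'   x, `b` in the xy plane); `cell_frac_matrix()`: its inverse;
#'   `cell_volume()`: the cell volume in cubic Angstrom.
#' @name cell
NULL

validate_cell <- function(cell) {
  if (!is.numeric(cell) || length(cell) != 6L || anyNA(cell))
    stop("cell must be numeric (a, b, c, alpha, beta, gamma)")
  if (any(cell[1:3] <= 0)) stop("cell edges must be positive")
  if (any(cell[4:6] <= 0) || any(cell[4:6] >= 180))
    stop("cell angles must lie in (0, 180) degrees")
  invisible(cell)
}

#' @rdname cell
#' @export
cell_orth_matrix <- function(cell) {
  validate_cell(cell)
  a <- cell[1]; b <- cell[2]; c <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  cg <- cos(ga); sg <- sin(ga); cb <- cos(be); ca <- cos(al)
  # standard PDB orthogonalization: a || x, b in xy plane
  v <- sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  matrix(c(a, b * cg, c * cb,
           0, b * sg, c * (ca - cb * cg) / sg,
           0, 0,      c * v / sg),
         nrow = 3, byrow = TRUE)
}

#' @rdname cell
#' @export
cell_frac_matrix <- function(cell) solve(cell_orth_matrix(cell))

#' @rdname cell
#' @export
cell_volume <- function(cell) {
  validate_cell(cell)
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  ca <- cos(al); cb <- cos(be); cg <- cos(ga)
  prod(cell[1:3]) * sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
}

# Cartesian (n x 3) -> fractional (n x 3)
cart_to_frac <- function(xyz, cell) {
  xyz <- matrix(xyz, ncol = 3)
  xyz %*% t(cell_frac_matrix(cell))
}

# fractional (n x 3) -> Cartesian (n x 3)
frac_to_cart <- function(frac, cell) {
  frac <- matrix(frac, ncol = 3)
  frac %*% t(cell_orth_matrix(cell))
}

#' Resolution of reflections
#'
#' Computes d-spacings (Angstrom) for Miller indices from the reciprocal
#' metric tensor of the cell: `1/d^2 = h' G* h`.
#'
#' @param hkl integer matrix (n x 3) of Miller indices.
#' @param cell unit cell, `c(a, b, c, alpha, beta, gamma)`.
#' @return numeric vector of d-spacings in Angstrom (`Inf` for (0,0,0)).
#' @export
d_spacing <- function(hkl, cell) {
  hkl <- matrix(hkl, ncol = 3)
  O <- cell_orth_matrix(cell)
  Gstar <- solve(t(O) %*% O)      # reciprocal metric tensor
  inv_d2 <- rowSums((hkl %*% Gstar) * hkl)
  ifelse(inv_d2 > 0, 1 / sqrt(inv_d2), Inf)
}

# sin(theta)/lambda = 1/(2 d)
stol <- function(hkl, cell) 1 / (2 * d_spacing(hkl, cell))
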