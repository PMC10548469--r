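#' Unit cell
#'
#' Construct a crystallographic unit cell from edge lengths (Angstrom) and
#' inter-axial angles (degrees). The cell must describe a proper (positive
#' volume) lattice: all lengths positive, all angles strictly between 0 and
#' 180 degrees, and the direct metric tensor positive definite.
#'
#' @param a,b,c cell edge lengths in Angstrom.
#' @param alpha,beta,gamma inter-axial angles in degrees (alpha between b and
#'   c, beta between a and c, gamma between a and b).
#' @return An object of class `unit_cell`.
#' @examples
#' uc <- unit_cell(9.968, 11.207, 13.394, 100.86, 104.42, 101.63)
#' cell_volume(uc)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  a <- unname(a); b <- unname(b); c <- unname(c)
  alpha <- unname(alpha); beta <- unname(beta); gamma <- unname(gamma)
  len <- c(a = a, b = b, c = c)
  ang <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(len)) || any(len <= 0)) {
    stop("unit cell lengths must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180)) {
    stop("unit cell angles must lie strictly between 0 and 180 degrees",
         call. = FALSE)
  }
  cell <- structure(list(a = a, b = b, c = c,
                         alpha = alpha, beta = beta, gamma = gamma),
                    class = "unit_cell")
  # positive-definite metric <=> real positive volume
  v2 <- .cell_volume_sq(cell)
  if (!is.finite(v2) || v2 <= 0) {
    stop("unit cell angles are geometrically inconsistent (non-positive volume)",
         call. = FALSE)
  }
  cell
}

.deg2rad <- function(x) x * pi / 180

.cell_volume_sq <- function(cell) {
  ca <- cos(.deg2rad(cell$alpha))
  cb <- cos(.deg2rad(cell$beta))
  cg <- cos(.deg2rad(cell$gamma))
  (cell$a * cell$b * cell$c)^2 *
    (1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
}

#' Cell volume
#'
#' @param cell a [unit_cell()].
#' @return Volume in cubic Angstrom (closed-form triclinic formula).
#' @export
cell_volume <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  sqrt(.cell_volume_sq(cell))
}

#' Cartesian basis matrix of a unit cell
#'
#' Columns are the Cartesian cell vectors a, b, c (Angstrom) under the fixed
#' convention used throughout the package: a along +x, b in the xy-plane with
#' positive y-component, right-handed frame (so c has a positive z-component
#' and the c* reciprocal axis points along +z).
#'
#' @param cell a [unit_cell()].
#' @return 3x3 numeric matrix whose columns are the cell vectors.
#' @export
cell_basis <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  ca <- cos(.deg2rad(cell$alpha))
  cb <- cos(.deg2rad(cell$beta))
  cg <- cos(.deg2rad(cell$gamma))
  sg <- sin(.deg2rad(cell$gamma))
  av <- c(cell$a, 0, 0)
  bv <- c(cell$b * cg, cell$b * sg, 0)
  cx <- cell$c * cb
  cy <- cell$c * (ca - cb * cg) / sg
  cz <- sqrt(max(cell$c^2 - cx^2 - cy^2, 0))
  cbind(a = av, b = bv, c = c(cx, cy, cz))
}

#' Fractional to Cartesian coordinates
#'
#' @param cell a [unit_cell()].
#' @param frac numeric vector of length 3, or an n x 3 matrix of fractional
#'   coordinates (rows are points).
#' @return Cartesian coordinates (Angstrom) with the same shape.
#' @seealso [cart_to_frac()]
#' @export
frac_to_cart <- function(cell, frac) {
  B <- cell_basis(cell)
  if (is.matrix(frac)) {
    out <- frac %*% t(B)
    colnames(out) <- c("x", "y", "z")
    out
  } else {
    drop(B %*% frac)
  }
}

#' Cartesian to fractional coordinates
#'
#' Inverse of [frac_to_cart()]; the round trip reproduces coordinates to
#' better than 1e-10 Angstrom.
#'
#' @inheritParams frac_to_cart
#' @param cart Cartesian coordinates (vector of length 3 or n x 3 matrix).
#' @export
cart_to_frac <- function(cell, cart) {
  Binv <- solve(cell_basis(cell))
  if (is.matrix(cart)) {
    out <- cart %*% t(Binv)
    colnames(out) <- c("fx", "fy", "fz")
    out
  } else {
    drop(Binv %*% cart)
  }
}

#' Miller index in canonical form
#'
#' Reduces (h k l) to lowest integer terms and applies the deterministic sign
#' convention that the first nonzero component is positive. The all-zero
#' index is rejected.
#'
#' @param h,k,l integers, or `h` may be a length-3 vector.
#' @param reduce reduce to lowest terms (default TRUE). Set FALSE to keep a
#'   multiple such as (0 2 0), e.g. when probing sub-layer spacings.
#' @return Integer vector of length 3 with class `miller_index`.
#' @export
miller_index <- function(h, k = NULL, l = NULL, reduce = TRUE) {
  hkl <- if (length(h) == 3 && is.null(k)) as.numeric(h) else as.numeric(c(h, k, l))
  if (length(hkl) != 3 || any(!is.finite(hkl)) || any(hkl != round(hkl))) {
    stop("Miller index must be three finite integers", call. = FALSE)
  }
  hkl <- as.integer(round(hkl))
  if (all(hkl == 0L)) stop("Miller index (0 0 0) is not a lattice plane", call. = FALSE)
  if (reduce) {
    g <- .gcd3(abs(hkl))
    hkl <- hkl %/% g
  }
  first <- hkl[which(hkl != 0L)[1]]
  if (first < 0L) hkl <- -hkl
  structure(hkl, class = "miller_index")
}

.gcd2 <- function(a, b) if (b == 0L) a else .gcd2(b, a %% b)
.gcd3 <- function(v) {
  v <- v[v != 0L]
  g <- v[1]
  for (x in v[-1]) g <- .gcd2(g, x)
  g
}

#' Interplanar d-spacing
#'
#' Perpendicular distance between adjacent (h k l) lattice planes, computed
#' from the reciprocal basis: d = 1 / |h a* + k b* + l c*|. Valid for any
#' triclinic cell.
#'
#' @param cell a [unit_cell()].
#' @param hkl a [miller_index()] or length-3 integer vector (not reduced here:
#'   d for (0 2 0) is half that of (0 1 0)).
#' @return d-spacing in Angstrom.
#' @examples
#' d_spacing(unit_cell(4, 4, 4), c(1, 1, 0))  # 4 / sqrt(2)
#' @export
d_spacing <- function(cell, hkl) {
  hkl <- as.numeric(hkl)
  if (length(hkl) != 3 || all(hkl == 0)) {
    stop("d-spacing requires a non-zero (h k l)", call. = FALSE)
  }
  # rows of solve(B) are the reciprocal vectors a*, b*, c* (no 2 pi factor)
  g <- drop(hkl %*% solve(cell_basis(cell)))
  1 / sqrt(sum(g^2))
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell: a=%.4f b=%.4f c=%.4f Angstrom; alpha=%.3f beta=%.3f gamma=%.3f deg; V=%.3f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, cell_volume(x)))
  invisible(x)
}

#' @export
print.miller_index <- function(x, ...) {
  cat(sprintf("(%d %d %d)\n", x[1], x[2], x[3]))
  invisible(x)
}
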