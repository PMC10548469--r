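# Element data: covalent radii (Cordero-style, Angstrom) used for bond
# detection, plus default van der Waals placeholders for unparameterized work.
.pt <- data.frame(
  symbol = c("H", "B", "C", "N", "O", "F", "Na", "Mg", "Al", "Si", "P", "S",
             "Cl", "K", "Ca", "Br", "I", "X", "Y", "Z"),
  r_cov = c(0.31, 0.84, 0.76, 0.71, 0.66, 0.57, 1.66, 1.41, 1.21, 1.11, 1.07,
            1.05, 1.02, 2.03, 1.76, 1.20, 1.39, 0.60, 0.60, 0.60),
  stringsAsFactors = FALSE
)
# X/Y/Z are reserved toy elements for the fixture generators.

#' Crystal structure
#'
#' Container for a unit cell, the asymmetric-unit atom sites, and the
#' fractional symmetry operators. On construction the structure is
#' symmetry-expanded to P1, duplicate images are merged (1e-3 Angstrom
#' tolerance), a clash check rejects overlapping distinct sites, and atoms
#' are grouped into molecular units by covalent-radius bond detection
#' (bonded if closer than 1.15 x the sum of covalent radii, minimum-image).
#' Units are unfolded across periodic boundaries so each molecule is whole.
#'
#' @param cell a [unit_cell()].
#' @param sites data.frame with columns `label`, `element`, `fx`, `fy`, `fz`
#'   and optionally `charge`, `type` (force-field type) and `formal_charge`
#'   (per molecular unit, applied by [assign_types_and_charges()]).
#' @param ops list of symmetry operators as returned by [parse_symop()];
#'   identity-only by default.
#' @param spacegroup informational space-group label.
#' @param clash_tol distinct expanded sites closer than this (Angstrom) are an
#'   error; merged instead if closer than `merge_tol`.
#' @param merge_tol duplicate-image merge tolerance (Angstrom).
#' @return Object of class `crystal_structure` with the expanded P1 cell
#'   cached in `$expanded` (see [expand_structure()]).
#' @export
crystal_structure <- function(cell, sites, ops = list(parse_symop("x,y,z")),
                              spacegroup = "P 1", clash_tol = 0.5,
                              merge_tol = 1e-3) {
  stopifnot(inherits(cell, "unit_cell"), is.data.frame(sites))
  need <- c("label", "element", "fx", "fy", "fz")
  if (!all(need %in% names(sites))) {
    stop("sites must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(sites) == 0) stop("structure needs at least one atom site", call. = FALSE)
  if (any(!is.finite(as.matrix(sites[, c("fx", "fy", "fz")])))) {
    stop("fractional coordinates must be finite", call. = FALSE)
  }
  if (!"charge" %in% names(sites)) sites$charge <- NA_real_
  if (!"type" %in% names(sites)) sites$type <- NA_character_
  if (!"formal_charge" %in% names(sites)) sites$formal_charge <- 0
  bad <- setdiff(unique(sites$element), .pt$symbol)
  if (length(bad) > 0) {
    stop("unrecognized element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  st <- structure(list(cell = cell, sites = sites, ops = ops,
                       spacegroup = spacegroup),
                  class = "crystal_structure")
  st$expanded <- .expand_p1(st, clash_tol = clash_tol, merge_tol = merge_tol)
  st
}

# Apply all symmetry operators, fold to [0,1), merge duplicates, clash-check,
# detect molecular units and unfold them to be whole.
.expand_p1 <- function(st, clash_tol = 0.5, merge_tol = 1e-3) {
  sites <- st$sites
  nops <- length(st$ops)
  frac0 <- as.matrix(sites[, c("fx", "fy", "fz")])
  all_frac <- NULL
  op_id <- integer(0)
  site_id <- integer(0)
  for (k in seq_len(nops)) {
    op <- st$ops[[k]]
    f <- t(op$R %*% t(frac0) + op$t)
    f <- f - floor(f)
    all_frac <- rbind(all_frac, f)
    op_id <- c(op_id, rep(k, nrow(f)))
    site_id <- c(site_id, seq_len(nrow(f)))
  }
  B <- cell_basis(st$cell)
  n <- nrow(all_frac)
  # duplicate merge + clash check with minimum-image distances
  keep <- rep(TRUE, n)
  if (n > 1) {
    for (i in 2:n) {
      df <- sweep(all_frac[1:(i - 1), , drop = FALSE], 2, all_frac[i, ])
      df <- df - round(df)
      d <- sqrt(rowSums((df %*% t(B))^2))
      j <- which(keep[1:(i - 1)] & d < merge_tol)
      if (length(j) > 0) { keep[i] <- FALSE; next }
      j <- which(keep[1:(i - 1)] & d < clash_tol)
      if (length(j) > 0) {
        stop(sprintf(
          "symmetry-expanded sites %s and %s overlap (%.3f Angstrom apart)",
          sites$label[site_id[j[1]]], sites$label[site_id[i]], min(d[keep[1:(i-1)]])),
          call. = FALSE)
      }
    }
  }
  frac <- all_frac[keep, , drop = FALSE]
  op_id <- op_id[keep]
  site_id <- site_id[keep]
  m <- nrow(frac)

  # bond detection (minimum image) and connected components
  rc <- .pt$r_cov[match(sites$element[site_id], .pt$symbol)]
  unit <- integer(m)
  shift <- matrix(0, m, 3)       # lattice shifts applied to unfold units
  nb <- vector("list", m)
  nbshift <- vector("list", m)
  if (m > 1) {
    for (i in 1:(m - 1)) {
      df <- sweep(frac[(i + 1):m, , drop = FALSE], 2, frac[i, ])
      sh <- -round(df)
      dfm <- df + sh
      d <- sqrt(rowSums((dfm %*% t(B))^2))
      bonded <- which(d < 1.15 * (rc[i] + rc[(i + 1):m]) & d > 1e-6)
      for (b in bonded) {
        j <- i + b
        nb[[i]] <- c(nb[[i]], j)
        nbshift[[i]] <- rbind(nbshift[[i]], sh[b, ])   # unfolds j next to i
        nb[[j]] <- c(nb[[j]], i)
        nbshift[[j]] <- rbind(nbshift[[j]], -sh[b, ])
      }
    }
  }
  uid <- 0L
  for (seed in seq_len(m)) {
    if (unit[seed] != 0L) next
    uid <- uid + 1L
    unit[seed] <- uid
    shift[seed, ] <- 0
    queue <- seed
    while (length(queue) > 0) {
      i <- queue[1]; queue <- queue[-1]
      if (length(nb[[i]]) == 0) next
      for (b in seq_along(nb[[i]])) {
        j <- nb[[i]][b]
        if (unit[j] == 0L) {
          unit[j] <- uid
          shift[j, ] <- shift[i, ] + nbshift[[i]][b, ]
          queue <- c(queue, j)
        }
      }
    }
  }
  ufrac <- frac + shift        # unfolded: units whole, may leave [0,1)
  cart <- ufrac %*% t(B)
  atoms <- data.frame(
    label = sites$label[site_id],
    element = sites$element[site_id],
    x = cart[, 1], y = cart[, 2], z = cart[, 3],
    fx = ufrac[, 1], fy = ufrac[, 2], fz = ufrac[, 3],
    charge = sites$charge[site_id],
    type = sites$type[site_id],
    formal_charge = sites$formal_charge[site_id],
    unit = unit, op = op_id, site = site_id,
    stringsAsFactors = FALSE, row.names = NULL)
  list(atoms = atoms, n_units = uid, n_ops = nops)
}

#' Symmetry-expanded P1 content of a structure
#'
#' @param structure a `crystal_structure`.
#' @return list with `atoms` (data.frame: element, Cartesian and fractional
#'   coordinates, charge, type, molecular `unit` id, generating operator
#'   `op`, asymmetric-unit `site` index), `n_units`, `n_ops`. Units are
#'   unfolded so molecules are whole; fractional coordinates may therefore
#'   lie slightly outside `[0,1)`.
#' @export
expand_structure <- function(structure) {
  stopifnot(inherits(structure, "crystal_structure"))
  structure$expanded
}

#' Number of molecular units in the expanded cell
#' @param structure a `crystal_structure`.
#' @export
n_molecular_units <- function(structure) expand_structure(structure)$n_units

#' Build a finite supercell body
#'
#' Replicates the symmetry-expanded P1 cell na x nb x nc times and returns
#' the result as a finite rigid [body()] (no periodicity). Molecular units
#' stay whole; unit ids are renumbered per replica.
#'
#' @param structure a `crystal_structure`.
#' @param na,nb,nc replication counts (>= 1) along a, b, c.
#' @param origin integer cell offset of the first replica (default c(0,0,0)).
#' @return A [body()] with `na*nb*nc` copies of the expanded cell.
#' @export
build_supercell <- function(structure, na = 1, nb = 1, nc = 1,
                            origin = c(0L, 0L, 0L)) {
  stopifnot(inherits(structure, "crystal_structure"))
  if (any(c(na, nb, nc) < 1)) stop("replication counts must be >= 1", call. = FALSE)
  exp <- expand_structure(structure)
  B <- cell_basis(structure$cell)
  cells <- as.matrix(expand.grid(ia = seq_len(na) - 1 + origin[1],
                                 ib = seq_len(nb) - 1 + origin[2],
                                 ic = seq_len(nc) - 1 + origin[3]))
  at <- exp$atoms
  nrep <- nrow(cells)
  idx <- rep(seq_len(nrow(at)), times = nrep)
  rep_id <- rep(seq_len(nrep), each = nrow(at))
  disp <- cells[rep_id, , drop = FALSE] %*% t(B)
  atoms <- at[idx, , drop = FALSE]
  atoms$x <- atoms$x + disp[, 1]
  atoms$y <- atoms$y + disp[, 2]
  atoms$z <- atoms$z + disp[, 3]
  atoms$unit <- atoms$unit + (rep_id - 1L) * exp$n_units
  atoms$cell_ia <- cells[rep_id, 1]
  atoms$cell_ib <- cells[rep_id, 2]
  atoms$cell_ic <- cells[rep_id, 3]
  rownames(atoms) <- NULL
  body(atoms, label = sprintf("%s supercell %dx%dx%d",
                              structure$spacegroup, na, nb, nc))
}

#' @export
print.crystal_structure <- function(x, ...) {
  cat(sprintf("crystal structure [%s]: %d asymmetric-unit site(s), %d operator(s), %d molecular unit(s)/cell\n",
              x$spacegroup, nrow(x$sites), length(x$ops), x$expanded$n_units))
  print(x$cell)
  invisible(x)
}
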