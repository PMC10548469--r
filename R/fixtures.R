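# Deterministic toy-crystal generators. These emulate the structural
# features the production code must handle - P1 and 2_1-screw cells,
# neutral molecular crystals, a hydrate-like water carrier, and an ionic
# multi-body asymmetric unit - without any external structure database.
# Toy atoms use the reserved elements X/Y/Z with explicit force-field
# types so the packaged Dreiding-style table is never touched.

#' Toy force-field parameters for generated structures
#'
#' Builds an [ff_params()] whose table contains the custom types a fixture
#' generator attached to its structure (attribute `"ff_extra"`), on top of
#' the packaged defaults.
#'
#' @param structure a fixture `crystal_structure` (or [body()]).
#' @param ... passed to [ff_params()] (e.g. `cutoff`).
#' @export
toy_ff_params <- function(structure, ...) {
  ff_params(extra = attr(structure, "ff_extra"), ...)
}

#' Simple-cubic Lennard-Jones crystal
#'
#' One neutral atom per P1 cubic cell with a custom 12-6 type: the analytic
#' oracle substrate. With `a = R0` and a nearest-neighbor-only cutoff its
#' lattice energy is exactly -3 D0 per atom (6 neighbors at the well
#' minimum, halved), its (0 0 1) slice energy -2 D0 and attachment energy
#' -D0.
#'
#' @param a cell edge (Angstrom).
#' @param D0 well depth (kcal/mol).
#' @param R0 equilibrium distance (Angstrom), default `a`.
#' @return `crystal_structure` with attribute `"ff_extra"` for
#'   [toy_ff_params()].
#' @export
make_sc_lj <- function(a = 3.5, D0 = 0.2, R0 = a) {
  stopifnot(a > 0, D0 >= 0, R0 > 0)
  sites <- data.frame(label = "X1", element = "X", fx = 0, fy = 0, fz = 0,
                      charge = 0, type = "X_sc", stringsAsFactors = FALSE)
  st <- crystal_structure(unit_cell(a, a, a), sites, spacegroup = "P 1 (toy sc)")
  attr(st, "ff_extra") <- data.frame(type = "X_sc", D0 = D0, R0 = R0,
                                     stringsAsFactors = FALSE)
  st
}

#' Rock-salt toy crystal
#'
#' Two interpenetrating fcc sublattices of point charges +q and -q in a P1
#' conventional cubic cell (8 ions, net charge zero): the electrostatic
#' oracle substrate, whose direct lattice sum under neutral-shell (whole
#' cell) summation approaches the rock-salt Madelung constant 1.7476.
#' The van der Waals well depth is set to zero so the energy is purely
#' Coulombic.
#'
#' @param a conventional cubic cell edge (Angstrom); nearest-neighbor
#'   distance is `a/2`.
#' @param q ion charge magnitude (e).
#' @export
make_rocksalt <- function(a = 5.64, q = 1) {
  stopifnot(a > 0, q > 0)
  cat_f <- rbind(c(0, 0, 0), c(.5, .5, 0), c(.5, 0, .5), c(0, .5, .5))
  an_f <- rbind(c(.5, 0, 0), c(0, .5, 0), c(0, 0, .5), c(.5, .5, .5))
  sites <- data.frame(
    label = c(paste0("CAT", 1:4), paste0("ANI", 1:4)),
    element = c(rep("X", 4), rep("Y", 4)),
    fx = c(cat_f[, 1], an_f[, 1]),
    fy = c(cat_f[, 2], an_f[, 2]),
    fz = c(cat_f[, 3], an_f[, 3]),
    charge = c(rep(q, 4), rep(-q, 4)),
    type = c(rep("X_ion", 4), rep("Y_ion", 4)),
    stringsAsFactors = FALSE)
  st <- crystal_structure(unit_cell(a, a, a), sites,
                          spacegroup = "P 1 (toy rock salt)")
  attr(st, "ff_extra") <- data.frame(type = c("X_ion", "Y_ion"),
                                     D0 = c(0, 0), R0 = c(1.5, 1.5),
                                     stringsAsFactors = FALSE)
  st
}

#' Diatomic molecular toy crystal
#'
#' One rigid X-Y diatomic per cell in P1 (or two per cell under the 2_1
#' screw operator `-x, y+1/2, -z`), optionally polar with opposite partial
#' charges on the two atoms, and optionally with a second molecule in the
#' basis at a different height - the substrate for molecular-unit
#' detection, termination scanning and first-molecular-layer probe slabs.
#'
#' @param cell length-3 cell edges (Angstrom) or a [unit_cell()].
#' @param bond_length X-Y bond length (Angstrom), along x.
#' @param charges length-2 partial charges for X and Y (e).
#' @param p21 add the 2_1 screw operator (two molecules per cell).
#' @param z fractional height of the (first) molecule.
#' @param second_z optional fractional height of a second basis molecule
#'   (P1 only), giving a two-molecule basis with a strongly bound layer
#'   pairing when the two heights are close.
#' @param D0,R0 van der Waals parameters of the toy types.
#' @export
make_diatomic_molecular <- function(cell = c(6, 6, 8), bond_length = 1.2,
                                    charges = c(0, 0), p21 = FALSE,
                                    z = 0.25, second_z = NULL,
                                    D0 = 0.15, R0 = 3.4) {
  uc <- if (inherits(cell, "unit_cell")) cell
        else unit_cell(cell[1], cell[2], cell[3])
  stopifnot(bond_length > 0, bond_length < min(uc$a, uc$b, uc$c))
  half <- bond_length / 2 / uc$a
  sites <- data.frame(
    label = c("X1", "Y1"), element = c("X", "Y"),
    fx = c(0.5 - half, 0.5 + half), fy = c(0.5, 0.5), fz = c(z, z),
    charge = charges, type = c("X_di", "Y_di"),
    stringsAsFactors = FALSE)
  if (!is.null(second_z)) {
    if (p21) stop("second_z is for P1 two-molecule bases", call. = FALSE)
    sites <- rbind(sites, data.frame(
      label = c("X2", "Y2"), element = c("X", "Y"),
      fx = c(0.5 - half, 0.5 + half), fy = c(0.5, 0.5),
      fz = c(second_z, second_z),
      charge = charges, type = c("X_di", "Y_di"),
      stringsAsFactors = FALSE))
  }
  ops <- if (p21) list(parse_symop("x,y,z"), parse_symop("-x,y+1/2,-z"))
         else list(parse_symop("x,y,z"))
  st <- crystal_structure(uc, sites, ops = ops,
                          spacegroup = if (p21) "P 21 (toy)" else "P 1 (toy)")
  attr(st, "ff_extra") <- data.frame(type = c("X_di", "Y_di"),
                                     D0 = c(D0, D0), R0 = c(R0, R0),
                                     stringsAsFactors = FALSE)
  st
}

#' Hydrate-like toy crystal
#'
#' A diatomic host molecule plus a small bent water molecule (real O and H
#' elements) in each P1 cell, exercising the hydrogen-bond pathway: the
#' water oxygen is an acceptor and its hydrogens are donors. The water can
#' be excluded, mirroring the choice of whether hydrate water belongs to
#' probe molecules and slabs.
#'
#' @param cell length-3 cell edges (Angstrom).
#' @param include_water keep the water molecule (default TRUE).
#' @param water_charge_O partial charge on O (H gets half the opposite).
#' @export
make_hydrate_like <- function(cell = c(7, 7, 9), include_water = TRUE,
                              water_charge_O = -0.8) {
  uc <- unit_cell(cell[1], cell[2], cell[3])
  sites <- data.frame(
    label = c("X1", "Y1"), element = c("X", "Y"),
    fx = c(0.42, 0.58), fy = c(0.5, 0.5), fz = c(0.25, 0.25),
    charge = c(0.2, -0.2), type = c("X_di", "Y_di"),
    stringsAsFactors = FALSE)
  if (include_water) {
    # bent O-H2 geometry, ~0.96 Angstrom bonds, in the next layer
    ow <- c(0.5, 0.5, 0.62)
    h1 <- ow + c(0.76, 0.0, 0.59) * 0.96 / cell[c(1, 2, 3)]
    h2 <- ow + c(-0.76, 0.0, 0.59) * 0.96 / cell[c(1, 2, 3)]
    sites <- rbind(sites, data.frame(
      label = c("OW", "HW1", "HW2"), element = c("O", "H", "H"),
      fx = c(ow[1], h1[1], h2[1]), fy = c(ow[2], h1[2], h2[2]),
      fz = c(ow[3], h1[3], h2[3]),
      charge = c(water_charge_O, -water_charge_O / 2, -water_charge_O / 2),
      type = NA_character_, stringsAsFactors = FALSE))
  }
  st <- crystal_structure(uc, sites, spacegroup = "P 1 (toy hydrate)")
  attr(st, "ff_extra") <- data.frame(type = c("X_di", "Y_di"),
                                     D0 = c(0.15, 0.15), R0 = c(3.4, 3.4),
                                     stringsAsFactors = FALSE)
  st
}

#' Ionic-triplet toy crystal
#'
#' Two single-atom +1 cations and one -2 anion per P1 cell: the smallest
#' analogue of a tri-ionic (2 cation + 1 anion) asymmetric unit. The three
#' ions are separate molecular units and the cell is charge neutral.
#'
#' @param cell length-3 cell edges (Angstrom).
#' @export
make_ionic_triplet <- function(cell = c(6, 6, 6)) {
  uc <- unit_cell(cell[1], cell[2], cell[3])
  sites <- data.frame(
    label = c("CAT1", "CAT2", "ANI1"), element = c("X", "X", "Y"),
    fx = c(0.25, 0.75, 0.5), fy = c(0.25, 0.75, 0.5), fz = c(0.2, 0.2, 0.6),
    charge = NA_real_, type = c("X_ion", "X_ion", "Y_ion"),
    formal_charge = c(1, 1, -2),
    stringsAsFactors = FALSE)
  st <- crystal_structure(uc, sites, spacegroup = "P 1 (toy tri-ionic)")
  attr(st, "ff_extra") <- data.frame(type = c("X_ion", "Y_ion"),
                                     D0 = c(0.1, 0.1), R0 = c(3.0, 3.2),
                                     stringsAsFactors = FALSE)
  st
}

#' Extract one molecular unit of a structure as a finite body
#'
#' Convenience for building probe molecules from a crystal: returns the
#' atoms of the chosen molecular unit of the expanded cell.
#'
#' @param structure a `crystal_structure`.
#' @param unit molecular unit id (default 1).
#' @param label body label.
#' @export
extract_molecule <- function(structure, unit = 1, label = NULL) {
  exp <- expand_structure(structure)
  at <- exp$atoms[exp$atoms$unit == unit, , drop = FALSE]
  if (nrow(at) == 0) stop("no such molecular unit: ", unit, call. = FALSE)
  rownames(at) <- NULL
  # re-base hb donor indices onto the extracted subset
  b <- body(at, label = label %||% sprintf("molecule unit %d", unit))
  b
}
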