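#' Force-field parameter set
#'
#' Loads the nonbonded parameter table (Dreiding-style 12-6 van der Waals
#' well depths `D0` in kcal/mol and equilibrium distances `R0` in Angstrom
#' per atom type) together with the global constants of the energy model:
#' the Coulomb constant, the dielectric constant, the nonbond cutoff, and
#' the 12-10 hydrogen-bond term parameters.
#'
#' @param file optional path to a parameter CSV with columns `type`, `D0`,
#'   `R0`; defaults to the packaged Dreiding-style table.
#' @param extra optional data.frame of additional rows (`type`, `D0`, `R0`),
#'   e.g. custom types for toy crystals; overrides duplicated types.
#' @param epsilon relative dielectric constant (>= 1, default 1 = vacuum).
#' @param cutoff nonbond cutoff radius in Angstrom (plain truncation).
#' @param hb_D0,hb_R0 hydrogen-bond 12-10 well depth (kcal/mol) and
#'   equilibrium donor-acceptor distance (Angstrom).
#' @param hb_cutoff donor-acceptor distance beyond which the hydrogen-bond
#'   term (and its replacement of the donor-acceptor van der Waals term) is
#'   not applied.
#' @param d0_mixing,r0_mixing combination rules for unlike pairs:
#'   `D0` geometric mean and `R0` arithmetic mean by default.
#' @return Object of class `ff_params`.
#' @export
ff_params <- function(file = NULL, extra = NULL, epsilon = 1, cutoff = 15,
                      hb_D0 = 9.5, hb_R0 = 2.75, hb_cutoff = 4.5,
                      d0_mixing = c("geometric", "arithmetic"),
                      r0_mixing = c("arithmetic", "geometric")) {
  if (is.null(file)) {
    file <- system.file("extdata", "dreiding_params.csv", package = "synthsearch")
  }
  types <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("type", "D0", "R0") %in% names(types))) {
    stop("parameter file needs columns type, D0, R0", call. = FALSE)
  }
  if (!is.null(extra)) {
    stopifnot(all(c("type", "D0", "R0") %in% names(extra)))
    types <- types[!types$type %in% extra$type, , drop = FALSE]
    types <- rbind(types[, c("type", "D0", "R0")],
                   extra[, c("type", "D0", "R0")])
  }
  if (any(types$D0 < 0) || any(types$R0 <= 0)) {
    stop("invalid parameters: need D0 >= 0 and R0 > 0", call. = FALSE)
  }
  if (epsilon < 1) stop("dielectric constant must be >= 1", call. = FALSE)
  if (cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)
  structure(list(
    types = types[, c("type", "D0", "R0")],
    ke = 332.0637,           # kcal Angstrom / (mol e^2)
    epsilon = epsilon,
    cutoff = cutoff,
    hb_D0 = hb_D0, hb_R0 = hb_R0, hb_cutoff = hb_cutoff,
    d0_mixing = match.arg(d0_mixing),
    r0_mixing = match.arg(r0_mixing)
  ), class = "ff_params")
}

.ff_lookup <- function(params, types, what) {
  i <- match(types, params$types$type)
  if (anyNA(i)) {
    stop("no force-field parameters for type(s): ",
         paste(unique(types[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  params$types[[what]][i]
}

#' Rigid body of atoms
#'
#' A finite rigid collection of atoms (a molecule, a dimer, or a slab) in
#' Cartesian coordinates, the common currency of the systematic search:
#' hosts and probes are both bodies.
#'
#' @param atoms data.frame with at least `element`, `x`, `y`, `z`; optional
#'   `charge` (e), `type` (force-field atom type), `unit` (molecular unit
#'   id), `hb_role` ("donor-H", "acceptor" or "none") and `hb_donor`
#'   (for donor hydrogens, row index of the bonded heavy atom).
#' @param label identity label, e.g. `"API molecule"` or `"carrier {010} slab"`.
#' @return Object of class `body`.
#' @export
body <- function(atoms, label = "body") {
  stopifnot(is.data.frame(atoms))
  need <- c("element", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    stop("body atoms need columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(atoms) < 1) stop("a body needs at least one atom", call. = FALSE)
  if (!"charge" %in% names(atoms)) atoms$charge <- NA_real_
  if (!"type" %in% names(atoms)) atoms$type <- NA_character_
  if (!"unit" %in% names(atoms)) atoms$unit <- 1L
  if (!"hb_role" %in% names(atoms)) atoms$hb_role <- "none"
  if (!"hb_donor" %in% names(atoms)) atoms$hb_donor <- NA_integer_
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, label = label), class = "body")
}

#' @export
print.body <- function(x, ...) {
  cat(sprintf("body '%s': %d atoms, %d molecular unit(s), net charge %s e\n",
              x$label, nrow(x$atoms), length(unique(x$atoms$unit)),
              if (all(is.na(x$atoms$charge))) "unset"
              else sprintf("%+.3f", sum(x$atoms$charge))))
  invisible(x)
}

#' Number of atoms in a body
#' @param x a [body()].
#' @export
n_atoms <- function(x) nrow(x$atoms)

#' Centroid of a body (Angstrom)
#' @param x a [body()].
#' @export
centroid <- function(x) {
  colMeans(as.matrix(x$atoms[, c("x", "y", "z")]))
}

# bonds within a finite body by covalent radii (no periodicity)
.body_bonds <- function(atoms) {
  n <- nrow(atoms)
  if (n < 2) return(data.frame(i = integer(0), j = integer(0)))
  rc <- .pt$r_cov[match(atoms$element, .pt$symbol)]
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  out_i <- integer(0); out_j <- integer(0)
  for (i in 1:(n - 1)) {
    dv <- sweep(xyz[(i + 1):n, , drop = FALSE], 2, xyz[i, ])
    d <- sqrt(rowSums(dv^2))
    hit <- which(d < 1.15 * (rc[i] + rc[(i + 1):n]) & d > 1e-6)
    out_i <- c(out_i, rep(i, length(hit)))
    out_j <- c(out_j, i + hit)
  }
  data.frame(i = out_i, j = out_j)
}

# Gasteiger-Marsili electronegativity coefficients a + b q + c q^2 keyed by
# assigned atom type (hybridization-aware where it matters).
.gasteiger_abc <- function(types, elements) {
  key <- function(t, e) switch(t,
    "H_" = , "H__HB" = c(7.17, 6.24, -0.56),
    "C_3" = c(7.98, 9.18, 1.88),
    "C_2" = , "C_R" = c(8.79, 9.32, 1.51),
    "C_1" = c(10.39, 9.45, 0.73),
    "N_3" = c(11.54, 10.82, 1.36),
    "N_2" = , "N_R" = c(12.87, 11.15, 0.85),
    "N_1" = c(15.68, 11.70, -0.27),
    "O_3" = c(14.18, 12.92, 1.39),
    "O_2" = , "O_R" = c(17.07, 13.79, 0.47),
    "F_" = c(14.66, 13.85, 2.31),
    "Cl" = c(11.00, 9.69, 1.35),
    "Br" = c(10.08, 8.47, 1.16),
    "I_" = c(9.90, 7.96, 0.96),
    "S_3" = c(10.14, 9.13, 1.38),
    "P_3" = c(8.90, 8.24, 0.96),
    c(7.0, 6.0, 0.5))   # bland default for metals / toy types
  t(mapply(function(t, e) key(t, e), types, elements))
}

#' Assign force-field atom types and partial charges
#'
#' Dreiding-style hybridization types are inferred from element and bonded
#' neighbor count (e.g. 4-coordinate carbon is `C_3`, 3-coordinate `C_2`;
#' hydrogen bonded to N/O/F becomes the donor type `H__HB`). Hydrogen-bond
#' roles are recorded: such hydrogens are donors, and N/O/F atoms are
#' acceptors. Charges come from the chosen scheme: an iterative
#' partial-equalization (Gasteiger-style) calculation seeded with each
#' molecular unit's formal charge, a user table keyed by site label, or
#' `"none"` to leave preset charges untouched. Atoms that already carry a
#' type keep it (so toy-crystal types survive).
#'
#' @param x a `crystal_structure` or [body()].
#' @param charge_scheme `"gasteiger"` (default), `"table"` or `"none"`.
#' @param charge_table for `"table"`: data.frame with columns `label`,
#'   `charge`.
#' @param params [ff_params()] used only to verify every assigned type is
#'   parameterized.
#' @return The input object with `type`, `charge`, `hb_role`, `hb_donor`
#'   filled in; the charge scheme used is recorded in attribute
#'   `charge_scheme`.
#' @export
assign_types_and_charges <- function(x, charge_scheme = c("gasteiger", "table", "none"),
                                     charge_table = NULL, params = ff_params()) {
  charge_scheme <- match.arg(charge_scheme)
  if (inherits(x, "crystal_structure")) {
    exp <- expand_structure(x)
    b <- body(exp$atoms, label = x$spacegroup)
    b <- assign_types_and_charges(b, charge_scheme, charge_table, params)
    x$expanded$atoms <- cbind(
      b$atoms[, c("label", "element", "x", "y", "z")],
      exp$atoms[, c("fx", "fy", "fz")],
      b$atoms[, c("charge", "type")],
      exp$atoms[, c("formal_charge", "unit", "op", "site")],
      b$atoms[, c("hb_role", "hb_donor")])
    # write types/charges back to the asymmetric unit (first image per site)
    first <- match(seq_len(nrow(x$sites)), x$expanded$atoms$site)
    x$sites$type <- x$expanded$atoms$type[first]
    x$sites$charge <- x$expanded$atoms$charge[first]
    attr(x, "charge_scheme") <- charge_scheme
    return(x)
  }
  stopifnot(inherits(x, "body"))
  at <- x$atoms
  bonds <- .body_bonds(at)
  deg <- tabulate(c(bonds$i, bonds$j), nbins = nrow(at))
  nbrs <- function(i) c(bonds$j[bonds$i == i], bonds$i[bonds$j == i])

  untyped <- which(is.na(at$type) | at$type == "")
  for (i in untyped) {
    e <- at$element[i]
    d <- deg[i]
    at$type[i] <- switch(e,
      "H" = {
        nb <- nbrs(i)
        if (length(nb) > 0 && any(at$element[nb] %in% c("N", "O", "F")))
          "H__HB" else "H_"
      },
      "C" = if (d >= 4) "C_3" else if (d == 3) "C_2" else "C_1",
      "N" = if (d >= 4 || d == 3) "N_3" else if (d == 2) "N_2" else "N_1",
      "O" = if (d >= 2) "O_3" else "O_2",
      "S" = "S_3", "P" = "P_3", "F" = "F_", "Cl" = "Cl", "Br" = "Br",
      "I" = "I_", "B" = "B_3", "Si" = "Si3", "Na" = "Na", "K" = "K_",
      "Mg" = "Mg", "Ca" = "Ca",
      "X" = "X_", "Y" = "Y_", "Z" = "Z_",   # reserved toy elements

      stop("no typing rule / force-field entry for element '", e, "'",
           call. = FALSE))
  }
  .ff_lookup(params, at$type, "D0")   # errors on unparameterized types

  # hydrogen-bond roles
  at$hb_role <- "none"
  at$hb_donor <- NA_integer_
  acc <- at$element %in% c("N", "O", "F")
  at$hb_role[acc] <- "acceptor"
  for (i in which(at$type == "H__HB")) {
    nb <- nbrs(i)
    heavy <- nb[at$element[nb] %in% c("N", "O", "F")]
    if (length(heavy) > 0) {
      at$hb_role[i] <- "donor-H"
      at$hb_donor[i] <- heavy[1]
    }
  }

  if (charge_scheme == "gasteiger") {
    at$charge <- .gasteiger(at, bonds)
  } else if (charge_scheme == "table") {
    if (is.null(charge_table) ||
        !all(c("label", "charge") %in% names(charge_table))) {
      stop("charge_table with columns label, charge is required", call. = FALSE)
    }
    j <- match(at$label, charge_table$label)
    if (anyNA(j)) {
      stop("charge table has no entry for label(s): ",
           paste(unique(at$label[is.na(j)]), collapse = ", "), call. = FALSE)
    }
    at$charge <- charge_table$charge[j]
  } else {
    if (anyNA(at$charge)) at$charge[is.na(at$charge)] <- 0
  }
  x$atoms <- at
  attr(x, "charge_scheme") <- charge_scheme
  x
}

# Iterative partial equalization of orbital electronegativity. Charge flows
# only along bonds, so each molecular unit's total charge is conserved at
# the formal charge it was seeded with (formal charge spread uniformly).
.gasteiger <- function(at, bonds, n_iter = 8) {
  n <- nrow(at)
  q <- numeric(n)
  if ("formal_charge" %in% names(at) && "unit" %in% names(at)) {
    for (u in unique(at$unit)) {
      idx <- which(at$unit == u)
      q[idx] <- sum(at$formal_charge[idx]) / length(idx)
    }
  }
  if (nrow(bonds) == 0 || n == 1) return(q)
  abc <- .gasteiger_abc(at$type, at$element)
  chi_plus <- rowSums(abc)                     # chi at q = +1
  chi_plus[at$element == "H"] <- 20.02
  for (k in seq_len(n_iter)) {
    chi <- abc[, 1] + abc[, 2] * q + abc[, 3] * q^2
    damp <- 0.5^k
    dq <- numeric(n)
    for (b in seq_len(nrow(bonds))) {
      i <- bonds$i[b]; j <- bonds$j[b]
      if (chi[j] > chi[i]) {
        tr <- (chi[j] - chi[i]) / chi_plus[i] * damp
        dq[i] <- dq[i] + tr; dq[j] <- dq[j] - tr
      } else {
        tr <- (chi[i] - chi[j]) / chi_plus[j] * damp
        dq[j] <- dq[j] + tr; dq[i] <- dq[i] - tr
      }
    }
    q <- q + dq
  }
  q
}

#' Energy breakdown
#'
#' Total nonbonded interaction energy and its components, all kcal/mol:
#' dispersive (12-6 van der Waals), electrostatic (Coulomb), and the 12-10
#' hydrogen-bond term. The polar component is the sum of electrostatic and
#' hydrogen-bond parts; the total is the sum of all three primitives.
#'
#' @param dispersive,electrostatic,hbond component energies (kcal/mol).
#' @return Object of class `energy_breakdown` with fields `total`,
#'   `dispersive`, `electrostatic`, `hbond`, `polar`.
#' @export
energy_breakdown <- function(dispersive = 0, electrostatic = 0, hbond = 0) {
  structure(list(
    total = dispersive + electrostatic + hbond,
    dispersive = dispersive,
    electrostatic = electrostatic,
    hbond = hbond,
    polar = electrostatic + hbond
  ), class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("energy: total %.6f = vdW %.6f + elec %.6f + hbond %.6f kcal/mol (polar %.6f)\n",
              x$total, x$dispersive, x$electrostatic, x$hbond, x$polar))
  invisible(x)
}

# deterministic summation: sort before adding so independently computed
# subsets recombine to bit-identical totals
.ssum <- function(x) if (length(x) == 0) 0 else sum(sort(x))

#' Atom-atom pair energy
#'
#' Evaluates the nonbonded energy of a single atom pair: 12-6 van der Waals
#' `D0[(R0/r)^12 - 2 (R0/r)^6]` with mixed parameters, Coulomb
#' `ke qi qj / (eps r)`, and - when one atom is a hydrogen-bond donor
#' hydrogen and the other an acceptor, and the donor heavy-atom position is
#' supplied - the Dreiding 12-10 hydrogen-bond term
#' `Dhb [5 (Rhb/rDA)^12 - 6 (Rhb/rDA)^10] cos^4(theta D-H...A)` evaluated on
#' the donor-acceptor distance. All terms are exactly zero at or beyond the
#' cutoff.
#'
#' @param atom_i,atom_j one-row data.frames (or lists) with `x`, `y`, `z`,
#'   `charge`, `type`, and optionally `hb_role`.
#' @param params [ff_params()].
#' @param donor_pos optional length-3 Cartesian position of the heavy donor
#'   atom bonded to the donor hydrogen (required to evaluate the angular
#'   hydrogen-bond term).
#' @return An [energy_breakdown()].
#' @export
pair_energy <- function(atom_i, atom_j, params, donor_pos = NULL) {
  pi_ <- c(atom_i$x, atom_i$y, atom_i$z)
  pj <- c(atom_j$x, atom_j$y, atom_j$z)
  r <- sqrt(sum((pi_ - pj)^2))
  if (r == 0) stop("atoms coincide: pair energy is singular", call. = FALSE)
  if (r >= params$cutoff) return(energy_breakdown())
  D0 <- .mix_d0(.ff_lookup(params, atom_i$type, "D0"),
                .ff_lookup(params, atom_j$type, "D0"), params)
  R0 <- .mix_r0(.ff_lookup(params, atom_i$type, "R0"),
                .ff_lookup(params, atom_j$type, "R0"), params)
  disp <- D0 * ((R0 / r)^12 - 2 * (R0 / r)^6)
  qi <- if (is.na(atom_i$charge)) 0 else atom_i$charge
  qj <- if (is.na(atom_j$charge)) 0 else atom_j$charge
  elec <- params$ke * qi * qj / (params$epsilon * r)
  hb <- 0
  roles <- c(atom_i$hb_role %||% "none", atom_j$hb_role %||% "none")
  if (!is.null(donor_pos) && any(roles == "donor-H") && any(roles == "acceptor")) {
    hpos <- if (roles[1] == "donor-H") pi_ else pj
    apos <- if (roles[1] == "donor-H") pj else pi_
    hb <- .hb_term(donor_pos, hpos, apos, params)
  }
  energy_breakdown(disp, elec, hb)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.mix_d0 <- function(a, b, params) {
  if (params$d0_mixing == "geometric") sqrt(a * b) else (a + b) / 2
}
.mix_r0 <- function(a, b, params) {
  if (params$r0_mixing == "arithmetic") (a + b) / 2 else sqrt(a * b)
}

# 12-10 hydrogen bond on donor(D)-H...acceptor(A) geometry; active only for
# near-linear arrangements (theta at H > 90 deg) inside the DA cutoff.
.hb_term <- function(dpos, hpos, apos, params) {
  rda <- sqrt(sum((dpos - apos)^2))
  if (rda >= params$hb_cutoff || rda == 0) return(0)
  v1 <- dpos - hpos
  v2 <- apos - hpos
  ct <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  if (ct > 0) return(0)       # theta < 90 deg: not a hydrogen bond
  x <- params$hb_R0 / rda
  params$hb_D0 * (5 * x^12 - 6 * x^10) * ct^4
}

# Donor-H atoms reference their bonded heavy atom by row index, which goes
# stale when bodies are subset or replicated; re-derive it from geometry
# (nearest N/O/F within covalent range) before building pair tables.
.fix_hb_donors <- function(at) {
  dh <- which(at$hb_role == "donor-H")
  if (length(dh) == 0) return(at)
  heavy <- which(at$element %in% c("N", "O", "F"))
  for (i in dh) {
    if (length(heavy) == 0) { at$hb_donor[i] <- NA_integer_; next }
    d2 <- (at$x[heavy] - at$x[i])^2 + (at$y[heavy] - at$y[i])^2 +
          (at$z[heavy] - at$z[i])^2
    j <- which.min(d2)
    at$hb_donor[i] <- if (d2[j] < 1.4^2) heavy[j] else NA_integer_
  }
  bad <- dh[is.na(at$hb_donor[dh])]
  if (length(bad) > 0) at$hb_role[bad] <- "none"
  at
}

# Precompute cross-pair parameter tables for repeated host/probe evaluation.
# Returns indices, mixed D0/R0, charge products, vdW-radius sums (for clash
# tests), donor-acceptor "replacement" pairs and hydrogen-bond triples.
.pair_tables <- function(A, B, params) {
  a <- .fix_hb_donors(A$atoms); b <- .fix_hb_donors(B$atoms)
  if (anyNA(a$type) || anyNA(b$type)) {
    bad <- c(which(is.na(a$type)), which(is.na(b$type)))
    stop("untyped atom(s) in energy evaluation (atom index ",
         paste(bad, collapse = ","), "); run assign_types_and_charges first",
         call. = FALSE)
  }
  na_ <- nrow(a); nb_ <- nrow(b)
  i <- rep(seq_len(na_), times = nb_)
  j <- rep(seq_len(nb_), each = na_)
  D0a <- .ff_lookup(params, a$type, "D0"); D0b <- .ff_lookup(params, b$type, "D0")
  R0a <- .ff_lookup(params, a$type, "R0"); R0b <- .ff_lookup(params, b$type, "R0")
  qa <- ifelse(is.na(a$charge), 0, a$charge)
  qb <- ifelse(is.na(b$charge), 0, b$charge)
  D0 <- .mix_d0(D0a[i], D0b[j], params)
  R0 <- .mix_r0(R0a[i], R0b[j], params)
  qq <- params$ke * qa[i] * qb[j] / params$epsilon
  rvdw <- (R0a[i] + R0b[j]) / 2 * 0.8   # clash threshold per pair

  # donor-acceptor heavy pairs whose vdW term the hydrogen bond replaces
  donA <- which(a$hb_role == "donor-H" & !is.na(a$hb_donor))
  donB <- which(b$hb_role == "donor-H" & !is.na(b$hb_donor))
  accA <- which(a$hb_role == "acceptor")
  accB <- which(b$hb_role == "acceptor")
  # triples: (heavy donor idx, H idx) on one side, acceptor on the other
  tAB <- if (length(donA) && length(accB)) {
    cbind(d = rep(a$hb_donor[donA], times = length(accB)),
          h = rep(donA, times = length(accB)),
          acc = rep(accB, each = length(donA)))
  } else matrix(integer(0), 0, 3, dimnames = list(NULL, c("d", "h", "acc")))
  tBA <- if (length(donB) && length(accA)) {
    cbind(d = rep(b$hb_donor[donB], times = length(accA)),
          h = rep(donB, times = length(accA)),
          acc = rep(accA, each = length(donB)))
  } else matrix(integer(0), 0, 3, dimnames = list(NULL, c("d", "h", "acc")))
  # linear pair index of (donor heavy in A, acceptor in B) etc.
  daAB <- if (nrow(tAB)) tAB[, "d"] + (tAB[, "acc"] - 1L) * na_ else integer(0)
  daBA <- if (nrow(tBA)) tBA[, "acc"] + (tBA[, "d"] - 1L) * na_ else integer(0)

  list(i = i, j = j, D0 = D0, R0 = R0, qq = qq, clash_r = rvdw,
       na = na_, nb = nb_, tAB = tAB, tBA = tBA, daAB = daAB, daBA = daBA)
}

# Core evaluator: host coordinates HX (na x 3), probe coordinates PX
# (nb x 3), precomputed tables. `mask` optionally restricts which cross
# pairs contribute (lattice-sum use). Returns component sums via sorted
# summation, or NULL if `clash_check` finds an overlapping pair.
.eval_cross <- function(HX, PX, tab, params, mask = NULL, clash_check = FALSE) {
  dx <- HX[tab$i, 1] - PX[tab$j, 1]
  dy <- HX[tab$i, 2] - PX[tab$j, 2]
  dz <- HX[tab$i, 3] - PX[tab$j, 3]
  r <- sqrt(dx * dx + dy * dy + dz * dz)
  if (clash_check && any(r < tab$clash_r)) return(NULL)
  live <- r < params$cutoff
  if (!is.null(mask)) live <- live & mask
  if (any(r[live] == 0)) {
    stop("atoms coincide: pair energy is singular", call. = FALSE)
  }
  x6 <- (tab$R0 / r)^6
  disp <- tab$D0 * (x6 * x6 - 2 * x6)
  elec <- tab$qq / r

  hb_vals <- numeric(0)
  kill <- logical(length(r))     # vdW terms replaced by the hydrogen bond
  for (side in c("AB", "BA")) {
    tri <- if (side == "AB") tab$tAB else tab$tBA
    if (nrow(tri) == 0) next
    if (side == "AB") {
      dpos <- HX[tri[, "d"], , drop = FALSE]
      hpos <- HX[tri[, "h"], , drop = FALSE]
      apos <- PX[tri[, "acc"], , drop = FALSE]
      pidx <- tab$daAB
    } else {
      dpos <- PX[tri[, "d"], , drop = FALSE]
      hpos <- PX[tri[, "h"], , drop = FALSE]
      apos <- HX[tri[, "acc"], , drop = FALSE]
      pidx <- tab$daBA
    }
    dda <- dpos - apos
    rda <- sqrt(rowSums(dda^2))
    ok <- rda < params$hb_cutoff & rda > 0
    if (!is.null(mask)) ok <- ok & mask[pidx]
    if (!any(ok)) next
    v1 <- dpos - hpos
    v2 <- apos - hpos
    ct <- rowSums(v1 * v2) / sqrt(rowSums(v1^2) * rowSums(v2^2))
    ok <- ok & ct <= 0
    if (!any(ok)) next
    xr <- params$hb_R0 / rda[ok]
    hb_vals <- c(hb_vals,
                 params$hb_D0 * (5 * xr^12 - 6 * xr^10) * ct[ok]^4)
    kill[pidx[ok]] <- TRUE
  }
  disp[kill] <- 0
  disp[!live] <- 0
  elec[!live] <- 0
  energy_breakdown(.ssum(disp), .ssum(elec), .ssum(hb_vals))
}

#' Body-body interaction energy
#'
#' Sum of all inter-body atom-atom pair energies within the cutoff. Bodies
#' are rigid: intra-body terms are never counted. The result is symmetric
#' in the order of its arguments, and its components are accumulated with
#' sorted summation so repeated evaluations are bit-reproducible.
#'
#' @param bodyA,bodyB typed and charged [body()] objects.
#' @param params [ff_params()].
#' @return An [energy_breakdown()].
#' @export
body_body_energy <- function(bodyA, bodyB, params) {
  stopifnot(inherits(bodyA, "body"), inherits(bodyB, "body"))
  tab <- .pair_tables(bodyA, bodyB, params)
  .eval_cross(as.matrix(bodyA$atoms[, c("x", "y", "z")]),
              as.matrix(bodyB$atoms[, c("x", "y", "z")]),
              tab, params)
}
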