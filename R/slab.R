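#' Re-orient a lattice so a Miller plane faces +z
#'
#' Finds an equivalent description of the direct lattice - an integer linear
#' recombination of the cell vectors with determinant +1 - in which the
#' first two cell vectors lie in the (h k l) plane and the plane normal
#' points along +z (the package's Cartesian convention puts c* along +z
#' automatically once a and b span the plane). The cell volume and atom
#' content are preserved exactly; the original (h k l) becomes (0 0 1) in
#' the transformed frame, so all slicing can be done on the Cartesian z
#' coordinate with layer spacing d(hkl).
#'
#' @param structure a `crystal_structure`.
#' @param hkl a [miller_index()] (reduced internally).
#' @param bound search bound for integer recombination coefficients.
#' @return A `crystal_structure` in P1 whose (0 0 1) plane is the original
#'   (h k l); attribute `"hkl"` records the parent index.
#' @export
surface_aligned_cell <- function(structure, hkl, bound = 4) {
  stopifnot(inherits(structure, "crystal_structure"))
  m <- as.integer(miller_index(hkl))
  B <- cell_basis(structure$cell)
  rng <- -bound:bound
  cand <- as.matrix(expand.grid(p = rng, q = rng, r = rng))
  cand <- cand[rowSums(abs(cand)) > 0, , drop = FALSE]
  dot <- drop(cand %*% m)
  len <- sqrt(rowSums((cand %*% t(B))^2))

  inplane <- cand[dot == 0, , drop = FALSE]
  iplen <- len[dot == 0]
  if (nrow(inplane) < 2) {
    stop("no in-plane lattice vectors found; increase 'bound'", call. = FALSE)
  }
  ord <- order(iplen, inplane[, 1], inplane[, 2], inplane[, 3])
  inplane <- inplane[ord, , drop = FALSE]
  u <- inplane[1, ]
  v <- NULL
  for (k in 2:nrow(inplane)) {
    w <- inplane[k, ]
    cr <- c(u[2] * w[3] - u[3] * w[2],
            u[3] * w[1] - u[1] * w[3],
            u[1] * w[2] - u[2] * w[1])
    if (any(cr != 0)) { v <- w; break }
  }
  if (is.null(v)) stop("no independent in-plane vector; increase 'bound'",
                       call. = FALSE)
  # stacking vector: advances exactly one d-spacing (m . w = 1)
  stackc <- cand[dot == 1, , drop = FALSE]
  stlen <- len[dot == 1]
  if (nrow(stackc) == 0) {
    stop("no stacking vector with unit plane index found; increase 'bound'",
         call. = FALSE)
  }
  ords <- order(stlen, stackc[, 1], stackc[, 2], stackc[, 3])
  w <- stackc[ords[1], ]
  M <- cbind(u, v, w)
  if (round(det(M)) == -1) M <- cbind(v, u, w)
  if (abs(round(det(M))) != 1) {
    # shortest two in-plane vectors should span the plane sublattice; fall
    # back to scanning pairs until a unimodular triple appears
    found <- FALSE
    for (k1 in 1:(nrow(inplane) - 1)) {
      for (k2 in (k1 + 1):min(nrow(inplane), 40)) {
        M <- cbind(inplane[k1, ], inplane[k2, ], w)
        if (round(det(M)) == -1) M <- cbind(inplane[k2, ], inplane[k1, ], w)
        if (round(det(M)) == 1) { found <- TRUE; break }
      }
      if (found) break
    }
    if (!found) stop("no unimodular recombination found; increase 'bound'",
                     call. = FALSE)
  }

  newvec <- B %*% M                      # columns: new a, b, c in old frame
  lens <- sqrt(colSums(newvec^2))
  ang <- function(x, y) acos(sum(x * y) / sqrt(sum(x^2) * sum(y^2))) * 180 / pi
  newcell <- unit_cell(lens[1], lens[2], lens[3],
                       ang(newvec[, 2], newvec[, 3]),
                       ang(newvec[, 1], newvec[, 3]),
                       ang(newvec[, 1], newvec[, 2]))

  exp <- expand_structure(structure)
  at <- exp$atoms
  fr <- as.matrix(at[, c("fx", "fy", "fz")])
  frnew <- fr %*% t(solve(M))
  # fold whole molecular units by centroid so nothing is cut
  for (u_ in unique(at$unit)) {
    idx <- which(at$unit == u_)
    cshift <- floor(colMeans(frnew[idx, , drop = FALSE]))
    frnew[idx, ] <- sweep(frnew[idx, , drop = FALSE], 2, cshift)
  }
  sites <- data.frame(label = at$label, element = at$element,
                      fx = frnew[, 1], fy = frnew[, 2], fz = frnew[, 3],
                      charge = at$charge, type = at$type,
                      formal_charge = at$formal_charge,
                      stringsAsFactors = FALSE)
  out <- crystal_structure(newcell, sites, spacegroup = "P 1 (aligned)")
  attr(out, "hkl") <- miller_index(hkl)
  attr(out, "n_asym_per_cell") <- exp$n_ops
  out
}

# Neighborhood of whole molecular units around the home cell, as one big
# coordinate set with unit ids and centroids. `nshell` cells in each
# direction (Chebyshev).
.unit_neighborhood <- function(structure, nshell) {
  sc <- build_supercell(structure, 2 * nshell + 1, 2 * nshell + 1,
                        2 * nshell + 1, origin = c(-nshell, -nshell, -nshell))
  at <- sc$atoms
  home <- at$cell_ia == 0 & at$cell_ib == 0 & at$cell_ic == 0
  cen <- do.call(rbind, lapply(split(seq_len(nrow(at)), at$unit), function(ix) {
    c(mean(at$x[ix]), mean(at$y[ix]), mean(at$z[ix]))
  }))
  list(atoms = at, home = home,
       unit_ids = as.integer(rownames(cen)), centroids = cen)
}

#' Lattice energy per asymmetric unit
#'
#' Half the interaction energy of one central asymmetric unit with all
#' whole molecular units within the summation radius, in kcal/mol. Direct
#' summation with charge-neutral-group truncation: a unit is included as a
#' whole or not at all, by centroid distance (`summation = "sphere"`), or by
#' whole neutral unit cells within a Chebyshev shell of cells
#' (`summation = "cells"`, appropriate for ionic lattices where single-ion
#' shells would leave charged surfaces).
#'
#' @param structure typed and charged `crystal_structure`.
#' @param params [ff_params()]. For lattice sums the pair cutoff acts as
#'   usual; pass a large cutoff for Coulombic systems.
#' @param radius summation radius in Angstrom.
#' @param summation `"sphere"` (unit-centroid distance) or `"cells"` (whole
#'   cells in the cube of side `2*ceiling(radius/min cell height)+1`).
#' @return Energy per asymmetric unit (kcal/mol) with attributes
#'   `"convergence"` (change from the next-smaller shell), `"net_charge"`
#'   (summation-cell net charge; non-neutral cells draw a warning) and
#'   `"n_units"` included.
#' @export
lattice_energy <- function(structure, params, radius = 25,
                           summation = c("sphere", "cells")) {
  summation <- match.arg(summation)
  res <- .lattice_sum(structure, params, radius, summation)
  prev <- .lattice_sum(structure, params,
                       max(radius - .min_cell_height(structure$cell), 1e-3),
                       summation)
  out <- res$energy
  attr(out, "convergence") <- abs(res$energy - prev$energy)
  attr(out, "net_charge") <- res$net_charge
  attr(out, "n_units") <- res$n_units
  out
}

.min_cell_height <- function(cell) {
  min(d_spacing(cell, c(1, 0, 0)), d_spacing(cell, c(0, 1, 0)),
      d_spacing(cell, c(0, 0, 1)))
}

.lattice_sum <- function(structure, params, radius, summation,
                         slice = NULL) {
  exp0 <- expand_structure(structure)
  nshell <- max(1L, as.integer(ceiling(radius / .min_cell_height(structure$cell))))
  nbh <- .unit_neighborhood(structure, nshell)
  at <- nbh$atoms
  q <- ifelse(is.na(at$charge), 0, at$charge)
  net <- sum(q[nbh$home])
  if (abs(net) > 1e-6) {
    warning(sprintf("summation cell carries net charge %+.4f e; ", net),
            "electrostatic sum may diverge", call. = FALSE)
  }
  central_units <- sort(unique(at$unit[nbh$home]))
  ucen <- nbh$centroids
  uid <- nbh$unit_ids
  energies <- numeric(0)
  comp <- c(dispersive = 0, electrostatic = 0, hbond = 0)
  # evaluate each central unit against included partner units
  for (cu in central_units) {
    cidx <- which(at$unit == cu)
    A <- body(at[cidx, , drop = FALSE], "central-unit")
    ccen <- c(mean(at$x[cidx]), mean(at$y[cidx]), mean(at$z[cidx]))
    if (summation == "sphere") {
      d <- sqrt(rowSums(sweep(ucen, 2, ccen)^2))
      inc <- uid[d <= radius & uid != cu]
    } else {
      inc <- uid[uid != cu]
    }
    if (!is.null(slice)) {
      # restrict partners to units whose centroid z lies in the same slice
      # (or outside it) as the central unit
      # centroids landing exactly on a boundary join the slice above
      slab_of <- floor(ucen[, 3] / slice$d - slice$offset + 1e-9)
      mine <- slab_of[match(cu, uid)]
      same <- uid[slab_of == mine]
      inc <- if (slice$mode == "slice") intersect(inc, same)
             else setdiff(inc, same)
    }
    if (length(inc) == 0) next
    Bidx <- which(at$unit %in% inc)
    Bb <- body(at[Bidx, , drop = FALSE], "partners")
    e <- body_body_energy(A, Bb, params)
    energies <- c(energies, e$total)
    comp <- comp + c(e$dispersive, e$electrostatic, e$hbond)
  }
  n_asym <- attr(structure, "n_asym_per_cell") %||% exp0$n_ops
  list(energy = .ssum(energies) / 2 / n_asym,
       components = comp / 2 / n_asym,
       net_charge = net,
       n_units = length(central_units))
}

#' Attachment energy of a surface termination
#'
#' Partitions the lattice energy at a given face and termination offset:
#' the slice energy is the interaction of the central unit with the other
#' units of its own d(hkl)-thick growth slice, and the attachment energy is
#' the interaction with everything outside that slice, so that
#' `E_latt = E_slice + E_att`. Units are assigned to slices by centroid z;
#' molecular units are never cut. The identity is also computed and checked
#' internally.
#'
#' @param structure a `crystal_structure` (surface-aligned structures are
#'   used as-is; otherwise the cell is aligned to `hkl` first).
#' @param hkl face index.
#' @param offset termination offset as a fraction of d(hkl) in `[0, 1)`.
#' @param params [ff_params()].
#' @param radius lattice summation radius (Angstrom).
#' @return Object of class `termination`: `hkl`, `offset`, `E_slice`,
#'   `E_att`, `E_latt` (kcal/mol per asymmetric unit) and the partition
#'   residual `identity_gap`.
#' @export
attachment_energy <- function(structure, hkl, offset = 0, params = ff_params(),
                              radius = 25) {
  if (offset < 0 || offset >= 1) stop("offset must lie in [0, 1)", call. = FALSE)
  al <- .ensure_aligned(structure, hkl)
  dd <- d_spacing(al$cell, c(0, 0, 1))
  slice_def <- list(d = dd, offset = offset, mode = "slice")
  att_def <- list(d = dd, offset = offset, mode = "attach")
  full <- .lattice_sum(al, params, radius, "sphere")
  sl <- .lattice_sum(al, params, radius, "sphere", slice = slice_def)
  at_ <- .lattice_sum(al, params, radius, "sphere", slice = att_def)
  gap <- full$energy - sl$energy - at_$energy
  structure(list(hkl = miller_index(hkl), offset = offset,
                 E_slice = sl$energy, E_att = at_$energy,
                 E_latt = full$energy, identity_gap = gap,
                 d_hkl = dd),
            class = "termination")
}

.ensure_aligned <- function(structure, hkl) {
  cur <- attr(structure, "hkl")
  if (!is.null(cur)) {
    if (!all(as.integer(cur) == as.integer(miller_index(hkl)))) {
      stop("structure is already aligned to face (",
           paste(as.integer(cur), collapse = " "),
           "); re-align from the original structure", call. = FALSE)
    }
    return(structure)
  }
  surface_aligned_cell(structure, hkl)
}

#' @export
print.termination <- function(x, ...) {
  cat(sprintf("termination (%d %d %d) offset %.2f d: E_slice %.6f, E_att %.6f, E_latt %.6f kcal/mol per asym unit\n",
              x$hkl[1], x$hkl[2], x$hkl[3], x$offset, x$E_slice, x$E_att, x$E_latt))
  invisible(x)
}

#' Scan surface terminations of a face
#'
#' Evaluates candidate terminations by shifting the surface cut through one
#' full d-spacing in steps of `step` (default 0.1, i.e. ten candidates) and
#' selects the termination with the lowest absolute attachment energy as
#' the most stable; ties break deterministically to the smallest offset.
#'
#' @inheritParams attachment_energy
#' @param step offset step as a fraction of d(hkl); `1/step` must be an
#'   integer.
#' @return list with `terminations` (data.frame: offset, E_slice, E_att,
#'   E_latt, selected flag), `selected` (the chosen `termination` object)
#'   and `d_hkl`.
#' @export
scan_terminations <- function(structure, hkl, step = 0.1, params = ff_params(),
                              radius = 25) {
  nstep <- 1 / step
  if (abs(nstep - round(nstep)) > 1e-9) {
    stop("step must divide 1 into an integer number of offsets", call. = FALSE)
  }
  nstep <- as.integer(round(nstep))
  al <- .ensure_aligned(structure, hkl)
  offsets <- (seq_len(nstep) - 1) * step
  terms <- lapply(offsets, function(o) {
    attachment_energy(al, hkl, o, params, radius)
  })
  eatt <- vapply(terms, function(t) t$E_att, numeric(1))
  sel <- which.min(round(abs(eatt), 9))   # stable argmin, first = smallest offset
  tab <- data.frame(offset = offsets,
                    E_slice = vapply(terms, function(t) t$E_slice, numeric(1)),
                    E_att = eatt,
                    E_latt = vapply(terms, function(t) t$E_latt, numeric(1)),
                    selected = seq_along(terms) == sel)
  list(terminations = tab, selected = terms[[sel]],
       d_hkl = terms[[1]]$d_hkl, hkl = miller_index(hkl))
}

#' BFDH face ranking
#'
#' Enumerates low-index faces up to `max_index`, reduces them to canonical
#' Miller indices, corrects d-spacings for lattice-centering extinctions
#' implied by the stored symmetry operators (an extinct reflection is
#' replaced by its first allowed multiple, e.g. (0 1 0) growth governed by
#' the (0 2 0) spacing under a 2_1 screw stacking), groups faces into
#' symmetry-equivalent families under the point-group rotations, and ranks
#' family representatives by descending effective d-spacing - the
#' Bravais-Friedel-Donnay-Harker morphological importance order.
#'
#' @param structure a `crystal_structure`.
#' @param n number of top families to return.
#' @param max_index enumeration bound on |h|, |k|, |l|.
#' @return data.frame: `h`, `k`, `l` (family representative), `d_eff`
#'   (extinction-corrected d-spacing, Angstrom), `multiplicity` (family
#'   size), ranked by descending `d_eff`.
#' @export
bfdh_faces <- function(structure, n = 5, max_index = 3) {
  stopifnot(inherits(structure, "crystal_structure"), n >= 1)
  rng <- -max_index:max_index
  cand <- as.matrix(expand.grid(h = rng, k = rng, l = rng))
  cand <- cand[rowSums(abs(cand)) > 0, , drop = FALSE]
  keys <- unique(t(apply(cand, 1, function(v) as.integer(miller_index(v)))))

  # pure-translation operators (lattice centerings + screw/glide translations
  # are not centerings; only rotation == identity counts)
  trans <- Filter(function(op) {
    all(op$R == diag(3)) && any(abs(op$t - round(op$t)) > 1e-9)
  }, structure$ops)
  allowed <- function(hkl) {
    if (length(trans) == 0) return(TRUE)
    all(vapply(trans, function(op) {
      ph <- sum(hkl * op$t)
      abs(ph - round(ph)) < 1e-9
    }, logical(1)))
  }
  d_eff <- apply(keys, 1, function(hkl) {
    mult <- 1
    while (!allowed(hkl * mult) && mult <= 6) mult <- mult + 1
    d_spacing(structure$cell, hkl * mult)
  })

  # group into symmetry-equivalent families: faces related by the stored
  # point-group rotations (reciprocal-space action hkl' = hkl %*% R) or by
  # Friedel inversion are equivalent, and so are faces the lattice metric
  # itself cannot distinguish (same sorted |h k l| and identical d-spacing,
  # e.g. the six {1 0 0} faces of a cubic cell stored as P1)
  rots <- unique(lapply(structure$ops, function(op) round(op$R)))
  fam <- rep(NA_integer_, nrow(keys))
  keystr <- apply(keys, 1, paste, collapse = ",")
  metkey <- paste(apply(keys, 1, function(v) paste(sort(abs(v)), collapse = ",")),
                  signif(d_eff, 10))
  nf <- 0L
  for (i in seq_len(nrow(keys))) {
    if (!is.na(fam[i])) next
    nf <- nf + 1L
    images <- unique(do.call(rbind, lapply(rots, function(R) {
      im <- drop(keys[i, ] %*% R)
      rbind(as.integer(miller_index(im)), as.integer(miller_index(-im)))
    })))
    imstr <- apply(images, 1, paste, collapse = ",")
    fam[keystr %in% imstr | metkey == metkey[i]] <- nf
  }
  rep_idx <- vapply(split(seq_len(nrow(keys)), fam), function(ix) {
    ix[order(-abs(d_eff[ix]),
             -keys[ix, 1], -keys[ix, 2], -keys[ix, 3])][1]
  }, integer(1))
  out <- data.frame(h = keys[rep_idx, 1], k = keys[rep_idx, 2],
                    l = keys[rep_idx, 3],
                    d_eff = d_eff[rep_idx],
                    # each reduced index stands for a +/- pair of faces
                    multiplicity = 2L * as.integer(table(fam)))
  out <- out[order(-out$d_eff, out$h, out$k, out$l), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, n)
}

#' Build a finite surface slab
#'
#' Cuts a finite slab [body()] from the surface-aligned crystal: the top
#' face lies at the selected termination cut, the surface normal is +z by
#' construction, molecular units are kept whole (assigned by centroid z),
#' and the exposed-face area is the in-plane cell area times the repeat
#' counts. With `layers = 1` the slab is the first molecular layer of the
#' face - the probe slab of a surface-surface search.
#'
#' @param structure a `crystal_structure`.
#' @param hkl face index.
#' @param termination a `termination` from [scan_terminations()] (or an
#'   offset fraction).
#' @param repeats length-2 integer vector of in-plane repeats (a, b).
#' @param layers slab thickness in d(hkl) layers (>= 1).
#' @param params [ff_params()] (only carried through for typing checks).
#' @return Object of class `slab`, a [body()] plus `hkl`, `offset`, `area`
#'   (Angstrom^2), `d_hkl`, `layers`, `repeats`.
#' @export
build_slab <- function(structure, hkl, termination = 0, repeats = c(2, 2),
                       layers = 1, params = NULL) {
  if (any(repeats < 1) || layers < 1) {
    stop("repeats and layers must be >= 1", call. = FALSE)
  }
  offset <- if (inherits(termination, "termination")) termination$offset
            else as.numeric(termination)
  al <- .ensure_aligned(structure, hkl)
  dd <- d_spacing(al$cell, c(0, 0, 1))
  nz <- layers + 2                      # overbuild, then select by centroid
  sc <- build_supercell(al, repeats[1], repeats[2], nz,
                        origin = c(0, 0, -layers - 1))
  at <- sc$atoms
  zc <- vapply(split(at$z, at$unit), mean, numeric(1))
  zid <- as.integer(names(zc))
  ztop <- offset * dd                  # top cut plane
  keep_units <- zid[zc < ztop - 1e-9 & zc >= ztop - layers * dd - 1e-9]
  sel <- at[at$unit %in% keep_units, , drop = FALSE]
  if (nrow(sel) == 0) stop("slab selection is empty; check termination offset",
                           call. = FALSE)
  rownames(sel) <- NULL
  B <- cell_basis(al$cell)
  area <- sqrt(sum(.cross3(B[, 1], B[, 2])^2)) * repeats[1] * repeats[2]
  b <- body(sel, label = sprintf("slab (%d %d %d) offset %.2f, %dx%d x %d layers",
                                 miller_index(hkl)[1], miller_index(hkl)[2],
                                 miller_index(hkl)[3], offset,
                                 repeats[1], repeats[2], layers))
  structure(c(b, list(hkl = miller_index(hkl), offset = offset, area = area,
                      d_hkl = dd, layers = layers, repeats = repeats)),
            class = c("slab", "body"))
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Surface rugosity of a slab
#'
#' Ratio of the true corrugated top-surface area to the projected in-plane
#' area. A height map is sampled on an in-plane grid as the upper envelope
#' of the atoms' van der Waals spheres (radius R0/2 per atom type), then
#' triangulated (two triangles per grid cell); the ratio of triangulated to
#' projected area is always >= 1, with 1 meaning an ideally flat face.
#'
#' @param slab a [build_slab()] result (or any body whose +z face is the
#'   surface of interest).
#' @param params [ff_params()] supplying per-type R0.
#' @param grid_resolution in-plane sampling step in Angstrom (> 0).
#' @return Rugosity ratio (dimensionless, >= 1) with attribute `"area"`
#'   (triangulated area, Angstrom^2).
#' @export
rugosity <- function(slab, params = ff_params(), grid_resolution = 0.2) {
  stopifnot(inherits(slab, "body"))
  if (grid_resolution <= 0) stop("grid_resolution must be > 0", call. = FALSE)
  at <- slab$atoms
  rv <- .ff_lookup(params, at$type, "R0") / 2
  xs <- seq(min(at$x), max(at$x), by = grid_resolution)
  ys <- seq(min(at$y), max(at$y), by = grid_resolution)
  if (length(xs) < 2 || length(ys) < 2) {
    stop("slab footprint smaller than one grid cell; reduce grid_resolution",
         call. = FALSE)
  }
  H <- matrix(-Inf, length(xs), length(ys))
  for (k in seq_len(nrow(at))) {
    ix <- which(abs(xs - at$x[k]) < rv[k])
    iy <- which(abs(ys - at$y[k]) < rv[k])
    if (length(ix) == 0 || length(iy) == 0) next
    dx2 <- (xs[ix] - at$x[k])^2
    dy2 <- (ys[iy] - at$y[k])^2
    rho2 <- outer(dx2, dy2, "+")
    cap <- rho2 < rv[k]^2
    if (!any(cap)) next
    hz <- matrix(-Inf, length(ix), length(iy))
    hz[cap] <- at$z[k] + sqrt(rv[k]^2 - rho2[cap])
    H[ix, iy] <- pmax(H[ix, iy], hz)
  }
  floorz <- min(at$z)                   # uncovered points fall to the base
  H[!is.finite(H)] <- floorz
  g <- grid_resolution
  nx <- length(xs); ny <- length(ys)
  a00 <- H[-nx, -ny]; a10 <- H[-1, -ny]; a01 <- H[-nx, -1]; a11 <- H[-1, -1]
  tri_area <- function(dzA, dzB) {
    # triangle with legs (g,0,dzA) and (0,g,dzB): area = g/2 * sqrt(g^2+dzA^2+dzB^2)
    0.5 * g * sqrt(g^2 + dzA^2 + dzB^2)
  }
  area <- sum(tri_area(a10 - a00, a01 - a00)) +
          sum(tri_area(a01 - a11, a10 - a11))
  proj <- g^2 * (nx - 1) * (ny - 1)
  out <- max(1, area / proj)
  attr(out, "area") <- area
  out
}
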