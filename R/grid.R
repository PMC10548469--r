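#' Systematic search configuration
#'
#' @param mode `"molecule-molecule"`, `"molecule-surface"` or
#'   `"surface-surface"`. Surface-host modes place the grid in the half
#'   space above the exposed (+z) face.
#' @param spacing orthogonal grid spacing in Angstrom (default 0.5 for
#'   molecular probes, 1.0 for slab probes).
#' @param extents Angstrom added beyond the host bounding box in each
#'   direction (scalar or length 3); for surface hosts, the +z extent above
#'   the top atom plane.
#' @param angle_step angular increment in degrees for each of the three
#'   rotation axes; must divide 360.
#' @param clash_distance grid points closer than this to any host atom are
#'   excluded (Angstrom).
#' @param top_n number of ranked poses to retain (>= 1).
#' @param hist_bin bin width for the retained energy histogram, kcal/atom.
#' @return Object of class `search_config`.
#' @export
search_config <- function(mode = c("molecule-molecule", "molecule-surface",
                                   "surface-surface"),
                          spacing = NULL, extents = 5, angle_step = 30,
                          clash_distance = 1.0, top_n = 10,
                          hist_bin = 0.005) {
  mode <- match.arg(mode)
  if (is.null(spacing)) {
    spacing <- if (mode == "surface-surface") 1.0 else 0.5
  }
  if (spacing <= 0) stop("spacing must be > 0", call. = FALSE)
  if (length(extents) == 1) extents <- rep(extents, 3)
  k <- 360 / angle_step
  if (abs(k - round(k)) > 1e-9) stop("angle_step must divide 360", call. = FALSE)
  if (top_n < 1) stop("top_n must be >= 1", call. = FALSE)
  structure(list(mode = mode, spacing = spacing, extents = extents,
                 angle_step = angle_step, clash_distance = clash_distance,
                 top_n = as.integer(top_n), hist_bin = hist_bin),
            class = "search_config")
}

#' Build the orthogonal search grid around a host
#'
#' In the molecular modes the grid covers the host bounding box inflated by
#' the configured extents; in the surface modes it covers the exposed face
#' footprint with all points strictly above the top surface atom plane.
#' Points whose nearest host atom is closer than the clash distance are
#' excluded (and counted).
#'
#' @param host a [body()] (or slab).
#' @param config a [search_config()].
#' @return matrix of grid points (n x 3, Angstrom) with attributes
#'   `"n_excluded"` and `"n_total"`.
#' @export
build_grid <- function(host, config) {
  stopifnot(inherits(host, "body"), inherits(config, "search_config"))
  at <- host$atoms
  sp <- config$spacing
  ex <- config$extents
  if (config$mode == "molecule-molecule") {
    xs <- seq(min(at$x) - ex[1], max(at$x) + ex[1], by = sp)
    ys <- seq(min(at$y) - ex[2], max(at$y) + ex[2], by = sp)
    zs <- seq(min(at$z) - ex[3], max(at$z) + ex[3], by = sp)
  } else {
    ztop <- max(at$z)
    xs <- seq(min(at$x), max(at$x), by = sp)
    ys <- seq(min(at$y), max(at$y), by = sp)
    zs <- seq(ztop + sp, ztop + max(sp, ex[3]), by = sp)
  }
  g <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  n_total <- nrow(g)
  hx <- as.matrix(at[, c("x", "y", "z")])
  keep <- rep(TRUE, n_total)
  if (config$clash_distance > 0) {
    for (k in seq_len(nrow(hx))) {
      d2 <- (g[, 1] - hx[k, 1])^2 + (g[, 2] - hx[k, 2])^2 + (g[, 3] - hx[k, 3])^2
      keep <- keep & d2 >= config$clash_distance^2
      if (!any(keep)) break
    }
  }
  g <- g[keep, , drop = FALSE]
  if (nrow(g) == 0) {
    stop("search grid is empty after clash exclusion; enlarge extents or ",
         "reduce clash_distance", call. = FALSE)
  }
  attr(g, "n_excluded") <- n_total - nrow(g)
  attr(g, "n_total") <- n_total
  g
}

# intrinsic z-y-x Euler rotation matrix, angles in degrees
.rot_zyx <- function(a, b, c) {
  ar <- .deg2rad(a); br <- .deg2rad(b); cr <- .deg2rad(c)
  Rz <- matrix(c(cos(ar), -sin(ar), 0, sin(ar), cos(ar), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  Ry <- matrix(c(cos(br), 0, sin(br), 0, 1, 0, -sin(br), 0, cos(br)), 3, 3,
               byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(cr), -sin(cr), 0, sin(cr), cos(cr)), 3, 3,
               byrow = TRUE)
  Rz %*% Ry %*% Rx
}

#' Exhaustive rigid-body systematic search
#'
#' Enumerates every pose of the rigid probe - each grid point combined with
#' every triple of rotation angles about the probe centroid - evaluates the
#' host-probe interaction energy, and returns the ranked top poses with
#' per-probe-atom normalized energy breakdowns. The engine is fully
#' deterministic: no randomness anywhere, ranking ascending by total energy
#' with ties broken by earlier grid index then lexicographic angles.
#' Poses with any interatomic distance below 0.8 x the mean vdW diameter
#' of the pair are skipped as clashes and counted, not scored.
#'
#' @param host stationary [body()] (typed and charged).
#' @param probe mobile [body()] (typed and charged); rigid.
#' @param config a [search_config()].
#' @param params [ff_params()].
#' @return Object of class `search_result`: `poses` (data.frame of the top
#'   poses: translation, angles, energy components in kcal/mol and
#'   kcal/atom), `histogram` of all scored pose totals (kcal/atom),
#'   `stats` (pose counts), `probe_atoms`, labels and the config echo.
#' @export
systematic_search <- function(host, probe, config, params) {
  stopifnot(inherits(host, "body"), inherits(probe, "body"))
  grid <- build_grid(host, config)
  angles <- seq(0, 360 - config$angle_step, by = config$angle_step)
  rot <- as.matrix(expand.grid(a3 = angles, a2 = angles, a1 = angles))
  rot <- rot[, c("a1", "a2", "a3"), drop = FALSE]   # a1 slowest: lexicographic
  HX <- as.matrix(host$atoms[, c("x", "y", "z")])
  P0 <- as.matrix(probe$atoms[, c("x", "y", "z")])
  P0 <- sweep(P0, 2, colMeans(P0))                  # centroid at origin
  tab <- .pair_tables(host, probe, params)

  span <- apply(P0, 2, function(v) diff(range(v)))
  gspan <- apply(grid, 2, function(v) diff(range(v)))
  if (config$mode == "molecule-molecule" &&
      any(span > gspan + 2 * config$extents + 1e-9)) {
    stop("probe is larger than the search box; enlarge extents", call. = FALSE)
  }

  npose <- nrow(grid) * nrow(rot)
  total <- disp <- elec <- hb <- rep(NA_real_, npose)
  G <- nrow(grid)
  gx <- grid[, 1]; gy <- grid[, 2]; gz <- grid[, 3]
  npairs <- length(tab$i)
  da_set <- unique(c(tab$daAB, tab$daBA))
  for (ri in seq_len(nrow(rot))) {
    PR <- P0 %*% t(.rot_zyx(rot[ri, 1], rot[ri, 2], rot[ri, 3]))
    tdisp <- numeric(G); telec <- numeric(G); thb <- numeric(G)
    clash <- logical(G)
    # hydrogen-bond triples first: they also decide which donor-acceptor
    # vdW terms are replaced, per grid point
    kills <- list()
    for (side in c("AB", "BA")) {
      tri <- if (side == "AB") tab$tAB else tab$tBA
      if (nrow(tri) == 0) next
      pidx <- if (side == "AB") tab$daAB else tab$daBA
      for (tt in seq_len(nrow(tri))) {
        if (side == "AB") {       # donor on host, acceptor on probe
          dp <- HX[tri[tt, "d"], ]; hp <- HX[tri[tt, "h"], ]
          ax <- PR[tri[tt, "acc"], 1] + gx
          ay <- PR[tri[tt, "acc"], 2] + gy
          az <- PR[tri[tt, "acc"], 3] + gz
          v1x <- dp[1] - hp[1]; v1y <- dp[2] - hp[2]; v1z <- dp[3] - hp[3]
          v2x <- ax - hp[1]; v2y <- ay - hp[2]; v2z <- az - hp[3]
          dax <- dp[1] - ax; day <- dp[2] - ay; daz <- dp[3] - az
        } else {                  # donor on probe, acceptor on host
          ap <- HX[tri[tt, "acc"], ]
          dx_ <- PR[tri[tt, "d"], 1] + gx
          dy_ <- PR[tri[tt, "d"], 2] + gy
          dz_ <- PR[tri[tt, "d"], 3] + gz
          hx_ <- PR[tri[tt, "h"], 1] + gx
          hy_ <- PR[tri[tt, "h"], 2] + gy
          hz_ <- PR[tri[tt, "h"], 3] + gz
          v1x <- dx_ - hx_; v1y <- dy_ - hy_; v1z <- dz_ - hz_
          v2x <- ap[1] - hx_; v2y <- ap[2] - hy_; v2z <- ap[3] - hz_
          dax <- dx_ - ap[1]; day <- dy_ - ap[2]; daz <- dz_ - ap[3]
        }
        rda <- sqrt(dax * dax + day * day + daz * daz)
        ct <- (v1x * v2x + v1y * v2y + v1z * v2z) /
          sqrt((v1x^2 + v1y^2 + v1z^2) * (v2x^2 + v2y^2 + v2z^2))
        ok <- rda < params$hb_cutoff & rda > 0 & ct <= 0
        if (any(ok)) {
          xr <- params$hb_R0 / rda[ok]
          hbv <- numeric(G)
          hbv[ok] <- params$hb_D0 * (5 * xr^12 - 6 * xr^10) * ct[ok]^4
          thb <- thb + hbv
          key <- as.character(pidx[tt])
          kills[[key]] <- if (is.null(kills[[key]])) ok else kills[[key]] | ok
        }
      }
    }
    for (pp in seq_len(npairs)) {
      i <- tab$i[pp]; j <- tab$j[pp]
      dx <- HX[i, 1] - (PR[j, 1] + gx)
      dy <- HX[i, 2] - (PR[j, 2] + gy)
      dz <- HX[i, 3] - (PR[j, 3] + gz)
      r <- sqrt(dx * dx + dy * dy + dz * dz)
      clash <- clash | (r < tab$clash_r[pp])
      live <- r < params$cutoff
      x6 <- (tab$R0[pp] / r)^6
      dterm <- tab$D0[pp] * (x6 * x6 - 2 * x6)
      eterm <- tab$qq[pp] / r
      dterm[!live] <- 0
      eterm[!live] <- 0
      if (pp %in% da_set) {
        km <- kills[[as.character(pp)]]
        if (!is.null(km)) dterm[km] <- 0
      }
      tdisp <- tdisp + dterm
      telec <- telec + eterm
    }
    sel <- which(!clash)
    off <- (ri - 1L) * G
    total[off + sel] <- tdisp[sel] + telec[sel] + thb[sel]
    disp[off + sel] <- tdisp[sel]
    elec[off + sel] <- telec[sel]
    hb[off + sel] <- thb[sel]
  }
  gidx <- rep(seq_len(nrow(grid)), times = nrow(rot))
  ridx <- rep(seq_len(nrow(rot)), each = nrow(grid))
  scored <- which(!is.na(total))
  ord <- scored[order(total[scored], gidx[scored], ridx[scored])]
  top <- utils::head(ord, config$top_n)
  np <- nrow(probe$atoms)
  poses <- data.frame(
    rank = seq_along(top),
    tx = grid[gidx[top], 1], ty = grid[gidx[top], 2], tz = grid[gidx[top], 3],
    a1 = rot[ridx[top], 1], a2 = rot[ridx[top], 2], a3 = rot[ridx[top], 3],
    total = total[top], dispersive = disp[top], electrostatic = elec[top],
    hbond = hb[top], polar = elec[top] + hb[top],
    total_per_atom = total[top] / np,
    dispersive_per_atom = disp[top] / np,
    electrostatic_per_atom = elec[top] / np,
    hbond_per_atom = hb[top] / np,
    polar_per_atom = (elec[top] + hb[top]) / np,
    grid_index = gidx[top], rot_index = ridx[top])
  rownames(poses) <- NULL
  structure(list(
    poses = poses,
    histogram = energy_histogram(total[scored] / np, config$hist_bin),
    stats = list(n_grid_points = nrow(grid),
                 n_grid_excluded = attr(grid, "n_excluded"),
                 n_rotations = nrow(rot),
                 n_poses = npose,
                 n_scored = length(scored),
                 n_clash_skipped = npose - length(scored)),
    probe_atoms = np,
    host_label = host$label,
    probe_label = probe$label,
    config = config
  ), class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("systematic search [%s]: host '%s' vs probe '%s' (%d atoms)\n",
              x$config$mode, x$host_label, x$probe_label, x$probe_atoms))
  cat(sprintf("  %d poses (%d scored, %d clash-skipped, %d grid points x %d rotations)\n",
              x$stats$n_poses, x$stats$n_scored, x$stats$n_clash_skipped,
              x$stats$n_grid_points, x$stats$n_rotations))
  if (nrow(x$poses) > 0) {
    cat(sprintf("  best: %.6f kcal/mol (%.6f kcal/atom)\n",
                x$poses$total[1], x$poses$total_per_atom[1]))
  }
  invisible(x)
}

#' Best (most negative) binding energy of a search, per probe atom
#' @param result a `search_result`.
#' @export
best_energy <- function(result) {
  stopifnot(inherits(result, "search_result"))
  result$poses$total_per_atom[1]
}

#' Histogram of pose energies
#'
#' Fixed-width binning anchored at zero, suitable for Gaussian fitting of
#' the full pose-energy distribution without storing every pose.
#'
#' @param values numeric energies (kcal/atom).
#' @param bin bin width.
#' @return list with `mids`, `counts`, `bin`; class `energy_histogram`.
#' @export
energy_histogram <- function(values, bin = 0.005) {
  values <- values[is.finite(values)]
  if (length(values) == 0) {
    return(structure(list(mids = numeric(0), counts = integer(0), bin = bin),
                     class = "energy_histogram"))
  }
  idx <- floor(values / bin)
  tabv <- table(idx)
  mids <- (as.numeric(names(tabv)) + 0.5) * bin
  structure(list(mids = mids, counts = as.integer(tabv), bin = bin,
                 n = length(values)),
            class = "energy_histogram")
}

#' Per-probe-atom normalization of an energy breakdown
#'
#' Divides every component by the probe atom count, yielding kcal/atom, the
#' common scale that makes molecule-probe and slab-probe searches directly
#' comparable.
#'
#' @param breakdown an [energy_breakdown()].
#' @param probe_atom_count number of atoms in the probe (>= 1).
#' @return An `energy_breakdown` in kcal/atom.
#' @export
normalize_per_atom <- function(breakdown, probe_atom_count) {
  stopifnot(inherits(breakdown, "energy_breakdown"))
  if (probe_atom_count < 1) {
    stop("probe_atom_count must be >= 1", call. = FALSE)
  }
  energy_breakdown(breakdown$dispersive / probe_atom_count,
                   breakdown$electrostatic / probe_atom_count,
                   breakdown$hbond / probe_atom_count)
}

#' Run a matrix of host/probe searches
#'
#' Schedules one systematic search per row of `specs` (host label, probe
#' label), with bodies looked up in `bodies`. Running both orderings of a
#' pair - each face acting first as the host slab and then as the probe -
#' is simply two rows. Duplicate rows are deduplicated with a warning.
#'
#' @param specs data.frame with columns `host`, `probe` and optionally
#'   `group` (e.g. `"API-API"`, `"API-carrier"`).
#' @param bodies named list of [body()] objects.
#' @param config a [search_config()] (or named list of configs keyed by
#'   mode).
#' @param params [ff_params()].
#' @return list with `results` (one `search_result` per row) and `table`
#'   (host, probe, group, probe_atoms, best total and per-atom energies and
#'   component breakdown at the best pose).
#' @export
pair_matrix <- function(specs, bodies, config, params) {
  stopifnot(is.data.frame(specs), all(c("host", "probe") %in% names(specs)))
  key <- paste(specs$host, specs$probe, sep = " | ")
  if (anyDuplicated(key)) {
    warning("duplicate search spec(s) removed: ",
            paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
    specs <- specs[!duplicated(key), , drop = FALSE]
  }
  missing <- setdiff(unique(c(specs$host, specs$probe)), names(bodies))
  if (length(missing) > 0) {
    stop("no body supplied for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  results <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    results[[i]] <- systematic_search(bodies[[specs$host[i]]],
                                      bodies[[specs$probe[i]]],
                                      config, params)
  }
  tab <- data.frame(
    host = specs$host, probe = specs$probe,
    group = if ("group" %in% names(specs)) specs$group
            else paste(specs$host, specs$probe, sep = "-"),
    probe_atoms = vapply(results, function(r) r$probe_atoms, numeric(1)),
    best_total = vapply(results, function(r) r$poses$total[1], numeric(1)),
    best_per_atom = vapply(results, best_energy, numeric(1)),
    dispersive_per_atom = vapply(results, function(r) r$poses$dispersive_per_atom[1], numeric(1)),
    electrostatic_per_atom = vapply(results, function(r) r$poses$electrostatic_per_atom[1], numeric(1)),
    hbond_per_atom = vapply(results, function(r) r$poses$hbond_per_atom[1], numeric(1)),
    stringsAsFactors = FALSE)
  list(results = results, table = tab)
}
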