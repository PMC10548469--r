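# Independent oracles and small generators shared across the suite.
# The oracles deliberately re-derive quantities with plain double loops and
# closed forms, never through the package's evaluation paths.

# Closed-form triclinic cell volume (independent of cell_basis)
triclinic_volume <- function(a, b, c, alpha, beta, gamma) {
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180)
  a * b * c * sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
}

# Reciprocal-metric d-spacing oracle for a general triclinic cell
d_spacing_oracle <- function(a, b, c, alpha, beta, gamma, h, k, l) {
  ar <- alpha * pi / 180; br <- beta * pi / 180; gr <- gamma * pi / 180
  V <- triclinic_volume(a, b, c, alpha, beta, gamma)
  s11 <- (b * c * sin(ar))^2
  s22 <- (a * c * sin(br))^2
  s33 <- (a * b * sin(gr))^2
  s12 <- a * b * c^2 * (cos(ar) * cos(br) - cos(gr))
  s23 <- a^2 * b * c * (cos(br) * cos(gr) - cos(ar))
  s13 <- a * b^2 * c * (cos(gr) * cos(ar) - cos(br))
  inv_d2 <- (s11 * h^2 + s22 * k^2 + s33 * l^2 +
             2 * s12 * h * k + 2 * s23 * k * l + 2 * s13 * h * l) / V^2
  1 / sqrt(inv_d2)
}

# random valid triclinic cell (rejection sampling on the metric)
random_cell <- function() {
  repeat {
    a <- runif(1, 3, 12); b <- runif(1, 3, 12); c <- runif(1, 3, 12)
    al <- runif(1, 60, 120); be <- runif(1, 60, 120); ga <- runif(1, 60, 120)
    ok <- try(unit_cell(a, b, c, al, be, ga), silent = TRUE)
    if (!inherits(ok, "try-error")) return(ok)
  }
}

# Brute-force pair-sum energy for two bodies: plain double loop, same
# physics (12-6 vdW with the configured mixing, Coulomb, 12-10 hydrogen
# bond with cos^4 angle replacing the donor-acceptor vdW term), written
# without touching the package's evaluators.
brute_body_energy <- function(A, B, params) {
  a <- A$atoms; b <- B$atoms
  look <- function(t, col) params$types[[col]][match(t, params$types$type)]
  disp <- 0; elec <- 0; hb <- 0
  # hydrogen-bond bookkeeping: which (donor heavy, acceptor) pairs are live
  hb_kill <- matrix(FALSE, nrow(a), nrow(b))
  hb_one <- function(dp, hp, ap) {
    rda <- sqrt(sum((dp - ap)^2))
    if (rda >= params$hb_cutoff || rda == 0) return(NA_real_)
    v1 <- dp - hp; v2 <- ap - hp
    ct <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    if (ct > 0) return(NA_real_)
    x <- params$hb_R0 / rda
    params$hb_D0 * (5 * x^12 - 6 * x^10) * ct^4
  }
  find_heavy <- function(at, i) {
    heavy <- which(at$element %in% c("N", "O", "F"))
    if (length(heavy) == 0) return(NA_integer_)
    d2 <- (at$x[heavy] - at$x[i])^2 + (at$y[heavy] - at$y[i])^2 +
      (at$z[heavy] - at$z[i])^2
    j <- which.min(d2)
    if (d2[j] < 1.4^2) heavy[j] else NA_integer_
  }
  for (i in which(a$hb_role == "donor-H")) {
    dh <- find_heavy(a, i)
    if (is.na(dh)) next
    for (j in which(b$hb_role == "acceptor")) {
      v <- hb_one(c(a$x[dh], a$y[dh], a$z[dh]), c(a$x[i], a$y[i], a$z[i]),
                  c(b$x[j], b$y[j], b$z[j]))
      if (!is.na(v)) { hb <- hb + v; hb_kill[dh, j] <- TRUE }
    }
  }
  for (j in which(b$hb_role == "donor-H")) {
    dh <- find_heavy(b, j)
    if (is.na(dh)) next
    for (i in which(a$hb_role == "acceptor")) {
      v <- hb_one(c(b$x[dh], b$y[dh], b$z[dh]), c(b$x[j], b$y[j], b$z[j]),
                  c(a$x[i], a$y[i], a$z[i]))
      if (!is.na(v)) { hb <- hb + v; hb_kill[i, dh] <- TRUE }
    }
  }
  for (j in seq_len(nrow(b))) {
    for (i in seq_len(nrow(a))) {
      r <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
                (a$z[i] - b$z[j])^2)
      if (r >= params$cutoff) next
      D0i <- look(a$type[i], "D0"); D0j <- look(b$type[j], "D0")
      R0i <- look(a$type[i], "R0"); R0j <- look(b$type[j], "R0")
      D0 <- if (params$d0_mixing == "geometric") sqrt(D0i * D0j) else (D0i + D0j) / 2
      R0 <- if (params$r0_mixing == "arithmetic") (R0i + R0j) / 2 else sqrt(R0i * R0j)
      if (!hb_kill[i, j]) disp <- disp + D0 * ((R0 / r)^12 - 2 * (R0 / r)^6)
      qi <- ifelse(is.na(a$charge[i]), 0, a$charge[i])
      qj <- ifelse(is.na(b$charge[j]), 0, b$charge[j])
      elec <- elec + params$ke * qi * qj / (params$epsilon * r)
    }
  }
  list(total = disp + elec + hb, dispersive = disp, electrostatic = elec,
       hbond = hb)
}

# Independent exhaustive pose enumerator: replays every grid point and
# rotation triple with its own rotation matrices and per-pose loops,
# including the clash rule, and returns the full ranked table.
brute_force_search <- function(host, probe, config, params) {
  grid <- build_grid(host, config)   # shared plumbing; energies are the oracle
  angles <- seq(0, 360 - config$angle_step, by = config$angle_step)
  rotmat <- function(a, b, c) {
    a <- a * pi / 180; b <- b * pi / 180; c <- c * pi / 180
    Rz <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
    Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
    Rx <- rbind(c(1, 0, 0), c(0, cos(c), -sin(c)), c(0, sin(c), cos(c)))
    Rz %*% Ry %*% Rx
  }
  look <- function(t, col) params$types[[col]][match(t, params$types$type)]
  ha <- host$atoms; pa <- probe$atoms
  P0 <- as.matrix(pa[, c("x", "y", "z")])
  P0 <- sweep(P0, 2, colMeans(P0))
  R0h <- look(ha$type, "R0"); R0p <- look(pa$type, "R0")
  rows <- list()
  k <- 0L
  trip <- expand.grid(a3 = angles, a2 = angles, a1 = angles)
  trip <- trip[, c("a1", "a2", "a3")]
  for (ri in seq_len(nrow(trip))) {
    PR <- P0 %*% t(rotmat(trip$a1[ri], trip$a2[ri], trip$a3[ri]))
    for (gi in seq_len(nrow(grid))) {
      k <- k + 1L
      PX <- sweep(PR, 2, grid[gi, ], "+")
      clash <- FALSE
      for (j in seq_len(nrow(pa))) {
        d <- sqrt((ha$x - PX[j, 1])^2 + (ha$y - PX[j, 2])^2 +
                  (ha$z - PX[j, 3])^2)
        if (any(d < 0.8 * (R0h + R0p[j]) / 2)) { clash <- TRUE; break }
      }
      if (clash) next
      pb <- probe
      pb$atoms$x <- PX[, 1]; pb$atoms$y <- PX[, 2]; pb$atoms$z <- PX[, 3]
      e <- brute_body_energy(host, pb, params)
      rows[[length(rows) + 1]] <- data.frame(
        gi = gi, ri = ri, total = e$total, dispersive = e$dispersive,
        electrostatic = e$electrostatic, hbond = e$hbond)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$total, out$gi, out$ri), , drop = FALSE]
}

# quick single-atom body
atom_body <- function(x, y, z, type = "X_sc", q = 0, element = "X",
                      label = "atom") {
  body(data.frame(element = element, x = x, y = y, z = z, charge = q,
                  type = type, stringsAsFactors = FALSE), label)
}

# random small neutral rigid bodies with custom toy types
random_body <- function(n, types, spread = 2.5, label = "random body") {
  at <- data.frame(
    element = "X",
    x = runif(n, -spread, spread), y = runif(n, -spread, spread),
    z = runif(n, -spread, spread),
    charge = { q <- runif(n, -0.3, 0.3); q - mean(q) },
    type = sample(types, n, replace = TRUE),
    stringsAsFactors = FALSE)
  body(at, label)
}

toy_types_params <- function(..., cutoff = 12) {
  ff_params(extra = data.frame(
    type = c("T_a", "T_b", "T_c"),
    D0 = c(0.12, 0.2, 0.08), R0 = c(3.0, 3.4, 2.8)), cutoff = cutoff, ...)
}
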