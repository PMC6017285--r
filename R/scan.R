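## Exhaustive position x orientation molecular-mechanics scan:
## per-point minima, penetration potential W(Z), Boltzmann-averaged PES,
## global minimum and inclusion classification.

#' Cartesian scan grid
#'
#' A regular lattice of guest centre-of-mass positions in the host frame.
#' The reference protocol uses -5..5 Å on each axis at 0.1 Å spacing; tests
#' and examples use coarser grids.
#'
#' @param xlim,ylim,zlim Length-2 bounds per axis (Å).
#' @param spacing Lattice spacing (Å), > 0.
#' @return An object of class `scan_grid` with the axis point vectors.
#' @export
#' @examples
#' scan_grid(spacing = 1)
scan_grid <- function(xlim = c(-5, 5), ylim = c(-5, 5), zlim = c(-5, 5),
                      spacing = 0.1) {
  stopifnot(spacing > 0, xlim[1] <= xlim[2], ylim[1] <= ylim[2],
            zlim[1] <= zlim[2])
  ax <- function(lim) seq(lim[1], lim[2], by = spacing)
  structure(
    list(xs = ax(xlim), ys = ax(ylim), zs = ax(zlim), spacing = spacing),
    class = "scan_grid"
  )
}

#' @export
print.scan_grid <- function(x, ...) {
  cat(sprintf("<scan_grid> %d x %d x %d points, spacing %.3g A\n",
              length(x$xs), length(x$ys), length(x$zs), x$spacing))
  invisible(x)
}

#' Generate a guest orientation set
#'
#' Either a regular lattice over the intrinsic Z-Y'-Z'' Euler angles
#' (reproducible, the default) or seeded uniform random rotations
#' (Shoemake's algorithm).  The default lattice is 36 x 18 x 36 = 23,328
#' orientations; beta is sampled at cell midpoints so the lattice never
#' degenerates at the poles.
#'
#' @param scheme `"euler-lattice"` or `"random"`.
#' @param count Target number of orientations (>= 1).  For the Euler
#'   lattice the realized count is `2n * n * 2n` with
#'   `n = round((count/4)^(1/3))`, the closest such product to the target;
#'   `count = 1` gives the identity orientation only.
#' @param seed RNG seed (used by the random scheme).
#' @return An object of class `orientation_set`: unit quaternion matrix `q`
#'   (one per row) plus a generator descriptor.
#' @export
#' @examples
#' generate_orientations(count = 32)
#' nrow(generate_orientations(count = 23000)$q)  # 23328
generate_orientations <- function(scheme = c("euler-lattice", "random"),
                                  count = 23000, seed = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(count >= 1)
  if (count == 1) {
    q <- matrix(c(1, 0, 0, 0), nrow = 1)
    desc <- list(scheme = scheme, count = 1L)
  } else if (scheme == "euler-lattice") {
    nb <- max(1L, as.integer(round((count / 4)^(1 / 3))))
    na <- 2L * nb
    alphas <- 2 * pi * (seq_len(na) - 1) / na
    betas <- pi * (seq_len(nb) - 0.5) / nb
    gammas <- 2 * pi * (seq_len(na) - 1) / na
    grid <- expand.grid(gamma = gammas, beta = betas, alpha = alphas)
    q <- t(mapply(euler_to_quaternion, grid$alpha, grid$beta, grid$gamma))
    desc <- list(scheme = scheme, count = nrow(q),
                 n_alpha = na, n_beta = nb, n_gamma = na)
  } else {
    q <- with_seed(seed, random_quaternions(as.integer(count)))
    desc <- list(scheme = scheme, count = as.integer(count), seed = seed)
  }
  structure(list(q = q, descriptor = desc), class = "orientation_set")
}

#' @export
print.orientation_set <- function(x, ...) {
  cat(sprintf("<orientation_set> %d orientations (%s)\n",
              nrow(x$q), x$descriptor$scheme))
  invisible(x)
}

## Distances below this floor are clamped to avoid numeric overflow in the
## r^-12 terms; per-point energies above the clamp are flagged clashes.
.r_floor <- 0.1
.e_clamp <- 1e6

#' Position x orientation energy scan
#'
#' At every grid point the total energy `E` is evaluated for every
#' orientation in the set and the minimum (with its intermolecular
#' components) is recorded.  The guest is treated rigidly, so its bonded
#' intramolecular energy is a conformational constant added to every
#' configuration.  Grid points where every orientation clashes
#' (a pair distance at the 0.1 Å hard floor driving the energy beyond
#' 1e6 kcal/mol) are flagged.
#'
#' @param host `mm_molecule`, already in its host frame (see
#'   [to_host_frame()]).
#' @param guest `mm_molecule`.
#' @param grid A [scan_grid()].
#' @param orientations An [generate_orientations()] set.
#' @param params [ff_params()].
#' @param solvent [solvent_model()].
#' @return An object of class `scan_result`; `tidy()` returns the per-point
#'   table with columns `x`, `y`, `z`, `e_min`, `einter_min`, `lj`, `ele`,
#'   `hbond`, `orient`, `clash`.
#' @export
mm_scan <- function(host, guest, grid, orientations, params,
                    solvent = solvent_model()) {
  pt <- .pair_table(host, guest, params)
  hxyz <- mol_coords(host)
  gref <- sweep(mol_coords(guest), 2, mol_com(guest))
  pts <- expand.grid(x = grid$xs, y = grid$ys, z = grid$zs,
                     KEEP.OUT.ATTRS = FALSE)
  P <- nrow(pts)
  px <- pts$x; py <- pts$y; pz <- pts$z
  eintra <- .guest_eintra_const(guest, params)

  best <- rep(Inf, P)
  best_lj <- best_ele <- best_hb <- rep(NA_real_, P)
  best_o <- rep(NA_integer_, P)
  clash_best <- rep(TRUE, P)
  eps <- solvent$epsilon
  nhb <- !pt$hb
  for (o in seq_len(nrow(orientations$q))) {
    g <- rotate_coords(gref, orientations$q[o, ])
    lj <- ele <- hb <- numeric(P)
    clash <- rep(FALSE, P)
    for (p in seq_along(pt$ii)) {
      gi <- pt$ii[p]; hj <- pt$jj[p]
      dx <- px + g[gi, 1] - hxyz[hj, 1]
      dy <- py + g[gi, 2] - hxyz[hj, 2]
      dz <- pz + g[gi, 3] - hxyz[hj, 3]
      R <- sqrt(dx * dx + dy * dy + dz * dz)
      low <- R < .r_floor
      if (any(low)) {
        R[low] <- .r_floor
        clash[low] <- TRUE
      }
      inv2 <- 1 / (R * R)
      inv6 <- inv2^3
      if (nhb[p]) {
        lj <- lj + pt$A[p] * inv6^2 - pt$B[p] * inv6
      } else {
        hb <- hb + pt$C[p] * inv6^2 - pt$D[p] * inv6 * inv2 * inv2
      }
      if (pt$qq[p] != 0) ele <- ele + (.coulomb / eps) * pt$qq[p] / R
    }
    einter <- lj + ele + hb
    over <- einter > .e_clamp
    if (any(over)) {
      einter[over] <- .e_clamp
      clash[over] <- TRUE
    }
    upd <- einter < best
    if (any(upd)) {
      best[upd] <- einter[upd]
      best_lj[upd] <- lj[upd]; best_ele[upd] <- ele[upd]
      best_hb[upd] <- hb[upd]; best_o[upd] <- o
      clash_best[upd] <- clash[upd]
    }
  }
  points <- tibble(
    x = px, y = py, z = pz,
    einter_min = best, e_min = best + eintra,
    lj = best_lj, ele = best_ele, hbond = best_hb,
    orient = best_o, clash = clash_best
  )
  structure(
    list(points = points, grid = grid, orientations = orientations,
         epsilon = eps, guest_eintra = eintra),
    class = "scan_result"
  )
}

.guest_eintra_const <- function(guest, params) {
  if (nrow(guest$bonds) + nrow(guest$angles) + nrow(guest$torsions) > 0) {
    ei <- intramolecular_energy(guest, params)
    ei$bond + ei$angle + ei$torsion
  } else {
    0
  }
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result> %d grid points, %d orientations, Emin = %.4g kcal/mol\n",
              nrow(x$points), nrow(x$orientations$q), min(x$points$e_min)))
  invisible(x)
}

#' Penetration potential W(Z)
#'
#' The curve joining the minimum intermolecular energy over every plane
#' Z = constant (all X, Y and orientations): the variation of Einter along
#' the cavity axis.  The components reported per level are those of the
#' minimizing configuration.
#'
#' @param scan A [mm_scan()] result.
#' @return A tibble of class `penetration_potential` with columns `z`, `W`,
#'   `lj`, `ele`, `hbond`, `x`, `y`, `orient`.
#' @export
penetration_potential <- function(scan) {
  out <- scan$points |>
    dplyr::group_by(.data$z) |>
    dplyr::arrange(.data$einter_min, .data$x, .data$y, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      z = .data$z, W = .data$einter_min, lj = .data$lj, ele = .data$ele,
      hbond = .data$hbond, x = .data$x, y = .data$y, orient = .data$orient
    )
  class(out) <- c("penetration_potential", class(out))
  out
}

#' Boltzmann-averaged potential energy surface
#'
#' At each grid point the Boltzmann-weighted mean of the total energy over
#' the orientation set, `<E> = sum(E_i exp(-E_i/kBT)) / sum(exp(-E_i/kBT))`,
#' computed with an overflow-safe running shift.  The per-point minimum and
#' arithmetic mean over orientations are returned alongside.  The host's Z
#' extent is split into four contiguous slabs of equal width (narrower rim
#' to wider rim) and each slab's surface is the per-(X,Y) minimum of `<E>`
#' within it.
#'
#' @inheritParams mm_scan
#' @param temperature Temperature (K) of the Boltzmann weights.
#' @return An object of class `pes_map`: `$points` (per-point `e_avg`,
#'   `e_min`, `e_mean`) and `$slabs` (per-domain per-(X,Y) surfaces with
#'   domain labels from `"narrower rim"` to `"wider rim"`).
#' @export
boltzmann_pes <- function(host, guest, grid, orientations, params,
                          solvent = solvent_model(), temperature = 293) {
  stopifnot(temperature > 0)
  kT <- .kb * temperature
  pt <- .pair_table(host, guest, params)
  hxyz <- mol_coords(host)
  gref <- sweep(mol_coords(guest), 2, mol_com(guest))
  pts <- expand.grid(x = grid$xs, y = grid$ys, z = grid$zs,
                     KEEP.OUT.ATTRS = FALSE)
  P <- nrow(pts)
  px <- pts$x; py <- pts$y; pz <- pts$z
  eintra <- .guest_eintra_const(guest, params)
  eps <- solvent$epsilon
  nhb <- !pt$hb

  m <- rep(Inf, P)       # running minimum (shift for the exponentials)
  s1 <- s2 <- rep(0, P)  # shifted partition sum and energy-weighted sum
  ssum <- rep(0, P)      # plain sum for the arithmetic mean
  n_o <- nrow(orientations$q)
  for (o in seq_len(n_o)) {
    g <- rotate_coords(gref, orientations$q[o, ])
    lj <- ele <- hb <- numeric(P)
    for (p in seq_along(pt$ii)) {
      gi <- pt$ii[p]; hj <- pt$jj[p]
      dx <- px + g[gi, 1] - hxyz[hj, 1]
      dy <- py + g[gi, 2] - hxyz[hj, 2]
      dz <- pz + g[gi, 3] - hxyz[hj, 3]
      R <- sqrt(dx * dx + dy * dy + dz * dz)
      R[R < .r_floor] <- .r_floor
      inv2 <- 1 / (R * R)
      inv6 <- inv2^3
      if (nhb[p]) {
        lj <- lj + pt$A[p] * inv6^2 - pt$B[p] * inv6
      } else {
        hb <- hb + pt$C[p] * inv6^2 - pt$D[p] * inv6 * inv2 * inv2
      }
      if (pt$qq[p] != 0) ele <- ele + (.coulomb / eps) * pt$qq[p] / R
    }
    E <- pmin(lj + ele + hb, .e_clamp) + eintra
    newm <- pmin(m, E)
    fac <- exp((newm - m) / kT)  # <= 1; 0*Inf cannot occur (s=0 when m=Inf)
    fac[!is.finite(fac)] <- 0
    w <- exp(-(E - newm) / kT)
    s1 <- s1 * fac + w
    s2 <- s2 * fac + E * w
    ssum <- ssum + E
    m <- newm
  }
  points <- tibble(
    x = px, y = py, z = pz,
    e_avg = s2 / s1, e_min = m, e_mean = ssum / n_o
  )
  slabs <- .pes_slabs(points, host)
  structure(
    list(points = points, slabs = slabs, temperature = temperature,
         grid = grid),
    class = "pes_map"
  )
}

.pes_slabs <- function(points, host) {
  zext <- range(mol_coords(host)[, 3])
  edges <- seq(zext[1], zext[2], length.out = 5)
  labels <- c("narrower rim", "centre (narrow side)",
              "centre (wide side)", "wider rim")
  purrr::map_dfr(1:4, function(k) {
    sel <- points$z >= edges[k] & points$z <= edges[k + 1]
    if (!any(sel)) {
      return(tibble(domain = character(), z_lo = numeric(), z_hi = numeric(),
                    x = numeric(), y = numeric(), energy = numeric()))
    }
    points[sel, ] |>
      dplyr::group_by(.data$x, .data$y) |>
      dplyr::summarise(energy = min(.data$e_avg), .groups = "drop") |>
      dplyr::mutate(domain = labels[k], z_lo = edges[k], z_hi = edges[k + 1],
                    .before = 1)
  })
}

#' Global minimum of a scan
#'
#' The lattice-and-orientation-set minimizer of the total energy.  Ties are
#' broken lexicographically by (Z, X, Y, orientation index).
#'
#' @param scan A [mm_scan()] result.
#' @param guest,params Supply the scanned guest and parameters to re-derive
#'   the full energy breakdown at the minimizing pose.
#' @param host,solvent As in the scan (needed with `guest`).
#' @return A list with `e_min` (kcal/mol), `pose` (the minimizing [pose()]),
#'   `orient` (orientation index) and, when the system is supplied,
#'   `breakdown` (the [energy_breakdown()] at the minimum).
#' @export
global_minimum <- function(scan, host = NULL, guest = NULL, params = NULL,
                           solvent = solvent_model()) {
  pts <- scan$points
  finite <- is.finite(pts$e_min) & !pts$clash
  if (!any(finite)) {
    finite <- is.finite(pts$e_min)
    if (!any(finite)) abort("scan has no finite energy anywhere")
  }
  cand <- pts[finite, ]
  cand <- cand[order(cand$e_min, cand$z, cand$x, cand$y, cand$orient), ]
  row <- cand[1, ]
  ps <- pose(com = c(row$x, row$y, row$z),
             quaternion = scan$orientations$q[row$orient, ])
  out <- list(e_min = row$e_min, pose = ps, orient = row$orient, point = row)
  if (!is.null(guest) && !is.null(host) && !is.null(params)) {
    out$breakdown <- total_energy(host, guest, ps, params, solvent)
  }
  out
}

#' Cavity geometry of a truncated-cone host
#'
#' Estimates the host's Z extent and the effective cavity wall radii at the
#' two rims from the atom positions (mean radial distance within the outer
#' quarter of the Z extent at each end).  The cavity radius at intermediate
#' Z is interpolated linearly.
#'
#' @param host `mm_molecule` in its host frame.
#' @return A list `z_lo`, `z_hi`, `r_lo`, `r_hi`.
#' @export
cavity_geometry <- function(host) {
  xyz <- mol_coords(host)
  z <- xyz[, 3]
  r <- sqrt(xyz[, 1]^2 + xyz[, 2]^2)
  z_lo <- min(z); z_hi <- max(z)
  span <- max(z_hi - z_lo, 1e-8)
  lo <- z <= z_lo + 0.25 * span
  hi <- z >= z_hi - 0.25 * span
  list(z_lo = z_lo, z_hi = z_hi, r_lo = mean(r[lo]), r_hi = mean(r[hi]))
}

#' Classify a guest placement as inclusion or non-inclusion
#'
#' A configuration is an inclusion complex when the guest is totally or
#' partially inside the host cavity: an atom is "inside" if its Z lies
#' within the host's Z extent and its radial distance is within the
#' linearly interpolated cavity wall radius at that Z.
#'
#' @param guest_xyz `n x 3` matrix of placed guest coordinates (host frame),
#'   e.g. from [place_guest()].
#' @param host `mm_molecule` in its host frame.
#' @return A one-row tibble with `inclusion` (logical), `fraction_inside`,
#'   `n_inside`, `n_atoms`.
#' @export
classify_inclusion <- function(guest_xyz, host) {
  cg <- cavity_geometry(host)
  z <- guest_xyz[, 3]
  r <- sqrt(guest_xyz[, 1]^2 + guest_xyz[, 2]^2)
  frac_z <- (z - cg$z_lo) / max(cg$z_hi - cg$z_lo, 1e-8)
  r_wall <- cg$r_lo + frac_z * (cg$r_hi - cg$r_lo)
  inside <- z >= cg$z_lo & z <= cg$z_hi & r <= r_wall
  tibble(
    inclusion = any(inside),
    fraction_inside = mean(inside),
    n_inside = sum(inside),
    n_atoms = length(inside)
  )
}
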