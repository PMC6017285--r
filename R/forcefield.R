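## AMBER-style force field: Lennard-Jones + continuum-dielectric
## electrostatics + 12-10 hydrogen-bond pairs between molecules, and
## harmonic bond/angle plus cosine torsion terms within a molecule.

#' Continuum solvent model
#'
#' The solvent enters the energy only through a relative dielectric constant
#' scaling the Coulomb term (epsilon = 80 for water, 26 for ethanol).
#'
#' @param epsilon Relative dielectric constant (>= 1).
#' @return An object of class `solvent_model`.
#' @export
solvent_model <- function(epsilon = 80) {
  if (!is.numeric(epsilon) || epsilon < 1) abort("epsilon must be >= 1")
  structure(list(epsilon = as.numeric(epsilon)), class = "solvent_model")
}

#' Force-field parameter set
#'
#' Holds per-type Lennard-Jones coefficients, per-pair 12-10 hydrogen-bond
#' coefficients, and bonded (bond/angle/torsion) parameters.  Per-type LJ
#' coefficients are combined geometrically across a pair:
#' `Aij = sqrt(Ai*Aj)`, `Bij = sqrt(Bi*Bj)`.
#'
#' @param types Tibble with columns `type`, `A` (kcal Å^12/mol), `B`
#'   (kcal Å^6/mol).  Alternatively columns `epsilon` (kcal/mol) and `rmin`
#'   (Å, pair-minimum distance for a like pair), converted via
#'   `A = epsilon*rmin^12`, `B = 2*epsilon*rmin^6`.
#' @param hbond Tibble with columns `donor`, `acceptor` (ff types of the
#'   donor hydrogen and the acceptor atom), `C` (kcal Å^12/mol), `D`
#'   (kcal Å^10/mol).  For flagged donor-H/acceptor pairs the 12-10 term
#'   replaces the 12-6 term.
#' @param bonds Tibble `type1`, `type2`, `kr` (kcal/mol/Å^2), `req` (Å).
#' @param angles Tibble `type1..type3`, `ktheta` (kcal/mol/rad^2),
#'   `theta_eq` (degrees).
#' @param torsions Tibble `type1..type4`, `Vn` (kcal/mol), `n` (multiplicity),
#'   `gamma` (degrees).  `"X"` acts as a wildcard in the outer positions.
#' @return An object of class `ff_params`.
#' @export
ff_params <- function(types,
                      hbond = NULL, bonds = NULL, angles = NULL,
                      torsions = NULL) {
  types <- as_tibble(types)
  if (!"A" %in% names(types)) {
    if (!all(c("epsilon", "rmin") %in% names(types))) {
      abort("types needs columns A/B or epsilon/rmin")
    }
    types$A <- types$epsilon * types$rmin^12
    types$B <- 2 * types$epsilon * types$rmin^6
  }
  if (any(types$A < 0) || any(types$B < 0)) abort("LJ A and B must be >= 0")
  hbond <- if (is.null(hbond)) {
    tibble(donor = character(), acceptor = character(),
           C = numeric(), D = numeric())
  } else as_tibble(hbond)
  if (any(hbond$C < 0) || any(hbond$D < 0)) abort("H-bond C and D must be >= 0")
  bonds <- if (is.null(bonds)) {
    tibble(type1 = character(), type2 = character(),
           kr = numeric(), req = numeric())
  } else as_tibble(bonds)
  angles <- if (is.null(angles)) {
    tibble(type1 = character(), type2 = character(), type3 = character(),
           ktheta = numeric(), theta_eq = numeric())
  } else as_tibble(angles)
  torsions <- if (is.null(torsions)) {
    tibble(type1 = character(), type2 = character(), type3 = character(),
           type4 = character(), Vn = numeric(), n = integer(),
           gamma = numeric())
  } else as_tibble(torsions)
  if (any(bonds$kr < 0) || any(angles$ktheta < 0)) {
    abort("force constants must be >= 0")
  }
  if (nrow(torsions) > 0 && any(torsions$n < 1)) {
    abort("torsion multiplicity n must be >= 1")
  }
  structure(
    list(types = types, hbond = hbond, bonds = bonds, angles = angles,
         torsions = torsions),
    class = "ff_params"
  )
}

#' Read force-field parameters from a YAML file
#'
#' Schema: top-level keys `atom_types` (map type -> `{A, B}` or
#' `{epsilon, rmin}`), and optional lists `hbond_pairs`
#' (`{donor, acceptor, C, D}`), `bonds` (`{types: [t1, t2], kr, req}`),
#' `angles` (`{types: [t1, t2, t3], ktheta, theta_eq}` with `theta_eq` in
#' degrees), `torsions` (`{types: [t1..t4], terms: [{Vn, n, gamma}]}` with
#' `gamma` in degrees).
#'
#' @param path Path to the YAML parameter table.
#' @return An [ff_params()] object.
#' @export
read_ff_params <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$atom_types)) abort("parameter file lacks 'atom_types'")
  types <- purrr::imap_dfr(y$atom_types, function(v, nm) {
    if (!is.null(v$A)) {
      tibble(type = nm, A = v$A, B = v$B %||% 0)
    } else if (!is.null(v$epsilon)) {
      tibble(type = nm, A = v$epsilon * v$rmin^12, B = 2 * v$epsilon * v$rmin^6)
    } else {
      abort(paste0("atom type '", nm, "' needs A/B or epsilon/rmin"))
    }
  })
  hb <- purrr::map_dfr(y$hbond_pairs %||% list(), function(p) {
    tibble(donor = p$donor, acceptor = p$acceptor, C = p$C, D = p$D)
  })
  bd <- purrr::map_dfr(y$bonds %||% list(), function(p) {
    tibble(type1 = p$types[[1]], type2 = p$types[[2]], kr = p$kr, req = p$req)
  })
  an <- purrr::map_dfr(y$angles %||% list(), function(p) {
    tibble(type1 = p$types[[1]], type2 = p$types[[2]], type3 = p$types[[3]],
           ktheta = p$ktheta, theta_eq = p$theta_eq)
  })
  to <- purrr::map_dfr(y$torsions %||% list(), function(p) {
    purrr::map_dfr(p$terms, function(tm) {
      tibble(type1 = p$types[[1]], type2 = p$types[[2]],
             type3 = p$types[[3]], type4 = p$types[[4]],
             Vn = tm$Vn, n = as.integer(tm$n), gamma = tm$gamma)
    })
  })
  ff_params(types,
            hbond = if (nrow(hb)) hb else NULL,
            bonds = if (nrow(bd)) bd else NULL,
            angles = if (nrow(an)) an else NULL,
            torsions = if (nrow(to)) to else NULL)
}

## Resolve per-atom LJ coefficients against the type table.
.lj_per_atom <- function(params, ff_types) {
  idx <- match(ff_types, params$types$type)
  if (anyNA(idx)) {
    abort(paste0("unresolvable ff_type(s): ",
                 paste(unique(ff_types[is.na(idx)]), collapse = ", ")))
  }
  list(A = params$types$A[idx], B = params$types$B[idx])
}

## Precompute the host-guest pair table: indices, combined LJ coefficients,
## charge products, and the hydrogen-bond pair mask with its C/D values.
.pair_table <- function(host, guest, params) {
  nh <- n_atoms(host); ng <- n_atoms(guest)
  ljh <- .lj_per_atom(params, host$atoms$ff_type)
  ljg <- .lj_per_atom(params, guest$atoms$ff_type)
  ii <- rep(seq_len(ng), times = nh)        # guest atom index
  jj <- rep(seq_len(nh), each = ng)         # host atom index
  A <- sqrt(ljg$A[ii] * ljh$A[jj])
  B <- sqrt(ljg$B[ii] * ljh$B[jj])
  qq <- guest$atoms$charge[ii] * host$atoms$charge[jj]
  rg <- guest$atoms$hbond_role[ii]
  rh <- host$atoms$hbond_role[jj]
  tg <- guest$atoms$ff_type[ii]
  th <- host$atoms$ff_type[jj]
  hb <- rep(FALSE, length(ii))
  C <- D <- numeric(length(ii))
  if (nrow(params$hbond) > 0) {
    key <- paste(params$hbond$donor, params$hbond$acceptor)
    k1 <- match(paste(tg, th), key)  # guest donor-H, host acceptor
    k2 <- match(paste(th, tg), key)  # host donor-H, guest acceptor
    m1 <- rg == "donor-H" & rh == "acceptor" & !is.na(k1)
    m2 <- rh == "donor-H" & rg == "acceptor" & !is.na(k2)
    hb <- m1 | m2
    C[m1] <- params$hbond$C[k1[m1]]; D[m1] <- params$hbond$D[k1[m1]]
    C[m2] <- params$hbond$C[k2[m2]]; D[m2] <- params$hbond$D[k2[m2]]
  }
  list(ii = ii, jj = jj, A = A, B = B, qq = qq, hb = hb, C = C, D = D,
       ng = ng, nh = nh)
}

## Intermolecular components from a pair table and pair distances.
.inter_components <- function(pt, R, epsilon) {
  inv2 <- 1 / (R * R)
  inv6 <- inv2^3
  inv10 <- inv6 * inv2 * inv2
  inv12 <- inv6^2
  nhb <- !pt$hb
  lj <- sum(pt$A[nhb] * inv12[nhb] - pt$B[nhb] * inv6[nhb])
  hbond <- sum(pt$C[pt$hb] * inv12[pt$hb] - pt$D[pt$hb] * inv10[pt$hb])
  ele <- (.coulomb / epsilon) * sum(pt$qq / R)
  c(lj = lj, ele = ele, hbond = hbond)
}

## dU/dR per pair (kcal/mol/A); same term selection as .inter_components.
.inter_dUdR <- function(pt, R, epsilon) {
  invR <- 1 / R
  inv2 <- invR * invR
  inv7 <- inv2^3 * invR
  inv11 <- inv7 * inv2 * inv2
  inv13 <- inv11 * inv2
  dU <- -(.coulomb / epsilon) * pt$qq * inv2
  nhb <- !pt$hb
  dU[nhb] <- dU[nhb] - 12 * pt$A[nhb] * inv13[nhb] + 6 * pt$B[nhb] * inv7[nhb]
  dU[pt$hb] <- dU[pt$hb] - 12 * pt$C[pt$hb] * inv13[pt$hb] +
    10 * pt$D[pt$hb] * inv11[pt$hb]
  dU
}

.pair_distances <- function(pt, guest_xyz, host_xyz) {
  diff <- guest_xyz[pt$ii, , drop = FALSE] - host_xyz[pt$jj, , drop = FALSE]
  R <- sqrt(rowSums(diff * diff))
  list(diff = diff, R = R)
}

.check_singularity <- function(pt, R) {
  if (any(R == 0)) {
    k <- which(R == 0)[1]
    abort(sprintf("coincident atoms: guest atom %d and host atom %d (Rij = 0)",
                  pt$ii[k], pt$jj[k]))
  }
}

#' Intermolecular interaction energy
#'
#' Sums the Lennard-Jones, continuum-dielectric electrostatic and 12-10
#' hydrogen-bond terms over all host-guest atom pairs (no distance cutoff).
#' For pairs flagged as donor-H/acceptor with tabulated C/D coefficients the
#' 12-10 term replaces the 12-6 term.
#'
#' @param host,guest `mm_molecule` objects.
#' @param params An [ff_params()] parameter set.
#' @param solvent A [solvent_model()].
#' @param guest_xyz Optional posed guest coordinates (defaults to the
#'   guest's stored coordinates).
#' @return A one-row tibble with columns `lj`, `ele`, `hbond` (kcal/mol).
#' @export
intermolecular_energy <- function(host, guest, params, solvent = solvent_model(),
                                  guest_xyz = NULL) {
  pt <- .pair_table(host, guest, params)
  gx <- guest_xyz %||% mol_coords(guest)
  d <- .pair_distances(pt, gx, mol_coords(host))
  .check_singularity(pt, d$R)
  as_tibble(as.list(.inter_components(pt, d$R, solvent$epsilon)))
}

## ---- intramolecular terms ----

.match_bond_param <- function(params, t1, t2) {
  tb <- params$bonds
  hit <- which((tb$type1 == t1 & tb$type2 == t2) |
                 (tb$type1 == t2 & tb$type2 == t1))
  if (length(hit) == 0) {
    abort(paste0("no bond parameters for type pair ", t1, "-", t2))
  }
  tb[hit[1], ]
}

.match_angle_param <- function(params, t1, t2, t3) {
  tb <- params$angles
  hit <- which((tb$type1 == t1 & tb$type2 == t2 & tb$type3 == t3) |
                 (tb$type1 == t3 & tb$type2 == t2 & tb$type3 == t1))
  if (length(hit) == 0) {
    abort(paste0("no angle parameters for types ", t1, "-", t2, "-", t3))
  }
  tb[hit[1], ]
}

.match_torsion_params <- function(params, t1, t2, t3, t4) {
  tb <- params$torsions
  ok <- function(a, b) a == b | a == "X"
  fwd <- ok(tb$type1, t1) & ok(tb$type2, t2) & ok(tb$type3, t3) & ok(tb$type4, t4)
  rev <- ok(tb$type1, t4) & ok(tb$type2, t3) & ok(tb$type3, t2) & ok(tb$type4, t1)
  hits <- tb[fwd | rev, , drop = FALSE]
  if (nrow(hits) == 0) {
    abort(paste0("no torsion parameters for types ",
                 paste(c(t1, t2, t3, t4), collapse = "-")))
  }
  ## prefer exact (non-wildcard) matches over wildcard entries
  exact <- hits[hits$type1 != "X" & hits$type4 != "X", , drop = FALSE]
  if (nrow(exact) > 0) exact else hits
}

.dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20) {
    abort("undefined dihedral: three collinear atoms")
  }
  m1 <- c(n1[2] * n2[3] - n1[3] * n2[2],
          n1[3] * n2[1] - n1[1] * n2[3],
          n1[1] * n2[2] - n1[2] * n2[1])
  b2n <- sqrt(sum(b2^2))
  atan2(sum(m1 * b2) / b2n, sum(n1 * n2))
}

#' Intramolecular (bonded) energy
#'
#' Harmonic bond stretching `kr*(r - req)^2` and angle bending
#' `ktheta*(theta - theta_eq)^2`, plus the cosine torsion series
#' `Vn/2 * (1 + cos(n*phi - gamma))` over the molecule's enumerated
#' topology.  Nonbonded intramolecular pairs are not evaluated: the
#' intramolecular energy is the bonded conformational strain.
#'
#' @param mol An `mm_molecule` with topology (see [derive_topology()]).
#' @param params An [ff_params()] with the needed bonded entries.
#' @param xyz Optional replacement coordinates.
#' @return A one-row tibble with columns `bond`, `angle`, `torsion`
#'   (kcal/mol).
#' @export
intramolecular_energy <- function(mol, params, xyz = NULL) {
  xyz <- xyz %||% mol_coords(mol)
  ty <- mol$atoms$ff_type
  e_bond <- 0
  for (b in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds[b, 1]; j <- mol$bonds[b, 2]
    p <- .match_bond_param(params, ty[i], ty[j])
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    e_bond <- e_bond + p$kr * (r - p$req)^2
  }
  e_angle <- 0
  for (a in seq_len(nrow(mol$angles))) {
    i <- mol$angles[a, 1]; j <- mol$angles[a, 2]; k <- mol$angles[a, 3]
    p <- .match_angle_param(params, ty[i], ty[j], ty[k])
    v1 <- xyz[i, ] - xyz[j, ]; v2 <- xyz[k, ] - xyz[j, ]
    cth <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    theta <- acos(pmin(1, pmax(-1, cth)))
    e_angle <- e_angle + p$ktheta * (theta - p$theta_eq * pi / 180)^2
  }
  e_tor <- 0
  for (t in seq_len(nrow(mol$torsions))) {
    q <- mol$torsions[t, ]
    phi <- .dihedral_angle(xyz[q[1], ], xyz[q[2], ], xyz[q[3], ], xyz[q[4], ])
    p <- .match_torsion_params(params, ty[q[1]], ty[q[2]], ty[q[3]], ty[q[4]])
    e_tor <- e_tor +
      sum(p$Vn / 2 * (1 + cos(p$n * phi - p$gamma * pi / 180)))
  }
  tibble(bond = as.numeric(e_bond), angle = as.numeric(e_angle),
         torsion = as.numeric(e_tor))
}

#' Energy breakdown of a host-guest configuration
#'
#' Evaluates the full force-field energy `E = Einter + Eintra`:
#' intermolecular Lennard-Jones, electrostatic and hydrogen-bond terms over
#' all host-guest pairs, plus the guest's bonded intramolecular terms
#' (and the host's, if `include_host_intra` and the host has topology).
#' The host is held at its input geometry, so any host intramolecular
#' energy is a constant offset.
#'
#' @inheritParams intermolecular_energy
#' @param pose A [pose()] placing the guest in the host frame.
#' @param include_host_intra Evaluate the host's bonded terms too
#'   (default FALSE: a rigid literature host geometry contributes a
#'   constant that is conventionally dropped).
#' @return A one-row tibble of class `energy_breakdown` with columns
#'   `total`, `inter`, `lj`, `ele`, `hbond`, `intra`, `bond`, `angle`,
#'   `torsion` (kcal/mol).  `total = inter + intra` and
#'   `inter = lj + ele + hbond` by construction.
#' @export
total_energy <- function(host, guest, pose = NULL, params, solvent = solvent_model(),
                         include_host_intra = FALSE) {
  gx <- if (is.null(pose)) mol_coords(guest) else place_guest(guest, pose)
  inter <- intermolecular_energy(host, guest, params, solvent, guest_xyz = gx)
  intra <- if (nrow(guest$bonds) + nrow(guest$angles) + nrow(guest$torsions) > 0) {
    intramolecular_energy(guest, params, xyz = gx)
  } else {
    tibble(bond = 0, angle = 0, torsion = 0)
  }
  if (include_host_intra &&
      nrow(host$bonds) + nrow(host$angles) + nrow(host$torsions) > 0) {
    hi <- intramolecular_energy(host, params)
    intra$bond <- intra$bond + hi$bond
    intra$angle <- intra$angle + hi$angle
    intra$torsion <- intra$torsion + hi$torsion
  }
  energy_breakdown(inter$lj, inter$ele, inter$hbond,
                   intra$bond, intra$angle, intra$torsion)
}

#' @rdname total_energy
#' @param lj,ele,hbond,bond,angle,torsion Component energies (kcal/mol).
#' @export
energy_breakdown <- function(lj = 0, ele = 0, hbond = 0,
                             bond = 0, angle = 0, torsion = 0) {
  inter <- lj + ele + hbond
  intra <- bond + angle + torsion
  out <- tibble(total = inter + intra, inter = inter, lj = lj, ele = ele,
                hbond = hbond, intra = intra, bond = bond, angle = angle,
                torsion = torsion)
  class(out) <- c("energy_breakdown", class(out))
  out
}

#' Force and torque on the guest
#'
#' Analytic derivatives of the intermolecular energy: the force is the
#' negative gradient with respect to a rigid translation of the guest
#' (equivalently the sum of per-atom forces), and the torque is
#' `sum(r_i x f_i)` with `r_i` taken relative to the guest centre of mass.
#'
#' @inheritParams total_energy
#' @return A list with `force` (kcal/mol/Å, length 3) and `torque`
#'   (kcal/mol, length 3), both in the host frame.
#' @export
force_and_torque <- function(host, guest, pose, params, solvent = solvent_model()) {
  pt <- .pair_table(host, guest, params)
  gx <- place_guest(guest, pose)
  d <- .pair_distances(pt, gx, mol_coords(host))
  .check_singularity(pt, d$R)
  dU <- .inter_dUdR(pt, d$R, solvent$epsilon)
  ## force on guest atom i from pair (i, j): -dU/dR * (ri - rj)/R
  fpair <- d$diff * (-dU / d$R)
  force <- colSums(fpair)
  rel <- gx[pt$ii, , drop = FALSE] -
    matrix(pose$com, nrow = length(pt$ii), ncol = 3, byrow = TRUE)
  torque <- c(
    sum(rel[, 2] * fpair[, 3] - rel[, 3] * fpair[, 2]),
    sum(rel[, 3] * fpair[, 1] - rel[, 1] * fpair[, 3]),
    sum(rel[, 1] * fpair[, 2] - rel[, 2] * fpair[, 1])
  )
  list(force = force, torque = torque)
}
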