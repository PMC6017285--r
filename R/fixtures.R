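## Synthetic systems: an idealized truncated-cone host of Lennard-Jones
## sites (cyclodextrin-like), rod guests, an analytic harmonic probe, and
## the packaged synthetic beta-cyclodextrin/eugenol pair.

#' Idealized truncated-cone host
#'
#' Rings of identical Lennard-Jones sites at radii interpolated linearly
#' between a narrower and a wider rim, stacked along Z and centred on the
#' origin — a cyclodextrin-like cavity with the wider rim at +Z.
#' Deterministic coordinates; optional alternating site charges (net zero
#' per ring when `sites_per_ring` is even) and optional acceptor flags on
#' the wider rim for exercising the 12-10 hydrogen-bond term.
#'
#' @param n_rings Number of site rings (>= 2).
#' @param sites_per_ring Sites per ring.
#' @param r_narrow,r_wide Rim radii (Å), `r_wide > r_narrow`.
#' @param height Host height (Å).
#' @param site_charge Magnitude of the alternating site charge (e),
#'   default 0.
#' @param hbond_acceptors Mark the wider-rim sites as H-bond acceptors
#'   (ff type `"HA"`).
#' @param ff_type Force-field type of the plain sites.
#' @return An `mm_molecule` with role `"host"`.
#' @export
#' @examples
#' host <- make_toy_host()
#' round(mol_com(host), 10)
make_toy_host <- function(n_rings = 4, sites_per_ring = 8,
                          r_narrow = 4, r_wide = 5, height = 8,
                          site_charge = 0, hbond_acceptors = FALSE,
                          ff_type = "HS") {
  stopifnot(n_rings >= 2, sites_per_ring >= 3, r_narrow > 0,
            r_wide >= r_narrow, height > 0)
  zs <- seq(-height / 2, height / 2, length.out = n_rings)
  radii <- r_narrow + (zs - zs[1]) / height * (r_wide - r_narrow)
  rows <- purrr::map_dfr(seq_len(n_rings), function(k) {
    ang <- 2 * pi * (seq_len(sites_per_ring) - 1) / sites_per_ring
    on_wide_rim <- k == n_rings
    tibble(
      element = "X",
      name = sprintf("S%d_%d", k, seq_len(sites_per_ring)),
      x = radii[k] * cos(ang),
      y = radii[k] * sin(ang),
      z = zs[k],
      charge = if (site_charge != 0) {
        site_charge * rep_len(c(1, -1), sites_per_ring)
      } else 0,
      ff_type = if (hbond_acceptors && on_wide_rim) "HA" else ff_type,
      hbond_role = if (hbond_acceptors && on_wide_rim) "acceptor" else "none"
    )
  })
  mm_molecule(rows, role = "host")
}

#' Rod-like toy guest
#'
#' Collinear sites along the body X axis, centre of mass at the origin.
#' With `polar = TRUE` the +X terminal site carries `+polar_charge` and the
#' -X terminal `-polar_charge` (a crude polar end).  With
#' `torsion = TRUE` the guest is instead a 4-site zig-zag chain (type
#' `"GZ"`) with bonds populated, so [derive_topology()] yields exactly one
#' torsion; a collinear chain would leave the dihedral undefined.
#' With `donor = TRUE` the +X terminal site is a hydrogen-bond donor
#' hydrogen (ff type `"HD"`).
#'
#' @param n_sites Number of sites (>= 1).
#' @param spacing Site spacing (Å).
#' @param polar Give the terminal sites opposite charges.
#' @param polar_charge Charge magnitude (e) for the polar end.
#' @param donor Flag the +X terminal site as a donor hydrogen.
#' @param torsion Build the 4-site zig-zag torsion guest instead.
#' @param ff_type Force-field type of plain sites.
#' @return An `mm_molecule` with role `"guest"`.
#' @export
#' @examples
#' make_toy_guest(n_sites = 3, spacing = 1.5)
make_toy_guest <- function(n_sites = 3, spacing = 1.5, polar = FALSE,
                           polar_charge = 0.2, donor = FALSE,
                           torsion = FALSE, ff_type = "GS") {
  stopifnot(n_sites >= 1, spacing > 0)
  if (torsion) {
    ## zig-zag chain with ~109.5 degree angles in the XY plane
    half <- (180 - 109.471) * pi / 180 / 2
    dirs <- cbind(cos(c(-half, half, -half)), sin(c(-half, half, -half)), 0)
    xyz <- rbind(c(0, 0, 0), apply(dirs * spacing, 2, cumsum))
    xyz <- sweep(xyz, 2, colMeans(xyz))
    atoms <- tibble(
      element = "X", name = paste0("G", 1:4),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      charge = 0, ff_type = "GZ", hbond_role = "none"
    )
    bonds <- cbind(1:3, 2:4)
    return(derive_topology(mm_molecule(atoms, bonds = bonds, role = "guest")))
  }
  xs <- (seq_len(n_sites) - (n_sites + 1) / 2) * spacing
  charge <- rep(0, n_sites)
  role <- rep("none", n_sites)
  type <- rep(ff_type, n_sites)
  if (polar && n_sites >= 2) {
    charge[n_sites] <- polar_charge
    charge[1] <- -polar_charge
  }
  if (donor) {
    type[n_sites] <- "HD"
    role[n_sites] <- "donor-H"
  }
  atoms <- tibble(
    element = "X", name = paste0("G", seq_len(n_sites)),
    x = xs, y = 0, z = 0, charge = charge, ff_type = type,
    hbond_role = role
  )
  bonds <- if (n_sites >= 2) cbind(seq_len(n_sites - 1), 2:n_sites) else
    matrix(integer(), ncol = 2)
  mm_molecule(atoms, bonds = bonds, role = "guest")
}

## Like-pair LJ well depth (kcal/mol) for the toy site types.  Chosen once
## so that the default 3-site rod guest sees a cavity minimum of about
## -10 kcal/mol in the default host -- energy scales comparable to a real
## cyclodextrin complex.
.toy_eps <- 0.2482
.toy_rmin <- 4.0

#' Force-field parameters for the toy systems
#'
#' Lennard-Jones parameters for the toy host/guest site types (`HS`, `GS`,
#' `GZ`, donor `HD`, acceptor `HA`), one 12-10 hydrogen-bond pair
#' (`HD`-`HA`), and bonded terms for the rod (`GS`) and zig-zag torsion
#' (`GZ`) guests.  The like-pair well depth is fixed so the default rod
#' guest's cavity minimum in the default host is about -10 kcal/mol.
#'
#' @return An [ff_params()] object.
#' @export
toy_ff_params <- function() {
  ff_params(
    types = tibble(
      type = c("HS", "GS", "GZ", "HD", "HA"),
      epsilon = c(.toy_eps, .toy_eps, .toy_eps, 0.02, .toy_eps),
      rmin = c(.toy_rmin, .toy_rmin, .toy_rmin, 2.0, .toy_rmin)
    ),
    hbond = tibble(donor = "HD", acceptor = "HA", C = 7557, D = 2385),
    bonds = tibble(type1 = c("GS", "GZ"), type2 = c("GS", "GZ"),
                   kr = 300, req = 1.5),
    angles = tibble(type1 = c("GS", "GZ"), type2 = c("GS", "GZ"),
                    type3 = c("GS", "GZ"),
                    ktheta = 60, theta_eq = c(180, 109.471)),
    torsions = tibble(type1 = "GZ", type2 = "GZ", type3 = "GZ", type4 = "GZ",
                      Vn = 2, n = 3L, gamma = 0)
  )
}

#' Analytic harmonic probe
#'
#' A single site of mass `m` in the external potential `E = k/2 |r|^2`,
#' with closed-form energy, force and oscillation period — the independent
#' oracle for the integrator.
#'
#' @param k Spring constant, kcal/mol/Å^2.
#' @param m Site mass, amu.
#' @return A list with `k`, `m`, `energy(x)`, `force(x)`, `period` (fs)
#'   and `body` (a [rigid_body()] for the site).
#' @export
#' @examples
#' pr <- make_harmonic_probe(k = 1, m = 12)
#' pr$period  # 2*pi*sqrt(m / (k in internal units))
make_harmonic_probe <- function(k = 1, m = 12) {
  stopifnot(k > 0, m > 0)
  site <- mm_molecule(
    tibble(element = "X", name = "P", x = 0, y = 0, z = 0, charge = 0,
           ff_type = "GS", mass = m),
    role = "guest"
  )
  list(
    k = k, m = m,
    energy = function(x) 0.5 * k * sum(x^2),
    force = function(x) -k * x,
    period = 2 * pi * sqrt(m / (k * .kcal2int)),
    body = rigid_body(site)
  )
}

#' Packaged synthetic beta-cyclodextrin and eugenol structures
#'
#' Loads the mol2 assets bundled with the package: a beta-cyclodextrin
#' conformer and a eugenol conformer, both generated synthetically
#' (distance-geometry embedding with force-field refinement and
#' Gasteiger partial charges) and therefore NOT identical to any
#' literature coordinate/charge set.  Hydroxyl hydrogens are flagged as
#' H-bond donors and oxygens as acceptors.  A matching element-class
#' Lennard-Jones parameter table ships alongside
#' (`params_bcd_eugenol.yaml`).
#'
#' @return A list with `host`, `guest` (`mm_molecule`s, host already in its
#'   host frame) and `params` ([ff_params()]).
#' @export
packaged_bcd_eugenol <- function() {
  hpath <- system.file("extdata", "bcd_synthetic.mol2", package = "cyclodyn")
  gpath <- system.file("extdata", "eugenol_synthetic.mol2",
                       package = "cyclodyn")
  ppath <- system.file("extdata", "params_bcd_eugenol.yaml",
                       package = "cyclodyn")
  if (hpath == "" || gpath == "" || ppath == "") {
    abort(paste0("packaged structures not installed; use the toy systems ",
                 "(make_toy_host()/make_toy_guest()) instead"))
  }
  host <- read_structure(hpath, "mol2", role = "host")
  guest <- read_structure(gpath, "mol2", role = "guest")
  host <- .flag_hbond_roles(host)
  guest <- .flag_hbond_roles(guest)
  host <- to_host_frame(host)
  gxyz <- sweep(mol_coords(guest), 2, mol_com(guest))
  guest <- with_coords(guest, gxyz)
  list(host = host, guest = guest, params = read_ff_params(ppath))
}

## Hydroxyl/polar hydrogens (bonded to O or N) become donor-H; O and N
## become acceptors.
.flag_hbond_roles <- function(mol) {
  el <- mol$atoms$element
  role <- rep("none", length(el))
  role[el %in% c("O", "N")] <- "acceptor"
  for (b in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds[b, 1]; j <- mol$bonds[b, 2]
    if (el[i] == "H" && el[j] %in% c("O", "N")) role[i] <- "donor-H"
    if (el[j] == "H" && el[i] %in% c("O", "N")) role[j] <- "donor-H"
  }
  mol$atoms$hbond_role <- role
  mol
}
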