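## Molecular containers, structure I/O, topology and rigid placement.

# Standard atomic masses (amu) for the elements a cyclodextrin/guest system
# can contain, plus "X" for synthetic toy sites (mass supplied by the spec
# or defaulting to 12).
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904,
  X = 12.0
)

#' Construct a parameterized molecule
#'
#' The central molecular container: an atom table plus bonded topology.
#' Atoms carry coordinates (Å), partial charges (e), force-field atom types
#' and a hydrogen-bonding role used to select 12-10 pair terms.
#'
#' @param atoms A data frame with columns `element`, `name`, `x`, `y`, `z`,
#'   `charge`, `ff_type` and optionally `hbond_role` (one of `"donor-H"`,
#'   `"acceptor"`, `"none"`; default `"none"`) and `mass` (amu; defaults to
#'   the standard atomic mass of `element`).
#' @param bonds Integer matrix with two columns of atom indices (may have
#'   zero rows).
#' @param angles,torsions Integer matrices with three/four columns; usually
#'   left empty and filled in by [derive_topology()].
#' @param role `"host"` or `"guest"`.
#' @return An object of class `mm_molecule`.
#' @export
#' @examples
#' atoms <- tibble::tibble(
#'   element = c("C", "C"), name = c("C1", "C2"),
#'   x = c(0, 1.5), y = 0, z = 0, charge = 0, ff_type = "GS"
#' )
#' mm_molecule(atoms, bonds = rbind(c(1L, 2L)), role = "guest")
mm_molecule <- function(atoms, bonds = matrix(integer(), ncol = 2),
                        angles = matrix(integer(), ncol = 3),
                        torsions = matrix(integer(), ncol = 4),
                        role = c("guest", "host")) {
  role <- match.arg(role)
  atoms <- as_tibble(atoms)
  required <- c("element", "name", "x", "y", "z", "charge", "ff_type")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atoms table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"hbond_role" %in% names(atoms)) atoms$hbond_role <- "none"
  if (!"mass" %in% names(atoms)) {
    m <- .element_masses[atoms$element]
    if (anyNA(m)) {
      abort(paste0("unknown element(s): ",
                   paste(unique(atoms$element[is.na(m)]), collapse = ", ")))
    }
    atoms$mass <- unname(m)
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) abort("non-finite atomic coordinates")
  if (!all(is.finite(atoms$charge))) abort("non-finite partial charges")
  if (!all(atoms$hbond_role %in% c("donor-H", "acceptor", "none"))) {
    abort("hbond_role must be one of 'donor-H', 'acceptor', 'none'")
  }
  bonds <- .as_index_matrix(bonds, 2)
  angles <- .as_index_matrix(angles, 3)
  torsions <- .as_index_matrix(torsions, 4)
  n <- nrow(atoms)
  for (idx in list(bonds, angles, torsions)) {
    if (length(idx) > 0 && (min(idx) < 1 || max(idx) > n)) {
      abort("topology index out of range")
    }
  }
  if (sum(atoms$mass) <= 0) abort("total mass must be positive")
  structure(
    list(atoms = atoms, bonds = bonds, angles = angles, torsions = torsions,
         role = role),
    class = "mm_molecule"
  )
}

.as_index_matrix <- function(m, ncol) {
  m <- as.matrix(m)
  if (length(m) == 0) {
    return(matrix(integer(), ncol = ncol))
  }
  storage.mode(m) <- "integer"
  if (NCOL(m) != ncol) abort(sprintf("index matrix must have %d columns", ncol))
  m
}

#' @export
print.mm_molecule <- function(x, ...) {
  cat(sprintf("<mm_molecule> %s: %d atoms, %d bonds, %d angles, %d torsions\n",
              x$role, nrow(x$atoms), nrow(x$bonds), nrow(x$angles),
              nrow(x$torsions)))
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol An `mm_molecule`.
#' @return Integer atom count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' Atomic coordinates of a molecule
#' @param mol An `mm_molecule`.
#' @return An `n x 3` numeric matrix of coordinates in Å.
#' @export
mol_coords <- function(mol) {
  unname(as.matrix(mol$atoms[, c("x", "y", "z")]))
}

#' Centre of mass of a molecule
#' @param mol An `mm_molecule`.
#' @return Numeric length-3 vector (Å).
#' @export
mol_com <- function(mol) {
  xyz <- mol_coords(mol)
  m <- mol$atoms$mass
  colSums(xyz * m) / sum(m)
}

with_coords <- function(mol, xyz) {
  mol$atoms$x <- xyz[, 1]
  mol$atoms$y <- xyz[, 2]
  mol$atoms$z <- xyz[, 3]
  mol
}

#' Read a molecular structure file
#'
#' Reads XYZ, PDB or SYBYL mol2 into an [mm_molecule()].  Partial charges
#' are trusted only from mol2 (the 9th atom-record column); PDB
#' occupancy/B-factor columns are ignored.  Formats without connectivity
#' (XYZ, PDB without CONECT) yield an empty bond list and a warning.
#'
#' @param path Path to the structure file.
#' @param format One of `"xyz"`, `"pdb"`, `"mol2"`.  Defaults to the file
#'   extension.
#' @param role `"host"` or `"guest"`.
#' @return An `mm_molecule`.  `ff_type` is taken from the mol2 atom-type
#'   column where available, otherwise from the element symbol.
#' @export
read_structure <- function(path, format = NULL, role = c("guest", "host")) {
  role <- match.arg(role)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  format <- format %||% tolower(tools::file_ext(path))
  switch(format,
    xyz = .read_xyz(path, role),
    pdb = .read_pdb(path, role),
    mol2 = .read_mol2(path, role),
    abort(paste0("unsupported structure format: ", format))
  )
}

.read_xyz <- function(path, role) {
  lines <- readLines(path)
  if (length(lines) < 2) abort("malformed XYZ: fewer than 2 lines")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) abort("malformed XYZ record at line 1: atom count expected")
  if (length(lines) < 2 + n) abort("malformed XYZ: truncated atom block")
  rec <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  bad <- which(vapply(rec, length, 1L) < 4)
  if (length(bad) > 0) {
    abort(sprintf("malformed XYZ record at line %d", 2 + bad[1]))
  }
  el <- vapply(rec, `[[`, "", 1)
  xyz <- t(vapply(rec, function(r) suppressWarnings(as.numeric(r[2:4])),
                  numeric(3)))
  if (anyNA(xyz)) {
    abort(sprintf("malformed XYZ record at line %d: non-numeric coordinate",
                  2 + which(rowSums(is.na(xyz)) > 0)[1]))
  }
  unknown <- setdiff(unique(el), names(.element_masses))
  if (length(unknown) > 0) {
    abort(paste0("unknown element(s): ", paste(unknown, collapse = ", ")))
  }
  atoms <- tibble(
    element = el, name = paste0(el, seq_len(n)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = 0, ff_type = el
  )
  warn_once_no_bonds("XYZ")
  mm_molecule(atoms, role = role)
}

warn_once_no_bonds <- function(fmt) {
  warn(paste0(fmt, " carries no connectivity; bond list left empty ",
              "(use derive_topology() after adding bonds)"))
}

.read_pdb <- function(path, role) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  el <- trimws(a$elesy)
  if (any(el == "" | is.na(el))) {
    el <- ifelse(el == "" | is.na(el), substr(trimws(a$elety), 1, 1), el)
  }
  unknown <- setdiff(unique(el), names(.element_masses))
  if (length(unknown) > 0) {
    abort(paste0("unknown element(s): ", paste(unknown, collapse = ", ")))
  }
  atoms <- tibble(
    element = el, name = trimws(a$elety),
    x = a$x, y = a$y, z = a$z,
    charge = 0, ff_type = el
  )
  ## bio3d does not expose CONECT records; PDB input starts bond-less.
  warn_once_no_bonds("PDB")
  mm_molecule(atoms, role = role)
}

.read_mol2 <- function(path, role) {
  m <- bio3d::read.mol2(path)
  a <- m$atom
  el <- sub("\\..*$", "", a$elety)
  ## SYBYL types carry the element before the dot; synthetic site types
  ## (toy fixtures) map to the generic site element "X"
  el[!el %in% names(.element_masses)] <- "X"
  atoms <- tibble(
    element = el, name = a$elena,
    x = a$x, y = a$y, z = a$z,
    charge = if (!is.null(a$charge)) a$charge else 0,
    ff_type = a$elety
  )
  bonds <- if (!is.null(m$bond) && nrow(m$bond) > 0) {
    cbind(as.integer(m$bond$origin), as.integer(m$bond$target))
  } else {
    matrix(integer(), ncol = 2)
  }
  mm_molecule(atoms, bonds = bonds, role = role)
}

#' Write a molecular structure file
#'
#' Writes XYZ (coordinates only) or SYBYL mol2 (coordinates, charges,
#' bonds).  Round-trips through [read_structure()].
#'
#' @param mol An `mm_molecule`.
#' @param path Output path.
#' @param format `"xyz"` or `"mol2"`; defaults to the file extension.
#' @param xyz Optional replacement coordinate matrix (e.g. a posed guest).
#' @return `path`, invisibly.
#' @export
write_structure <- function(mol, path, format = NULL, xyz = NULL) {
  format <- format %||% tolower(tools::file_ext(path))
  if (!is.null(xyz)) mol <- with_coords(mol, xyz)
  switch(format,
    xyz = .write_xyz(mol, path),
    mol2 = .write_mol2(mol, path),
    abort(paste0("unsupported structure format: ", format))
  )
  invisible(path)
}

.write_xyz <- function(mol, path) {
  a <- mol$atoms
  lines <- c(
    as.character(nrow(a)),
    "written by cyclodyn",
    sprintf("%-3s %17.10f %17.10f %17.10f", a$element, a$x, a$y, a$z)
  )
  writeLines(lines, path)
}

.write_mol2 <- function(mol, path) {
  a <- mol$atoms
  n <- nrow(a)
  nb <- nrow(mol$bonds)
  lines <- c(
    "@<TRIPOS>MOLECULE",
    "cyclodyn",
    sprintf(" %d %d 1", n, nb),
    "SMALL",
    "USER_CHARGES",
    "@<TRIPOS>ATOM",
    sprintf("%7d %-8s %12.6f %12.6f %12.6f %-8s %5d %-8s %12.6f",
            seq_len(n), a$name, a$x, a$y, a$z, a$ff_type, 1L, "MOL",
            a$charge)
  )
  if (nb > 0) {
    lines <- c(lines, "@<TRIPOS>BOND",
               sprintf("%6d %5d %5d %s", seq_len(nb), mol$bonds[, 1],
                       mol$bonds[, 2], "1"))
  } else {
    lines <- c(lines, "@<TRIPOS>BOND")
  }
  writeLines(lines, path)
}

#' Enumerate angles and torsions from the bond graph
#'
#' Every path of two bonds defines one angle and every path of three bonds
#' one proper torsion; duplicates under reversal are removed.  Disconnected
#' atoms simply contribute no bonded terms.
#'
#' @param mol An `mm_molecule` with bonds.
#' @return The molecule with `angles` and `torsions` filled in.
#' @export
#' @examples
#' chain <- make_toy_guest(n_sites = 4)
#' derive_topology(chain)$torsions
derive_topology <- function(mol) {
  bonds <- mol$bonds
  n <- n_atoms(mol)
  nbr <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds[b, 1]; j <- bonds[b, 2]
    nbr[[i]] <- c(nbr[[i]], j)
    nbr[[j]] <- c(nbr[[j]], i)
  }
  nbr <- lapply(nbr, function(v) sort(unique(v)))

  angles <- list()
  for (j in seq_len(n)) {
    nb <- nbr[[j]]
    if (length(nb) >= 2) {
      cmb <- utils::combn(nb, 2)
      angles[[length(angles) + 1]] <-
        cbind(cmb[1, ], rep(j, ncol(cmb)), cmb[2, ])
    }
  }
  angles <- if (length(angles) > 0) do.call(rbind, angles) else
    matrix(integer(), ncol = 3)

  torsions <- list()
  for (b in seq_len(nrow(bonds))) {
    j <- bonds[b, 1]; k <- bonds[b, 2]
    for (i in setdiff(nbr[[j]], k)) {
      for (l in setdiff(nbr[[k]], j)) {
        if (i == l) next  # 3-ring path, not a proper torsion
        quad <- if (j < k || (j == k)) c(i, j, k, l) else c(l, k, j, i)
        torsions[[length(torsions) + 1]] <- quad
      }
    }
  }
  torsions <- if (length(torsions) > 0) {
    tm <- do.call(rbind, torsions)
    ## canonical direction: smaller central atom first, then dedupe
    flip <- tm[, 2] > tm[, 3] | (tm[, 2] == tm[, 3] & tm[, 1] > tm[, 4])
    tm[flip, ] <- tm[flip, 4:1]
    unique(tm)
  } else {
    matrix(integer(), ncol = 4)
  }

  mol$angles <- .as_index_matrix(angles, 3)
  mol$torsions <- .as_index_matrix(torsions, 4)
  mol
}

#' Host-fixed reference frame
#'
#' The frame origin is the host's centre of mass and the Z axis is the
#' symmetry (cone) axis: the principal axis whose moment of inertia is most
#' isolated from the other two.  A symmetric-top host has two nearly equal
#' moments and one distinct moment, and the distinct one belongs to the
#' symmetry axis — the smallest moment for a tall narrow host, the largest
#' for a flat torus like a cyclodextrin macrocycle; the isolation rule
#' covers both.  The sign of Z is chosen so that +Z points toward the wider
#' rim (the rim whose atoms lie at larger mean radial distance from the
#' axis).
#'
#' @param host An `mm_molecule` with at least 3 non-collinear atoms.
#' @return A list of class `host_frame` with `origin` (length-3) and `axes`
#'   (3x3 rotation matrix whose columns are the X, Y, Z axes in input
#'   coordinates).
#' @export
host_frame <- function(host) {
  xyz <- mol_coords(host)
  m <- host$atoms$mass
  if (nrow(xyz) < 3) abort("host must have at least 3 atoms")
  origin <- colSums(xyz * m) / sum(m)
  rel <- sweep(xyz, 2, origin)
  ## inertia tensor
  r2 <- rowSums(rel^2)
  inertia <- diag(sum(m * r2), 3) - t(rel * m) %*% rel
  ev <- eigen(inertia, symmetric = TRUE)
  vals <- ev$values  # decreasing order
  scale <- max(abs(vals), 1)
  if (vals[3] < 1e-9 * scale) {
    abort("degenerate inertia: host atoms are collinear")
  }
  ## the symmetry axis carries the moment most isolated from the other two
  iso <- vapply(1:3, function(k) min(abs(vals[k] - vals[-k])), 0)
  pick <- which.max(iso)
  if (iso[pick] < 1e-9 * scale) {
    abort("degenerate inertia: cone axis is not unique")
  }
  zaxis <- ev$vectors[, pick]
  ## orient +Z toward the wider rim
  zc <- rel %*% zaxis
  rad <- sqrt(pmax(r2 - zc[, 1]^2, 0))
  wplus <- mean(rad[zc > 0])
  wminus <- mean(rad[zc < 0])
  if (is.finite(wplus) && is.finite(wminus) && wplus < wminus) zaxis <- -zaxis
  ## deterministic X: projection of the first atom off the axis
  xref <- rel[1, ] - sum(rel[1, ] * zaxis) * zaxis
  if (sqrt(sum(xref^2)) < 1e-8) {
    k <- which.max(apply(rel, 1, function(r) {
      sum((r - sum(r * zaxis) * zaxis)^2)
    }))
    xref <- rel[k, ] - sum(rel[k, ] * zaxis) * zaxis
    if (sqrt(sum(xref^2)) < 1e-8) abort("degenerate (collinear) host geometry")
  }
  xaxis <- xref / sqrt(sum(xref^2))
  yaxis <- c(
    zaxis[2] * xaxis[3] - zaxis[3] * xaxis[2],
    zaxis[3] * xaxis[1] - zaxis[1] * xaxis[3],
    zaxis[1] * xaxis[2] - zaxis[2] * xaxis[1]
  )
  axes <- cbind(xaxis, yaxis, zaxis)
  dimnames(axes) <- NULL
  structure(list(origin = origin, axes = axes), class = "host_frame")
}

#' Transform a molecule into its host frame
#'
#' Applies the [host_frame()] transform so the centre of mass sits at the
#' origin and the cone axis lies along +Z (wider rim up).
#'
#' @param host An `mm_molecule`.
#' @param frame Optional precomputed `host_frame`.
#' @return The transformed `mm_molecule`.
#' @export
to_host_frame <- function(host, frame = host_frame(host)) {
  xyz <- sweep(mol_coords(host), 2, frame$origin) %*% frame$axes
  with_coords(host, xyz)
}

#' Rigid-body pose of a guest
#'
#' A pose is the guest centre-of-mass position (Å, host frame) plus an
#' orientation, given either as a unit quaternion or as intrinsic Z-Y'-Z''
#' Euler angles.
#'
#' @param com Length-3 centre-of-mass position, Å.
#' @param quaternion Unit quaternion `c(w, x, y, z)` (normalized on input).
#' @param euler Alternative: Euler angles `c(alpha, beta, gamma)`, radians.
#' @return An object of class `pose`.
#' @export
#' @examples
#' pose(c(0, 0, -2), euler = c(0, pi / 2, 0))
pose <- function(com = c(0, 0, 0), quaternion = NULL, euler = NULL) {
  stopifnot(length(com) == 3, all(is.finite(com)))
  if (is.null(quaternion)) {
    quaternion <- if (is.null(euler)) c(1, 0, 0, 0) else
      euler_to_quaternion(euler[1], euler[2], euler[3])
  }
  nq <- sqrt(sum(quaternion^2))
  if (abs(nq - 1) > 1e-6) abort("quaternion norm too far from 1")
  structure(list(com = as.numeric(com), q = quaternion / nq), class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  cat(sprintf("<pose> com = (%.3f, %.3f, %.3f) A, q = (%.4f, %.4f, %.4f, %.4f)\n",
              x$com[1], x$com[2], x$com[3], x$q[1], x$q[2], x$q[3], x$q[4]))
  invisible(x)
}

#' Place a guest molecule at a pose
#'
#' Rigid placement: the reference conformation is centred on its centre of
#' mass, rotated by the pose quaternion and translated to the pose centre of
#' mass.  Internal distances are preserved exactly.
#'
#' @param guest An `mm_molecule`.
#' @param pose A [pose()].
#' @return An `n x 3` matrix of guest atom coordinates (Å).
#' @export
place_guest <- function(guest, pose) {
  ref <- sweep(mol_coords(guest), 2, mol_com(guest))
  sweep(rotate_coords(ref, pose$q), 2, pose$com, `+`)
}
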