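# Independent brute-force oracles.  These deliberately share no code with
# the package internals: plain scalar double loops, their own rotation,
# angle and dihedral arithmetic.

KB <- 1.9872041e-3
KCOUL <- 332.0637

# Rotate one 3-vector by a quaternion (w, x, y, z), scalar formula
# v' = v + 2 w (u x v) + 2 u x (u x v) with u the vector part.
oracle_rotate <- function(v, q) {
  u <- q[2:4]
  cross <- function(a, b) {
    c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1])
  }
  uv <- cross(u, v)
  v + 2 * q[1] * uv + 2 * cross(u, uv)
}

oracle_place <- function(guest, pose) {
  xyz <- as.matrix(guest$atoms[, c("x", "y", "z")])
  m <- guest$atoms$mass
  com <- colSums(xyz * m) / sum(m)
  out <- xyz
  for (i in seq_len(nrow(xyz))) {
    out[i, ] <- oracle_rotate(xyz[i, ] - com, pose$q) + pose$com
  }
  out
}

# Full Eq.-style energy: intermolecular 12-6 / Coulomb / 12-10 pairs plus
# the guest's bonded terms, all as scalar loops.
brute_force_energy <- function(host, guest, pose, params,
                               solvent = solvent_model()) {
  hxyz <- as.matrix(host$atoms[, c("x", "y", "z")])
  gxyz <- oracle_place(guest, pose)
  lookup_lj <- function(type) {
    k <- which(params$types$type == type)
    c(A = params$types$A[k], B = params$types$B[k])
  }
  lj <- ele <- hbond <- 0
  for (i in seq_len(nrow(gxyz))) {
    for (j in seq_len(nrow(hxyz))) {
      R <- sqrt(sum((gxyz[i, ] - hxyz[j, ])^2))
      gi <- guest$atoms[i, ]; hj <- host$atoms[j, ]
      is_hb <- FALSE
      if (nrow(params$hbond) > 0) {
        for (p in seq_len(nrow(params$hbond))) {
          dn <- params$hbond$donor[p]; ac <- params$hbond$acceptor[p]
          if ((gi$hbond_role == "donor-H" && hj$hbond_role == "acceptor" &&
               gi$ff_type == dn && hj$ff_type == ac) ||
              (hj$hbond_role == "donor-H" && gi$hbond_role == "acceptor" &&
               hj$ff_type == dn && gi$ff_type == ac)) {
            is_hb <- TRUE
            hbond <- hbond + params$hbond$C[p] / R^12 - params$hbond$D[p] / R^10
            break
          }
        }
      }
      if (!is_hb) {
        a1 <- lookup_lj(gi$ff_type); a2 <- lookup_lj(hj$ff_type)
        lj <- lj + sqrt(a1[["A"]] * a2[["A"]]) / R^12 -
          sqrt(a1[["B"]] * a2[["B"]]) / R^6
      }
      ele <- ele + KCOUL * gi$charge * hj$charge / (solvent$epsilon * R)
    }
  }
  bond <- 0
  ty <- guest$atoms$ff_type
  for (b in seq_len(nrow(guest$bonds))) {
    i <- guest$bonds[b, 1]; j <- guest$bonds[b, 2]
    k <- which((params$bonds$type1 == ty[i] & params$bonds$type2 == ty[j]) |
                 (params$bonds$type1 == ty[j] & params$bonds$type2 == ty[i]))[1]
    r <- sqrt(sum((gxyz[i, ] - gxyz[j, ])^2))
    bond <- bond + params$bonds$kr[k] * (r - params$bonds$req[k])^2
  }
  angle <- 0
  for (a in seq_len(nrow(guest$angles))) {
    i <- guest$angles[a, 1]; j <- guest$angles[a, 2]; k <- guest$angles[a, 3]
    hit <- which((params$angles$type1 == ty[i] & params$angles$type2 == ty[j] &
                    params$angles$type3 == ty[k]) |
                   (params$angles$type1 == ty[k] & params$angles$type2 == ty[j] &
                      params$angles$type3 == ty[i]))[1]
    v1 <- gxyz[i, ] - gxyz[j, ]; v2 <- gxyz[k, ] - gxyz[j, ]
    th <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
    angle <- angle + params$angles$ktheta[hit] *
      (th - params$angles$theta_eq[hit] * pi / 180)^2
  }
  torsion <- 0
  for (t in seq_len(nrow(guest$torsions))) {
    q4 <- guest$torsions[t, ]
    tb <- params$torsions
    okm <- function(a, b) a == b | a == "X"
    hit <- which((okm(tb$type1, ty[q4[1]]) & okm(tb$type2, ty[q4[2]]) &
                    okm(tb$type3, ty[q4[3]]) & okm(tb$type4, ty[q4[4]])) |
                   (okm(tb$type1, ty[q4[4]]) & okm(tb$type2, ty[q4[3]]) &
                      okm(tb$type3, ty[q4[2]]) & okm(tb$type4, ty[q4[1]])))
    b1 <- gxyz[q4[2], ] - gxyz[q4[1], ]
    b2 <- gxyz[q4[3], ] - gxyz[q4[2], ]
    b3 <- gxyz[q4[4], ] - gxyz[q4[3], ]
    cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])
    n1 <- cr(b1, b2); n2 <- cr(b2, b3)
    phi <- atan2(sum(cr(n1, n2) * b2 / sqrt(sum(b2^2))), sum(n1 * n2))
    for (h in hit) {
      torsion <- torsion + tb$Vn[h] / 2 * (1 + cos(tb$n[h] * phi -
                                                     tb$gamma[h] * pi / 180))
    }
  }
  list(lj = lj, ele = ele, hbond = hbond, bond = bond, angle = angle,
       torsion = torsion,
       inter = lj + ele + hbond, intra = bond + angle + torsion,
       total = lj + ele + hbond + bond + angle + torsion)
}

with_coords_test <- function(mol, xyz) {
  mol$atoms$x <- xyz[, 1]
  mol$atoms$y <- xyz[, 2]
  mol$atoms$z <- xyz[, 3]
  mol
}

# Central-difference gradient of Einter with respect to COM translation.
numeric_force <- function(host, guest, pose, params, solvent, h = 1e-5) {
  e_at <- function(com) {
    sum(intermolecular_energy(
      host, guest, params, solvent,
      guest_xyz = place_guest(guest, pose(com, quaternion = pose$q))
    ))
  }
  vapply(1:3, function(a) {
    d <- c(0, 0, 0); d[a] <- h
    -(e_at(pose$com + d) - e_at(pose$com - d)) / (2 * h)
  }, 0)
}

# A seeded random small system: charged host atoms in a shell, a bonded
# 4-site guest with its own bonded parameters, optional H-bond pair.
random_toy_system <- function(seed) {
  set.seed(seed)
  nh <- 5L
  host <- mm_molecule(
    tibble::tibble(
      element = "X", name = paste0("H", 1:nh),
      x = runif(nh, 3, 6) * sample(c(-1, 1), nh, TRUE),
      y = runif(nh, 3, 6) * sample(c(-1, 1), nh, TRUE),
      z = runif(nh, -3, 3),
      charge = runif(nh, -0.3, 0.3),
      ff_type = sample(c("HT", "HA"), nh, TRUE)
    ),
    role = "host"
  )
  host$atoms$hbond_role[host$atoms$ff_type == "HA"] <- "acceptor"
  gx <- cbind(cumsum(c(0, runif(3, 1.2, 1.6))),
              c(0, runif(3, -0.8, 0.8)), c(0, runif(3, -0.8, 0.8)))
  guest <- mm_molecule(
    tibble::tibble(
      element = "X", name = paste0("G", 1:4),
      x = gx[, 1], y = gx[, 2], z = gx[, 3],
      charge = runif(4, -0.3, 0.3),
      ff_type = c("GT", "GT", "GT", "HD"),
      hbond_role = c("none", "none", "none", "donor-H")
    ),
    bonds = cbind(1:3, 2:4), role = "guest"
  )
  guest <- derive_topology(guest)
  params <- ff_params(
    types = tibble::tibble(
      type = c("HT", "HA", "GT", "HD"),
      A = runif(4, 1e4, 1e6), B = runif(4, 10, 500)
    ),
    hbond = tibble::tibble(donor = "HD", acceptor = "HA",
                           C = runif(1, 5e3, 1e4), D = runif(1, 1e3, 3e3)),
    bonds = tibble::tibble(type1 = c("GT", "GT"), type2 = c("GT", "HD"),
                           kr = runif(2, 100, 400), req = runif(2, 1.2, 1.6)),
    angles = tibble::tibble(
      type1 = c("GT", "GT"), type2 = c("GT", "GT"), type3 = c("GT", "HD"),
      ktheta = runif(2, 30, 80), theta_eq = runif(2, 100, 140)
    ),
    torsions = tibble::tibble(type1 = "GT", type2 = "GT", type3 = "GT",
                              type4 = "HD", Vn = runif(1, 0.5, 3),
                              n = sample(1:3, 1), gamma = runif(1, 0, 360))
  )
  ps <- pose(com = runif(3, -1, 1),
             euler = runif(3, 0, 2 * pi))
  list(host = host, guest = guest, params = params, pose = ps)
}
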