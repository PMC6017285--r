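# Grid scan, penetration potential, Boltzmann PES, global minimum and
# inclusion classification.

toy_system <- function() {
  list(host = make_toy_host(), guest = make_toy_guest(),
       params = toy_ff_params())
}

test_that("orientation sets honour their generator descriptors", {
  os <- generate_orientations(count = 23000)
  expect_equal(nrow(os$q), 36L * 18L * 36L)  # 23,328, closest lattice to target
  expect_true(all(abs(rowSums(os$q^2) - 1) < 1e-12))

  one <- generate_orientations(count = 1)
  expect_equal(one$q, matrix(c(1, 0, 0, 0), 1))

  r1 <- generate_orientations("random", count = 50, seed = 9)
  r2 <- generate_orientations("random", count = 50, seed = 9)
  expect_identical(r1$q, r2$q)
  expect_true(all(abs(rowSums(r1$q^2) - 1) < 1e-12))
})

test_that("a single-site guest scan equals a direct per-point pair sum", {
  sys <- toy_system()
  guest1 <- make_toy_guest(n_sites = 1)
  grid <- scan_grid(xlim = c(-1, 1), ylim = c(-1, 1), zlim = c(-1, 1),
                    spacing = 1)
  os <- generate_orientations(count = 5, scheme = "random", seed = 1)
  sc <- mm_scan(sys$host, guest1, grid, os, sys$params)
  td <- tidy(sc)
  expect_equal(nrow(td), 27L)
  for (k in seq_len(nrow(td))) {
    ref <- brute_force_energy(sys$host, guest1,
                              pose(com = c(td$x[k], td$y[k], td$z[k])),
                              sys$params)
    expect_equal(td$einter_min[k], ref$inter, tolerance = 1e-12)
    expect_equal(td$e_min[k], ref$total, tolerance = 1e-12)
  }
})

test_that("a zero-parameter guest scans to zero everywhere", {
  host <- make_toy_host()
  params <- ff_params(types = tibble::tibble(type = c("HS", "NUL"),
                                             A = c(10, 0), B = c(1, 0)))
  ghost <- make_toy_guest(n_sites = 2, ff_type = "NUL")
  ghost$bonds <- matrix(integer(), ncol = 2)
  sc <- mm_scan(host, ghost, scan_grid(spacing = 2.5),
                generate_orientations(count = 3, scheme = "random", seed = 2),
                params)
  expect_true(all(abs(tidy(sc)$e_min) < 1e-12))
})

test_that("W(Z) is a well: deeper inside the cavity than outside", {
  sys <- toy_system()
  grid <- scan_grid(spacing = 0.5)
  os <- generate_orientations(count = 60, scheme = "random", seed = 5)
  sc <- mm_scan(sys$host, sys$guest, grid, os, sys$params)
  w <- penetration_potential(sc)
  expect_lt(min(w$W[abs(w$z) < 2]), w$W[w$z == 5])
  expect_lt(min(w$W[abs(w$z) < 2]), w$W[w$z == -5])
  # every W is the plane minimum: no tidy point on that plane lies below it
  td <- tidy(sc)
  for (zz in c(-5, 0, 5)) {
    expect_equal(w$W[w$z == zz], min(td$einter_min[td$z == zz]))
  }
})

test_that("a Z-symmetric system gives a symmetric W and repulsion stays positive", {
  host <- make_toy_host(r_narrow = 4.5, r_wide = 4.5)  # cylinder
  guest1 <- make_toy_guest(n_sites = 1)
  grid <- scan_grid(xlim = c(-2, 2), ylim = c(-2, 2), spacing = 0.5)
  os <- generate_orientations(count = 1)
  sc <- mm_scan(host, guest1, grid, os, toy_ff_params())
  w <- penetration_potential(sc)
  expect_equal(w$W, rev(w$W), tolerance = 1e-9)

  # purely repulsive guest: W >= 0 everywhere
  params <- ff_params(types = tibble::tibble(type = c("HS", "REP"),
                                             A = c(1e5, 1e5), B = c(100, 0)))
  rep_guest <- make_toy_guest(n_sites = 1, ff_type = "REP")
  sc2 <- mm_scan(host, rep_guest, grid, os, params)
  expect_true(all(penetration_potential(sc2)$W >= 0))
})

test_that("Boltzmann averages sit between the minimum and the mean", {
  sys <- toy_system()
  grid <- scan_grid(xlim = c(-1, 1), ylim = c(-1, 1), zlim = c(-3, 3),
                    spacing = 1)
  os <- generate_orientations(count = 40, scheme = "random", seed = 11)
  pes <- boltzmann_pes(sys$host, sys$guest, grid, os, sys$params,
                       temperature = 293)
  pts <- tidy(pes)
  expect_true(all(pts$e_min <= pts$e_avg + 1e-9))
  expect_true(all(pts$e_avg <= pts$e_mean + 1e-9))

  # T -> 0 collapses the average onto the minimum
  cold <- boltzmann_pes(sys$host, sys$guest, grid, os, sys$params,
                        temperature = 1e-6)
  expect_equal(tidy(cold)$e_avg, tidy(cold)$e_min, tolerance = 1e-6)

  # equal energies average to themselves: a free guest sees 0 everywhere
  params0 <- ff_params(types = tibble::tibble(type = c("HS", "NUL"),
                                              A = c(10, 0), B = c(1, 0)))
  ghost <- make_toy_guest(n_sites = 1, ff_type = "NUL")
  p0 <- boltzmann_pes(sys$host, ghost, grid, os, params0)
  expect_true(all(abs(tidy(p0)$e_avg) < 1e-12))

  # four Z-domains spanning the host extent
  expect_equal(length(unique(pes$slabs$domain)), 4L)
})

test_that("the two-level Boltzmann average matches the closed form", {
  # one grid point, two orientations with energies {0, 1} kcal/mol:
  # <E> = exp(-1/kT) / (1 + exp(-1/kT))
  host <- mm_molecule(
    tibble::tibble(element = "X", name = "h", x = 0, y = 0, z = 10,
                   charge = 1, ff_type = "PT"),
    role = "host"
  )
  # guest: one charged site offset from its COM partner so that rotating
  # changes the distance to the host charge
  guest <- mm_molecule(
    tibble::tibble(element = "X", name = c("g1", "g2"),
                   x = c(-1, 1), y = 0, z = 0,
                   charge = c(0, 1), ff_type = "PT"),
    role = "guest"
  )
  params <- ff_params(types = tibble::tibble(type = "PT", A = 0, B = 0))
  solv <- solvent_model(1)
  q_up <- euler_to_quaternion(0, pi / 2, 0)    # charge toward host
  q_dn <- euler_to_quaternion(0, -pi / 2, 0)   # charge away
  os <- generate_orientations(count = 1)
  os$q <- rbind(q_up, q_dn)
  grid <- scan_grid(xlim = c(0, 0), ylim = c(0, 0), zlim = c(0, 0),
                    spacing = 1)
  pes <- boltzmann_pes(host, guest, grid, os, params, solv,
                       temperature = 293)
  kT <- mm_constants()$kb * 293
  e_up <- 332.0637 / 9   # charge at z = +1, distance 9
  e_dn <- 332.0637 / 11
  w <- exp(-(c(e_up, e_dn) - min(e_up, e_dn)) / kT)
  expected <- sum(c(e_up, e_dn) * w) / sum(w)
  expect_equal(tidy(pes)$e_avg, expected, tolerance = 1e-10)
})

test_that("refining the orientation set never raises a per-point minimum", {
  sys <- toy_system()
  grid <- scan_grid(xlim = c(-1, 1), ylim = c(-1, 1), zlim = c(-2, 2),
                    spacing = 1)
  small <- generate_orientations(count = 10, scheme = "random", seed = 3)
  big <- small
  extra <- generate_orientations(count = 15, scheme = "random", seed = 4)
  big$q <- rbind(small$q, extra$q)
  s1 <- mm_scan(sys$host, sys$guest, grid, small, sys$params)
  s2 <- mm_scan(sys$host, sys$guest, grid, big, sys$params)
  expect_true(all(tidy(s2)$e_min <= tidy(s1)$e_min + 1e-12))
})

test_that("the global minimum matches a continuous minimizer within a spacing", {
  host <- make_toy_host()
  guest1 <- make_toy_guest(n_sites = 1)
  params <- toy_ff_params()
  grid <- scan_grid(xlim = c(-1, 1), ylim = c(-1, 1), zlim = c(-4.5, 4.5),
                    spacing = 0.1)
  sc <- mm_scan(host, guest1, grid, generate_orientations(count = 1), params)
  gm <- global_minimum(sc, host, guest1, params)
  # independent continuous minimizer started from the lattice argmin
  efun <- function(p) {
    brute_force_energy(host, guest1, pose(com = p), params)$total
  }
  opt <- stats::optim(gm$pose$com, efun, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  expect_lt(sqrt(sum((opt$par - gm$pose$com)^2)), 0.1)
  expect_lte(opt$value, gm$e_min + 1e-12)
  expect_equal(gm$breakdown$total, gm$e_min, tolerance = 1e-9)
  expect_equal(gm$breakdown$total, gm$breakdown$inter + gm$breakdown$intra,
               tolerance = 1e-12)
})

test_that("a monotone external field puts the minimizer on the grid boundary", {
  # single positive host charge far on +Z attracts a negative guest charge:
  # energy decreases monotonically toward +Z
  host <- mm_molecule(
    tibble::tibble(element = "X", name = "h", x = 0, y = 0, z = 100,
                   charge = 1, ff_type = "PT"),
    role = "host"
  )
  guest <- mm_molecule(
    tibble::tibble(element = "X", name = "g", x = 0, y = 0, z = 0,
                   charge = -1, ff_type = "PT"),
    role = "guest"
  )
  params <- ff_params(types = tibble::tibble(type = "PT", A = 0, B = 0))
  grid <- scan_grid(xlim = c(-1, 1), ylim = c(-1, 1), zlim = c(-2, 2),
                    spacing = 1)
  sc <- mm_scan(host, guest, grid, generate_orientations(count = 1), params,
                solvent_model(1))
  gm <- global_minimum(sc)
  expect_equal(gm$pose$com[3], 2)
})

test_that("inclusion classification counts atoms inside the cavity", {
  host <- make_toy_host()
  guest <- make_toy_guest(n_sites = 3)
  centre <- classify_inclusion(place_guest(guest, pose()), host)
  expect_true(centre$inclusion)
  expect_equal(centre$fraction_inside, 1)

  far <- classify_inclusion(place_guest(guest, pose(c(100, 0, 0))), host)
  expect_false(far$inclusion)
  expect_equal(far$fraction_inside, 0)

  # rod straddling the wider rim along Z: per-atom hand geometry
  rod <- make_toy_guest(n_sites = 5, spacing = 2)
  up <- pose(com = c(0, 0, 4), euler = c(0, pi / 2, 0))  # rod along Z
  xyz <- place_guest(rod, up)
  cg <- cavity_geometry(host)
  inside_hand <- sum(
    xyz[, 3] >= cg$z_lo & xyz[, 3] <= cg$z_hi &
      sqrt(xyz[, 1]^2 + xyz[, 2]^2) <=
        cg$r_lo + (xyz[, 3] - cg$z_lo) / (cg$z_hi - cg$z_lo) *
          (cg$r_hi - cg$r_lo)
  )
  res <- classify_inclusion(xyz, host)
  expect_equal(res$n_inside, inside_hand)
  expect_gt(res$fraction_inside, 0)
  expect_lt(res$fraction_inside, 1)
})
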