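# Rigid-body integrator: free flight, harmonic-probe closed forms,
# isokinetic constraints, quaternion hygiene, determinism, reversibility,
# termination protocol and residence times.

kb <- mm_constants()$kb
c_int <- mm_constants()$kcal_to_internal

probe_state <- function(probe, x0 = c(0, 0, 0), v0 = c(0, 0, 0)) {
  rigid_body_state(x0, v0, c(1, 0, 0, 0), c(0, 0, 0), probe$body)
}

test_that("initial velocities carry exact equipartition kinetic energies", {
  guest <- make_toy_guest(torsion = TRUE)  # non-linear: 3 live axes
  body <- rigid_body(guest)
  expect_equal(body$rot_dof, 3L)
  v <- initial_velocities(293, body, seed = 4)
  ke_t <- 0.5 * body$mass * sum(v$velocity^2) / c_int
  ke_r <- 0.5 * sum(body$inertia * v$omega_body^2) / c_int
  expect_equal(ke_t, 1.5 * kb * 293, tolerance = 1e-10)
  expect_equal(ke_t, 0.87337, tolerance = 1e-5)
  expect_equal(ke_r, 1.5 * kb * 293, tolerance = 1e-10)

  # same seed reproduces, doubled temperature scales speeds by sqrt(2)
  v2 <- initial_velocities(293, body, seed = 4)
  expect_identical(v, v2)
  v586 <- initial_velocities(586, body, seed = 4)
  expect_equal(v586$velocity, sqrt(2) * v$velocity, tolerance = 1e-12)

  # a linear rod has one dead axis and a 2-dof rotational target
  rodb <- rigid_body(make_toy_guest(n_sites = 3))
  expect_equal(rodb$rot_dof, 2L)
  vr <- initial_velocities(293, rodb, seed = 1)
  expect_equal(0.5 * sum(rodb$inertia * vr$omega_body^2) / c_int,
               kb * 293, tolerance = 1e-10)
})

test_that("free flight is uniform straight-line motion", {
  pr <- make_harmonic_probe(k = 1, m = 12)
  st <- probe_state(pr, v0 = c(0.01, -0.02, 0.005))
  for (i in 1:50) st <- md_step(st, c(0, 0, 0), c(0, 0, 0), dt = 1)
  expect_equal(st$com, 50 * c(0.01, -0.02, 0.005), tolerance = 1e-12)
  expect_equal(st$velocity, c(0.01, -0.02, 0.005), tolerance = 1e-14)
})

test_that("the harmonic probe oscillates at its analytic period", {
  pr <- make_harmonic_probe(k = 1, m = 12)
  st <- probe_state(pr, x0 = c(1, 0, 0))
  n_per <- 100
  steps <- ceiling(n_per * pr$period)
  xs <- numeric(steps)
  for (i in seq_len(steps)) {
    st <- md_step(st, pr$force(st$com), c(0, 0, 0), dt = 1)
    xs[i] <- st$com[1]
  }
  up <- which(diff(sign(xs)) > 0)  # upward zero crossings
  crossing <- up + xs[up] / (xs[up] - xs[up + 1])
  period_est <- (crossing[length(crossing)] - crossing[1]) /
    (length(crossing) - 1)
  expect_lt(abs(period_est - pr$period) / pr$period, 0.001)
})

test_that("microcanonical total energy drifts less than 1e-3 kcal/mol over 1e5 steps", {
  pr <- make_harmonic_probe(k = 1, m = 12)
  st <- probe_state(pr, x0 = c(1, 0, 0))
  v_prev <- st$velocity
  n <- 100000L
  e0 <- NA_real_
  emin <- Inf; emax <- -Inf
  for (i in seq_len(n)) {
    x_t <- st$com
    st <- md_step(st, pr$force(x_t), c(0, 0, 0), dt = 1)
    # synchronize: the mean of the two half-step velocities is v(t), which
    # pairs with the pre-step position x(t)
    v_sync <- (v_prev + st$velocity) / 2
    e <- 0.5 * pr$m * sum(v_sync^2) / c_int + pr$energy(x_t)
    if (i == 1) e0 <- e
    emin <- min(emin, e); emax <- max(emax, e)
    v_prev <- st$velocity
  }
  expect_lt(emax - emin, 1e-3)
})

test_that("the isokinetic constraint pins both kinetic reservoirs every step", {
  host <- make_toy_host()
  guest <- make_toy_guest(torsion = TRUE)
  params <- toy_ff_params()
  body <- rigid_body(guest)
  v0 <- initial_velocities(293, body, seed = 2)
  st <- rigid_body_state(c(0, 0, 5.5), v0$velocity, c(1, 0, 0, 0),
                         v0$omega_body, body)
  th <- thermostat_spec(293)
  target <- 1.5 * kb * 293
  for (i in 1:1000) {
    ft <- force_and_torque(host, guest,
                           pose(st$com, quaternion = st$q), params)
    st <- md_step(st, ft$force, ft$torque, dt = 1, thermostat = th)
    ke <- kinetic_energy(st)
    expect_equal(ke$ke_trans, target, tolerance = 1e-9)
    expect_equal(ke$ke_rot, target, tolerance = 1e-9)
  }
  expect_equal(sum(st$q^2), 1, tolerance = 1e-10)
})

test_that("the quaternion norm stays within 1e-8 of unity over 1e6 steps", {
  guest <- make_toy_guest(torsion = TRUE)
  body <- rigid_body(guest)
  v0 <- initial_velocities(293, body, seed = 6)
  st <- rigid_body_state(c(0, 0, 0), v0$velocity, c(1, 0, 0, 0),
                         v0$omega_body, body)
  worst <- 0
  for (i in seq_len(1e6)) {
    st <- md_step(st, c(0, 0, 0), c(0, 0, 0), dt = 1)
    if (i %% 1000 == 0) worst <- max(worst, abs(sum(st$q^2) - 1))
  }
  worst <- max(worst, abs(sum(st$q^2) - 1))
  expect_lt(worst, 1e-8)
})

test_that("reversing the velocities retraces the translational path", {
  pr <- make_harmonic_probe(k = 2, m = 10)
  x0 <- c(0.8, -0.3, 0.2)
  st <- probe_state(pr, x0 = x0, v0 = c(0.003, 0.004, -0.001))
  for (i in 1:1000) st <- md_step(st, pr$force(st$com), c(0, 0, 0), dt = 1)
  ## leap-frog reversal: the stored velocity is staggered at t - dt/2, so
  ## the reversed run needs -v(t + dt/2) = -(v + dt f(x_t)/m)
  ci <- mm_constants()$kcal_to_internal
  st$velocity <- -(st$velocity + 1 * pr$force(st$com) * ci / pr$m)
  for (i in 1:1000) st <- md_step(st, pr$force(st$com), c(0, 0, 0), dt = 1)
  expect_equal(st$com, x0, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("trajectories are deterministic and their frames reproduce energies", {
  host <- make_toy_host()
  guest <- make_toy_guest()
  params <- toy_ff_params()
  t1 <- run_trajectory(host, guest, params, max_steps = 3000, seed = 11)
  t2 <- run_trajectory(host, guest, params, max_steps = 3000, seed = 11)
  expect_identical(t1$frames, t2$frames)

  # every frame's stored energy is reproducible from its stored pose
  fr <- t1$frames
  for (k in seq_len(nrow(fr))) {
    eb <- total_energy(host, guest,
                       pose(c(fr$x[k], fr$y[k], fr$z[k]),
                            quaternion = c(fr$qw[k], fr$qx[k], fr$qy[k],
                                           fr$qz[k])),
                       params)
    expect_equal(fr$einter[k], eb$inter, tolerance = 1e-8)
    expect_equal(fr$e_total[k], eb$total, tolerance = 1e-8)
  }
  # sampling clock: strictly increasing 0.1 ps ticks
  expect_equal(diff(fr$time_ps), rep(0.1, nrow(fr) - 1), tolerance = 1e-12)
})

test_that("a purely repulsive host expels the guest with ~zero residence", {
  params <- ff_params(
    types = tibble::tibble(type = c("HS", "GS"),
                           A = c(1e5, 1e5), B = c(0, 0)),
    bonds = tibble::tibble(type1 = "GS", type2 = "GS", kr = 300, req = 1.5),
    angles = tibble::tibble(type1 = "GS", type2 = "GS", type3 = "GS",
                            ktheta = 60, theta_eq = 180)
  )
  host <- make_toy_host()
  guest <- make_toy_guest(n_sites = 2)
  tr <- run_trajectory(host, guest, params, max_steps = 60000,
                       exit_patience = 10, seed = 3)
  expect_equal(tr$termination, "escaped")
  expect_equal(tr$residence_ps, 0)

  # a binding host with a tiny step cap is flagged non-terminated
  short <- run_trajectory(host, guest, toy_ff_params(), max_steps = 500,
                          seed = 3)
  expect_equal(short$termination, "max_steps")
})

test_that("residence time counts bound frames and is monotone in the threshold", {
  fake <- structure(
    list(frames = tibble::tibble(einter = c(rep(-5, 1000), rep(1, 20))),
         dt = 1, sample_every = 100, temperature = 293),
    class = "md_trajectory"
  )
  rt <- residence_time(fake, threshold = -1)
  expect_equal(rt$residence_ps, 100)      # 1000 frames x 0.1 ps
  expect_equal(rt$n_segments, 1L)

  none <- residence_time(fake, threshold = -10)
  expect_equal(none$residence_ps, 0)

  set.seed(8)
  fake$frames <- tibble::tibble(einter = rnorm(500, mean = -1, sd = 2))
  ths <- seq(-4, 2, by = 0.5)
  res <- vapply(ths, function(th) {
    residence_time(fake, threshold = th)$residence_ps
  }, 0)
  expect_true(all(diff(res) >= 0))
})

test_that("the four canonical dispositions start where they claim", {
  host <- make_toy_host()
  cg <- cavity_geometry(host)
  for (region in c("narrow-rim", "wide-rim")) {
    for (heading in c("radical-first", "phenyl-first")) {
      d <- initial_disposition(region, heading, seed = 5)
      p <- cyclodyn:::.disposition_pose(d, host)
      zc <- if (region == "narrow-rim") cg$z_lo - 1 else cg$z_hi + 1
      expect_equal(p$com, c(0, 0, zc), tolerance = 1e-12)
      # the head end (+X body axis) points toward the cavity iff
      # radical-first
      head_lab <- quaternion_to_matrix(p$q) %*% c(1, 0, 0)
      into <- if (region == "narrow-rim") 1 else -1
      expected_sign <- if (heading == "radical-first") into else -into
      expect_equal(sign(head_lab[3]), expected_sign)
    }
  }
})
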