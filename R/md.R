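## Constant-temperature rigid-body dynamics of the guest in the host's
## field: leap-frog translation, quaternion orientation propagation from
## the body-frame angular velocity, and per-step scalar rescaling that
## holds the translational and rotational kinetic energies separately at
## their equipartition targets (Gaussian-isokinetic-style constraint).

#' Thermostat specification
#'
#' Constant-temperature mode: the translational and rotational kinetic
#' energies are each constrained to their equipartition target
#' (`dof/2 * kB * T`) by a scalar rescaling of the half-step velocities at
#' every step.  `thermostat_spec(NULL)`-style absence (pass `NULL` to the
#' integrator) gives plain microcanonical leap-frog.
#'
#' @param temperature Temperature in K (> 0), default 293.
#' @return An object of class `thermostat_spec`.
#' @export
thermostat_spec <- function(temperature = 293) {
  stopifnot(temperature > 0)
  structure(list(temperature = temperature), class = "thermostat_spec")
}

#' Rigid-body representation of a guest molecule
#'
#' Computes the total mass, the principal moments of inertia of the
#' reference conformation about its centre of mass, and the body frame
#' (principal axes).  Principal moments below a tolerance (a linear rod's
#' moment about its own axis) are flagged as degenerate rotational degrees
#' of freedom; angular velocity about such axes is pinned to zero and the
#' rotational equipartition target counts only the live axes.
#'
#' @param guest An `mm_molecule`.
#' @return A list of class `rigid_body` with `mass` (amu), `inertia`
#'   (length-3 principal moments, amu Å^2), `axes` (3x3, columns = principal
#'   axes in the reference coordinates), `body_xyz` (reference coordinates
#'   in the body frame, COM at origin) and `rot_dof` (0-3).
#' @export
rigid_body <- function(guest) {
  xyz <- mol_coords(guest)
  m <- guest$atoms$mass
  com <- colSums(xyz * m) / sum(m)
  rel <- sweep(xyz, 2, com)
  r2 <- rowSums(rel^2)
  itens <- diag(sum(m * r2), 3) - t(rel * m) %*% rel
  ev <- eigen(itens, symmetric = TRUE)
  ord <- order(ev$values, decreasing = TRUE)
  vals <- ev$values[ord]
  vecs <- ev$vectors[, ord, drop = FALSE]
  if (det(vecs) < 0) vecs[, 3] <- -vecs[, 3]
  tol <- 1e-9 * max(vals, 1)
  live <- vals > tol
  structure(
    list(mass = sum(m), inertia = vals, axes = vecs,
         body_xyz = rel %*% vecs, rot_dof = sum(live), live_axes = live),
    class = "rigid_body"
  )
}

#' Draw initial rigid-body velocities
#'
#' The speed magnitudes are fixed exactly by the temperature —
#' translational kinetic energy `3/2 kB T` and rotational kinetic energy
#' `dof/2 kB T` over the live principal axes — while the directions are
#' uniform on the sphere from the seeded generator.
#'
#' @param temperature Temperature in K.
#' @param body A [rigid_body()].
#' @param seed RNG seed.
#' @return A list with `velocity` (Å/fs, lab frame) and `omega_body`
#'   (rad/fs, body frame; zero along degenerate axes).
#' @export
#' @examples
#' rb <- rigid_body(make_toy_guest(n_sites = 3))
#' v <- initial_velocities(293, rb, seed = 1)
#' 0.5 * rb$mass * sum(v$velocity^2) / mm_constants()$kcal_to_internal
#' 1.5 * mm_constants()$kb * 293  # equal by construction
initial_velocities <- function(temperature = 293, body, seed = NULL) {
  stopifnot(temperature > 0)
  kT_int <- .kb * temperature * .kcal2int
  with_seed(seed, {
    u <- rnorm(3)
    u <- u / sqrt(sum(u^2))
    speed <- sqrt(3 * kT_int / body$mass)
    velocity <- speed * u
    omega <- c(0, 0, 0)
    if (body$rot_dof > 0) {
      w <- rnorm(3)
      w[!body$live_axes] <- 0
      w <- w / sqrt(sum(w^2))
      target <- body$rot_dof / 2 * kT_int
      s <- sqrt(2 * target / sum(body$inertia * w^2))
      omega <- s * w
    }
    list(velocity = velocity, omega_body = omega)
  })
}

#' Rigid-body dynamical state
#'
#' @param com Centre of mass (Å, host frame).
#' @param velocity Half-step COM velocity (Å/fs).
#' @param quaternion Unit orientation quaternion (body -> lab).
#' @param omega_body Body-frame angular velocity (rad/fs).
#' @param body A [rigid_body()].
#' @return A list of class `rigid_body_state`.
#' @export
rigid_body_state <- function(com, velocity, quaternion, omega_body, body) {
  nq <- sqrt(sum(quaternion^2))
  if (abs(nq - 1) > 1e-6) abort("quaternion norm too far from 1")
  q <- quaternion / nq
  ## angular momentum is propagated in the LAB frame, where it is exactly
  ## conserved under zero torque
  ang_mom <- as.numeric(quaternion_to_matrix(q) %*%
                          (body$inertia * as.numeric(omega_body)))
  structure(
    list(com = as.numeric(com), velocity = as.numeric(velocity),
         q = q, omega = as.numeric(omega_body), ang_mom = ang_mom,
         body = body),
    class = "rigid_body_state"
  )
}

#' Kinetic energies of a state
#'
#' @param state A [rigid_body_state()].
#' @return A one-row tibble `ke_trans`, `ke_rot` (kcal/mol) at the stored
#'   half-step velocities.
#' @export
kinetic_energy <- function(state) {
  kt <- 0.5 * state$body$mass * sum(state$velocity^2) / .kcal2int
  kr <- 0.5 * sum(state$body$inertia * state$omega^2) / .kcal2int
  tibble(ke_trans = kt, ke_rot = kr)
}

#' One leap-frog step of the rigid-body integrator
#'
#' Translational half-step velocity update from the COM force, rotational
#' update of the body-frame angular velocity from the torque via Euler's
#' equations, and quaternion advance by the exact constant-omega rotation
#' over the step, followed by renormalization.  With a thermostat the
#' half-step translational and rotational velocities are each rescaled by a
#' scalar so their kinetic energies sit exactly at the equipartition
#' targets; with `thermostat = NULL` the step is plain (microcanonical)
#' leap-frog.
#'
#' @param state A [rigid_body_state()].
#' @param force COM force, kcal/mol/Å (length 3, lab frame).
#' @param torque Torque about the COM, kcal/mol (length 3, lab frame).
#' @param dt Time step in fs (> 0).
#' @param thermostat A [thermostat_spec()] or `NULL`.
#' @return The advanced `rigid_body_state`.
#' @export
md_step <- function(state, force, torque, dt = 1, thermostat = NULL) {
  if (!all(is.finite(force)) || !all(is.finite(torque))) {
    abort("non-finite force or torque; integration aborted")
  }
  body <- state$body
  v <- state$velocity + dt * (force * .kcal2int) / body$mass
  if (!is.null(thermostat)) {
    target <- 1.5 * .kb * thermostat$temperature * .kcal2int
    ke <- 0.5 * body$mass * sum(v * v)
    v <- v * sqrt(target / ke)
  }
  com <- state$com + dt * v

  omega <- state$omega
  q <- state$q
  L <- state$ang_mom
  if (body$rot_dof > 0) {
    Rm <- quaternion_to_matrix(q)
    ## leap-frog on the lab-frame angular momentum
    L <- L + dt * torque * .kcal2int
    I <- body$inertia
    Lb <- as.numeric(crossprod(Rm, L))
    Lb[!body$live_axes] <- 0
    omega <- ifelse(body$live_axes, Lb / I, 0)
    if (!is.null(thermostat)) {
      target_r <- body$rot_dof / 2 * .kb * thermostat$temperature * .kcal2int
      ke_r <- 0.5 * sum(I * omega^2)
      if (ke_r > 0) {
        lambda <- sqrt(target_r / ke_r)
        omega <- omega * lambda
        L <- L * lambda
      }
    }
    q <- quat_multiply(q, quat_from_rotvec(omega * dt))
    q <- q / sqrt(sum(q^2))
  }
  state$com <- com
  state$velocity <- v
  state$q <- q
  state$omega <- omega
  state$ang_mom <- L
  state
}

#' Initial disposition of a guest trajectory
#'
#' The four canonical start classes: the guest centre of mass on the cavity
#' axis 1 Å beyond the narrower (-Z) or wider (+Z) rim plane, with either
#' the guest's "head" end (body +X: the substituent/radical end) or its
#' "tail" end (body -X: the phenyl/ring end) pointing toward the cavity.
#' The remaining rotational freedom (the spin about the pointing axis) is
#' drawn from the seeded generator unless `spin` is given.
#'
#' @param region `"narrow-rim"` or `"wide-rim"`.
#' @param heading `"radical-first"` or `"phenyl-first"` — which guest end
#'   points toward the cavity.
#' @param offset Distance beyond the rim plane, Å (default 1).
#' @param spin Optional fixed spin angle about the approach axis (radians);
#'   default random.
#' @param seed RNG seed for the random spin.
#' @return An object of class `initial_disposition`.
#' @export
initial_disposition <- function(region = c("narrow-rim", "wide-rim"),
                                heading = c("radical-first", "phenyl-first"),
                                offset = 1, spin = NULL, seed = NULL) {
  region <- match.arg(region)
  heading <- match.arg(heading)
  structure(
    list(region = region, heading = heading, offset = offset, spin = spin,
         seed = seed),
    class = "initial_disposition"
  )
}

.disposition_pose <- function(disp, host) {
  cg <- cavity_geometry(host)
  zc <- if (disp$region == "narrow-rim") cg$z_lo - disp$offset else
    cg$z_hi + disp$offset
  ## direction into the cavity along the axis
  dir <- if (disp$region == "narrow-rim") 1 else -1
  ## align body +X with the approach direction (radical-first) or against
  ## it (phenyl-first): rotate +X onto (0, 0, dir_head)
  head_sign <- if (disp$heading == "radical-first") dir else -dir
  beta <- if (head_sign > 0) -pi / 2 else pi / 2  # Ry(beta): x -> ±z
  spin <- disp$spin %||% with_seed(disp$seed, runif(1, 0, 2 * pi))
  q <- quat_multiply(c(cos(beta / 2), 0, sin(beta / 2), 0),
                     c(cos(spin / 2), sin(spin / 2), 0, 0))
  pose(com = c(0, 0, zc), quaternion = q)
}

#' Run a single rigid-body trajectory
#'
#' Propagates the guest in the host's field at constant temperature from an
#' [initial_disposition()].  The configuration and energies are registered
#' every `sample_every` steps of `dt`.  Integration stops when the guest
#' centre of mass lies outside the host envelope (a cylinder of the larger
#' rim radius + 2 Å over the host Z extent + 2 Å margins) while the
#' intermolecular energy is no longer attractive enough to re-enter
#' (`Einter > -kB T`), sustained over `exit_patience` consecutive sampled
#' frames — or at `max_steps`, in which case the trajectory is flagged
#' non-terminated.
#'
#' @param host `mm_molecule` in its host frame.
#' @param guest `mm_molecule`.
#' @param params [ff_params()].
#' @param solvent [solvent_model()].
#' @param initial An [initial_disposition()].
#' @param thermostat A [thermostat_spec()] (default 293 K) or `NULL`.
#' @param dt Time step, fs.
#' @param sample_every Steps between registered frames.
#' @param max_steps Hard cap on integration steps.
#' @param exit_patience Consecutive qualifying sampled frames required to
#'   stop.
#' @param seed RNG seed (spin + initial velocity directions).
#' @return An object of class `md_trajectory`: `$frames` (time in ps,
#'   rigid-body state, energy breakdown per frame), `$termination`,
#'   `$residence_ps` and metadata.  `tidy()` returns the frame table.
#' @export
run_trajectory <- function(host, guest, params, solvent = solvent_model(),
                           initial = initial_disposition(),
                           thermostat = thermostat_spec(293),
                           dt = 1, sample_every = 100, max_steps = 200000,
                           exit_patience = 50, seed = NULL) {
  body <- rigid_body(guest)
  initial$seed <- initial$seed %||% seed
  p0 <- .disposition_pose(initial, host)
  vel <- initial_velocities(
    if (is.null(thermostat)) 293 else thermostat$temperature, body,
    seed = if (is.null(seed)) NULL else seed + 1L
  )
  ## the dynamical orientation maps the PRINCIPAL body frame to the lab;
  ## compose the disposition pose with the reference->principal alignment
  q0 <- p0$q
  qaxes <- .matrix_to_quaternion(body$axes)
  q0 <- quat_multiply(q0, qaxes)
  state <- rigid_body_state(p0$com, vel$velocity, q0, vel$omega_body, body)

  cg <- cavity_geometry(host)
  env_r <- max(cg$r_lo, cg$r_hi) + 2
  env_z <- c(cg$z_lo - 2, cg$z_hi + 2)
  kT <- .kb * (if (is.null(thermostat)) 293 else thermostat$temperature)

  pt <- .pair_table(host, guest, params)
  hxyz <- mol_coords(host)
  eintra <- .guest_eintra_const(guest, params)
  bxyz <- body$body_xyz

  ## flattened per-pair coefficients for the inlined inner loop; H-bond
  ## pairs take the 12-10 coefficients in place of the 12-6 ones
  c12 <- ifelse(pt$hb, pt$C, pt$A)
  c6 <- ifelse(pt$hb, 0, pt$B)
  c10 <- ifelse(pt$hb, pt$D, 0)
  kq <- (.coulomb / solvent$epsilon) * pt$qq
  bx <- bxyz[pt$ii, 1]; by <- bxyz[pt$ii, 2]; bz <- bxyz[pt$ii, 3]
  hx <- hxyz[pt$jj, 1]; hy <- hxyz[pt$jj, 2]; hz <- hxyz[pt$jj, 3]
  hbm <- pt$hb
  mass <- body$mass
  inertia <- body$inertia
  live <- body$live_axes
  rot <- body$rot_dof > 0
  iso <- !is.null(thermostat)
  if (iso) {
    target_t <- 1.5 * .kb * thermostat$temperature * .kcal2int
    target_r <- body$rot_dof / 2 * .kb * thermostat$temperature * .kcal2int
  }

  com <- state$com; v <- state$velocity; q <- state$q; omega <- state$omega
  Llab <- state$ang_mom

  n_samples_max <- floor(max_steps / sample_every) + 2L
  fr <- matrix(NA_real_, nrow = n_samples_max, ncol = 16)
  colnames(fr) <- c("time_ps", "x", "y", "z", "qw", "qx", "qy", "qz",
                    "vx", "vy", "vz", "lj", "ele", "hbond", "einter",
                    "e_total")
  fi <- 0L
  consec <- 0L
  termination <- "max_steps"
  floor2 <- .r_floor^2
  ## recorded orientations are relative to the guest's REFERENCE
  ## conformation, so pose(com, q) + place_guest() reproduces the frame
  qaxes_conj <- c(qaxes[1], -qaxes[2:4])

  ## one force/torque (and optionally energy) evaluation at (com, q)
  step <- 0L
  repeat {
    ## rotation matrix from q (body -> lab)
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    r11 <- 1 - 2 * (y * y + z * z); r12 <- 2 * (x * y - w * z)
    r13 <- 2 * (x * z + w * y)
    r21 <- 2 * (x * y + w * z); r22 <- 1 - 2 * (x * x + z * z)
    r23 <- 2 * (y * z - w * x)
    r31 <- 2 * (x * z - w * y); r32 <- 2 * (y * z + w * x)
    r33 <- 1 - 2 * (x * x + y * y)
    gx <- r11 * bx + r12 * by + r13 * bz + com[1]
    gy <- r21 * bx + r22 * by + r23 * bz + com[2]
    gz <- r31 * bx + r32 * by + r33 * bz + com[3]
    dx <- gx - hx; dy <- gy - hy; dz <- gz - hz
    r2 <- dx * dx + dy * dy + dz * dz
    if (any(r2 < floor2)) r2[r2 < floor2] <- floor2
    inv2 <- 1 / r2
    invr <- sqrt(inv2)
    inv6 <- inv2 * inv2 * inv2
    inv12 <- inv6 * inv6
    inv10 <- inv6 * inv2 * inv2
    ## -dU/dR * 1/R per pair
    coef <- (12 * c12 * inv12 - 6 * c6 * inv6 - 10 * c10 * inv10) * inv2 +
      kq * invr * inv2
    fx <- coef * dx; fy <- coef * dy; fz <- coef * dz
    force <- c(sum(fx), sum(fy), sum(fz))
    relx <- gx - com[1]; rely <- gy - com[2]; relz <- gz - com[3]
    torque <- c(
      sum(rely * fz - relz * fy),
      sum(relz * fx - relx * fz),
      sum(relx * fy - rely * fx)
    )

    sampled <- step %% sample_every == 0L
    if (sampled) {
      e_lj <- sum((c12 * inv12 - c6 * inv6)[!hbm])
      e_hb <- if (any(hbm)) sum((c12 * inv12 - c10 * inv10)[hbm]) else 0
      e_ele <- sum(kq * invr)
      einter <- e_lj + e_ele + e_hb
      fi <- fi + 1L
      qref <- quat_multiply(q, qaxes_conj)
      fr[fi, ] <- c(step * dt / 1000, com, qref, v, e_lj, e_ele, e_hb,
                    einter, einter + eintra)
      if (step > 0L) {
        outside <- (com[1]^2 + com[2]^2) > env_r^2 ||
          com[3] < env_z[1] || com[3] > env_z[2]
        if (outside && einter > -kT) {
          consec <- consec + 1L
          if (consec >= exit_patience) {
            termination <- "escaped"
            break
          }
        } else {
          consec <- 0L
        }
      }
    }
    if (step >= max_steps) break
    step <- step + 1L

    ## leap-frog advance (same scheme as md_step)
    v <- v + dt * (force * .kcal2int) / mass
    if (iso) {
      ke <- 0.5 * mass * sum(v * v)
      v <- v * sqrt(target_t / ke)
    }
    com <- com + dt * v
    if (rot) {
      Llab <- Llab + dt * torque * .kcal2int
      Lb <- c(
        r11 * Llab[1] + r21 * Llab[2] + r31 * Llab[3],
        r12 * Llab[1] + r22 * Llab[2] + r32 * Llab[3],
        r13 * Llab[1] + r23 * Llab[2] + r33 * Llab[3]
      )
      Lb[!live] <- 0
      omega <- ifelse(live, Lb / inertia, 0)
      if (iso) {
        ke_r <- 0.5 * sum(inertia * omega^2)
        if (ke_r > 0) {
          lambda <- sqrt(target_r / ke_r)
          omega <- omega * lambda
          Llab <- Llab * lambda
        }
      }
      rv <- omega * dt
      theta <- sqrt(sum(rv * rv))
      if (theta > 1e-300) {
        sa <- sin(theta / 2) / theta
        dq <- c(cos(theta / 2), rv * sa)
        q <- c(
          q[1] * dq[1] - q[2] * dq[2] - q[3] * dq[3] - q[4] * dq[4],
          q[1] * dq[2] + q[2] * dq[1] + q[3] * dq[4] - q[4] * dq[3],
          q[1] * dq[3] - q[2] * dq[4] + q[3] * dq[1] + q[4] * dq[2],
          q[1] * dq[4] + q[2] * dq[3] - q[3] * dq[2] + q[4] * dq[1]
        )
        q <- q / sqrt(sum(q * q))
      }
    }
  }
  frames <- as_tibble(as.data.frame(fr[seq_len(fi), , drop = FALSE]))
  frames$eintra <- eintra
  frames <- frames[, c("time_ps", "x", "y", "z", "qw", "qx", "qy", "qz",
                       "vx", "vy", "vz", "lj", "ele", "hbond", "einter",
                       "eintra", "e_total")]
  traj <- structure(
    list(frames = frames, termination = termination,
         disposition = initial, seed = seed, dt = dt,
         sample_every = sample_every, epsilon = solvent$epsilon,
         temperature = if (is.null(thermostat)) NA_real_ else
           thermostat$temperature),
    class = "md_trajectory"
  )
  traj$residence_ps <- residence_time(traj)$residence_ps
  traj
}

## Rotation matrix -> quaternion (Shepperd's method, robust branch choice).
.matrix_to_quaternion <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf(
    "<md_trajectory> %d frames (%.1f ps), %s/%s start, %s; residence %.1f ps\n",
    nrow(x$frames), max(x$frames$time_ps), x$disposition$region,
    x$disposition$heading, x$termination, x$residence_ps))
  invisible(x)
}

#' Residence time of a trajectory
#'
#' The total sampled time during which the host-guest interaction is
#' attractive enough to keep the molecules together: frames with
#' `Einter < threshold` (default `-kB T` at the trajectory temperature).
#'
#' @param traj An `md_trajectory`.
#' @param threshold Energy threshold in kcal/mol (default `-kB T`).
#' @return A one-row tibble with `residence_ps`, `n_frames_bound`,
#'   `n_segments` (count of contiguous bound segments) and
#'   `longest_segment_ps`.
#' @export
residence_time <- function(traj, threshold = NULL) {
  temp <- if (is.na(traj$temperature)) 293 else traj$temperature
  threshold <- threshold %||% (-.kb * temp)
  bound <- traj$frames$einter < threshold
  dt_ps <- traj$dt * traj$sample_every / 1000
  runs <- rle(bound)
  seg <- runs$lengths[runs$values]
  tibble(
    residence_ps = sum(bound) * dt_ps,
    n_frames_bound = sum(bound),
    n_segments = length(seg),
    longest_segment_ps = if (length(seg)) max(seg) * dt_ps else 0
  )
}
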