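## Trajectory analysis: position probability densities, the ensemble
## binding free energy, and simulation summaries.

#' Position probability density over a voxel grid
#'
#' Bins every sampled guest centre-of-mass position into half-open voxels
#' `[origin + k*spacing, origin + (k+1)*spacing)` and normalizes by the
#' total number of sampled positions across the input set.  Positions
#' falling outside the grid are counted in an overflow tally (so the
#' in-grid probabilities sum to 1 only when nothing overflows).
#'
#' @param trajectories A list of `md_trajectory` objects (or a single one).
#' @param origin Length-3 lower corner of the grid (Å).  Default: snapped
#'   to cover all sampled positions.
#' @param spacing Voxel edge length (Å), default 0.5.
#' @param dim Length-3 integer voxel counts.  Default: derived from the
#'   data extent.
#' @return An object of class `density_grid` with the count and probability
#'   arrays; `tidy()` returns one row per voxel.
#' @export
position_density <- function(trajectories, origin = NULL, spacing = 0.5,
                             dim = NULL) {
  trajectories <- .as_traj_list(trajectories)
  if (length(trajectories) == 0) abort("need at least one trajectory")
  pos <- dplyr::bind_rows(lapply(trajectories, function(t) {
    t$frames[, c("x", "y", "z")]
  }))
  if (nrow(pos) == 0) abort("trajectories contain no frames")
  if (is.null(origin)) {
    origin <- floor(apply(pos, 2, min) / spacing) * spacing
  }
  if (is.null(dim)) {
    dim <- pmax(1L, as.integer(ceiling(
      (apply(pos, 2, max) - origin) / spacing + 1e-9
    )))
  }
  idx <- floor(sweep(as.matrix(pos), 2, origin) / spacing) + 1L
  inside <- idx[, 1] >= 1 & idx[, 1] <= dim[1] &
    idx[, 2] >= 1 & idx[, 2] <= dim[2] &
    idx[, 3] >= 1 & idx[, 3] <= dim[3]
  counts <- array(0L, dim = dim)
  if (any(inside)) {
    lin <- (idx[inside, 3] - 1L) * dim[1] * dim[2] +
      (idx[inside, 2] - 1L) * dim[1] + idx[inside, 1]
    tab <- tabulate(lin, nbins = prod(dim))
    counts <- array(tab, dim = dim)
  }
  n_total <- nrow(pos)
  structure(
    list(origin = as.numeric(origin), spacing = spacing, dim = dim,
         counts = counts, prob = counts / n_total,
         n_total = n_total, n_overflow = sum(!inside)),
    class = "density_grid"
  )
}

.as_traj_list <- function(x) {
  if (inherits(x, "md_trajectory")) list(x) else x
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf(
    "<density_grid> %d x %d x %d voxels of %.2f A, %d positions (%d overflow)\n",
    x$dim[1], x$dim[2], x$dim[3], x$spacing, x$n_total, x$n_overflow))
  invisible(x)
}

#' Project a density onto a coordinate plane
#'
#' Marginal sum over the discarded axis; the projected map carries the same
#' total probability as the 3-D grid.
#'
#' @param density A [position_density()] grid.
#' @param plane `"xy"` or `"xz"`.
#' @return A tibble of class `density_projection` with the two retained
#'   voxel-centre coordinates and `prob`.
#' @export
project_density <- function(density, plane = c("xy", "xz")) {
  plane <- match.arg(plane)
  drop_axis <- if (plane == "xy") 3L else 2L
  keep <- setdiff(1:3, drop_axis)
  mat <- apply(density$prob, keep, sum)
  centres <- lapply(1:3, function(a) {
    density$origin[a] + (seq_len(density$dim[a]) - 0.5) * density$spacing
  })
  grid <- expand.grid(a = centres[[keep[1]]], b = centres[[keep[2]]],
                      KEEP.OUT.ATTRS = FALSE)
  nm <- c("x", "y", "z")[keep]
  out <- tibble(!!nm[1] := grid$a, !!nm[2] := grid$b,
                prob = as.vector(mat))
  attr(out, "plane") <- plane
  class(out) <- c("density_projection", class(out))
  out
}

#' Density from a subset of trajectories
#'
#' Restricts the position probability density to trajectories matching a
#' predicate on their initial disposition — the four canonical groupings
#' (by heading or by start region) are available as named presets.
#'
#' @param trajectories List of `md_trajectory`.
#' @param subset A preset name (`"radical-first"`, `"phenyl-first"`,
#'   `"narrow-rim"`, `"wide-rim"`) or a predicate function taking an
#'   [initial_disposition()] and returning a logical.
#' @inheritParams position_density
#' @return A `density_grid` over the matching trajectories only.
#' @export
subset_density <- function(trajectories, subset, origin = NULL,
                           spacing = 0.5, dim = NULL) {
  trajectories <- .as_traj_list(trajectories)
  pred <- if (is.function(subset)) {
    subset
  } else {
    switch(subset,
      "radical-first" = function(d) d$heading == "radical-first",
      "phenyl-first" = function(d) d$heading == "phenyl-first",
      "narrow-rim" = function(d) d$region == "narrow-rim",
      "wide-rim" = function(d) d$region == "wide-rim",
      abort(paste0("unknown subset preset: ", subset))
    )
  }
  keep <- vapply(trajectories, function(t) isTRUE(pred(t$disposition)), TRUE)
  if (!any(keep)) abort("subset matches no trajectory")
  position_density(trajectories[keep], origin = origin, spacing = spacing,
                   dim = dim)
}

#' Ensemble binding free energy
#'
#' `F = -kB T log( sum_i exp(-W_i / kB T) )` over the complex energies
#' registered along the trajectories, evaluated with the log-sum-exp shift
#' so large energy ranges cannot overflow.  With a single energy `F = W1`;
#' with `N` identical energies `F = W - kB T log N`; always
#' `F <= min(W_i)`.
#'
#' @param energies Numeric vector of complex energies `W_i` (kcal/mol).
#' @param temperature Temperature in K.
#' @return The free energy `F` in kcal/mol.
#' @export
#' @examples
#' binding_free_energy(c(0, 0), 293)  # -kB T log 2
binding_free_energy <- function(energies, temperature = 293) {
  if (length(energies) == 0) abort("energies must be non-empty")
  stopifnot(temperature > 0, all(is.finite(energies)))
  kT <- .kb * temperature
  xs <- -energies / kT
  m <- max(xs)
  -kT * (m + log(sum(exp(xs - m))))
}

#' Summarize a set of trajectories
#'
#' Per-trajectory residence times and binding free energies (over that
#' trajectory's registered frames) plus the simulation-level means: `Emean`
#' is the frame-weighted mean of per-frame total energies (with component
#' means alongside), `Fmean` and `tmean` are unweighted means of the
#' per-trajectory values.
#'
#' @param trajectories List of `md_trajectory`.
#' @param temperature Temperature in K used in the free energy and the
#'   default residence threshold.
#' @return An object of class `simulation_summary`: `$per_trajectory` and
#'   `$overall` tibbles.  `glance()` returns `$overall`.
#' @export
summarize_trajectories <- function(trajectories, temperature = 293) {
  trajectories <- .as_traj_list(trajectories)
  if (length(trajectories) == 0) abort("need at least one trajectory")
  per <- purrr::imap_dfr(trajectories, function(t, i) {
    rt <- residence_time(t, threshold = -.kb * temperature)
    fr <- t$frames
    tibble(
      trajectory = i,
      region = t$disposition$region,
      heading = t$disposition$heading,
      n_frames = nrow(fr),
      t_ps = rt$residence_ps,
      F = binding_free_energy(fr$e_total, temperature),
      e_mean = mean(fr$e_total),
      einter_mean = mean(fr$einter),
      eintra_mean = mean(fr$eintra),
      terminated = t$termination != "max_steps"
    )
  })
  all_frames <- dplyr::bind_rows(lapply(trajectories, `[[`, "frames"))
  overall <- tibble(
    n_trajectories = length(trajectories),
    n_frames = nrow(all_frames),
    e_mean = mean(all_frames$e_total),
    einter_mean = mean(all_frames$einter),
    eintra_mean = mean(all_frames$eintra),
    lj_mean = mean(all_frames$lj),
    ele_mean = mean(all_frames$ele),
    hbond_mean = mean(all_frames$hbond),
    f_mean = mean(per$F),
    f_min = min(per$F),
    f_max = max(per$F),
    t_mean_ps = mean(per$t_ps),
    t_min_ps = min(per$t_ps),
    t_max_ps = max(per$t_ps)
  )
  structure(
    list(per_trajectory = per, overall = overall, temperature = temperature),
    class = "simulation_summary"
  )
}

#' @export
print.simulation_summary <- function(x, ...) {
  o <- x$overall
  cat(sprintf(
    paste0("<simulation_summary> %d trajectories, %d frames\n",
           "  Emean = %.2f (inter %.2f, intra %.2f) kcal/mol\n",
           "  Fmean = %.2f kcal/mol [%.2f, %.2f]\n",
           "  tmean = %.1f ps [%.1f, %.1f]\n"),
    o$n_trajectories, o$n_frames, o$e_mean, o$einter_mean, o$eintra_mean,
    o$f_mean, o$f_min, o$f_max, o$t_mean_ps, o$t_min_ps, o$t_max_ps))
  invisible(x)
}
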