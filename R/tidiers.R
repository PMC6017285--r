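## broom-style tidiers for the result objects.

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a scan result
#'
#' @param x A `scan_result`.
#' @param ... Unused.
#' @return The per-grid-point tibble (`x`, `y`, `z`, `e_min`, `einter_min`,
#'   components, argmin orientation, clash flag).
#' @export
tidy.scan_result <- function(x, ...) x$points

#' Glance at a scan result
#'
#' @param x A `scan_result`.
#' @param ... Unused.
#' @return One-row tibble: grid size, orientation count, `e_min`,
#'   `einter_min`, guest intramolecular constant.
#' @export
glance.scan_result <- function(x, ...) {
  tibble(
    n_points = nrow(x$points),
    n_orientations = nrow(x$orientations$q),
    e_min = min(x$points$e_min),
    einter_min = min(x$points$einter_min),
    guest_eintra = x$guest_eintra,
    epsilon = x$epsilon
  )
}

#' Tidy a Boltzmann PES map
#'
#' @param x A `pes_map`.
#' @param ... Unused.
#' @return The per-point tibble with `e_avg`, `e_min`, `e_mean`.
#' @export
tidy.pes_map <- function(x, ...) x$points

#' Tidy an MD trajectory
#'
#' @param x An `md_trajectory`.
#' @param ... Unused.
#' @return The frame table: time (ps), rigid-body state and energy
#'   breakdown per registered frame.
#' @export
tidy.md_trajectory <- function(x, ...) x$frames

#' Glance at an MD trajectory
#'
#' @param x An `md_trajectory`.
#' @param ... Unused.
#' @return One-row tibble: frames, duration, residence time, mean energies,
#'   termination reason and start class.
#' @export
glance.md_trajectory <- function(x, ...) {
  tibble(
    n_frames = nrow(x$frames),
    duration_ps = max(x$frames$time_ps),
    residence_ps = x$residence_ps,
    e_mean = mean(x$frames$e_total),
    einter_mean = mean(x$frames$einter),
    termination = x$termination,
    region = x$disposition$region,
    heading = x$disposition$heading
  )
}

#' Tidy a density grid
#'
#' @param x A `density_grid`.
#' @param ... Unused.
#' @return Tibble with voxel centre coordinates, `count` and `prob`.
#' @export
tidy.density_grid <- function(x, ...) {
  centres <- lapply(1:3, function(a) {
    x$origin[a] + (seq_len(x$dim[a]) - 0.5) * x$spacing
  })
  grid <- expand.grid(x = centres[[1]], y = centres[[2]], z = centres[[3]],
                      KEEP.OUT.ATTRS = FALSE)
  tibble(
    x = grid$x, y = grid$y, z = grid$z,
    count = as.vector(x$counts), prob = as.vector(x$prob)
  )
}

#' Tidy a simulation summary
#'
#' @param x A `simulation_summary`.
#' @param ... Unused.
#' @return The per-trajectory tibble (residence time, free energy, mean
#'   energies per trajectory).
#' @export
tidy.simulation_summary <- function(x, ...) x$per_trajectory

#' Glance at a simulation summary
#'
#' @param x A `simulation_summary`.
#' @param ... Unused.
#' @return The one-row overall tibble (`e_mean`, `f_mean`, `t_mean_ps`,
#'   component means, ranges).
#' @export
glance.simulation_summary <- function(x, ...) x$overall

#' Glance at a study
#'
#' @param x An `inclusion_study`.
#' @param ... Unused.
#' @return One-row tibble combining the scan minimum, inclusion
#'   classification and (when MD ran) the simulation means.
#' @export
glance.inclusion_study <- function(x, ...) {
  base <- tibble(
    e_min = x$minimum$e_min,
    inclusion = x$inclusion$inclusion,
    fraction_inside = x$inclusion$fraction_inside,
    n_trajectories = length(x$trajectories)
  )
  if (!is.null(x$summary)) {
    dplyr::bind_cols(base, x$summary$overall[, c("e_mean", "f_mean",
                                                 "t_mean_ps")])
  } else {
    base
  }
}
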