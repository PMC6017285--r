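## ggplot2 autoplot methods for the result types.

#' Plot the penetration potential
#'
#' W(Z) with its Lennard-Jones, electrostatic and H-bond contributions
#' along the cavity axis.
#'
#' @param object A [penetration_potential()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.penetration_potential <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("z", "W", "lj", "ele", "hbond")],
    cols = c("W", "lj", "ele", "hbond"),
    names_to = "term", values_to = "energy"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$z, y = .data$energy,
                                     colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Z (Å)", y = "energy (kcal/mol)",
                  colour = NULL,
                  title = "Penetration potential along the cavity axis") +
    ggplot2::theme_minimal()
}

#' Plot a Boltzmann PES map
#'
#' The four Z-domain surfaces (per-(X,Y) minimum of the orientation-averaged
#' energy), faceted from the narrower to the wider rim.
#'
#' @param object A `pes_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pes_map <- function(object, ...) {
  slabs <- object$slabs
  slabs$domain <- factor(slabs$domain, levels = unique(slabs$domain))
  ggplot2::ggplot(slabs, ggplot2::aes(x = .data$x, y = .data$y,
                                      fill = .data$energy)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~domain, nrow = 1) +
    ggplot2::scale_fill_viridis_c(name = "<E> (kcal/mol)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "X (Å)", y = "Y (Å)",
                  title = "Boltzmann-averaged potential energy surface") +
    ggplot2::theme_minimal()
}

#' Plot an MD trajectory
#'
#' Energy components and the axial centre-of-mass coordinate against time.
#'
#' @param object An `md_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.md_trajectory <- function(object, ...) {
  fr <- object$frames
  long <- tidyr::pivot_longer(
    fr[, c("time_ps", "e_total", "einter", "z")],
    cols = c("e_total", "einter", "z"),
    names_to = "series", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_ps, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (ps)", y = NULL,
                  title = "Trajectory energies and axial position") +
    ggplot2::theme_minimal()
}

#' Plot a density projection
#'
#' @param object A [project_density()] map.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.density_projection <- function(object, ...) {
  nm <- setdiff(names(object), "prob")
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[nm[1]]],
                                       y = .data[[nm[2]]],
                                       fill = .data$prob)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "probability") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste0(toupper(nm[1]), " (Å)"),
                  y = paste0(toupper(nm[2]), " (Å)"),
                  title = "Centre-of-mass position probability density") +
    ggplot2::theme_minimal()
}
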