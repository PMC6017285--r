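## Full-study orchestration: grid scan -> MD protocol -> observables.

#' Run a complete inclusion-complex study
#'
#' Composes the whole pipeline on one host/guest system: the
#' position-by-orientation energy scan (penetration potential, Boltzmann
#' PES, global minimum and inclusion classification), the MD protocol
#' (`n_per_disposition` trajectories from each of the four canonical
#' starting dispositions — by default 3 x 4 = 12), and the trajectory
#' observables (position probability density and simulation summary).
#' Everything is reproducible from the seed: trajectory seeds are derived
#' deterministically from `seed`.
#'
#' @param host `mm_molecule` in its host frame.
#' @param guest `mm_molecule`.
#' @param params [ff_params()].
#' @param solvent [solvent_model()] (water by default).
#' @param grid [scan_grid()] for the energy scan.
#' @param orientations [generate_orientations()] set for the scan and PES.
#' @param temperature Process temperature, K.
#' @param n_per_disposition Trajectories per disposition class (default 3).
#' @param dt,sample_every,max_steps,exit_patience MD controls, see
#'   [run_trajectory()].
#' @param voxel Density voxel edge, Å.
#' @param seed Master seed.
#' @param output_dir Optional directory: per-trajectory frame CSVs, the
#'   W(Z) and summary CSV/JSON products and a manifest are written there.
#' @return An object of class `inclusion_study` with elements `scan`, `w`,
#'   `pes`, `minimum`, `inclusion`, `trajectories`, `density`, `summary`.
#' @export
run_study <- function(host, guest, params, solvent = solvent_model(),
                      grid = scan_grid(spacing = 0.5),
                      orientations = generate_orientations(count = 500),
                      temperature = 293, n_per_disposition = 3,
                      dt = 1, sample_every = 100, max_steps = 200000,
                      exit_patience = 50, voxel = 0.5, seed = 1,
                      output_dir = NULL) {
  scan <- mm_scan(host, guest, grid, orientations, params, solvent)
  w <- penetration_potential(scan)
  pes <- boltzmann_pes(host, guest, grid, orientations, params, solvent,
                       temperature)
  minimum <- global_minimum(scan, host, guest, params, solvent)
  inclusion <- classify_inclusion(place_guest(guest, minimum$pose), host)

  dispositions <- expand.grid(
    region = c("narrow-rim", "wide-rim"),
    heading = c("radical-first", "phenyl-first"),
    stringsAsFactors = FALSE
  )
  trajectories <- list()
  if (n_per_disposition > 0) {
    k <- 0L
    for (d in seq_len(nrow(dispositions))) {
      for (rep in seq_len(n_per_disposition)) {
        k <- k + 1L
        trajectories[[k]] <- run_trajectory(
          host, guest, params, solvent,
          initial = initial_disposition(dispositions$region[d],
                                        dispositions$heading[d]),
          thermostat = thermostat_spec(temperature),
          dt = dt, sample_every = sample_every, max_steps = max_steps,
          exit_patience = exit_patience,
          seed = as.integer(seed) + 1000L * k
        )
      }
    }
  }
  density <- if (length(trajectories) > 0) {
    position_density(trajectories, spacing = voxel)
  }
  summary <- if (length(trajectories) > 0) {
    summarize_trajectories(trajectories, temperature)
  }
  study <- structure(
    list(scan = scan, w = w, pes = pes, minimum = minimum,
         inclusion = inclusion, trajectories = trajectories,
         density = density, summary = summary, seed = seed,
         temperature = temperature),
    class = "inclusion_study"
  )
  if (!is.null(output_dir)) write_study(study, output_dir)
  study
}

#' @export
print.inclusion_study <- function(x, ...) {
  cat(sprintf("<inclusion_study> Emin = %.3f kcal/mol (%s, %.0f%% of guest inside)\n",
              x$minimum$e_min,
              if (x$inclusion$inclusion) "inclusion" else "non-inclusion",
              100 * x$inclusion$fraction_inside))
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}

#' Write study products to a directory
#'
#' Writes the penetration potential and PES slabs as CSV, per-trajectory
#' frame tables as CSV, the density as a Gaussian cube file, the summary as
#' JSON, and a manifest listing everything with the seed.
#'
#' @param study An `inclusion_study`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$w, file.path(dir, "penetration_potential.csv"),
                   row.names = FALSE)
  utils::write.csv(study$pes$slabs, file.path(dir, "pes_slabs.csv"),
                   row.names = FALSE)
  files <- c("penetration_potential.csv", "pes_slabs.csv")
  for (i in seq_along(study$trajectories)) {
    f <- sprintf("trajectory_%02d.csv", i)
    utils::write.csv(study$trajectories[[i]]$frames, file.path(dir, f),
                     row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(study$density)) {
    write_cube(study$density, file.path(dir, "density.cube"))
    files <- c(files, "density.cube")
  }
  if (!is.null(study$summary)) {
    jsonlite::write_json(
      list(per_trajectory = study$summary$per_trajectory,
           overall = study$summary$overall),
      file.path(dir, "summary.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA
    )
    files <- c(files, "summary.json")
  }
  jsonlite::write_json(
    list(seed = study$seed, temperature = study$temperature,
         emin = study$minimum$e_min,
         inclusion = study$inclusion$inclusion,
         n_trajectories = length(study$trajectories), files = files),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Write a density grid as a Gaussian cube file
#'
#' Volumetric export for molecular visualization tools.  Cube files are in
#' Bohr by convention; coordinates are converted from Å.
#'
#' @param density A [position_density()] grid.
#' @param path Output path.
#' @param field `"prob"` (default) or `"counts"`.
#' @return `path`, invisibly.
#' @export
write_cube <- function(density, path, field = c("prob", "counts")) {
  field <- match.arg(field)
  bohr <- 1 / 0.529177210903
  o <- density$origin * bohr
  s <- density$spacing * bohr
  d <- density$dim
  vals <- density[[field]]
  lines <- c(
    "cyclodyn centre-of-mass density",
    sprintf("field: %s", field),
    sprintf("%5d %11.6f %11.6f %11.6f", 1L, o[1], o[2], o[3]),
    sprintf("%5d %11.6f %11.6f %11.6f", d[1], s, 0, 0),
    sprintf("%5d %11.6f %11.6f %11.6f", d[2], 0, s, 0),
    sprintf("%5d %11.6f %11.6f %11.6f", d[3], 0, 0, s),
    sprintf("%5d %11.6f %11.6f %11.6f %11.6f", 1L, 0, 0, 0, 0)
  )
  body <- character(0)
  for (ix in seq_len(d[1])) {
    for (iy in seq_len(d[2])) {
      row <- vals[ix, iy, ]
      chunks <- split(row, ceiling(seq_along(row) / 6))
      body <- c(body, vapply(chunks, function(ch) {
        paste(sprintf("%13.5e", ch), collapse = " ")
      }, ""))
    }
  }
  writeLines(c(lines, body), path)
  invisible(path)
}
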