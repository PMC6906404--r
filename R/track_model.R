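# energy deposited per unit volume for 1 Gy in unit-density matter
.EV_PER_UM3_PER_GY <- 1e-15 / 1.602176634e-19 # ~6241.5 eV/um^3
.EV_TO_J <- 1.602176634e-19
.E_MIN_EV <- 10.79 # ionization energy of liquid water

#' Surrogate track-structure model
#'
#' Aggregate description of low-LET electron track structure used to generate
#' per-nucleus event lists without a transport engine. Tracks are isotropic
#' uniform random chords through each nucleus; interaction clusters are
#' Poisson-spaced along chords; each cluster emits a random number of direct
#' energy depositions (energies \code{>= 10.79} eV, shifted-exponential with
#' mean \code{mean_deposit_eV}) jittered by an isotropic Gaussian of per-axis
#' sigma \code{cluster_radius_um}, and a Poisson number of hydroxyl-radical
#' interaction positions (\code{oh_per_direct_ratio} per direct event)
#' displaced by 2.5 ns of diffusion (isotropic Gaussian, radial RMS
#' \code{sqrt(6 D t)} = 6.48 nm at the defaults).
#'
#' The cluster linear density is derived from the energy-normalization
#' constraint (fluence x density x events/cluster x mean energy = 1 Gy per
#' unit volume), so the mean nucleus dose equals the prescribed dose by
#' construction. The \code{"paper-6MV"} preset is calibrated so that at 1 Gy
#' the per-nucleus dose coefficient of variation is about 0.06 and the
#' downstream damage module meets its yield/OER/complexity targets.
#'
#' @param preset preset name; currently \code{"paper-6MV"}.
#' @param ... named overrides of preset fields.
#' @return an object of class \code{track_model} (a named list).
#' @examples
#' m <- track_model()
#' oh_displacement_rms(m) * 1e3 # nm
#' @export
track_model <- function(preset = "paper-6MV", ...) {
  if (!identical(preset, "paper-6MV"))
    stop("unknown preset: ", preset, call. = FALSE)
  m <- list(
    preset = preset,
    fluence_per_um2_per_Gy = 10,
    mean_deposit_eV = 40,
    energy_threshold_eV = .E_MIN_EV,
    oh_per_direct_ratio = 1.3,
    oh_diffusion_m2_s = 2.8e-9,
    oh_time_s = 2.5e-9,
    cluster_mean_direct = 10.2, # geometric mean directs per cluster
    cluster_cap_direct = 25L,   # truncation of the sparse cluster size
    p_dense = 0.055,            # dense track-end cluster admixture
    dense_min = 39,
    dense_extra_mean = 3
  )
  ov <- list(...)
  bad <- setdiff(names(ov), c(names(m), "oh_sigma_um", "cluster_radius_um",
                              "cluster_density_per_um"))
  if (length(bad)) stop("unknown track model fields: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  m[names(ov)] <- ov
  # per-axis sigma of the 3D isotropic displacement, um
  if (is.null(m$oh_sigma_um))
    m$oh_sigma_um <- sqrt(2 * m$oh_diffusion_m2_s * m$oh_time_s) * 1e6
  # direct-event jitter: same spatial scale as the radical cloud, so direct
  # and indirect events are exchangeable within a cluster
  if (is.null(m$cluster_radius_um)) m$cluster_radius_um <- m$oh_sigma_um
  if (is.null(m$cluster_density_per_um)) {
    # mean of the truncated geometric: E[min(K, cap)] for K ~ Geom(1/mu)
    mu <- m$cluster_mean_direct
    ksparse <- mu * (1 - (1 - 1 / mu)^m$cluster_cap_direct)
    kbar <- (1 - m$p_dense) * ksparse +
      m$p_dense * (m$dense_min + m$dense_extra_mean)
    m$cluster_density_per_um <- .EV_PER_UM3_PER_GY /
      (m$fluence_per_um2_per_Gy * kbar * m$mean_deposit_eV)
  }
  class(m) <- "track_model"
  m
}

#' @export
print.track_model <- function(x, ...) {
  cat(sprintf("track_model '%s': fluence %g /um^2/Gy, mean deposit %g eV,\n",
              x$preset, x$fluence_per_um2_per_Gy, x$mean_deposit_eV))
  cat(sprintf("  OH/direct %g, OH displacement RMS %.3f nm, clusters %.2f /um\n",
              x$oh_per_direct_ratio, oh_displacement_rms(x) * 1e3,
              x$cluster_density_per_um))
  invisible(x)
}

#' Root-mean-square hydroxyl-radical displacement
#'
#' \eqn{\sqrt{6 D t}} for diffusion coefficient D and scavenging time t.
#'
#' @param model a \code{track_model}.
#' @return RMS displacement in micrometres (6.48e-3 at the defaults).
#' @export
oh_displacement_rms <- function(model) {
  sqrt(6 * model$oh_diffusion_m2_s * model$oh_time_s) * 1e6
}

#' Sample hydroxyl-radical displacement magnitudes
#'
#' @param n number of draws.
#' @param model a \code{track_model}.
#' @param seed integer seed.
#' @return numeric vector of displacement magnitudes, micrometres.
#' @export
sample_oh_displacements <- function(n, model = track_model(), seed = 1) {
  .cpp_rnorm3_norm(as.integer(n), model$oh_sigma_um, as.double(seed))
}

#' Generate surrogate track events for a voxelized tumor
#'
#' For each requested cell, a Poisson number of track chords (isotropic
#' uniform random chords of the nucleus bounding sphere, rate proportional to
#' dose and cross-section) is generated; interaction clusters are placed along
#' the chords and retained where they fall in a nucleus voxel of the owning
#' cell; direct and hydroxyl-radical events are emitted around each cluster
#' and dropped if they leave the nucleus voxels.
#'
#' @param grid a \code{voxel_grid}.
#' @param dose prescribed dose, Gy (>= 0).
#' @param model a \code{track_model}.
#' @param seed integer seed; each cell uses child stream
#'   \code{child_seed(seed, cell_id, 0)}.
#' @param cells integer vector of cell ids to irradiate (default: all).
#' @param voxel_energy if TRUE, attach the per-voxel deposited energy array.
#' @return a data frame of class \code{event_table} with columns
#'   \code{cell_id, track_id, kind ("D"/"I"), x_um, y_um, z_um, energy_eV}
#'   (energy is NA for indirect events). Attributes: \code{nucleus_dose_Gy}
#'   (named per cell), \code{n_tracks}, and optionally \code{voxel_energy_eV}.
#' @export
generate_events <- function(grid, dose, model = track_model(), seed = 1,
                            cells = NULL, voxel_energy = FALSE) {
  if (dose < 0) stop("dose must be >= 0", call. = FALSE)
  nv <- nucleus_voxel_volumes(grid)
  if (nrow(grid$cells) == 0 || sum(nv) == 0)
    stop("grid has no nucleus voxels", call. = FALSE)
  if (is.null(cells)) cells <- grid$cells$id
  mats <- .cells_mats(grid$cells)
  res <- .cpp_generate_events(grid$type, grid$cell, grid$dims[1],
                              grid$box_side, grid$voxel_size, mats$centers,
                              mats$axes, mats$rot, mats$ns,
                              as.integer(cells), nv[as.character(cells)],
                              dose, unclass(model), as.double(seed),
                              isTRUE(voxel_energy))
  out <- data.frame(cell_id = res$cell_id, track_id = res$track_id,
                    kind = ifelse(res$kind == 0L, "D", "I"),
                    x_um = res$x_um, y_um = res$y_um, z_um = res$z_um,
                    energy_eV = res$energy_eV)
  class(out) <- c("event_table", "data.frame")
  attr(out, "nucleus_dose_Gy") <- setNames(res$nucleus_dose_Gy,
                                           as.character(cells))
  attr(out, "n_tracks") <- setNames(res$n_tracks, as.character(cells))
  if (isTRUE(voxel_energy))
    attr(out, "voxel_energy_eV") <- array(res$voxel_energy_eV, dim = grid$dims)
  out
}

#' Dose to nuclei from an event table
#'
#' Total retained direct energy per nucleus divided by the nucleus mass
#' (density 1 g/cm3).
#'
#' @param events an \code{event_table}.
#' @param nucleus_volumes_um3 named numeric vector of nucleus volumes (um^3),
#'   names = cell ids; e.g. \code{nucleus_voxel_volumes(grid)} or
#'   \code{nucleus_volumes(cells)}.
#' @return named numeric vector of doses in Gy (0 for cells without events).
#' @examples
#' ev <- data.frame(cell_id = 1, track_id = 0, kind = "D", x_um = 0,
#'                  y_um = 0, z_um = 0, energy_eV = 0.874e6)
#' nucleus_dose(ev, c("1" = 140)) # ~1.0003 Gy
#' @export
nucleus_dose <- function(events, nucleus_volumes_um3) {
  stopifnot(!is.null(names(nucleus_volumes_um3)))
  dir <- events[events$kind == "D", , drop = FALSE]
  e <- tapply(dir$energy_eV, as.character(dir$cell_id), sum)
  out <- setNames(numeric(length(nucleus_volumes_um3)),
                  names(nucleus_volumes_um3))
  if (length(e)) out[names(e)] <- unname(e)
  out * .EV_TO_J / (nucleus_volumes_um3 * 1e-15)
}

#' Write / read the event TSV interchange format
#'
#' Header \code{cell_id track_id kind x_um y_um z_um energy_eV}, tab-separated,
#' '.' decimal; kind D (direct) or I (indirect); energy empty for I.
#'
#' @param events an \code{event_table}.
#' @param path file path.
#' @export
write_events_tsv <- function(events, path) {
  df <- as.data.frame(events)
  df$energy_eV <- ifelse(df$kind == "I", "",
                         formatC(df$energy_eV, digits = 10, format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_events_tsv
#' @param grid optional \code{voxel_grid}; if given, cell ids are validated
#'   against it.
#' @return \code{import_events}: an \code{event_table}.
#' @export
import_events <- function(path, grid = NULL) {
  cols <- c("cell_id", "track_id", "kind", "x_um", "y_um", "z_um", "energy_eV")
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = c("integer", "integer", "character",
                                         "numeric", "numeric", "numeric",
                                         "character"),
                          stringsAsFactors = FALSE)
  if (!identical(names(df), cols))
    stop("event TSV parse error: expected header ",
         paste(cols, collapse = "\t"), call. = FALSE)
  ln <- seq_len(nrow(df)) + 1L # line numbers incl. header
  bad <- which(!df$kind %in% c("D", "I"))
  if (length(bad))
    stop("event TSV parse error at line ", bad[1] + 1L,
         ": kind must be D or I", call. = FALSE)
  en <- suppressWarnings(as.numeric(df$energy_eV))
  badE <- which(df$kind == "D" & (is.na(en) | en < .E_MIN_EV))
  if (length(badE))
    stop(sprintf("event TSV parse error at line %d: direct event energy must be >= %.2f eV",
                 ln[badE[1]], .E_MIN_EV), call. = FALSE)
  if (!is.null(grid)) {
    badC <- which(!df$cell_id %in% grid$cells$id)
    if (length(badC))
      stop("event TSV parse error at line ", ln[badC[1]],
           ": unknown cell id ", df$cell_id[badC[1]], call. = FALSE)
  }
  out <- data.frame(cell_id = df$cell_id, track_id = df$track_id,
                    kind = df$kind, x_um = df$x_um, y_um = df$y_um,
                    z_um = df$z_um,
                    energy_eV = ifelse(df$kind == "I", NA_real_, en))
  class(out) <- c("event_table", "data.frame")
  out
}
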