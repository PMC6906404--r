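#' Ellipsoid volume from full axis lengths
#'
#' @param d1,d2,d3 full axis lengths (diameters), micrometres.
#' @return volume in cubic micrometres, \eqn{(\pi/6) d_1 d_2 d_3}.
#' @examples
#' ellipsoid_volume(14, 14, 14) # smallest cell, ~1437 um^3
#' ellipsoid_volume(20, 14, 14) # largest cell, ~2053 um^3
#' @export
ellipsoid_volume <- function(d1, d2, d3) {
  pi / 6 * d1 * d2 * d3
}

#' Cell number density
#'
#' @param n number of cells.
#' @param box_side cube side length in micrometres.
#' @return density in cells per cubic centimetre.
#' @examples
#' cell_density(1224, 200) # 1.53e8 cells/cm^3
#' @export
cell_density <- function(n, box_side) {
  n / (box_side * 1e-4)^3
}

# default linear scale of the concentric nucleus: volume fraction 0.08
.NUCLEUS_FRACTION <- 0.08

#' Place random non-overlapping ellipsoidal cells in a cube
#'
#' Random sequential addition: cell centers are sampled uniformly (subject to
#' the whole ellipsoid lying inside the box), orientations uniformly over
#' proper rotations, and the major axis uniformly over \code{axis_ranges$major};
#' the two minor axes are fixed at \code{axis_ranges$minor}. A candidate is
#' accepted if it overlaps no previously accepted cell. The overlap test is a
#' bounding-sphere prescreen (and an inscribed-sphere quick reject) followed by
#' mutual surface-point sampling (\code{n_surface} quasi-uniform points per
#' cell) against the exact ellipsoid interior test, so overlaps smaller than
#' the surface sampling resolution can in principle be missed.
#'
#' Each cell carries a concentric, similar nucleus occupying
#' \code{nucleus_fraction} of the cell volume (linear scale
#' \code{nucleus_fraction^(1/3)}).
#'
#' @param box_side cube side, micrometres.
#' @param target_count number of cells to place.
#' @param axis_ranges list with \code{major = c(min, max)} and scalar
#'   \code{minor}, full axis lengths in micrometres.
#' @param nucleus_fraction nucleus/cell volume ratio.
#' @param seed integer seed.
#' @param n_surface surface sample points per cell used in the overlap test.
#' @param max_attempts attempt budget before a packing failure is raised.
#' @return a data frame of class \code{radcell_cells}: one row per cell with
#'   id, center (\code{x, y, z}), full axes (\code{d1, d2, d3}), rotation
#'   matrix entries (\code{r11..r33}, row-major; rows index world axes),
#'   \code{nucleus_scale}, \code{status} and \code{po2} (NA until assigned).
#' @examples
#' cells <- place_cells(40, 3, seed = 1)
#' nrow(cells)
#' @export
place_cells <- function(box_side, target_count,
                        axis_ranges = list(major = c(14, 20), minor = 14),
                        nucleus_fraction = .NUCLEUS_FRACTION, seed = 1,
                        n_surface = 256, max_attempts = 5e6) {
  stopifnot(box_side > 0, target_count >= 0)
  if (target_count == 0) return(.cells_df(NULL, nucleus_fraction))
  res <- .cpp_place_cells(box_side, as.integer(target_count),
                          axis_ranges$major[1], axis_ranges$major[2],
                          axis_ranges$minor, as.integer(n_surface),
                          as.double(max_attempts), as.double(seed))
  if (res$placed < target_count) {
    stop(sprintf(paste0("packing failure: placed %d of %d cells within %g ",
                        "attempts (box %g um)"),
                 res$placed, target_count, res$attempts, box_side),
         call. = FALSE)
  }
  .cells_df(res, nucleus_fraction)
}

.cells_df <- function(res, nucleus_fraction) {
  ns <- nucleus_fraction^(1 / 3)
  if (is.null(res) || res$placed == 0) {
    out <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), d1 = numeric(0), d2 = numeric(0),
                      d3 = numeric(0))
    for (k in paste0("r", c(11, 12, 13, 21, 22, 23, 31, 32, 33)))
      out[[k]] <- numeric(0)
    out$nucleus_scale <- numeric(0)
    out$status <- character(0)
    out$po2 <- numeric(0)
    class(out) <- c("radcell_cells", "data.frame")
    return(out)
  }
  n <- res$placed
  out <- data.frame(id = seq_len(n), x = res$centers[, 1], y = res$centers[, 2],
                    z = res$centers[, 3], d1 = 2 * res$axes[, 1],
                    d2 = 2 * res$axes[, 2], d3 = 2 * res$axes[, 3])
  rn <- paste0("r", c(11, 12, 13, 21, 22, 23, 31, 32, 33))
  for (k in seq_len(9)) out[[rn[k]]] <- res$rot[, k]
  out$nucleus_scale <- rep(ns, n)
  out$status <- rep("viable", n)
  out$po2 <- rep(NA_real_, n)
  class(out) <- c("radcell_cells", "data.frame")
  out
}

# internal: split a cells data frame into matrices for the C++ kernels
.cells_mats <- function(cells) {
  rn <- paste0("r", c(11, 12, 13, 21, 22, 23, 31, 32, 33))
  list(centers = as.matrix(cells[, c("x", "y", "z")]),
       axes = as.matrix(cells[, c("d1", "d2", "d3")]) / 2,
       rot = as.matrix(cells[, rn]),
       ns = cells$nucleus_scale)
}

#' Voxelize a cell population onto a cubic lattice
#'
#' Each voxel is classified by testing its center against each cell's nucleus
#' ellipsoid, then the cell ellipsoid, in the cell's rotated frame. The
#' index-to-coordinate map is \code{X = -(box_side/2 - voxel_size/2) +
#' voxel_size * i} per axis with 0-based indices (for the default 0.2 mm box
#' and 2 um voxels, X = -99 + 2 i um).
#'
#' @param cells a \code{radcell_cells} data frame (pairwise non-overlapping).
#' @param box_side cube side, micrometres; must be a multiple of
#'   \code{voxel_size}.
#' @param voxel_size voxel edge, micrometres (default 2).
#' @return an object of class \code{voxel_grid}: list with integer arrays
#'   \code{type} (0 intercellular, 1 nucleus, 2 cytoplasm) and \code{cell}
#'   (0 or the owning cell id), plus \code{dims}, \code{box_side},
#'   \code{voxel_size} and the cell table.
#' @examples
#' g <- voxelize(place_cells(40, 2, seed = 1), 40)
#' table(g$type)
#' @export
voxelize <- function(cells, box_side, voxel_size = 2) {
  m <- box_side / voxel_size
  if (abs(m - round(m)) > 1e-9)
    stop("voxel_size must divide box_side", call. = FALSE)
  m <- as.integer(round(m))
  if (nrow(cells) > 0) {
    mats <- .cells_mats(cells)
    res <- .cpp_voxelize(mats$centers, mats$axes, mats$rot, mats$ns,
                         box_side, voxel_size)
    type <- array(res$type, dim = c(m, m, m))
    cellid <- array(res$cell, dim = c(m, m, m))
  } else {
    type <- array(0L, dim = c(m, m, m))
    cellid <- array(0L, dim = c(m, m, m))
  }
  structure(list(type = type, cell = cellid, dims = c(m, m, m),
                 box_side = box_side, voxel_size = voxel_size, cells = cells),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d voxels of %g um (box %g um), %d cells\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_size, x$box_side,
              nrow(x$cells)))
  tt <- tabulate(x$type + 1L, nbins = 3L)
  cat(sprintf("  intercellular %d, nucleus %d, cytoplasm %d\n",
              tt[1], tt[2], tt[3]))
  invisible(x)
}

#' Voxel center coordinates from 0-based indices
#'
#' @param grid a \code{voxel_grid}.
#' @param idx integer matrix (n x 3) of 0-based voxel indices.
#' @return n x 3 matrix of center coordinates in micrometres.
#' @examples
#' g <- voxelize(place_cells(0, 0), 200)
#' voxel_centers(g, rbind(c(0, 0, 0), c(50, 50, 50)))
#' @export
voxel_centers <- function(grid, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  x0 <- -(grid$box_side / 2 - grid$voxel_size / 2)
  x0 + grid$voxel_size * idx
}

#' Nucleus volumes on the voxel lattice
#'
#' Voxel-counted nucleus volume per cell (used as the nucleus mass reference
#' for dose scoring, density 1 g/cm3).
#'
#' @param grid a \code{voxel_grid}.
#' @return named numeric vector, cubic micrometres, one entry per cell id.
#' @export
nucleus_voxel_volumes <- function(grid) {
  nuc <- grid$cell[grid$type == 1L]
  n <- nrow(grid$cells)
  cnt <- tabulate(nuc, nbins = n)
  setNames(cnt * grid$voxel_size^3, as.character(seq_len(n)))
}

#' Analytic nucleus volumes
#'
#' @param cells a \code{radcell_cells} data frame.
#' @return named numeric vector of nucleus volumes, cubic micrometres.
#' @export
nucleus_volumes <- function(cells) {
  v <- ellipsoid_volume(cells$d1, cells$d2, cells$d3) * cells$nucleus_scale^3
  setNames(v, as.character(cells$id))
}

#' Persist / load a voxel grid
#'
#' The two integer arrays are written as gzip-compressed raw binary
#' (little-endian 32-bit) next to a JSON sidecar holding dims, voxel size, box
#' side and the full cell table.
#'
#' @param grid a \code{voxel_grid}.
#' @param prefix file path prefix; writes \code{<prefix>_type.bin.gz},
#'   \code{<prefix>_cell.bin.gz} and \code{<prefix>.json}.
#' @return \code{prefix}, invisibly.
#' @export
write_grid <- function(grid, prefix) {
  for (nm in c("type", "cell")) {
    con <- gzfile(paste0(prefix, "_", nm, ".bin.gz"), "wb")
    writeBin(as.integer(grid[[nm]]), con, size = 4L, endian = "little")
    close(con)
  }
  meta <- list(dims = grid$dims, box_side = grid$box_side,
               voxel_size = grid$voxel_size,
               cells = grid$cells[, setdiff(names(grid$cells), NULL)])
  jsonlite::write_json(meta, paste0(prefix, ".json"), digits = NA,
                       auto_unbox = TRUE, na = "null")
  invisible(prefix)
}

#' @rdname write_grid
#' @export
read_grid <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  m <- as.integer(meta$dims)
  arrs <- lapply(c("type", "cell"), function(nm) {
    con <- gzfile(paste0(prefix, "_", nm, ".bin.gz"), "rb")
    on.exit(close(con))
    array(readBin(con, "integer", n = prod(m), size = 4L, endian = "little"),
          dim = m)
  })
  cells <- as.data.frame(meta$cells)
  if (nrow(cells)) class(cells) <- c("radcell_cells", "data.frame")
  structure(list(type = arrs[[1]], cell = arrs[[2]], dims = m,
                 box_side = meta$box_side, voxel_size = meta$voxel_size,
                 cells = cells),
            class = "voxel_grid")
}

#' Export the cell table as CSV
#'
#' @param cells a \code{radcell_cells} data frame.
#' @param path output file.
#' @export
write_cells_csv <- function(cells, path) {
  write.csv(as.data.frame(cells), path, row.names = FALSE)
  invisible(path)
}
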