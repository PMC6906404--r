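#' Oxygenation / vascular model parameters
#'
#' Chronic-hypoxia model for millimetre-scale tumors: a connected vessel
#' network is grown to a target relative vascular volume (RVV); each cell is
#' assigned a pO2 from its distance d to the nearest vessel voxel,
#' \eqn{pO_2(d) = \max(po2\_floor,\; p_0 e^{-d/L})}, cells farther than the
#' necrosis distance become necrotic, and cells overlapping the network become
#' vessel units. The decay length L is calibrated against printed summary
#' statistics of the pO2 distribution (\code{\link{calibrate_oxygenation}});
#' the vessel morphology parameters (tube radius, turning noise, branching
#' rate) set how clustered the network is and were fixed once so the default
#' calibration reproduces a strongly hypoxic head-and-neck-like tumor.
#'
#' @param rvv target relative vascular volume (voxel fraction), default 0.021.
#' @param p0 blood oxygen tension at the vessel wall, mmHg, default 30.
#' @param nd necrosis distance, micrometres, default 130.
#' @param decay_length pO2 decay length L, micrometres (calibrated default).
#' @param po2_floor lower bound on viable-cell pO2, mmHg.
#' @param vessel_radius_um vessel tube radius, micrometres.
#' @param sigma_turn per-step direction noise of the growth walk.
#' @param branch_p per-step branching probability.
#' @param consume_radius_um cells closer than this to a vessel voxel become
#'   vessel units (default: the minor cell semi-axis, 7 um).
#' @return an object of class \code{oxygenation_params}.
#' @export
oxygenation_params <- function(rvv = 0.021, p0 = 30, nd = 130,
                               decay_length = 28, po2_floor = 0,
                               vessel_radius_um = 6, sigma_turn = 0.10,
                               branch_p = 0.005, consume_radius_um = 7) {
  stopifnot(rvv > 0, rvv < 1, p0 > 0, nd > 0, decay_length > 0,
            po2_floor >= 0, vessel_radius_um > 0)
  structure(list(rvv = rvv, p0 = p0, nd = nd, decay_length = decay_length,
                 po2_floor = po2_floor, vessel_radius_um = vessel_radius_um,
                 sigma_turn = sigma_turn, branch_p = branch_p,
                 consume_radius_um = consume_radius_um),
            class = "oxygenation_params")
}

#' Replicate a tumor block into a larger cube
#'
#' Tiles \code{n_side^3} copies of a voxelized block. The voxel arrays are not
#' materialized at the assembled scale; the assembly records the block, the
#' copy layout and a re-indexed cell table with global centers and unique ids
#' (\code{id = (copy - 1) * n_block + block_id}).
#'
#' @param grid a \code{voxel_grid} block.
#' @param n_side copies per axis (default 5: 125 copies; 0.2 mm block ->
#'   1 mm assembled side).
#' @return an object of class \code{tumor_assembly}.
#' @examples
#' g <- voxelize(place_cells(40, 2, seed = 1), 40)
#' a <- replicate_tumor(g, 2)
#' nrow(a$cells) # 16
#' @export
replicate_tumor <- function(grid, n_side = 5) {
  stopifnot(n_side >= 1, n_side == round(n_side))
  side <- grid$box_side * n_side
  nb <- nrow(grid$cells)
  copies <- expand.grid(cx = seq_len(n_side), cy = seq_len(n_side),
                        cz = seq_len(n_side))
  off <- (as.matrix(copies) - (n_side + 1) / 2) * grid$box_side
  cells <- do.call(rbind, lapply(seq_len(nrow(copies)), function(k) {
    cc <- as.data.frame(grid$cells)
    cc$copy <- k
    cc$block_id <- cc$id
    cc$id <- (k - 1L) * nb + cc$id
    cc$x <- cc$x + off[k, 1]
    cc$y <- cc$y + off[k, 2]
    cc$z <- cc$z + off[k, 3]
    cc
  }))
  rownames(cells) <- NULL
  structure(list(block = grid, n_side = n_side, side_um = side,
                 dims = as.integer(grid$dims[1] * n_side),
                 voxel_size = grid$voxel_size, cells = cells),
            class = "tumor_assembly")
}

#' @export
print.tumor_assembly <- function(x, ...) {
  cat(sprintf("tumor_assembly: %d^3 copies, side %g um, %d cells, %d^3 voxels\n",
              x$n_side, x$side_um, nrow(x$cells), x$dims))
  invisible(x)
}

#' Grow a connected vessel network through an assembled tumor
#'
#' A branching random-walk tree of tubes (radius
#' \code{params$vessel_radius_um}) enters at one face and grows, with
#' direction persistence and random branching, until the painted voxel
#' fraction reaches the target RVV. All branches grow from one tree, so the
#' network has a single connected component by construction (verified and
#' recorded).
#'
#' @param assembly a \code{tumor_assembly} (or a \code{voxel_grid}).
#' @param params an \code{oxygenation_params}.
#' @param seed integer seed.
#' @return an object of class \code{vessel_network}: 0-based linear voxel
#'   indices of vessel voxels, lattice dims, voxel size, achieved RVV and
#'   component count.
#' @export
grow_vessels <- function(assembly, params = oxygenation_params(), seed = 1) {
  if (params$rvv <= 0) stop("rvv must be > 0", call. = FALSE)
  n <- if (inherits(assembly, "tumor_assembly")) assembly$dims
       else assembly$dims[1]
  vs <- assembly$voxel_size
  res <- .cpp_grow_vessels(as.integer(n), params$rvv,
                           params$vessel_radius_um / vs, params$sigma_turn,
                           params$branch_p, 5e7, as.double(seed))
  if (res$achieved < params$rvv * 0.95)
    stop(sprintf("vessel growth failed: achieved RVV %.4f < target %.4f within step budget",
                 res$achieved, params$rvv), call. = FALSE)
  vessel_network(res$idx, n, vs, achieved_rvv = res$achieved,
                 n_components = res$n_components)
}

#' Construct a vessel network from voxel indices
#'
#' Mainly for tests and imported networks.
#'
#' @param idx0 0-based linear voxel indices (x fastest).
#' @param dims voxels per side of the cubic lattice.
#' @param voxel_size voxel edge, micrometres.
#' @param achieved_rvv,n_components optional metadata.
#' @return a \code{vessel_network}.
#' @export
vessel_network <- function(idx0, dims, voxel_size,
                           achieved_rvv = length(idx0) / dims^3,
                           n_components = NA_integer_) {
  structure(list(idx0 = as.integer(idx0), dims = as.integer(dims),
                 voxel_size = voxel_size, achieved_rvv = achieved_rvv,
                 n_components = n_components),
            class = "vessel_network")
}

#' @export
print.vessel_network <- function(x, ...) {
  cat(sprintf("vessel_network: %d voxels (RVV %.4f) on %d^3, %s component(s)\n",
              length(x$idx0), x$achieved_rvv, x$dims,
              ifelse(is.na(x$n_components), "?", x$n_components)))
  invisible(x)
}

# 0-based voxel index of positions on the assembled lattice (centered cube)
.position_voxel <- function(xyz, side_um, voxel_size, dims) {
  ijk <- floor((xyz + side_um / 2) / voxel_size)
  ijk <- pmin(pmax(ijk, 0), dims - 1)
  as.integer(ijk[, 1] + dims * (ijk[, 2] + dims * ijk[, 3]))
}

#' Distance from cell centers to the nearest vessel voxel
#'
#' Exact Euclidean distance transform on the voxel lattice, evaluated at the
#' voxel containing each cell center (center-to-voxel-center distances).
#'
#' @param assembly a \code{tumor_assembly}.
#' @param network a \code{vessel_network} on the same lattice.
#' @return numeric vector of distances in micrometres, one per cell.
#' @export
vessel_distances <- function(assembly, network) {
  xyz <- as.matrix(assembly$cells[, c("x", "y", "z")])
  q <- .position_voxel(xyz, assembly$side_um, assembly$voxel_size,
                       assembly$dims)
  .cpp_vessel_distances(assembly$dims, network$idx0, q) * assembly$voxel_size
}

#' Assign per-cell oxygen tension and viability status
#'
#' Cells within \code{consume_radius_um} of a vessel voxel become vessel
#' units; cells farther than the necrosis distance become necrotic (no pO2);
#' remaining cells are viable with
#' \eqn{pO_2 = \max(po2\_floor, p_0 e^{-d/L})}.
#'
#' @param assembly a \code{tumor_assembly}.
#' @param network a \code{vessel_network}.
#' @param params an \code{oxygenation_params}.
#' @param distances optional precomputed \code{\link{vessel_distances}}.
#' @return the assembly cell table with \code{dist_um}, \code{status}
#'   (\code{"viable"}, \code{"necrotic"}, \code{"vessel"}) and \code{po2}
#'   (NA unless viable).
#' @export
assign_po2 <- function(assembly, network, params = oxygenation_params(),
                       distances = NULL) {
  if (length(network$idx0) == 0)
    stop("vessel network is empty", call. = FALSE)
  cells <- assembly$cells
  d <- if (is.null(distances)) vessel_distances(assembly, network)
       else distances
  status <- ifelse(d < params$consume_radius_um, "vessel",
                   ifelse(d > params$nd, "necrotic", "viable"))
  po2 <- ifelse(status == "viable",
                pmax(params$po2_floor, params$p0 * exp(-d / params$decay_length)),
                NA_real_)
  cells$dist_um <- d
  cells$status <- status
  cells$po2 <- po2
  cells
}

#' Hypoxic fraction of viable cells
#'
#' @param cells a cell table with \code{status} and \code{po2} assigned.
#' @param threshold pO2 threshold, mmHg.
#' @return fraction of viable cells with pO2 below the threshold.
#' @export
hypoxic_fraction <- function(cells, threshold) {
  v <- cells$status == "viable"
  if (!any(v)) stop("no viable cells", call. = FALSE)
  mean(cells$po2[v] < threshold)
}

#' Calibrate the pO2 decay length against printed oxygenation statistics
#'
#' Grows the vessel network (unless given), computes cell-to-vessel distances
#' once, and searches the decay length L so that the mean viable-cell pO2
#' matches \code{targets$mean_po2} (the mean is strictly increasing in L, so
#' the root is unique); the achieved hypoxic fraction HP10 is reported
#' alongside.
#'
#' @param assembly a \code{tumor_assembly}.
#' @param params an \code{oxygenation_params}.
#' @param targets list with \code{mean_po2} (mmHg) and \code{hp10} (fraction).
#' @param seed integer seed (used if the network must be grown).
#' @param network optional pre-grown \code{vessel_network}.
#' @param interval search interval for L, micrometres.
#' @return list with \code{decay_length}, the oxygenated cell table at the
#'   calibrated L, the \code{network}, and a \code{report} data frame.
#' @export
calibrate_oxygenation <- function(assembly, params = oxygenation_params(),
                                  targets = list(mean_po2 = 9.4, hp10 = 0.58),
                                  seed = 1, network = NULL,
                                  interval = c(2, 500)) {
  if (targets$mean_po2 >= params$p0)
    stop("calibration failure: target mean pO2 >= p0 is unreachable",
         call. = FALSE)
  if (is.null(network)) network <- grow_vessels(assembly, params, seed)
  d <- vessel_distances(assembly, network)
  objective <- function(L) {
    p <- params
    p$decay_length <- L
    cells <- assign_po2(assembly, network, p, distances = d)
    mean(cells$po2[cells$status == "viable"]) - targets$mean_po2
  }
  lo <- objective(interval[1])
  hi <- objective(interval[2])
  if (lo * hi > 0)
    stop("calibration failure: target mean pO2 not bracketed by the search interval",
         call. = FALSE)
  L <- uniroot(objective, interval, tol = 1e-3)$root
  params$decay_length <- L
  cells <- assign_po2(assembly, network, params, distances = d)
  mean_po2 <- mean(cells$po2[cells$status == "viable"])
  hp10 <- hypoxic_fraction(cells, 10)
  report <- data.frame(target = c("mean_po2", "hp10"),
                       desired = c(targets$mean_po2, targets$hp10),
                       achieved = c(mean_po2, hp10))
  list(decay_length = L, cells = cells, network = network, report = report)
}
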