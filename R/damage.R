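#' DNA damage-induction parameters
#'
#' Parameters of the event-to-lesion conversion: spatial clustering of events
#' into cylindrical 10 base-pair DNA segments (B-DNA cylinder 3.4 nm long,
#' 2.3 nm diameter; the clustering capture radius is the cylinder
#' half-diagonal), assignment of each event to a base-pair/strand site as a
#' sugar or base radical, oxygen-dependent conversion of sugar radicals to
#' strand breaks, DSB calling (two or more strand breaks within 10 bp, by
#' default on opposite strands) with merging of DSBs separated by fewer than
#' 10 undamaged base pairs (multiplicity), complexity classification
#' (elementary damages > 15), and binomial thinning by the DNA volume
#' fraction.
#'
#' The strand-break probability follows a hyperbolic saturation curve in pO2:
#' \deqn{P(pO_2) = p_{anox} + (p_{oxic} - p_{anox}) \frac{pO_2}{pO_2 + k_{1/2}}}
#' with half-effect constant \code{k_half_mmHg}. \code{p_break_oxic},
#' \code{p_break_anoxic} and the cluster-size setting of the track model are
#' calibration targets (see \code{\link{calibrate_damage}}); the shipped
#' defaults are calibrated for the \code{"paper-6MV"} preset.
#'
#' @param ... named overrides.
#' @return an object of class \code{damage_params}.
#' @export
damage_params <- function(...) {
  cyl_l <- 3.4e-3 # um
  cyl_d <- 2.3e-3
  cap <- sqrt((cyl_l / 2)^2 + (cyl_d / 2)^2)
  p <- list(
    energy_threshold_eV = .E_MIN_EV,
    segment_length_bp = 10L,
    cylinder_length_um = cyl_l,
    cylinder_diameter_um = cyl_d,
    capture_radius_um = cap,
    chain_radius_um = 2 * cap,
    merge_gap_bp = 10L,
    cdsb_elementary_threshold = 15L,
    dna_volume_fraction = 0.200,
    sugar_hit_fraction_direct = 0.5,
    sugar_hit_fraction_oh = 0.2,
    p_break_oxic = 0.47,
    p_break_anoxic = 0.2135,
    k_half_mmHg = 3,
    opposite_strand_rule = TRUE
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown damage parameters: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  p[names(ov)] <- ov
  stopifnot(p$p_break_anoxic >= 0, p$p_break_oxic <= 1,
            p$p_break_anoxic <= p$p_break_oxic,
            p$capture_radius_um > 0, p$merge_gap_bp > 0,
            p$dna_volume_fraction >= 0, p$dna_volume_fraction <= 1)
  class(p) <- "damage_params"
  p
}

#' Strand-break conversion probability at a given oxygen tension
#'
#' @param po2 oxygen partial pressure, mmHg (>= 0); vectorized.
#' @param params a \code{damage_params}.
#' @return conversion probability per sugar radical.
#' @examples
#' p <- damage_params()
#' p_break(0, p)   # p_break_anoxic
#' p_break(760, p) # ~p_break_oxic
#' @export
p_break <- function(po2, params = damage_params()) {
  if (any(po2 < 0)) stop("po2 must be >= 0", call. = FALSE)
  params$p_break_anoxic + (params$p_break_oxic - params$p_break_anoxic) *
    po2 / (po2 + params$k_half_mmHg)
}

#' DNA volume fraction for a target DSB yield
#'
#' The damage algorithm's whole-nucleus (unthinned) DSB yield is a property of
#' the calibrated preset; thinning by the DNA volume fraction scales the yield
#' linearly, so the fraction for a target yield is \code{target / raw_yield}.
#' With the shipped calibration the paper-style targets 20.1, 30.1 and
#' 40.2 DSB/Gy/cell map to fractions near 0.133, 0.200 and 0.267.
#'
#' @param target_yield desired DSB yield per Gy per cell under full oxia.
#' @param raw_yield whole-nucleus DSB yield per Gy per cell of the calibrated
#'   preset before thinning.
#' @return DNA volume fraction in [0, 1].
#' @export
dna_volume_for_yield <- function(target_yield, raw_yield = .RAW_DSB_YIELD) {
  f <- target_yield / raw_yield
  if (f < 0 || f > 1)
    stop("target yield implies a DNA volume fraction outside [0, 1]",
         call. = FALSE)
  f
}

# whole-nucleus DSB yield (per Gy per cell, full oxia, before DNA-volume
# thinning) measured for the shipped calibrated preset; see the methods
# vignette and calibrate_damage()
.RAW_DSB_YIELD <- 159.0

#' Cluster nucleus events into 10 base-pair DNA segments
#'
#' Greedy single-linkage clustering of the (direct and indirect) events of one
#' nucleus: an event joins the nearest existing segment whose centroid is
#' within the capture radius, otherwise it seeds a new segment. A new segment
#' within the chain radius of an existing one is assigned the next genomic
#' offset of that segment's chain (consecutive 10-bp windows); otherwise it
#' starts a new chain, genomically unrelated to all others. Each event is
#' assigned a base-pair index (uniform 1-10), a strand (uniform 1|2) and a
#' moiety (sugar with the kind-specific probability, else base); duplicate
#' (bp, strand) sites collapse.
#'
#' @param events an \code{event_table} restricted to one cell.
#' @param params a \code{damage_params}.
#' @param seed integer seed.
#' @return list with \code{sites} (one row per radical site: segment, chain,
#'   chain_pos, segment centroid, bp, strand, moiety, n_events),
#'   \code{segments} (per segment: centroid, chain, chain_pos, n_events,
#'   contributing track ids) and \code{event_segment} (segment of each event,
#'   1-based). Site rows are emitted in segment-creation / site order: this is
#'   the stream order consumed by \code{\link{radicals_to_lesions}}.
#' @export
cluster_events <- function(events, params = damage_params(), seed = 1) {
  if (nrow(events) == 0) {
    return(list(sites = .empty_sites(), segments = .empty_segments(),
                event_segment = integer(0)))
  }
  if (length(unique(events$cell_id)) != 1L)
    stop("cluster_events operates on the events of a single nucleus",
         call. = FALSE)
  res <- .cpp_cluster_events(events$x_um, events$y_um, events$z_um,
                             ifelse(events$kind == "D", 0L, 1L),
                             as.integer(events$track_id),
                             unclass(params), as.double(seed))
  sites <- data.frame(segment = res$segment, chain = res$chain,
                      chain_pos = res$chain_pos, seg_x = res$seg_x,
                      seg_y = res$seg_y, seg_z = res$seg_z, bp = res$bp,
                      strand = res$strand,
                      moiety = c("sugar", "base")[res$moiety],
                      n_events = res$n_events)
  segs <- data.frame(segment = seq_along(res$segment_tracks),
                     n_events = res$segment_n_events,
                     track_ids = res$segment_tracks)
  attr(sites, "cell_id") <- events$cell_id[1]
  list(sites = sites, segments = segs,
       event_segment = res$event_segment + 1L)
}

.empty_sites <- function() {
  data.frame(segment = integer(0), chain = integer(0), chain_pos = integer(0),
             seg_x = numeric(0), seg_y = numeric(0), seg_z = numeric(0),
             bp = integer(0), strand = integer(0), moiety = character(0),
             n_events = integer(0))
}

.empty_segments <- function() {
  data.frame(segment = integer(0), n_events = integer(0),
             track_ids = character(0))
}

#' Convert radical sites to lesions at a given oxygen tension
#'
#' Sugar radicals become strand breaks with probability
#' \code{\link{p_break}(po2)} and modified sugars otherwise; base radicals
#' always become modified bases. One uniform deviate is consumed per sugar
#' site in row order, so the operation reproduces the fused simulation kernel
#' when given the matching child seed.
#'
#' @param sites the \code{sites} table from \code{\link{cluster_events}}.
#' @param po2 oxygen partial pressure, mmHg (scalar, >= 0).
#' @param params a \code{damage_params}.
#' @param seed integer seed.
#' @return \code{sites} with a \code{lesion} column
#'   (\code{"strand_break"}, \code{"modified_sugar"}, \code{"modified_base"}).
#' @export
radicals_to_lesions <- function(sites, po2, params = damage_params(),
                                seed = 1) {
  if (length(po2) != 1L || po2 < 0)
    stop("po2 must be a scalar >= 0", call. = FALSE)
  moi <- ifelse(sites$moiety == "sugar", 1L, 2L)
  les <- .cpp_lesions(moi, p_break(po2, params), as.double(seed))
  sites$lesion <- c("strand_break", "modified_sugar", "modified_base")[les]
  sites
}

#' Call double-strand breaks from lesion-resolved segments
#'
#' Within a segment, two or more strand breaks (with at least one on each
#' strand under the default opposite-strand rule) form a DSB candidate.
#' Candidates on the same chain whose breaks are separated by fewer than
#' \code{merge_gap_bp} undamaged base pairs merge into one DSB whose
#' multiplicity counts the merged candidates. A DSB's elementary damages are
#' all lesions (strand breaks, modified sugars, modified bases) of its
#' contiguous damaged region: the damaged base pairs connected to its breaks
#' through undamaged runs shorter than \code{merge_gap_bp}, on either strand.
#' A DSB is complex when its elementary damages exceed
#' \code{cdsb_elementary_threshold}.
#'
#' This is a plain-R reference implementation of the same rules used by the
#' fused simulation kernel (the two are compared in the test suite).
#'
#' @param sites lesion-resolved site table from
#'   \code{\link{radicals_to_lesions}}.
#' @param segments the \code{segments} table from \code{\link{cluster_events}}.
#' @param params a \code{damage_params}.
#' @return data frame of class \code{dsb_table}: \code{x_um, y_um, z_um, n_sb,
#'   n_elementary, multiplicity, is_complex, track_ids}.
#' @export
call_dsbs <- function(sites, segments, params = damage_params()) {
  out <- .empty_dsbs()
  if (nrow(sites) == 0) return(out)
  if (is.null(sites$lesion)) stop("lesion types not resolved", call. = FALSE)
  seg_info <- sites[!duplicated(sites$segment),
                    c("segment", "chain", "chain_pos", "seg_x", "seg_y",
                      "seg_z")]
  rows <- list()
  for (ch in unique(seg_info$chain)) {
    segs <- seg_info[seg_info$chain == ch, , drop = FALSE]
    segs <- segs[order(segs$chain_pos), , drop = FALSE]
    ss <- sites[sites$chain == ch, , drop = FALSE]
    ss$abs_bp <- ss$chain_pos * 10L + ss$bp
    # per damaged base pair: sites, breaks, owning segment
    dmg <- aggregate(cbind(nsites = rep(1L, nrow(ss)),
                           nbrk = as.integer(ss$lesion == "strand_break")) ~
                       abs_bp + segment, data = ss, FUN = sum)
    dmg <- dmg[order(dmg$abs_bp), , drop = FALSE]
    cands <- list()
    for (sg in segs$segment) {
      si <- ss[ss$segment == sg, , drop = FALSE]
      brk <- si[si$lesion == "strand_break", , drop = FALSE]
      ok <- if (params$opposite_strand_rule) {
        any(brk$strand == 1) && any(brk$strand == 2)
      } else nrow(brk) >= 2
      if (ok) {
        cands[[length(cands) + 1L]] <- list(
          seg = sg, nsb = nrow(brk), minb = min(brk$abs_bp),
          maxb = max(brk$abs_bp))
      }
    }
    i <- 1L
    while (i <= length(cands)) {
      mult <- 1L
      gmin <- cands[[i]]$minb
      gmax <- cands[[i]]$maxb
      j <- i + 1L
      while (j <= length(cands)) {
        span <- cands[[j]]$minb - gmax - 1L
        ndmg <- sum(dmg$abs_bp > gmax & dmg$abs_bp < cands[[j]]$minb)
        if (span - ndmg < params$merge_gap_bp) {
          mult <- mult + 1L
          gmax <- max(gmax, cands[[j]]$maxb)
          j <- j + 1L
        } else break
      }
      # attribution region: expand through damaged bps separated by
      # undamaged runs < merge_gap
      inreg <- dmg$abs_bp >= gmin & dmg$abs_bp <= gmax
      repeat {
        grew <- FALSE
        lo <- min(dmg$abs_bp[inreg])
        hi <- max(dmg$abs_bp[inreg])
        below <- dmg$abs_bp < lo
        if (any(below)) {
          nb <- max(dmg$abs_bp[below])
          if (lo - nb - 1L < params$merge_gap_bp) {
            inreg[dmg$abs_bp == nb] <- TRUE
            grew <- TRUE
          }
        }
        above <- dmg$abs_bp > hi
        if (any(above)) {
          na_ <- min(dmg$abs_bp[above])
          if (na_ - hi - 1L < params$merge_gap_bp) {
            inreg[dmg$abs_bp == na_] <- TRUE
            grew <- TRUE
          }
        }
        if (!grew) break
      }
      reg <- dmg[inreg, , drop = FALSE]
      reg_segs <- unique(reg$segment)
      sinfo <- seg_info[match(reg$segment, seg_info$segment), ]
      nsb <- sum(reg$nbrk)
      wx <- reg$nbrk
      tracks <- sort(unique(as.integer(unlist(strsplit(
        segments$track_ids[segments$segment %in% reg_segs], ";",
        fixed = TRUE)))))
      rows[[length(rows) + 1L]] <- data.frame(
        x_um = sum(sinfo$seg_x * wx) / nsb,
        y_um = sum(sinfo$seg_y * wx) / nsb,
        z_um = sum(sinfo$seg_z * wx) / nsb,
        n_sb = nsb,
        n_elementary = sum(reg$nsites),
        multiplicity = mult,
        is_complex = NA,
        track_ids = paste(tracks, collapse = ";"))
      i <- j
    }
  }
  if (length(rows)) {
    out <- do.call(rbind, rows)
    out$is_complex <- out$n_elementary > params$cdsb_elementary_threshold
    class(out) <- c("dsb_table", "data.frame")
  }
  out
}

.empty_dsbs <- function() {
  out <- data.frame(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                    n_sb = integer(0), n_elementary = integer(0),
                    multiplicity = integer(0), is_complex = logical(0),
                    track_ids = character(0))
  class(out) <- c("dsb_table", "data.frame")
  out
}

#' Thin DSBs by the DNA volume fraction
#'
#' Each DSB is independently retained with probability \code{fraction},
#' irrespective of complexity (complexity is classified before thinning).
#'
#' @param dsbs a \code{dsb_table}.
#' @param fraction retention probability in [0, 1].
#' @param seed integer seed.
#' @return the retained subset of \code{dsbs}.
#' @export
thin_by_dna_volume <- function(dsbs, fraction, seed = 1) {
  if (fraction < 0 || fraction > 1)
    stop("fraction must be in [0, 1]", call. = FALSE)
  keep <- .u01(nrow(dsbs), seed) < fraction
  dsbs[keep, , drop = FALSE]
}

#' Simulate DNA damage for cells of a voxelized tumor (fused kernel)
#'
#' Runs track generation, clustering, lesion conversion, DSB calling and
#' DNA-volume thinning per cell in compiled code. Per-cell stage streams are
#' \code{child_seed(seed, cell_id, stage)} with stages 0 (tracks), 1
#' (clustering/site assignment), 2 (lesions), 3 (thinning), so the modular
#' operations (\code{\link{generate_events}}, \code{\link{cluster_events}},
#' \code{\link{radicals_to_lesions}}, \code{\link{call_dsbs}},
#' \code{\link{thin_by_dna_volume}}) reproduce any single cell exactly.
#'
#' @param grid a \code{voxel_grid}.
#' @param dose dose in Gy.
#' @param po2 oxygen tension, mmHg; scalar or one value per simulated cell.
#' @param model a \code{track_model}.
#' @param params a \code{damage_params}.
#' @param seed integer master seed.
#' @param cells cell ids to simulate (default all).
#' @param include_indirect include hydroxyl-radical events (FALSE reproduces
#'   the direct-only ablation).
#' @param details if TRUE, also return the per-DSB table (post-thinning).
#' @param track_seed optional separate master seed for the track stage, so
#'   the same physical/chemical tracks can be reused across conditions or
#'   tumor copies while damage is re-randomized.
#' @return list with \code{cells} (per-cell counts: DSBs and complex DSBs
#'   after thinning, whole-nucleus counts before thinning, nucleus dose,
#'   event/track counts), \code{cdsb} (positions and contributing tracks of
#'   retained complex DSBs) and optionally \code{dsb_details}.
#' @export
simulate_cell_damage <- function(grid, dose, po2, model = track_model(),
                                 params = damage_params(), seed = 1,
                                 cells = NULL, include_indirect = TRUE,
                                 details = FALSE, track_seed = seed) {
  if (dose < 0) stop("dose must be >= 0", call. = FALSE)
  if (is.null(cells)) cells <- grid$cells$id
  pb <- p_break(po2, params)
  if (length(pb) == 1L) pb <- rep(pb, length(cells))
  if (length(pb) != length(cells))
    stop("po2 must be scalar or one value per cell", call. = FALSE)
  nv <- nucleus_voxel_volumes(grid)
  mats <- .cells_mats(grid$cells)
  res <- .cpp_simulate_damage_cells(grid$type, grid$cell, grid$dims[1],
                                    grid$box_side, grid$voxel_size,
                                    mats$centers, mats$axes, mats$rot,
                                    mats$ns, as.integer(cells),
                                    nv[as.character(cells)], dose,
                                    unclass(model), unclass(params), pb,
                                    params$dna_volume_fraction,
                                    isTRUE(include_indirect),
                                    isTRUE(details), as.double(seed),
                                    as.double(track_seed))
  cells_df <- data.frame(cell_id = res$cell_id, n_dsb = res$n_dsb,
                         n_cdsb = res$n_cdsb, n_dsb_raw = res$n_dsb_raw,
                         n_cdsb_raw = res$n_cdsb_raw,
                         nucleus_dose_Gy = res$nucleus_dose_Gy,
                         n_direct = res$n_direct,
                         n_indirect = res$n_indirect,
                         n_tracks = res$n_tracks)
  cdsb <- data.frame(cell_id = res$cdsb_cell, x_um = res$cdsb_x,
                     y_um = res$cdsb_y, z_um = res$cdsb_z,
                     track_ids = res$cdsb_tracks)
  out <- list(cells = cells_df, cdsb = cdsb)
  if (isTRUE(details)) {
    out$dsb_details <- data.frame(cell_id = res$dsb_cell, n_sb = res$dsb_nsb,
                                  n_elementary = res$dsb_nelem,
                                  multiplicity = res$dsb_mult,
                                  is_complex = res$dsb_cplx == 1L)
  }
  out
}

#' Induce DNA damage from an event table (modular path)
#'
#' Runs clustering, lesion conversion, DSB calling and thinning per cell on an
#' existing event table (generated or imported), using the same child-seed
#' scheme as \code{\link{simulate_cell_damage}}.
#'
#' @param events an \code{event_table}.
#' @param po2 oxygen tension, mmHg; scalar or named vector by cell id.
#' @param params a \code{damage_params}.
#' @param seed integer master seed.
#' @param include_indirect include hydroxyl-radical events.
#' @return a \code{dsb_table} with a \code{cell_id} column.
#' @export
induce_damage_events <- function(events, po2, params = damage_params(),
                                 seed = 1, include_indirect = TRUE) {
  if (!include_indirect) events <- events[events$kind == "D", , drop = FALSE]
  out <- list()
  for (cid in unique(events$cell_id)) {
    ev <- events[events$cell_id == cid, , drop = FALSE]
    cl <- cluster_events(ev, params, child_seed(seed, cid, .STAGE_CLUSTER))
    p2 <- if (length(po2) == 1L && is.null(names(po2))) po2
          else unname(po2[as.character(cid)])
    sites <- radicals_to_lesions(cl$sites, p2, params,
                                 child_seed(seed, cid, .STAGE_LESIONS))
    dsbs <- call_dsbs(sites, cl$segments, params)
    dsbs <- thin_by_dna_volume(dsbs, params$dna_volume_fraction,
                               child_seed(seed, cid, .STAGE_THIN))
    if (nrow(dsbs)) {
      dsbs <- cbind(cell_id = cid, dsbs)
      out[[length(out) + 1L]] <- dsbs
    }
  }
  if (!length(out)) {
    res <- cbind(cell_id = integer(0), .empty_dsbs())
  } else {
    res <- do.call(rbind, out)
    rownames(res) <- NULL
  }
  class(res) <- c("dsb_table", "data.frame")
  res
}

#' Write a DSB table as CSV
#'
#' Columns: cell_id, dose_Gy, replicate, x_um, y_um, z_um, n_sb,
#' n_elementary, multiplicity, is_complex, track_ids (;-joined).
#'
#' @param dsbs a \code{dsb_table} with \code{cell_id}.
#' @param path output file.
#' @param dose_Gy,replicate provenance columns.
#' @export
write_dsb_csv <- function(dsbs, path, dose_Gy = NA_real_, replicate = 1L) {
  df <- data.frame(cell_id = dsbs$cell_id, dose_Gy = dose_Gy,
                   replicate = replicate, x_um = dsbs$x_um, y_um = dsbs$y_um,
                   z_um = dsbs$z_um, n_sb = dsbs$n_sb,
                   n_elementary = dsbs$n_elementary,
                   multiplicity = dsbs$multiplicity,
                   is_complex = dsbs$is_complex, track_ids = dsbs$track_ids)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Calibrate the damage preset against yield, OER and complexity targets
#'
#' Three one-dimensional searches against whole-nucleus (unthinned) 1 Gy
#' yields measured on a sample of cells:
#' \itemize{
#'   \item the DNA volume fraction is set to
#'     \code{dsb_yield_oxic / raw oxic yield} (thinning is exactly linear);
#'   \item the track model's mean cluster size is tuned so the complex-DSB
#'     share of the whole-nucleus yield matches \code{cdsb_fraction};
#'   \item \code{p_break_anoxic} is tuned so the oxic/anoxic yield ratio
#'     matches \code{oer_dsb} (set equal to \code{p_break_oxic} when the
#'     target is 1).
#' }
#' The cluster-size and OER searches interact weakly and are iterated.
#'
#' @param grid a \code{voxel_grid}.
#' @param model a \code{track_model} (starting point).
#' @param targets list with \code{dsb_yield_oxic} (per Gy per cell),
#'   \code{oer_dsb} and \code{cdsb_fraction}.
#' @param params starting \code{damage_params}.
#' @param seed integer seed.
#' @param n_cells number of cells sampled per evaluation.
#' @param dose evaluation dose, Gy.
#' @param rel_tol relative tolerance on each target.
#' @param max_iter outer iterations.
#' @return list with calibrated \code{params}, \code{model} and a
#'   \code{report} data frame (target, desired, achieved). If a target is
#'   unreachable within parameter bounds the report is returned with
#'   \code{converged = FALSE} and a warning.
#' @export
calibrate_damage <- function(grid, model = track_model(),
                             targets = list(dsb_yield_oxic = 30.1,
                                            oer_dsb = 4.6,
                                            cdsb_fraction = 2.9 / 30.1),
                             params = damage_params(), seed = 1,
                             n_cells = 120, dose = 1, rel_tol = 0.03,
                             max_iter = 4) {
  ids <- grid$cells$id
  if (length(ids) > n_cells) ids <- ids[seq_len(n_cells)]
  measure <- function(model, params, po2, rep) {
    r <- simulate_cell_damage(grid, dose, po2, model, params,
                              seed = child_seed(seed, 90, rep), cells = ids)
    c(dsb = mean(r$cells$n_dsb_raw) / dose,
      cdsb = mean(r$cells$n_cdsb_raw) / dose)
  }
  mu <- model$cluster_mean_direct
  converged <- TRUE
  y <- measure(model, params, 760, 0)
  for (it in seq_len(max_iter)) {
    frac <- y["cdsb"] / y["dsb"]
    if (abs(frac / targets$cdsb_fraction - 1) > rel_tol) {
      # complex share rises with cluster size: log-scale secant step
      mu2 <- mu * (targets$cdsb_fraction / frac)^0.6
      mu2 <- min(max(mu2, 2), 60)
      model <- track_model(model$preset, cluster_mean_direct = mu2,
                           fluence_per_um2_per_Gy = model$fluence_per_um2_per_Gy,
                           mean_deposit_eV = model$mean_deposit_eV,
                           oh_per_direct_ratio = model$oh_per_direct_ratio)
      mu <- mu2
      y <- measure(model, params, 760, it)
    } else break
  }
  frac <- y["cdsb"] / y["dsb"]
  if (abs(frac / targets$cdsb_fraction - 1) > 2 * rel_tol) converged <- FALSE

  fr <- targets$dsb_yield_oxic / y["dsb"]
  if (fr > 1) {
    converged <- FALSE
    fr <- 1
  }
  params$dna_volume_fraction <- as.numeric(fr)

  if (abs(targets$oer_dsb - 1) < 1e-12) {
    params$p_break_anoxic <- params$p_break_oxic
    oer <- 1
  } else {
    target_anox <- y["dsb"] / targets$oer_dsb
    lo <- 1e-3
    hi <- params$p_break_oxic
    ya <- NA
    for (it in seq_len(8)) {
      mid <- (lo + hi) / 2
      params$p_break_anoxic <- mid
      ya <- measure(model, params, 0, 100 + it)["dsb"]
      if (abs(ya / target_anox - 1) < rel_tol) break
      if (ya > target_anox) hi <- mid else lo <- mid
    }
    oer <- y["dsb"] / ya
    if (abs(oer / targets$oer_dsb - 1) > 3 * rel_tol) converged <- FALSE
  }

  report <- data.frame(
    target = c("dsb_yield_oxic", "oer_dsb", "cdsb_fraction"),
    desired = c(targets$dsb_yield_oxic, targets$oer_dsb,
                targets$cdsb_fraction),
    achieved = c(as.numeric(y["dsb"] * params$dna_volume_fraction),
                 as.numeric(oer), as.numeric(frac)))
  if (!converged)
    warning("calibration did not reach all targets; see report",
            call. = FALSE)
  list(params = params, model = model, report = report,
       converged = converged)
}
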