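#' Experiment configuration
#'
#' Bundles geometry, track preset, dose schedule, oxygen conditions, damage
#' parameters, misrejoining parameters and seeds for the pipeline runners.
#' \code{dsb_yield}, \code{r0} and \code{p_nlmr} may be vectors; the runners
#' loop over their combinations (the damage simulation is shared across
#' \code{r0}/\code{p_nlmr}, and tracks are shared across oxygen conditions).
#'
#' @param box_side block side, micrometres.
#' @param n_cells cells in the block.
#' @param axis_ranges see \code{\link{place_cells}}.
#' @param doses dose schedule, Gy (default: the 10-point schedule
#'   0.001...1 Gy).
#' @param conditions named numeric vector of uniform pO2 conditions, mmHg.
#' @param dsb_yield target DSB yield(s) per Gy per cell under full oxia.
#' @param r0 characteristic misrejoining distance(s), micrometres.
#' @param p_nlmr non-lethal misrejoining probability(ies).
#' @param model a \code{track_model}.
#' @param params a \code{damage_params}.
#' @param oxy an \code{oxygenation_params} (for \code{\link{run_tumor_1mm}}).
#' @param n_side replication factor per axis for the assembled tumor.
#' @param dose_1mm dose delivered to the assembled tumor, Gy.
#' @param collect_details collect per-DSB detail tables at the largest dose.
#' @param seed master seed.
#' @param out_dir optional output directory; runners write CSV/JSON there.
#' @return an object of class \code{experiment_config}.
#' @export
experiment_config <- function(box_side = 200, n_cells = 1224,
                              axis_ranges = list(major = c(14, 20), minor = 14),
                              doses = c(0.001, 0.003, 0.01, 0.03, 0.06, 0.1,
                                        0.3, 0.5, 0.7, 1),
                              conditions = c(oxic = 760, anoxic = 0),
                              dsb_yield = 30.1, r0 = 0.7, p_nlmr = 0.5,
                              model = track_model(), params = damage_params(),
                              oxy = oxygenation_params(), n_side = 5,
                              dose_1mm = 1, collect_details = TRUE, seed = 1,
                              out_dir = NULL) {
  stopifnot(length(doses) >= 1, all(doses >= 0), all(r0 > 0),
            all(p_nlmr > 0), all(p_nlmr <= 1), n_cells >= 0)
  if (is.null(names(conditions)))
    names(conditions) <- paste0("po2_", conditions)
  structure(list(box_side = box_side, n_cells = n_cells,
                 axis_ranges = axis_ranges, doses = doses,
                 conditions = conditions, dsb_yield = dsb_yield, r0 = r0,
                 p_nlmr = p_nlmr, model = model, params = params, oxy = oxy,
                 n_side = n_side, dose_1mm = dose_1mm,
                 collect_details = collect_details, seed = seed,
                 out_dir = out_dir),
            class = "experiment_config")
}

#' Read an experiment configuration from JSON
#'
#' Keys mirror the arguments of \code{\link{experiment_config}}; nested
#' \code{model}, \code{params} and \code{oxy} objects are passed as named
#' overrides to their constructors.
#'
#' @param path JSON file.
#' @return an \code{experiment_config}.
#' @export
read_config <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- js
  if (!is.null(js$model)) args$model <- do.call(track_model, as.list(js$model))
  if (!is.null(js$params)) args$params <- do.call(damage_params, as.list(js$params))
  if (!is.null(js$oxy)) args$oxy <- do.call(oxygenation_params, as.list(js$oxy))
  if (!is.null(js$conditions)) args$conditions <- unlist(js$conditions)
  if (!is.null(js$axis_ranges)) args$axis_ranges <- as.list(js$axis_ranges)
  do.call(experiment_config, args)
}

# build the block geometry for a config (stage-1 child stream)
.config_geometry <- function(config) {
  cells <- place_cells(config$box_side, config$n_cells, config$axis_ranges,
                       seed = child_seed(config$seed, 1, 0))
  voxelize(cells, config$box_side)
}

# damage + misrejoining over the dose schedule for one DNA-volume fraction.
# Tracks are shared across conditions (same track stream per dose); lesion
# and thinning streams are shared too, which couples the oxic/anoxic
# realizations through common random numbers (variance reduction for OERs).
.run_damage_grid <- function(grid, config, params, include_indirect = TRUE) {
  doses <- config$doses
  dmax <- max(doses)
  res <- list(per_dose = NULL, per_cell = list(), details = list(),
              mr = list())
  for (ci in seq_along(config$conditions)) {
    cname <- names(config$conditions)[ci]
    po2 <- config$conditions[[ci]]
    for (di in seq_along(doses)) {
      want_details <- config$collect_details && doses[di] == dmax
      sim <- simulate_cell_damage(
        grid, doses[di], po2, config$model, params,
        seed = child_seed(config$seed, 2, di),
        include_indirect = include_indirect, details = want_details)
      pc <- sim$cells
      pc$dose_Gy <- doses[di]
      pc$condition <- cname
      # misrejoining per r0; survival is a deterministic map of n_mr
      for (ri in seq_along(config$r0)) {
        mr <- misrejoin_cells(sim$cdsb, pc$cell_id, config$r0[ri],
                              p_nlmr = config$p_nlmr[1],
                              seed = child_seed(config$seed, 3,
                                                1000 * ci + 10 * di + ri))
        pc[[paste0("n_mr_r", ri)]] <- mr$n_mr
      }
      res$per_cell[[paste0(cname, "_", di)]] <- pc
      if (want_details && !is.null(sim$dsb_details)) {
        dd <- sim$dsb_details
        dd$condition <- cname
        dd$dose_Gy <- doses[di]
        res$details[[cname]] <- dd
      }
    }
  }
  res$per_cell_df <- do.call(rbind, res$per_cell)
  rownames(res$per_cell_df) <- NULL
  res
}

#' Run the sensitivity-analysis pipeline
#'
#' For every combination of target DSB yield, r0 and non-lethal probability in
#' the config, and every oxygen condition: simulates the dose schedule on the
#' block tumor, computes per-dose means over all cells (including zero-damage
#' cells), fits the linear yields and linear-quadratic misrejoining/killing
#' responses with the negative-alpha refit rule, and derives OERs, SF2 and
#' D10.
#'
#' @param config an \code{experiment_config}.
#' @param grid optional pre-built \code{voxel_grid} (default: built from the
#'   config).
#' @return an object of class \code{sensitivity_result}: list with
#'   \code{per_dose} (means and SEMs), \code{fits}, \code{summary} (one row
#'   per parameter combination, Tables 3-5 layout), \code{per_cell},
#'   \code{dsb_details} and \code{provenance}.
#' @export
run_sensitivity <- function(config, grid = NULL) {
  if (length(config$doses) < 2)
    stop("sensitivity fits need at least 2 dose points in the schedule",
         call. = FALSE)
  if (is.null(grid)) grid <- .config_geometry(config)
  doses <- config$doses
  conds <- names(config$conditions)
  per_dose <- NULL
  fits <- NULL
  summary_rows <- NULL
  per_cell_keep <- NULL
  details_keep <- NULL
  for (yi in seq_along(config$dsb_yield)) {
    yld <- config$dsb_yield[yi]
    params <- config$params
    params$dna_volume_fraction <- dna_volume_for_yield(yld)
    run <- .run_damage_grid(grid, config, params)
    pcd <- run$per_cell_df
    if (yi == 1L) {
      per_cell_keep <- pcd
      details_keep <- run$details
    }
    agg <- do.call(rbind, lapply(conds, function(cn) {
      do.call(rbind, lapply(seq_along(doses), function(di) {
        s <- pcd[pcd$condition == cn & pcd$dose_Gy == doses[di], ]
        row <- data.frame(dsb_yield = yld, condition = cn, dose_Gy = doses[di],
                          mean_dsb = mean(s$n_dsb), sem_dsb = .sem(s$n_dsb),
                          mean_cdsb = mean(s$n_cdsb),
                          sem_cdsb = .sem(s$n_cdsb),
                          mean_dose_Gy = mean(s$nucleus_dose_Gy))
        for (ri in seq_along(config$r0)) {
          nm <- s[[paste0("n_mr_r", ri)]]
          row[[paste0("mean_nmr_r", ri)]] <- mean(nm)
          row[[paste0("sem_nmr_r", ri)]] <- .sem(nm)
          for (pi in seq_along(config$p_nlmr)) {
            surv <- config$p_nlmr[pi]^nm
            row[[paste0("mean_surv_r", ri, "_p", pi)]] <- mean(surv)
          }
        }
        row
      }))
    }))
    per_dose <- rbind(per_dose, agg)

    yield_fits <- list()
    for (cn in conds) {
      a <- agg[agg$condition == cn, ]
      fd <- fit_yield(a$dose_Gy, a$mean_dsb, "DSB")
      fc <- fit_yield(a$dose_Gy, a$mean_cdsb, "cDSB")
      yield_fits[[cn]] <- list(dsb = fd, cdsb = fc)
      fits <- rbind(fits,
                    cbind(dsb_yield = yld, r0 = NA, p_nlmr = NA,
                          fit_report("DSB", cn, fd)),
                    cbind(dsb_yield = yld, r0 = NA, p_nlmr = NA,
                          fit_report("cDSB", cn, fc)))
    }
    oer_dsb <- .or_na(oer_yield(yield_fits[[1]]$dsb,
                                yield_fits[[conds[length(conds)]]]$dsb))
    oer_cdsb <- .or_na(oer_yield(yield_fits[[1]]$cdsb,
                                 yield_fits[[conds[length(conds)]]]$cdsb))

    for (ri in seq_along(config$r0)) {
      mr_fits <- list()
      for (cn in conds) {
        a <- agg[agg$condition == cn, ]
        fm <- fit_lq_counts(a$dose_Gy, a[[paste0("mean_nmr_r", ri)]])
        mr_fits[[cn]] <- fm
        fits <- rbind(fits, cbind(dsb_yield = yld, r0 = config$r0[ri],
                                  p_nlmr = NA,
                                  fit_report("misrejoinings", cn, fm)))
      }
      for (pi in seq_along(config$p_nlmr)) {
        k_fits <- list()
        for (cn in conds) {
          a <- agg[agg$condition == cn, ]
          fk <- fit_lq_survival(a$dose_Gy,
                                a[[paste0("mean_surv_r", ri, "_p", pi)]])
          k_fits[[cn]] <- fk
          fits <- rbind(fits, cbind(dsb_yield = yld, r0 = config$r0[ri],
                                    p_nlmr = config$p_nlmr[pi],
                                    fit_report("killing", cn, fk)))
        }
        oxic <- conds[1]
        anox <- conds[length(conds)]
        srow <- data.frame(
          dsb_yield = yld, r0 = config$r0[ri], p_nlmr = config$p_nlmr[pi],
          m_dsb = yield_fits[[oxic]]$dsb$slope,
          m_cdsb = yield_fits[[oxic]]$cdsb$slope,
          oer_dsb = oer_dsb, oer_cdsb = oer_cdsb,
          alpha_mr = mr_fits[[oxic]]$alpha, beta_mr = mr_fits[[oxic]]$beta,
          refit_mr = mr_fits[[oxic]]$refit_pure_quadratic,
          alpha_mr_anox = mr_fits[[anox]]$alpha,
          beta_mr_anox = mr_fits[[anox]]$beta,
          refit_mr_anox = mr_fits[[anox]]$refit_pure_quadratic,
          alpha_killing = k_fits[[oxic]]$alpha,
          beta_killing = k_fits[[oxic]]$beta,
          refit_killing = k_fits[[oxic]]$refit_pure_quadratic,
          alpha_killing_anox = k_fits[[anox]]$alpha,
          beta_killing_anox = k_fits[[anox]]$beta,
          refit_killing_anox = k_fits[[anox]]$refit_pure_quadratic,
          sf2 = sf_at_dose(k_fits[[oxic]], 2),
          sf2_anox = sf_at_dose(k_fits[[anox]], 2),
          d10 = .or_na(d10(k_fits[[oxic]])),
          d10_anox = .or_na(d10(k_fits[[anox]])),
          oer_killing = .or_na(oer_killing(k_fits[[oxic]], k_fits[[anox]])))
        summary_rows <- rbind(summary_rows, srow)
      }
    }
  }
  out <- structure(list(per_dose = per_dose, fits = fits,
                        summary = summary_rows, per_cell = per_cell_keep,
                        dsb_details = details_keep, grid = grid,
                        provenance = list(seed = config$seed,
                                          config = config)),
                   class = "sensitivity_result")
  .write_outputs(out, config, "sensitivity")
  out
}

.sem <- function(x) stats::sd(x) / sqrt(length(x))

# degenerate fits (no damage / no killing at small scale) yield NA summaries
# rather than aborting a whole run
.or_na <- function(expr) tryCatch(expr, error = function(e) NA_real_)

.write_outputs <- function(res, config, prefix) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  pd <- file.path(config$out_dir, paste0(prefix, "_per_dose.csv"))
  write.csv(res$per_dose, pd, row.names = FALSE)
  if (!is.null(res$summary))
    write.csv(res$summary, file.path(config$out_dir,
                                     paste0(prefix, "_summary.csv")),
              row.names = FALSE)
  if (!is.null(res$fits))
    jsonlite::write_json(res$fits,
                         file.path(config$out_dir, paste0(prefix, "_fits.json")),
                         dataframe = "rows", digits = NA, auto_unbox = TRUE)
  invisible(NULL)
}

#' Direct-only ablation
#'
#' Repeats the default-combination dose-response with and without the indirect
#' (hydroxyl-radical) events, on the same tracks, and tabulates the paired
#' DSB/cDSB yields and OERs.
#'
#' @param config an \code{experiment_config} (scalar dsb_yield).
#' @param grid optional pre-built grid.
#' @return list with \code{table} (rows "direct+indirect" and "direct-only":
#'   DSB/cDSB yield slopes and OERs), \code{per_dose} for both variants, and
#'   provenance.
#' @export
run_direct_only <- function(config, grid = NULL) {
  if (is.null(grid)) grid <- .config_geometry(config)
  params <- config$params
  params$dna_volume_fraction <- dna_volume_for_yield(config$dsb_yield[1])
  doses <- config$doses
  conds <- names(config$conditions)
  variant <- function(include_indirect) {
    run <- .run_damage_grid(grid, config, params, include_indirect)
    pcd <- run$per_cell_df
    agg <- aggregate(cbind(n_dsb, n_cdsb) ~ condition + dose_Gy, pcd, mean)
    fits <- lapply(setNames(conds, conds), function(cn) {
      a <- agg[agg$condition == cn, ]
      a <- a[order(a$dose_Gy), ]
      list(dsb = fit_yield(a$dose_Gy, a$n_dsb, "DSB"),
           cdsb = fit_yield(a$dose_Gy, a$n_cdsb, "cDSB"))
    })
    list(agg = agg, fits = fits)
  }
  full <- variant(TRUE)
  donly <- variant(FALSE)
  mk_row <- function(v, label) {
    ox <- conds[1]
    an <- conds[length(conds)]
    data.frame(model = label,
               dsb_yield = v$fits[[ox]]$dsb$slope,
               cdsb_yield = v$fits[[ox]]$cdsb$slope,
               oer_dsb = .or_na(oer_yield(v$fits[[ox]]$dsb, v$fits[[an]]$dsb)),
               oer_cdsb = .or_na(oer_yield(v$fits[[ox]]$cdsb,
                                           v$fits[[an]]$cdsb)))
  }
  tab <- rbind(mk_row(full, "direct+indirect"), mk_row(donly, "direct-only"))
  out <- list(table = tab,
              per_dose = rbind(cbind(model = "direct+indirect", full$agg),
                               cbind(model = "direct-only", donly$agg)),
              provenance = list(seed = config$seed, config = config))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(tab, file.path(config$out_dir, "direct_only_table.csv"),
              row.names = FALSE)
  }
  out
}

#' Simulate a dose to an assembled (replicated) hypoxic tumor
#'
#' Replicates the block \code{n_side^3} times, grows a connected vessel
#' network, assigns per-cell pO2 and viability, and simulates DNA damage and
#' misrejoining in every viable cell of every copy. The same track streams are
#' reused across copies (per block cell id); lesion placement, thinning and
#' misrejoining are re-randomized per copy, and the strand-break probability
#' follows each cell's pO2.
#'
#' @param config an \code{experiment_config}; uses \code{dose_1mm},
#'   \code{n_side}, \code{oxy} and the first \code{dsb_yield}/\code{r0}/
#'   \code{p_nlmr}.
#' @param grid optional pre-built block grid.
#' @param oxygenation optional result of \code{\link{calibrate_oxygenation}}
#'   (reuses its network and cell table).
#' @return list with \code{endpoints} (one row per viable cell: copy, ids,
#'   position, pO2, DSB/cDSB counts, misrejoinings, survival),
#'   \code{oxygen_summary}, \code{cells} (all statuses) and provenance.
#' @export
run_tumor_1mm <- function(config, grid = NULL, oxygenation = NULL) {
  if (is.null(grid)) grid <- .config_geometry(config)
  assembly <- replicate_tumor(grid, config$n_side)
  if (is.null(oxygenation)) {
    network <- grow_vessels(assembly, config$oxy,
                            seed = child_seed(config$seed, 5, 0))
    cells <- assign_po2(assembly, network, config$oxy)
  } else {
    network <- oxygenation$network
    cells <- oxygenation$cells
  }
  params <- config$params
  params$dna_volume_fraction <- dna_volume_for_yield(config$dsb_yield[1])
  dose <- config$dose_1mm
  track_seed <- child_seed(config$seed, 2, 0)
  rows <- list()
  for (copy in seq_len(config$n_side^3)) {
    cc <- cells[cells$copy == copy & cells$status == "viable", , drop = FALSE]
    if (!nrow(cc)) next
    sim <- simulate_cell_damage(grid, dose, cc$po2, config$model, params,
                                seed = child_seed(config$seed, 6, copy),
                                cells = cc$block_id,
                                track_seed = track_seed)
    cdsb <- sim$cdsb
    mr <- misrejoin_cells(cdsb, cc$block_id, config$r0[1], config$p_nlmr[1],
                          seed = child_seed(config$seed, 7, copy))
    rows[[copy]] <- data.frame(copy = copy, cell_id = cc$id,
                               block_id = cc$block_id, x = cc$x, y = cc$y,
                               z = cc$z, po2 = cc$po2, dist_um = cc$dist_um,
                               n_dsb = sim$cells$n_dsb,
                               n_cdsb = sim$cells$n_cdsb,
                               n_mr = mr$n_mr, p_surv = mr$p_surv)
  }
  endpoints <- do.call(rbind, rows)
  rownames(endpoints) <- NULL
  oxsum <- data.frame(
    n_cells = nrow(cells),
    n_viable = sum(cells$status == "viable"),
    n_necrotic = sum(cells$status == "necrotic"),
    n_vessel = sum(cells$status == "vessel"),
    mean_po2 = mean(cells$po2[cells$status == "viable"]),
    median_po2 = stats::median(cells$po2[cells$status == "viable"]),
    hp10 = hypoxic_fraction(cells, 10), hp5 = hypoxic_fraction(cells, 5),
    hp2.5 = hypoxic_fraction(cells, 2.5), hp1 = hypoxic_fraction(cells, 1))
  out <- list(endpoints = endpoints, oxygen_summary = oxsum, cells = cells,
              network = network,
              provenance = list(seed = config$seed, config = config))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(endpoints, file.path(config$out_dir, "tumor1mm_endpoints.csv"),
              row.names = FALSE)
    write.csv(oxsum, file.path(config$out_dir, "tumor1mm_oxygen.csv"),
              row.names = FALSE)
  }
  out
}

#' Univariate endpoint histograms
#'
#' Frequency distributions of per-cell endpoints (DSBs, complex DSBs,
#' misrejoinings, survival probability), per condition if a condition column
#' is present.
#'
#' @param per_cell per-cell endpoint table (e.g. \code{per_cell} of a
#'   \code{sensitivity_result} or \code{endpoints} of
#'   \code{\link{run_tumor_1mm}}).
#' @param endpoints columns to summarize (defaults to those present among
#'   n_dsb, n_cdsb, n_mr, p_surv).
#' @param normalize report relative frequencies instead of counts.
#' @return data frame \code{endpoint, condition, bin_lo, bin_hi, count, freq};
#'   zero rows with attribute \code{empty = TRUE} for an empty input.
#' @export
summarize_distributions <- function(per_cell,
                                    endpoints = intersect(
                                      c("n_dsb", "n_cdsb", "n_mr", "p_surv"),
                                      names(per_cell)),
                                    normalize = FALSE) {
  empty <- data.frame(endpoint = character(0), condition = character(0),
                      bin_lo = numeric(0), bin_hi = numeric(0),
                      count = integer(0), freq = numeric(0))
  if (is.null(per_cell) || nrow(per_cell) == 0) {
    attr(empty, "empty") <- TRUE
    return(empty)
  }
  cond <- if ("condition" %in% names(per_cell)) per_cell$condition else "all"
  out <- list()
  for (ep in endpoints) {
    x <- per_cell[[ep]]
    for (cn in unique(cond)) {
      xi <- x[cond == cn]
      if (ep == "p_surv") {
        br <- seq(0, 1, by = 0.05)
        h <- hist(xi, breaks = br, plot = FALSE, include.lowest = TRUE)
        lo <- utils::head(h$breaks, -1)
        hi <- h$breaks[-1]
        cnt <- h$counts
      } else {
        lo <- seq(0, max(xi, 1))
        cnt <- tabulate(xi + 1L, nbins = length(lo))
        hi <- lo + 1
      }
      out[[length(out) + 1L]] <- data.frame(
        endpoint = ep, condition = cn, bin_lo = lo, bin_hi = hi, count = cnt,
        freq = if (sum(cnt) > 0) cnt / sum(cnt) else 0)
    }
  }
  res <- do.call(rbind, out)
  if (normalize) res$count <- res$freq
  res
}

#' DSB property histograms
#'
#' Distributions of strand breaks per DSB, elementary damages per DSB and
#' multiplicity, per condition.
#'
#' @param dsb_details per-DSB table (\code{dsb_details} of a
#'   \code{sensitivity_result}, or from \code{\link{simulate_cell_damage}}).
#' @param normalize report relative frequencies.
#' @return long data frame \code{property, condition, value, count, freq}.
#' @export
dsb_property_histograms <- function(dsb_details, normalize = FALSE) {
  if (is.data.frame(dsb_details)) dsb_details <- list(all = dsb_details)
  out <- list()
  for (cn in names(dsb_details)) {
    dd <- dsb_details[[cn]]
    for (prop in c("n_sb", "n_elementary", "multiplicity")) {
      x <- dd[[prop]]
      tb <- table(x)
      out[[length(out) + 1L]] <- data.frame(
        property = prop, condition = cn, value = as.integer(names(tb)),
        count = as.integer(tb), freq = as.integer(tb) / length(x))
    }
  }
  res <- do.call(rbind, out)
  if (normalize) res$count <- res$freq
  res
}

#' Bivariate frequency table of pO2 against an endpoint
#'
#' @param po2 per-cell pO2 values.
#' @param endpoint per-cell endpoint values.
#' @param po2_breaks,endpoint_breaks bin edges.
#' @return data frame of bin pairs and counts.
#' @export
bivariate_histogram <- function(po2, endpoint,
                                po2_breaks = seq(0, 32, by = 2),
                                endpoint_breaks = NULL) {
  if (is.null(endpoint_breaks)) {
    endpoint_breaks <- if (max(endpoint) <= 1) seq(0, 1, by = 0.05)
                       else seq(0, max(endpoint) + 1)
  }
  bx <- cut(po2, po2_breaks, include.lowest = TRUE, right = FALSE)
  by <- cut(endpoint, endpoint_breaks, include.lowest = TRUE, right = FALSE)
  tb <- as.data.frame(table(po2_bin = bx, endpoint_bin = by),
                      stringsAsFactors = FALSE)
  names(tb)[3] <- "count"
  tb
}
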