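test_that("the oxygen curve hits its closed-form anchor points", {
  p <- damage_params()
  expect_error(p_break(-1, p), ">= 0")
  expect_identical(p_break(0, p), p$p_break_anoxic)
  expect_equal(p_break(760, p), p$p_break_oxic, tolerance = 0.01)
  # exactly the midpoint at the half-effect pressure
  expect_equal(p_break(p$k_half_mmHg, p),
               p$p_break_anoxic + (p$p_break_oxic - p$p_break_anoxic) / 2,
               tolerance = 1e-12)
})

test_that("damage parameter validation and presets", {
  expect_error(damage_params(nonsense = 1), "unknown")
  expect_error(damage_params(p_break_anoxic = 0.9, p_break_oxic = 0.5))
  expect_equal(damage_params()$capture_radius_um,
               sqrt(1.7e-3^2 + 1.15e-3^2), tolerance = 1e-12)
  # paper-style yield targets map to their printed DNA volume fractions
  expect_equal(dna_volume_for_yield(30.1), 0.200, tolerance = 0.06)
  expect_equal(dna_volume_for_yield(20.1) / dna_volume_for_yield(30.1),
               20.1 / 30.1, tolerance = 1e-12)
  expect_error(dna_volume_for_yield(1e4), "outside")
})

test_that("cluster_events: empty input, co-located pair, sparse singletons", {
  expect_equal(nrow(cluster_events(data.frame())$sites), 0)

  ev2 <- data.frame(cell_id = 1L, track_id = 0L, kind = "D",
                    x_um = c(0, 1e-3), y_um = 0, z_um = 0, energy_eV = 20)
  cl <- cluster_events(ev2, seed = 1)
  expect_equal(max(cl$event_segment), 1L)
  expect_lte(nrow(cl$sites), 2)

  # 1e4 isolated events scattered in a nucleus-sized ball: nearest-neighbour
  # distances dwarf the capture radius, so segments are almost all singletons
  set.seed(2)
  n <- 1e4
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * 3.2 * runif(n)^(1 / 3)
  evs <- data.frame(cell_id = 1L, track_id = 0L, kind = "D",
                    x_um = u[, 1], y_um = u[, 2], z_um = u[, 3],
                    energy_eV = 20)
  cl <- cluster_events(evs, seed = 3)
  expect_gte(mean(cl$segments$n_events == 1L), 0.99)
})

test_that("mixed events in one nucleus cluster deterministically", {
  g <- tiny_grid()
  ev <- generate_events(g, 0.2, seed = 11)
  one <- ev[ev$cell_id == 1L, ]
  a <- cluster_events(one, seed = 5)
  b <- cluster_events(one, seed = 5)
  expect_identical(a, b)
  expect_error(cluster_events(ev), "single nucleus")
  expect_true(all(a$sites$bp %in% 1:10))
  expect_true(all(a$sites$strand %in% 1:2))
  expect_true(all(a$sites$moiety %in% c("sugar", "base")))
  # at most one site per (segment, bp, strand)
  expect_false(any(duplicated(a$sites[, c("segment", "bp", "strand")])))
})

test_that("radicals_to_lesions maps moieties per the oxygen curve", {
  sites <- make_sites(data.frame(segment = 1L, chain = 1L, chain_pos = 0L,
                                 bp = 1:6, strand = rep(1:2, 3),
                                 lesion = "x"))
  sites$moiety <- c("sugar", "sugar", "base", "sugar", "base", "sugar")
  out0 <- radicals_to_lesions(sites, 0,
                              damage_params(p_break_anoxic = 0,
                                            p_break_oxic = 0.5), seed = 1)
  expect_true(all(out0$lesion[out0$moiety == "sugar"] == "modified_sugar"))
  expect_true(all(out0$lesion[out0$moiety == "base"] == "modified_base"))
  out1 <- radicals_to_lesions(sites, 760,
                              damage_params(p_break_anoxic = 1,
                                            p_break_oxic = 1), seed = 1)
  expect_true(all(out1$lesion[out1$moiety == "sugar"] == "strand_break"))
  expect_error(radicals_to_lesions(sites, -5), "scalar >= 0")
})

test_that("call_dsbs implements the worked DSB-definition cases", {
  p <- damage_params()
  # two breaks on opposite strands in one segment -> one DSB, multiplicity 1
  s1 <- make_sites(data.frame(segment = 1L, chain = 1L, chain_pos = 0L,
                              bp = c(3L, 5L), strand = c(1L, 2L),
                              lesion = "strand_break"))
  d <- call_dsbs(s1, make_segments(s1), p)
  expect_equal(nrow(d), 1)
  expect_equal(d$n_sb, 2)
  expect_equal(d$multiplicity, 1)
  expect_equal(d$n_elementary, 2)
  expect_false(d$is_complex)

  # two breaks on the same strand: no DSB under the opposite-strand rule,
  # one DSB when the rule is disabled
  s2 <- make_sites(data.frame(segment = 1L, chain = 1L, chain_pos = 0L,
                              bp = c(3L, 5L), strand = c(1L, 1L),
                              lesion = "strand_break"))
  expect_equal(nrow(call_dsbs(s2, make_segments(s2), p)), 0)
  expect_equal(nrow(call_dsbs(s2, make_segments(s2),
                              damage_params(opposite_strand_rule = FALSE))),
               1)

  # two candidates separated by 5 undamaged bp -> one DSB, multiplicity 2
  s3 <- make_sites(data.frame(segment = c(1L, 1L, 2L, 2L),
                              chain = 1L, chain_pos = c(0L, 0L, 1L, 1L),
                              bp = c(9L, 10L, 6L, 7L),
                              strand = c(1L, 2L, 1L, 2L),
                              lesion = "strand_break"))
  d3 <- call_dsbs(s3, make_segments(s3), p)
  # gap: abs positions 10 and 16 -> 5 undamaged bp in between
  expect_equal(nrow(d3), 1)
  expect_equal(d3$multiplicity, 2)
  expect_equal(d3$n_sb, 4)

  # candidates separated by >= 10 undamaged bp stay separate
  s4 <- make_sites(data.frame(segment = c(1L, 1L, 2L, 2L),
                              chain = 1L, chain_pos = c(0L, 0L, 2L, 2L),
                              bp = c(1L, 2L, 9L, 10L),
                              strand = c(1L, 2L, 1L, 2L),
                              lesion = "strand_break"))
  d4 <- call_dsbs(s4, make_segments(s4), p)
  expect_equal(nrow(d4), 2)
  expect_equal(d4$multiplicity, c(1, 1))

  # intermediate damaged base pairs shrink the undamaged gap and trigger the
  # merge; the merged DSB's elementary damages cover its damaged region
  s5 <- make_sites(data.frame(segment = c(1L, 1L, 2L, 2L, 2L, 2L, 2L, 2L,
                                          3L, 3L),
                              chain = 1L,
                              chain_pos = c(0L, 0L, rep(1L, 6), 2L, 2L),
                              bp = c(9L, 10L, 1L, 2L, 3L, 4L, 5L, 6L,
                                     1L, 2L),
                              strand = c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L,
                                         1L, 2L),
                              lesion = c("strand_break", "strand_break",
                                         rep("modified_base", 6),
                                         "strand_break", "strand_break")))
  d5 <- call_dsbs(s5, make_segments(s5), p)
  # candidate breaks end at abs 10 and resume at abs 21: 10 bp between, 6 of
  # them damaged -> 4 undamaged < 10: merge; the region spans all 10 lesions
  expect_equal(nrow(d5), 1)
  expect_equal(d5$multiplicity, 2)
  expect_equal(d5$n_sb, 4)
  expect_equal(d5$n_elementary, 10)
})

test_that("thinning is complexity-blind binomial with exact edge cases", {
  dsbs <- call_dsbs(make_sites(data.frame(segment = 1L, chain = 1L,
                                          chain_pos = 0L, bp = c(3L, 5L),
                                          strand = 1:2,
                                          lesion = "strand_break")),
                    data.frame(segment = 1L, n_events = 1L, track_ids = "0"))
  big <- dsbs[rep(1, 1e5), ]
  expect_error(thin_by_dna_volume(big, 1.2), "0, 1")
  expect_equal(nrow(thin_by_dna_volume(big, 1, seed = 1)), 1e5)
  expect_equal(nrow(thin_by_dna_volume(big, 0, seed = 1)), 0)
  kept <- nrow(thin_by_dna_volume(big, 0.2, seed = 7))
  expect_lt(abs(kept - 20000), 3 * sqrt(1e5 * 0.2 * 0.8))
})

test_that("modular chain reproduces the fused kernel cell-for-cell", {
  g <- tiny_grid()
  params <- damage_params()
  master <- 314
  fused <- simulate_cell_damage(g, 0.5, 50, params = params, seed = master,
                                details = TRUE)
  ev <- generate_events(g, 0.5, seed = master)
  dsb_mod <- induce_damage_events(ev, 50, params, seed = master)
  for (cid in g$cells$id) {
    mod_c <- dsb_mod[dsb_mod$cell_id == cid, ]
    expect_equal(nrow(mod_c), fused$cells$n_dsb[fused$cells$cell_id == cid],
                 label = sprintf("cell %d DSB count", cid))
    det_c <- fused$dsb_details[fused$dsb_details$cell_id == cid, ]
    expect_equal(sort(mod_c$n_elementary), sort(det_c$n_elementary))
    expect_equal(sort(mod_c$n_sb), sort(det_c$n_sb))
    expect_equal(sort(mod_c$multiplicity), sort(det_c$multiplicity))
    expect_equal(sum(mod_c$is_complex),
                 fused$cells$n_cdsb[fused$cells$cell_id == cid])
  }
  # complex-DSB positions agree too
  cd_mod <- dsb_mod[dsb_mod$is_complex, ]
  expect_equal(sort(round(cd_mod$x_um, 9)), sort(round(fused$cdsb$x_um, 9)))
})

test_that("damage induction is deterministic and dose-linear through 0", {
  g <- tiny_grid()
  a <- simulate_cell_damage(g, 0.5, 760, seed = 77)
  b <- simulate_cell_damage(g, 0.5, 760, seed = 77)
  expect_identical(a$cells, b$cells)
  doses <- c(0.25, 0.5, 1)
  y <- vapply(doses, function(D) {
    mean(simulate_cell_damage(g, D, 760, seed = 78,
                              cells = 1:5)$cells$n_dsb_raw)
  }, 0)
  fit <- fit_yield(doses, y)
  # intercept-free linearity: a free intercept is consistent with zero
  co <- stats::lm(y ~ doses)
  ci <- confint(co)[1, ]
  expect_true(ci[1] < 0 && ci[2] > 0 || abs(coef(co)[1]) < 0.05 * fit$slope)
})

test_that("anoxia lowers the DSB yield but raises mean DSB complexity", {
  g <- std_grid()
  ox <- simulate_cell_damage(g, 1, 760, seed = 99, cells = 1:120,
                             details = TRUE)
  an <- simulate_cell_damage(g, 1, 0, seed = 99, cells = 1:120,
                             details = TRUE)
  expect_gt(mean(ox$cells$n_dsb_raw), 2 * mean(an$cells$n_dsb_raw))
  expect_gte(mean(an$dsb_details$n_elementary),
             mean(ox$dsb_details$n_elementary))
})

test_that("calibrate_damage reaches its targets and honors OER = 1", {
  g <- std_grid()
  sub <- voxelize(g$cells[1:60, ], 200)
  # unit-OER short circuit
  cal1 <- calibrate_damage(sub, targets = list(dsb_yield_oxic = 30.1,
                                               oer_dsb = 1,
                                               cdsb_fraction = 0.0963),
                           seed = 5, n_cells = 40, max_iter = 1)
  expect_equal(cal1$params$p_break_anoxic, cal1$params$p_break_oxic)
  # from a perturbed anoxic conversion probability, the search recovers the
  # yield within 5 % and the OER within 10 %
  cal <- calibrate_damage(sub, params = damage_params(p_break_anoxic = 0.27),
                          targets = list(dsb_yield_oxic = 30.1,
                                         oer_dsb = 4.6,
                                         cdsb_fraction = 0.0963),
                          seed = 6, n_cells = 60, max_iter = 2)
  r <- cal$report
  expect_equal(r$achieved[r$target == "dsb_yield_oxic"], 30.1,
               tolerance = 0.05)
  expect_equal(r$achieved[r$target == "oer_dsb"], 4.6, tolerance = 0.10)
  expect_equal(r$achieved[r$target == "cdsb_fraction"], 0.0963,
               tolerance = 0.25)
})
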