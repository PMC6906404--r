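test_that("hydroxyl-radical displacement statistics match the diffusion law", {
  m <- track_model()
  expect_equal(oh_displacement_rms(m), sqrt(6 * 2.8e-9 * 2.5e-9) * 1e6,
               tolerance = 1e-12)
  r <- sample_oh_displacements(2e4, m, seed = 9)
  expect_equal(sqrt(mean(r^2)), 6.48e-3, tolerance = 0.02)
})

test_that("generate_events validates inputs and honors dose zero", {
  g <- tiny_grid()
  expect_error(generate_events(g, -0.1), ">= 0")
  expect_error(generate_events(voxelize(place_cells(40, 0), 40), 1),
               "no nucleus voxels")
  ev <- generate_events(g, 0, seed = 1)
  expect_equal(nrow(ev), 0)
  expect_true(all(attr(ev, "nucleus_dose_Gy") == 0))
})

test_that("events respect the direct-energy threshold and nucleus membership", {
  g <- tiny_grid()
  ev <- generate_events(g, 0.5, seed = 2)
  expect_gt(nrow(ev), 0)
  dir <- ev[ev$kind == "D", ]
  expect_true(all(dir$energy_eV >= 10.79))
  expect_true(all(is.na(ev$energy_eV[ev$kind == "I"])))
  # every event position lies in a nucleus voxel of its own cell
  idx <- floor((as.matrix(ev[, c("x_um", "y_um", "z_um")]) + g$box_side / 2) /
                 g$voxel_size) + 1
  lin <- cbind(idx[, 1], idx[, 2], idx[, 3])
  expect_true(all(g$type[lin] == 1L))
  expect_true(all(g$cell[lin] == ev$cell_id))
  expect_true(all(ev$track_id >= 0))
})

test_that("energy bookkeeping: voxel sum equals event sum, dose is linear", {
  g <- tiny_grid()
  ev <- generate_events(g, 0.5, seed = 3, voxel_energy = TRUE)
  vox <- attr(ev, "voxel_energy_eV")
  expect_equal(sum(vox), sum(ev$energy_eV[ev$kind == "D"]), tolerance = 1e-9)
  # doubling all energies doubles the dose
  nv <- nucleus_voxel_volumes(g)
  d1 <- nucleus_dose(ev, nv)
  ev2 <- ev
  ev2$energy_eV <- 2 * ev2$energy_eV
  expect_equal(nucleus_dose(ev2, nv), 2 * d1, tolerance = 1e-12)
})

test_that("nucleus_dose closed form: 0.874 MeV into 140 um^3 is ~1 Gy", {
  ev <- data.frame(cell_id = 1, track_id = 0, kind = "D", x_um = 0, y_um = 0,
                   z_um = 0, energy_eV = 0.874e6)
  expect_equal(unname(nucleus_dose(ev, c("1" = 140))), 1.0003,
               tolerance = 1e-4)
  expect_equal(unname(nucleus_dose(ev[0, ], c("1" = 140))), 0)
})

test_that("per-nucleus dose distribution matches the prescription", {
  g <- std_grid()
  sim <- simulate_cell_damage(g, 1, 760, seed = 201, cells = 1:150)
  d <- sim$cells$nucleus_dose_Gy
  expect_lt(abs(mean(d) - 1.00), 2 * sd(d) / sqrt(length(d)) + 0.01)
  expect_gt(sd(d), 0.045)
  expect_lt(sd(d), 0.075)
})

test_that("mean event counts and dose scale linearly with prescribed dose", {
  g <- tiny_grid()
  for (seed in c(5, 6)) {
    n_ev <- dose_m <- numeric(0)
    for (D in c(0.25, 0.5, 1)) {
      ev <- generate_events(g, D, seed = seed)
      n_ev <- c(n_ev, nrow(ev))
      dose_m <- c(dose_m, mean(attr(ev, "nucleus_dose_Gy")))
    }
    expect_equal(n_ev[3] / n_ev[1], 4, tolerance = 0.15)
    expect_equal(n_ev[3] / n_ev[2], 2, tolerance = 0.15)
    expect_equal(dose_m / c(0.25, 0.5, 1), rep(1, 3), tolerance = 0.2)
  }
})

test_that("event TSV round-trips and rejects malformed records", {
  g <- tiny_grid()
  ev <- generate_events(g, 0.1, seed = 4)
  path <- file.path(withr::local_tempdir(), "events.tsv")
  write_events_tsv(ev, path)
  back <- import_events(path, g)
  expect_equal(nrow(back), nrow(ev))
  expect_equal(back$cell_id, ev$cell_id)
  expect_equal(back$kind, ev$kind)
  expect_equal(back$x_um, ev$x_um, tolerance = 1e-9)
  expect_equal(back$energy_eV[back$kind == "D"],
               ev$energy_eV[ev$kind == "D"], tolerance = 1e-8)

  # empty file with header -> zero events
  writeLines("cell_id\ttrack_id\tkind\tx_um\ty_um\tz_um\tenergy_eV", path)
  expect_equal(nrow(import_events(path)), 0)

  # sub-threshold direct event -> threshold error with line number
  writeLines(c("cell_id\ttrack_id\tkind\tx_um\ty_um\tz_um\tenergy_eV",
               "1\t0\tD\t0\t0\t0\t5"), path)
  expect_error(import_events(path), "line 2.*10.79")

  # unknown cell id
  writeLines(c("cell_id\ttrack_id\tkind\tx_um\ty_um\tz_um\tenergy_eV",
               "99\t0\tD\t0\t0\t0\t20"), path)
  expect_error(import_events(path, g), "unknown cell id 99")

  # bad kind
  writeLines(c("cell_id\ttrack_id\tkind\tx_um\ty_um\tz_um\tenergy_eV",
               "1\t0\tQ\t0\t0\t0\t20"), path)
  expect_error(import_events(path), "kind")
})

test_that("track ids identify statistically independent primaries", {
  g <- tiny_grid()
  ev <- generate_events(g, 0.3, seed = 8)
  one <- ev[ev$cell_id == ev$cell_id[1], ]
  expect_true(all(table(one$track_id) >= 1))
  # events of one track are collinear-ish (clusters along a chord): the rms
  # distance to the track's principal axis is far below the nucleus radius
  tr <- names(sort(table(one$track_id), decreasing = TRUE))[1]
  pts <- as.matrix(one[one$track_id == as.integer(tr),
                       c("x_um", "y_um", "z_um")])
  if (nrow(pts) >= 10) {
    ctr <- colMeans(pts)
    sv <- svd(sweep(pts, 2, ctr))
    resid <- sqrt(mean(sv$d[2]^2 + sv$d[3]^2) / nrow(pts))
    expect_lt(resid, 0.2) # um; nucleus radius ~3 um
  }
})
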