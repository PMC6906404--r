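# fabricate a minimal assembly-like object with chosen cell centers (the
# oxygen operations only use cells, dims, voxel_size, side_um)
fake_assembly <- function(centers, side_um, voxel_size = 2) {
  cells <- data.frame(id = seq_len(nrow(centers)), x = centers[, 1],
                      y = centers[, 2], z = centers[, 3], copy = 1L,
                      block_id = seq_len(nrow(centers)))
  structure(list(block = NULL, n_side = 1L, side_um = side_um,
                 dims = as.integer(side_um / voxel_size),
                 voxel_size = voxel_size, cells = cells),
            class = "tumor_assembly")
}

# linear voxel index (0-based) of a voxel-center position
vox_of <- function(x, y, z, side, vs = 2) {
  n <- side / vs
  i <- floor((c(x, y, z) + side / 2) / vs)
  as.integer(i[1] + n * (i[2] + n * i[3]))
}

test_that("replicate_tumor tiles cells with unique ids and global centers", {
  g <- tiny_grid()
  a1 <- replicate_tumor(g, 1)
  expect_equal(nrow(a1$cells), nrow(g$cells))
  expect_equal(a1$cells$x, g$cells$x)
  a2 <- replicate_tumor(g, 2)
  expect_equal(nrow(a2$cells), 8 * nrow(g$cells))
  expect_equal(sort(unique(a2$cells$copy)), 1:8)
  expect_false(anyDuplicated(a2$cells$id) > 0)
  expect_equal(a2$side_um, 2 * g$box_side)
  expect_equal(a2$dims, 2L * g$dims[1])
  # copies preserve within-block geometry
  b1 <- a2$cells[a2$cells$copy == 1, ]
  b8 <- a2$cells[a2$cells$copy == 8, ]
  expect_equal(diff(b1$x), diff(b8$x))
  # default five-fold replication of the standard block gives 153000 cells
  expect_equal(1224 * 125, 153000)
})

test_that("vessel growth hits the RVV target as one connected component", {
  g <- tiny_grid()
  a <- replicate_tumor(g, 2) # 120 um, 60^3 voxels
  oxy <- oxygenation_params(rvv = 0.021)
  for (seed in 1:3) {
    net <- grow_vessels(a, oxy, seed = seed)
    expect_equal(net$achieved_rvv, 0.021, tolerance = 0.05)
    expect_equal(net$n_components, 1L)
  }
  expect_error(oxygenation_params(rvv = 0), "rvv")
})

test_that("pO2 assignment follows distance, necrosis and consumption rules", {
  side <- 400
  centers <- rbind(c(1, 1, 1),       # essentially at the vessel
                   c(41, 1, 1),      # 40 um away
                   c(131 + 1, 1, 1), # 131 um: beyond the necrosis distance
                   c(101, 1, 1))     # 100 um: viable, hypoxic
  a <- fake_assembly(centers, side)
  net <- vessel_network(vox_of(1, 1, 1, side), a$dims, 2)
  oxy <- oxygenation_params(p0 = 30, nd = 130, decay_length = 28,
                            consume_radius_um = 0.5)
  cells <- assign_po2(a, net, oxy)
  expect_equal(cells$status, c("vessel", "viable", "necrotic", "viable"))
  expect_true(is.na(cells$po2[1]) && is.na(cells$po2[3]))
  expect_equal(cells$po2[2], 30 * exp(-40 / 28), tolerance = 1e-6)
  expect_equal(cells$dist_um[4], 100, tolerance = 1e-9)
  # d -> 0 recovers p0 when consumption is disabled
  oxy0 <- oxygenation_params(consume_radius_um = 0)
  expect_equal(assign_po2(a, net, oxy0)$po2[1], 30, tolerance = 1e-9)
  # pO2 non-increasing in distance
  expect_true(all(diff(cells$po2[c(2, 4)]) <= 0))
  expect_error(assign_po2(a, vessel_network(integer(0), a$dims, 2), oxy),
               "empty")
})

test_that("the distance transform is exact against brute force", {
  side <- 60
  a <- fake_assembly(rbind(c(-29, -29, -29), c(1, 5, -7), c(29, 29, 29)),
                     side)
  vox <- c(vox_of(1, 1, 1, side), vox_of(-19, 11, 3, side),
           vox_of(25, -27, 15, side))
  net <- vessel_network(vox, a$dims, 2)
  d <- vessel_distances(a, net)
  # brute force from voxel centers
  vc <- rbind(c(1, 1, 1), c(-19, 11, 3), c(25, -27, 15))
  cc <- rbind(c(-29, -29, -29), c(1, 5, -7), c(29, 29, 29))
  for (i in 1:3) {
    expect_equal(d[i], min(sqrt(rowSums((vc - matrix(cc[i, ], 3, 3,
                                                     byrow = TRUE))^2))),
                 tolerance = 1e-9)
  }
})

test_that("hypoxic_fraction counts viable cells below threshold", {
  cells <- data.frame(status = c("viable", "viable", "necrotic", "vessel",
                                 "viable"),
                      po2 = c(5, 15, NA, NA, 9.9))
  expect_equal(hypoxic_fraction(cells, 10), 2 / 3)
  expect_equal(hypoxic_fraction(cells, Inf), 1)
  expect_equal(hypoxic_fraction(cells, 0), 0)
  expect_error(hypoxic_fraction(cells[3:4, ], 10), "no viable")
})

test_that("decay-length calibration is monotone and detects degenerate targets", {
  side <- 400
  set.seed(4)
  centers <- matrix(runif(3 * 300, -side / 2 + 10, side / 2 - 10), ncol = 3)
  a <- fake_assembly(centers, side)
  net <- vessel_network(c(vox_of(1, 1, 1, side), vox_of(-99, 1, 1, side),
                          vox_of(101, -99, 51, side)), a$dims, 2)
  oxy <- oxygenation_params(nd = 1e4) # keep everything viable here
  mean_po2 <- function(L) {
    p <- oxy
    p$decay_length <- L
    cells <- assign_po2(a, net, p)
    mean(cells$po2[cells$status == "viable"])
  }
  expect_gt(mean_po2(60), mean_po2(30)) # doubling L raises the mean
  cal <- calibrate_oxygenation(a, oxy, targets = list(mean_po2 = 9.4,
                                                      hp10 = 0.58),
                               network = net)
  expect_equal(cal$report$achieved[1], 9.4, tolerance = 1e-3)
  expect_error(
    calibrate_oxygenation(a, oxy, targets = list(mean_po2 = 30, hp10 = 0.5),
                          network = net),
    "unreachable")
})
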