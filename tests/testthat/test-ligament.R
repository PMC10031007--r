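test_that("the ligament table carries the literature thicknesses", {
  tab <- default_ligament_table()
  expect_equal(ligament_thickness("MPFL"), 2.90)
  expect_equal(ligament_thickness("LPFL"), 1.80)
  expect_equal(ligament_thickness("sMCL_ant"), 2.10)
  expect_equal(ligament_thickness("sMCL_post"), 2.10)
  expect_equal(ligament_thickness("LCL"), 2.20)
  expect_equal(ligament_thickness("ALL"), 1.50)
  expect_equal(ligament_thickness("POL"), 1.00)
  expect_equal(ligament_thickness("OPL"), 1.44)
  expect_error(ligament_thickness("XYZ"), "unknown")
  expect_identical(nrow(tab), 8L)
})

test_that("parallel attachments give a rectangular slab of exact thickness", {
  og <- cbind(seq(0, 10, length.out = 4), 0, 0)
  ig <- cbind(seq(0, 10, length.out = 4), 30, 0)
  lg <- predict_ligament("sMCL_ant", og, ig, thickness = 2)
  v <- lg$solid$vertices
  expect_true(is_watertight(lg$solid))
  expect_equal(range(v[, 3]), c(-1, 1), tolerance = 1e-6)
  expect_equal(range(v[, 2]), c(0, 30), tolerance = 1e-6)
  expect_equal(mesh_volume(lg$solid), 10 * 30 * 2, tolerance = 1e-6)
})

test_that("the solid clears an obstacle placed between the attachments", {
  og <- cbind(seq(-6, 6, length.out = 8), -14, 0.5)
  ig <- cbind(seq(-6, 6, length.out = 8), 14, 0.5)
  obs <- obstacle_set(list(icosphere(3, 6)))
  lg <- predict_ligament("LCL", og, ig, obs, thickness = 2.2)
  expect_lt(max_penetration_depth(lg$solid$vertices, obs), 1e-6)
  expect_true(is_watertight(lg$solid))
})

test_that("solid volume tracks midsurface area times thickness", {
  og <- cbind(seq(0, 12, length.out = 6), 0, 0)
  ig <- cbind(seq(0, 12, length.out = 6), 25, 0)
  lg <- predict_ligament("ALL", og, ig, thickness = 1.5)
  G <- wrap_grid_nodes(lg$midsurface)
  nr <- dim(G)[1]; nc <- dim(G)[2]
  area <- 0
  for (r in seq_len(nr - 1)) for (c in seq_len(nc - 1)) {
    d1 <- G[r + 1, c, ] - G[r, c, ]
    d2 <- G[r, c + 1, ] - G[r, c, ]
    d3 <- G[r + 1, c + 1, ] - G[r, c + 1, ]
    area <- area + sqrt(sum(pracma::cross(d1, d2)^2)) / 2 +
      sqrt(sum(pracma::cross(d3, d2)^2)) / 2
  }
  expect_lt(abs(mesh_volume(lg$solid) - area * 1.5) / (area * 1.5), 0.05)
})

test_that("one-point attachments reduce to a wrapped tube of the thickness", {
  lg <- predict_ligament("POL", matrix(c(0, 0, 0), 1), matrix(c(0, 30, 0), 1),
                         thickness = 1.0)
  expect_true(is_watertight(lg$solid))
  # tube radius = thickness/2 around a straight chain
  v <- lg$solid$vertices
  r <- sqrt(v[, 1]^2 + v[, 3]^2)
  expect_lt(max(r) - 0.5, 1e-6)
  expect_gte(wrap_length(lg$midsurface), 30 - 1e-9)
})

test_that("opposed attachment curve orientations are auto-reversed", {
  og <- cbind(seq(0, 10, length.out = 5), 0, 0)
  ig <- cbind(seq(10, 0, length.out = 5), 30, 0)  # reversed direction
  lg <- predict_ligament("OPL", og, ig, thickness = 1.44)
  G <- wrap_grid_nodes(lg$midsurface)
  # fibres must run parallel, not cross: column x-positions align
  expect_lt(max(abs(G[1, , 1] - G[dim(G)[1], , 1])), 1e-6)
})

test_that("the patellar tendon sleeve reproduces cylinders and frustums", {
  th <- 2 * pi * (0:23) / 24
  o <- cbind(5 * cos(th), 5 * sin(th), 0)
  i <- cbind(5 * cos(th + 0.2), 5 * sin(th + 0.2), 40)
  pt <- predict_patellar_tendon(o, i)
  v <- pt$solid$vertices
  r <- sqrt(v[, 1]^2 + v[, 2]^2)
  expect_lt(max(abs(r - 5)) / 5, 0.01)
  expect_equal(range(v[, 3]), c(0, 40), tolerance = 1e-9)
  expect_true(is.na(pt$spec$thickness))  # thickness inherent, not assigned

  i2 <- cbind(3 * cos(th), 3 * sin(th), 40)
  pt2 <- predict_patellar_tendon(o, i2)
  v2 <- pt2$solid$vertices
  mid <- abs(v2[, 3] - 20) < 1
  expect_lt(abs(mean(sqrt(v2[mid, 1]^2 + v2[mid, 2]^2)) - 4) / 4, 0.02)

  # opposite loop orientation is fixed automatically
  i3 <- i[nrow(i):1, ]
  pt3 <- predict_patellar_tendon(o, i3)
  r3 <- sqrt(pt3$solid$vertices[, 1]^2 + pt3$solid$vertices[, 2]^2)
  expect_lt(max(abs(r3 - 5)) / 5, 0.01)

  expect_error(predict_patellar_tendon(o[1:2, ], i), "at least 3")
})

test_that("sleeve fibres wrap around an interposed obstacle", {
  th <- 2 * pi * (0:23) / 24
  o <- cbind(4 * cos(th), 4 * sin(th) - 1, -25)
  i <- cbind(4 * cos(th), 4 * sin(th) - 1, 25)
  obs <- obstacle_set(list(icosphere(3, 8)))
  pt <- predict_patellar_tendon(o, i, obs)
  expect_lt(max_penetration_depth(pt$solid$vertices, obs), 1e-6)
})
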