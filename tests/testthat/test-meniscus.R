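test_that("cross-section triangles follow the height/width construction", {
  tri <- cross_section_triangle(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1),
                                height = 2, width = 3)
  expect_equal(unname(tri), rbind(c(3, 0, 0), c(0, 0, 1), c(0, 0, -1)))
  # area = h*d/2
  area <- sqrt(sum(pracma::cross(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])^2)) / 2
  expect_equal(area, 3)
  # rigid equivariance
  th <- 0.8
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tri2 <- cross_section_triangle(as.numeric(R %*% c(0, 0, 0)),
                                 as.numeric(R %*% c(1, 0, 0)),
                                 as.numeric(R %*% c(0, 0, 1)), 2, 3)
  expect_equal(unname(tri2), unname(tri %*% t(R)), tolerance = 1e-12)
  expect_error(cross_section_triangle(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0), 2, 3),
               "orthonormal")
})

test_that("the meniscal center is the planar arc-length centroid", {
  th <- seq(0, pi, length.out = 101)
  semi <- cbind(8 * cos(th), 8 * sin(th), 2)
  cen <- meniscal_center(semi)
  # analytic semicircle arc centroid: (0, 2R/pi) in-plane
  expect_lt(sqrt(sum((cen$center - c(0, 16 / pi, 2))^2)), 0.05 * 8)
  expect_equal(abs(cen$plane_normal[3]), 1, tolerance = 1e-9)

  # symmetric C-shape: center on the symmetry plane
  thc <- seq(-2, 2, length.out = 80)
  cshape <- cbind(6 * cos(thc), 6 * sin(thc), 0)
  expect_lt(abs(meniscal_center(cshape)$center[2]), 1e-6)

  expect_error(meniscal_center(cbind(0:9, 0, 0)), "collinear")
  expect_error(meniscal_center(rbind(c(0, 0, 0), c(1, 0, 0))), "at least 3")
})

# a broad flat "plateau" (flattened sphere) used as the tibial analog
flat_plateau <- function() icosphere(3, 1) |>
  (function(m) { m$vertices <- m$vertices %*% diag(c(40, 40, 2)); m })()

test_that("constant profiles yield the prescribed wedge cross-sections", {
  disk <- flat_plateau()
  obs <- obstacle_set(list(disk))
  topz <- function(x, y) 2 * sqrt(max(0, 1 - (x / 40)^2 - (y / 40)^2))
  a <- c(-14, 3, topz(-14, 3))
  b <- c(14, 3, topz(14, 3))
  hp <- polynomial_profile(c(4))
  wp <- polynomial_profile(c(8))
  men <- build_meniscus(obs, a, b, hp, wp, n_nodes = 40,
                        center = c(0, -15, 4), up_hint = c(0, 0, 1))
  expect_true(is_watertight(men$surface))
  v <- men$surface$vertices
  stations <- round(seq(5, 35, length.out = 10))
  for (i in stations) {
    apex <- v[(i - 1) * 3 + 1, ]
    top <- v[(i - 1) * 3 + 2, ]
    bot <- v[(i - 1) * 3 + 3, ]
    expect_lt(abs(sqrt(sum((top - bot)^2)) - 4) / 4, 0.02)
    node <- (top + bot) / 2
    expect_lt(abs(sqrt(sum((apex - node)^2)) - 8) / 8, 0.02)
  }
})

test_that("a degenerate height profile still builds, with a warning", {
  disk <- flat_plateau()
  obs <- obstacle_set(list(disk))
  hp0 <- polynomial_profile(c(0.0))
  wp <- polynomial_profile(c(6))
  expect_warning(
    men <- build_meniscus(obs, c(-12, 2, 2), c(12, 2, 2), hp0, wp,
                          n_nodes = 30, center = c(0, -15, 2)),
    "degenerate")
  expect_true(is_watertight(men$surface))
})

test_that("penetration correction clears a pressing femoral obstacle", {
  disk <- flat_plateau()
  ball <- icosphere(3, 9)
  ball$vertices <- sweep(ball$vertices, 2, c(0, -4, -9.5))  # presses on the path
  obs <- obstacle_set(list(disk, ball))
  hp <- polynomial_profile(c(4))
  wp <- polynomial_profile(c(7))
  a <- closest_point(disk, c(-16, 2, 3))$point
  b <- closest_point(disk, c(16, 2, 3))$point
  men <- build_meniscus(obs, a, b, hp, wp, n_nodes = 50, center = c(0, -18, 2))
  expect_lt(max_penetration_depth(men$surface$vertices, obs), 1e-6)
  expect_true(is_watertight(men$surface))
  # centerline respects the h/2 offset from the femoral ball at its nodes
  dball <- vapply(seq_len(nrow(men$centerline$nodes)), function(i) {
    closest_point(ball, men$centerline$nodes[i, ])$distance
  }, numeric(1))
  expect_true(all(dball >= 2 - 1e-5))
})

test_that("doubling the station count changes the wedge volume by < 2%", {
  disk <- flat_plateau()
  obs <- obstacle_set(list(disk))
  hp <- polynomial_profile(c(4, 1, -1))
  wp <- polynomial_profile(c(7, 1))
  a <- closest_point(disk, c(-14, 3, 3))$point
  b <- closest_point(disk, c(14, 3, 3))$point
  men1 <- build_meniscus(obs, a, b, hp, wp, n_nodes = 40, center = c(0, -15, 3))
  men2 <- build_meniscus(obs, a, b, hp, wp, n_nodes = 80, center = c(0, -15, 3))
  v1 <- abs(mesh_volume(men1$surface))
  v2 <- abs(mesh_volume(men2$surface))
  expect_lt(abs(v2 - v1) / v1, 0.02)
})

test_that("wildly non-positive profiles are rejected", {
  disk <- flat_plateau()
  obs <- obstacle_set(list(disk))
  neg <- polynomial_profile(c(-3))
  expect_error(build_meniscus(obs, c(-12, 2, 2), c(12, 2, 2), neg,
                              polynomial_profile(c(6)), center = c(0, -15, 2)),
               "non-positive")
})
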