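sphere10 <- icosphere(3, 10)

test_that("a free chain is the straight segment", {
  r <- wrap_chain(c(-7, 2, 1), c(5, -3, 4), n_nodes = 50)
  d <- sqrt(sum((c(-7, 2, 1) - c(5, -3, 4))^2))
  expect_equal(wrap_length(r), d, tolerance = 1e-9)
  expect_true(r$converged)
})

test_that("taut chain around a sphere matches the great-circle length", {
  obs <- obstacle_set(list(sphere10))
  # anchors on the sphere at central angle pi/2
  r <- wrap_chain(c(10, 0, 0), c(0, 10, 0), obs, n_nodes = 200)
  ref <- 10 * pi / 2
  expect_lt(abs(wrap_length(r) - ref) / ref, 0.02)
  expect_true(all(diff(r$energy_trace) <= 1e-9))
  # near-half wrap, independent graph shortest-path oracle
  skip_if_not_installed("igraph")
  a <- c(10, 0, 0)
  b <- c(-10 * cos(0.2), 10 * sin(0.2), 0)
  r2 <- wrap_chain(a, b, obs, n_nodes = 200)
  ora <- oracle_graph_path_length(sphere10, a, b)
  expect_lt(abs(wrap_length(r2) - ora) / ora, 0.02)
})

test_that("doubling the chain resolution barely changes the length", {
  obs <- obstacle_set(list(sphere10))
  r1 <- wrap_chain(c(10, 0, 0), c(0, 10, 0), obs, n_nodes = 200)
  r2 <- wrap_chain(c(10, 0, 0), c(0, 10, 0), obs, n_nodes = 400)
  expect_lt(abs(wrap_length(r2) - wrap_length(r1)) / wrap_length(r1), 0.005)
})

test_that("chain length never undercuts the anchor distance", {
  obs <- obstacle_set(list(sphere10))
  set.seed(17)
  for (k in 1:5) {
    a <- c(10.0001, 0, 0)
    th <- runif(1, 0.5, pi - 0.3)
    b <- 10.0001 * c(cos(th), sin(th), 0)
    r <- wrap_chain(a, b, obs, n_nodes = 80)
    expect_gte(wrap_length(r) + 1e-9, sqrt(sum((a - b)^2)))
    expect_true(all(diff(r$energy_trace) <= 1e-9))
  }
})

test_that("offset chains respect the per-node clearance, reducing to
           wrap_chain at zero offset", {
  obs <- obstacle_set(list(sphere10))
  a <- c(10, 0, 0); b <- c(0, 10, 0)
  r0 <- wrap_chain(a, b, obs, n_nodes = 100)
  rz <- wrap_chain_offset(a, b, obs, n_nodes = 100,
                          offset_profile = rep(0, 100))
  expect_equal(r0$nodes, rz$nodes)

  # anchors lifted so the constant offset is feasible at the ends too
  c_off <- 1.5
  a2 <- c(11.5, 0, 0); b2 <- c(0, 11.5, 0)
  rc <- wrap_chain_offset(a2, b2, obs, n_nodes = 120,
                          offset_profile = rep(c_off, 120))
  # clearance is exact w.r.t. the obstacle surface; the distance to the
  # sphere center additionally reflects facet inscription
  sd <- vapply(seq_len(120), function(i) {
    closest_point(sphere10, rc$nodes[i, ])$distance
  }, numeric(1))
  expect_true(all(sd >= c_off - 1e-6))
  contact <- sd < c_off + 1e-3
  expect_true(any(contact))
  dists <- sqrt(rowSums(rc$nodes^2))
  expect_true(all(dists[contact] <= 10 + c_off + 1e-6))
  expect_true(all(dists[contact] >= 10 * cos(0.13) + c_off - 1e-6))

  expect_error(wrap_chain_offset(c(0, 0, 0), c(20, 0, 0), obs, 50,
                                 offset_profile = rep(1, 50)),
               "inside obstacle")
})

test_that("no converged node penetrates any obstacle beyond tolerance", {
  obs <- obstacle_set(list(sphere10, icosphere(2, 4)))
  r <- wrap_chain(c(10, 0, 0), c(-10, 0.5, 0), obs, n_nodes = 150)
  expect_lt(max_penetration_depth(r$nodes, obs), 1e-6)
})

test_that("membranes stay planar in free space and clear obstacles", {
  oc <- cbind(seq(0, 10, length.out = 6), 0, 0)
  ic <- cbind(seq(0, 10, length.out = 6), 30, 0)
  m <- wrap_membrane(oc, ic, n_rows = 12)
  G <- wrap_grid_nodes(m)
  expect_lt(max(abs(G[, , 3])), 1e-9)
  expect_true(all(diff(m$energy_trace) <= 1e-9))

  # curves bracketing a sphere (cylinder analog): clearance at every node
  obs <- obstacle_set(list(icosphere(2, 5)))
  oc2 <- cbind(seq(-6, 6, length.out = 8), -12, 0.5)
  ic2 <- cbind(seq(-6, 6, length.out = 8), 12, 0.5)
  m2 <- wrap_membrane(oc2, ic2, obs, n_rows = 20)
  expect_lt(max_penetration_depth(m2$nodes, obs), 1e-6)

  expect_error(wrap_membrane(rbind(c(0, 0, 0)), rbind(c(0, 1, 0))), "at least 2")
  expect_error(wrap_membrane(oc, ic[1:3, ]), "same number")
})

test_that("project_out moves interior points to the surface, idempotently", {
  obs <- obstacle_set(list(sphere10))
  p <- project_out(c(0, 0, 0), obs)
  # lands exactly on the (faceted) sphere surface
  expect_lt(closest_point(sphere10, p)$distance, 1e-9)
  expect_gt(sqrt(sum(p^2)), 10 * cos(0.13))
  outp <- c(30, -2, 5)
  expect_equal(project_out(outp, obs), outp)
  pts <- runif_pts(60, -12, 12, seed = 51)
  once <- project_out(pts, obs)
  twice <- project_out(once, obs)
  expect_equal(twice, once)
  expect_lt(max_penetration_depth(once, obs), 1e-6)
})

test_that("obstacle sets validate watertightness and inflation", {
  expect_error(obstacle_set(list(flat_grid_mesh(3))), "watertight")
  expect_error(obstacle_set(list(sphere10), inflation = -1), ">= 0")
  obs <- obstacle_set(list(sphere10), inflation = 2)
  p <- project_out(c(11, 0, 0), obs)
  expect_equal(sqrt(sum(p^2)), 12, tolerance = 1e-9)
})
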