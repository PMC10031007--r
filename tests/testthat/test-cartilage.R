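test_that("thickness between concentric spheres is the shell width", {
  bone <- icosphere(3, 10)
  cart <- icosphere(3, 11)
  tm <- compute_thickness(bone, cart, seq_len(n_vertices(bone)))
  expect_lt(max(abs(tm$values - 1)), 1e-3)
  expect_length(tm$edge_indices, 0)  # closed region has no boundary

  same <- compute_thickness(bone, bone, seq_len(n_vertices(bone)))
  expect_true(all(same$values == 0))
})

test_that("a prescribed smooth field is recovered exactly (construct-recover)", {
  bone <- icosphere(3, 10)
  nrm <- vertex_normals(bone)
  t_field <- 0.8 + 0.4 * sin(bone$vertices[, 3] / 4)
  cart <- bone
  cart$vertices <- bone$vertices + t_field * nrm
  tm <- compute_thickness(bone, cart, seq_len(n_vertices(bone)))
  expect_lt(max(abs(tm$values - t_field)), 1e-6)
})

test_that("edge sealing zeroes exactly the region boundary, idempotently", {
  g <- flat_grid_mesh(7)  # 7x7 grid, use interior 5x5 block as region
  region <- which(g$vertices[, 1] >= 2 & g$vertices[, 1] <= 6 &
                    g$vertices[, 2] >= 2 & g$vertices[, 2] <= 6)
  edges <- region_edges(g, region)
  # boundary ring of the 5x5 block: those not in the inner 3x3
  inner <- which(g$vertices[, 1] >= 3 & g$vertices[, 1] <= 5 &
                   g$vertices[, 2] >= 3 & g$vertices[, 2] <= 5)
  expect_setequal(edges, setdiff(region, inner))
  tm <- thickness_map("femur", region, rep(1, length(region)),
                      edge_indices = edges, reference_length = 400)
  sealed <- seal_edges(tm)
  expect_true(all(sealed$values[match(edges, region)] == 0))
  expect_true(all(sealed$values[match(inner, region)] == 1))
  expect_identical(seal_edges(sealed), sealed)

  # region covering a closed component: no edges, map unchanged
  s <- icosphere(2, 5)
  expect_length(region_edges(s, seq_len(n_vertices(s))), 0)
})

test_that("mean_map normalizes by femoral length before averaging", {
  region <- 1:10
  mk <- function(vals, len) thickness_map("femur", region, vals,
                                          reference_length = len)
  a <- mk(rep(1, 10), 420)
  expect_equal(mean_map(list(a, a, a))$values, a$values)

  b <- mk(rep(2, 10), 420)
  expect_equal(mean_map(list(a, b))$values, rep(1.5, 10))

  # values proportional to length: normalized maps identical
  lens <- c(400, 440, 420)
  base <- seq(0.5, 2.3, length.out = 10)
  maps <- lapply(lens, function(L) mk(base * L / 420, L))
  mm <- mean_map(maps)
  expect_equal(mm$reference_length, 420)
  expect_lt(max(abs(mm$values - base)), 1e-9)

  # permutation invariance
  expect_equal(mean_map(maps[c(3, 1, 2)])$values, mm$values)
  expect_error(mean_map(list(a, mk(rep(1, 10), NA))), "reference_length")
})

test_that("femoral length is landmark-based, rigid and homogeneous", {
  tpl <- synthetic_knee_template(2)
  L <- femoral_length(tpl$femur, tpl$landmarks)
  expect_equal(L, tpl$femoral_length)
  th <- 0.6
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  rot <- tpl$femur
  rot$vertices <- tpl$femur$vertices %*% t(R)
  expect_equal(femoral_length(rot, tpl$landmarks), L, tolerance = 1e-12)
  big <- tpl$femur
  big$vertices <- tpl$femur$vertices * 1.1
  expect_equal(femoral_length(big, tpl$landmarks), 1.1 * L, tolerance = 1e-12)
})

test_that("prediction displaces along normals and scales linearly", {
  bone <- icosphere(3, 10)
  region <- seq_len(n_vertices(bone))
  tm <- thickness_map("femur", region, rep(1, length(region)),
                      reference_length = 100)
  cart <- predict_cartilage(bone, tm, target_length = 100)
  # displacement is exactly 1 mm along each vertex normal; the radius is 11
  # up to the (sub-1e-4) angle between mesh normals and the radial direction
  disp <- sqrt(rowSums((cart$vertices - bone$vertices)^2))
  expect_lt(max(abs(disp - 1)), 1e-12)
  expect_lt(max(abs(sqrt(rowSums(cart$vertices^2)) - 11)), 1e-4)
  cart2 <- predict_cartilage(bone, tm, target_length = 110)
  expect_lt(max(abs(sqrt(rowSums(cart2$vertices^2)) - 11.1)), 1e-4)
  # never moves a vertex inward
  expect_true(all(rowSums((cart$vertices - bone$vertices) *
                            vertex_normals(bone)) >= -1e-12))
})

test_that("predict/measure round trip recovers the scaled map", {
  tpl <- synthetic_knee_template(3)
  reg <- tpl$regions$femoral
  tm <- thickness_map("femur", reg$indices, tpl$truth_fields$femoral,
                      edge_indices = region_edges(tpl$femur, reg$indices),
                      reference_length = tpl$femoral_length)
  tm <- seal_edges(tm)
  cart <- predict_cartilage(tpl$femur, tm, target_length = 1.1 * tpl$femoral_length)
  back <- compute_thickness(tpl$femur, cart, reg$indices)
  expect_lt(max(abs(back$values - 1.1 * tm$values)), 1e-6)
})

test_that("relative error maps guard the sealed-edge floor", {
  tm <- thickness_map("femur", 1:4, c(1, 2, 0.01, 0), reference_length = 400)
  rel <- relative_error_map(c(0.5, 0.5, 0.5, 0.5), tm)
  expect_equal(rel[1:2], c(0.5, 0.25))
  expect_true(all(is.na(rel[3:4])))
  expect_equal(relative_error_map(rep(0, 4), tm)[1:2], c(0, 0))
  expect_error(relative_error_map(c(1, 2), tm), "match")
})

test_that("thickness map CSV+JSON round trip", {
  tm <- thickness_map("patella", c(2L, 5L, 9L), c(0.5, 1.25, 0),
                      edge_indices = 9L, reference_length = 431.5,
                      region_name = "patellar")
  p <- withr::local_tempfile(fileext = ".csv")
  write_thickness_map(tm, p)
  tm2 <- read_thickness_map(p)
  expect_equal(tm2$values, tm$values)
  expect_identical(tm2$region, tm$region)
  expect_identical(tm2$edge_indices, tm$edge_indices)
  expect_equal(tm2$reference_length, tm$reference_length)
})
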