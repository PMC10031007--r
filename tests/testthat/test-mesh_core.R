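test_that("mesh construction enforces the corresponded-mesh invariants", {
  v <- diag(3)
  expect_error(knee_mesh(v, rbind(c(1, 2, 4))), "outside")
  expect_error(knee_mesh(v, rbind(c(1, 1, 2))), "degenerate")
  expect_error(knee_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3)),
               "empty")
  m <- knee_mesh(v, rbind(c(1, 2, 3)), bone_label = "patella", case_id = "t")
  expect_identical(n_vertices(m), 3L)
  expect_identical(n_faces(m), 1L)
})

test_that("PLY read handles a minimal closed mesh and flags bad indices", {
  p <- withr::local_tempfile(fileext = ".ply")
  writeLines(tetra_ply_lines(), p)
  m <- read_mesh(p)
  expect_equal(n_vertices(m), 4L)
  expect_equal(n_faces(m), 4L)
  expect_true(is_watertight(m))
  writeLines(tetra_ply_lines(bad_face_index = TRUE), p)
  expect_error(read_mesh(p), "outside")
})

test_that("write/read round trips preserve coordinates and connectivity", {
  m <- icosphere(2, 7.5)
  for (ext in c(".ply", ".obj")) {
    p <- withr::local_tempfile(fileext = ext)
    write_mesh(m, p)
    m2 <- read_mesh(p)
    expect_lt(max(abs(m2$vertices - m$vertices)), 1e-6)
    expect_identical(m2$faces, m$faces)
  }
  # STL loses shared vertices; merge must restore counts on a clean mesh
  p <- withr::local_tempfile(fileext = ".stl")
  write_mesh(m, p)
  m3 <- read_mesh(p)
  expect_equal(n_vertices(m3), n_vertices(m))
  expect_equal(n_faces(m3), n_faces(m))
})

test_that("vertex normals are radial on a sphere, exact on a plane, and
           match angle-weighted accumulation at a cube corner", {
  s <- icosphere(3, 10)
  vn <- vertex_normals(s)
  ang <- acos(pmin(1, rowSums(vn * s$vertices / 10)))
  expect_lt(max(ang) * 180 / pi, 1)

  g <- flat_grid_mesh(5)
  gn <- vertex_normals(g)
  expect_equal(gn, matrix(rep(c(0, 0, 1), each = 25), 25, 3))

  cube <- unit_cube_mesh()
  cn <- vertex_normals(cube)
  # independent accumulation at vertex 1 = (0,0,0)
  fn <- face_normals(cube)
  acc <- c(0, 0, 0)
  for (f in seq_len(nrow(cube$faces))) {
    k <- match(1L, cube$faces[f, ])
    if (is.na(k)) next
    others <- cube$faces[f, -k]
    e1 <- cube$vertices[others[1], ] - cube$vertices[1, ]
    e2 <- cube$vertices[others[2], ] - cube$vertices[1, ]
    w <- acos(sum(e1 * e2) / sqrt(sum(e1^2) * sum(e2^2)))
    acc <- acc + w * fn[f, ]
  }
  acc <- acc / sqrt(sum(acc^2))
  expect_equal(unname(cn[1, ]), unname(acc), tolerance = 1e-12)
})

test_that("closest_point matches the exhaustive all-triangle oracle", {
  s <- icosphere(2, 10)
  q <- runif_pts(100, -15, 15, seed = 11)
  for (i in seq_len(nrow(q))) {
    got <- closest_point(s, q[i, ])
    ora <- oracle_closest(s, q[i, ])
    expect_lt(abs(got$distance - ora$distance), 1e-12)
    # the returned face must achieve the minimum
    expect_lt(ora$all[got$face_index] - ora$distance, 1e-12)
    # unique minimisers must agree exactly
    if (sort(ora$all)[2] - ora$distance > 1e-9) {
      expect_identical(got$face_index, ora$face)
    }
  }
  # on-vertex query
  onv <- closest_point(s, s$vertices[5, ])
  expect_equal(onv$distance, 0)
  expect_equal(onv$point, s$vertices[5, ])
})

test_that("is_inside agrees with a 3-ray parity oracle and handles bands", {
  s <- icosphere(2, 10)
  q <- runif_pts(1000, -14, 14, seed = 21)
  d <- vapply(seq_len(nrow(q)), function(i) closest_point(s, q[i, ])$distance,
              numeric(1))
  keep <- d > 1e-3  # skip the on-surface tolerance band
  got <- is_inside(s, q[keep, , drop = FALSE])
  ora <- vapply(which(keep), function(i) oracle_inside_parity(s, q[i, ]),
                logical(1))
  expect_identical(unname(got), unname(ora))
  expect_true(is_inside(s, c(0, 0, 0)))
  expect_false(is_inside(s, c(0, 0, 100)))
  expect_error(is_inside(flat_grid_mesh(3), c(0, 0, 0)), "watertight")
})

test_that("vertex normals rotate with the mesh (rigid equivariance)", {
  s <- icosphere(2, 5)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  s2 <- s
  s2$vertices <- s$vertices %*% t(R)
  expect_lt(max(abs(vertex_normals(s2) - vertex_normals(s) %*% t(R))), 1e-9)
})

test_that("splines interpolate, measure arc length, and stay monotone", {
  # two points: straight segment
  sp <- fit_spline(rbind(c(0, 0, 0), c(3, 4, 0)))
  expect_equal(spline_length(sp), 5, tolerance = 1e-9)
  expect_equal(spline_eval(sp, 0)[1, ], c(0, 0, 0))

  # closed circle: arc length within 0.1% of the circumference
  th <- 2 * pi * (0:63) / 64
  circ <- fit_spline(cbind(5 * cos(th), 5 * sin(th), 0), closed = TRUE)
  expect_equal(spline_length(circ), 10 * pi, tolerance = 1e-3)

  # arc length is additive and monotone in t
  tt <- seq(0, 1, by = 0.1)
  lens <- vapply(tt, function(t1) spline_length(circ, 0, t1, n = 512),
                 numeric(1))
  expect_true(all(diff(lens) > 0))
  expect_equal(lens[11], spline_length(circ, 0, 0.5, n = 512) +
                 spline_length(circ, 0.5, 1, n = 512), tolerance = 1e-4)

  expect_error(fit_spline(rbind(c(0, 0, 0))), "at least")
  expect_error(fit_spline(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))),
               "coincident")
})
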