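test_that("frames match the analytic circle and helix frames", {
  th <- 2 * pi * (0:63) / 64
  circ <- cbind(10 * cos(th), 10 * sin(th), 0)
  fr <- estimate_frames(circ)
  # normals point toward the circle center within 1 degree
  inward <- -cbind(cos(th), sin(th), 0)
  ang <- acos(pmin(1, abs(rowSums(fr$normal * inward))))
  expect_lt(max(ang[2:63]) * 180 / pi, 1)

  # helix with known torsion: frame rotation about the tangent matches
  tt <- seq(0, 4 * pi, length.out = 256)
  r <- 5; c_ <- 2
  helix <- cbind(r * cos(tt), r * sin(tt), c_ * tt)
  frh <- estimate_frames(helix)
  inward_h <- -cbind(cos(tt), sin(tt), 0)
  angh <- acos(pmin(1, abs(rowSums(frh$normal * inward_h))))
  expect_lt(max(angh[5:250]) * 180 / pi, 2)
  # binormal z-component is constant r/sqrt(r^2+c^2) for a helix
  bz <- abs(frh$binormal[5:250, 3])
  expect_lt(max(abs(bz - r / sqrt(r^2 + c_^2))) / (r / sqrt(r^2 + c_^2)), 0.02)
})

test_that("straight centerlines fall back to parallel transport without flips", {
  line <- cbind(0, 0, seq(0, 20, length.out = 30))
  fr <- estimate_frames(line)
  expect_lt(max(abs(sweep(fr$normal, 2, fr$normal[1, ]))), 1e-9)
  expect_lt(max(abs(sweep(fr$tangent, 2, c(0, 0, 1)))), 1e-9)
  expect_error(estimate_frames(rbind(c(0, 0, 0), c(0, 0, 0))), "duplicated")
})

test_that("frames are orthonormal and continuous on general centerlines", {
  set.seed(61)
  tt <- seq(0, 1, length.out = 100)
  P <- cbind(30 * tt, 8 * sin(2 * pi * tt), 5 * cos(3 * pi * tt))
  fr <- estimate_frames(P)
  for (M in fr) expect_lt(max(abs(rowSums(M^2) - 1)), 1e-9)
  expect_lt(max(abs(rowSums(fr$tangent * fr$normal))), 1e-9)
  # no flips: successive normals within 90 degrees
  dots <- rowSums(fr$normal[-1, ] * fr$normal[-100, ])
  expect_true(all(dots > 0))
})

test_that("straight tubes reproduce cylinders and frustums exactly", {
  line <- cbind(0, 0, seq(0, 30, length.out = 20))
  cyl <- build_tube(line, rep(2, 20), 32)
  rr <- sqrt(cyl$surface$vertices[, 1]^2 + cyl$surface$vertices[, 2]^2)
  ring_v <- seq_len(20 * 32)  # exclude cap apices
  expect_lt(max(abs(rr[ring_v] - 2)), 1e-9)
  expect_true(is_watertight(cyl$surface))
  # lateral surface area + caps within 1% at 64 segments
  cyl64 <- build_tube(line, rep(2, 20), 64)
  area <- sum(sqrt(rowSums(pracma::cross(
    cyl64$surface$vertices[cyl64$surface$faces[, 2], ] -
      cyl64$surface$vertices[cyl64$surface$faces[, 1], ],
    cyl64$surface$vertices[cyl64$surface$faces[, 3], ] -
      cyl64$surface$vertices[cyl64$surface$faces[, 1], ])^2))) / 2
  expect_lt(abs(area - (2 * pi * 2 * 30 + 2 * pi * 4)) / (2 * pi * 2 * 30 + 2 * pi * 4),
            0.01)

  fru <- build_tube(line, seq(1, 3, length.out = 20), 32)
  rrf <- sqrt(fru$surface$vertices[ring_v, 1]^2 + fru$surface$vertices[ring_v, 2]^2)
  expect_lt(max(abs(rrf - rep(seq(1, 3, length.out = 20), each = 32))), 1e-9)
})

test_that("a closed circular centerline builds a torus with the right volume", {
  th <- 2 * pi * (0:95) / 96
  cl <- cbind(10 * cos(th), 10 * sin(th), 0)
  tor <- build_tube(cl, rep(1, 96), 48, closed = TRUE)
  expect_true(is_watertight(tor$surface))
  # every vertex at distance 1 from the centerline circle
  d_axis <- abs(sqrt(tor$surface$vertices[, 1]^2 + tor$surface$vertices[, 2]^2) - 10)
  d_cl <- sqrt(d_axis^2 + tor$surface$vertices[, 3]^2)
  expect_lt(max(abs(d_cl - 1)), 1e-6)
  expect_lt(abs(mesh_volume(tor$surface) - 2 * pi^2 * 10) / (2 * pi^2 * 10), 0.01)
})

test_that("tube building is equivariant under rigid motion", {
  set.seed(71)
  tt <- seq(0, 1, length.out = 25)
  P <- cbind(20 * tt, 5 * sin(2 * pi * tt), 0)
  t1 <- build_tube(P, seq(1, 2, length.out = 25), 16)
  th <- 0.9
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  shift <- c(3, -4, 7)
  t2 <- build_tube(sweep(P %*% t(R), 2, -shift), seq(1, 2, length.out = 25), 16)
  expect_lt(max(abs(sweep(t1$surface$vertices %*% t(R), 2, -shift) -
                      t2$surface$vertices)), 1e-9)
})

test_that("radius profiles evaluate, floor, and flag degenerate stations", {
  const <- polynomial_profile(c(2.5))
  expect_equal(radius_profile_from_polynomial(const, 7), rep(2.5, 7))
  quad <- polynomial_profile(c(1, 1, -1))
  expect_equal(radius_profile_from_polynomial(quad, 3),
               1 + c(0, 0.5, 1) - c(0, 0.5, 1)^2)
  dipping <- polynomial_profile(c(0.05, 2))  # below floor at s = 0
  expect_warning(r <- radius_profile_from_polynomial(dipping, 10), "floored")
  expect_equal(r[1], 0.1)
  neg <- polynomial_profile(c(-1))
  expect_error(radius_profile_from_polynomial(neg, 5), "non-positive")
  expect_error(build_tube(cbind(0, 0, 0:3), c(1, 1, -1, 1)), "> 0")
})
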