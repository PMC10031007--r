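test_that("the three metrics follow their formulas on fixed distances", {
  rep1 <- distance_report(c(3, 4))
  expect_equal(rep1$asd, 3.5)
  expect_equal(rep1$rmse, sqrt(12.5))
  expect_equal(rep1$hd, 4)
  expect_identical(rep1$n, 2L)
  expect_error(distance_report(numeric(0)), "no distances")
  expect_error(distance_report(c(1, -1)), ">= 0")
})

test_that("point-to-set comparison matches a brute-force scan", {
  set.seed(81)
  pred <- matrix(rnorm(600), 200, 3)
  ref <- matrix(rnorm(600), 200, 3)
  rep1 <- compare_points_to_surface(pred, ref)
  ora <- vapply(seq_len(200), function(i) {
    sqrt(min(colSums((t(pred) - ref[i, ])^2)))
  }, numeric(1))
  expect_lt(max(abs(rep1$distances - ora)), 1e-12)
  expect_lt(abs(rep1$rmse - sqrt(mean(ora^2))), 1e-12)
  expect_lt(abs(rep1$asd - mean(ora)), 1e-12)
  expect_lt(abs(rep1$hd - max(ora)), 1e-12)

  ident <- compare_points_to_surface(ref, ref)
  expect_equal(ident$hd, 0)
})

test_that("asd <= rmse <= hd on every report (power-mean ordering)", {
  set.seed(82)
  for (k in 1:20) {
    rep1 <- distance_report(rexp(50))
    expect_lte(rep1$asd, rep1$rmse + 1e-12)
    expect_lte(rep1$rmse, rep1$hd + 1e-12)
  }
})

test_that("metrics are invariant under a common rigid motion", {
  set.seed(83)
  pred <- matrix(rnorm(150), 50, 3)
  ref <- matrix(rnorm(150), 50, 3)
  th <- 1.1
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  shift <- c(5, -2, 9)
  a <- compare_points_to_surface(pred, ref)
  b <- compare_points_to_surface(sweep(pred %*% t(R), 2, -shift),
                                 sweep(ref %*% t(R), 2, -shift))
  expect_equal(a$rmse, b$rmse, tolerance = 1e-9)
  expect_equal(a$hd, b$hd, tolerance = 1e-9)
})

test_that("thickness-map comparison works in value space", {
  region <- 1:30
  mk <- function(vals) thickness_map("femur", region, vals, reference_length = 420)
  a <- mk(seq(0.5, 3, length.out = 30))
  expect_equal(compare_thickness_maps(a, a)$hd, 0)
  b <- mk(a$values + 0.3)
  cmp <- compare_thickness_maps(b, a)
  expect_equal(cmp$asd, 0.3, tolerance = 1e-12)
  expect_equal(cmp$rmse, 0.3, tolerance = 1e-12)
  expect_equal(cmp$hd, 0.3, tolerance = 1e-12)
  set.seed(84)
  pert <- abs(rnorm(30, sd = 0.2))
  cmp2 <- compare_thickness_maps(mk(a$values + pert), a)
  expect_lt(abs(cmp2$rmse - sqrt(mean(pert^2))), 1e-12)
  expect_error(compare_thickness_maps(a, thickness_map("femur", 1:5, rep(1, 5))),
               "different regions")
})

test_that("leave-one-out reduces correctly in degenerate and noisy cohorts", {
  region <- 1:50
  mk <- function(vals, len = 420) thickness_map("femur", region, vals,
                                                reference_length = len)
  same <- replicate(4, list(map = mk(seq(1, 2, length.out = 50))))
  res <- leave_one_out(
    lapply(seq_len(4), function(i) list(map = mk(seq(1, 2, length.out = 50)))),
    builder = function(train) mean_map(lapply(train, `[[`, "map")),
    predictor = function(model, case) model,
    comparator = function(pred, case) compare_thickness_maps(pred, case$map))
  expect_true(all(res$pooled$median == 0))
  expect_error(leave_one_out(list(1), identity, identity, identity),
               "at least 2")
})

test_that("LOO error of a mean under i.i.d. noise matches the closed form", {
  n <- 20
  sigma <- 0.1
  rmses <- c()
  for (seed in 1:3) {
    cohort <- generate_cohort(n, seed = seed, thickness_noise_sd = sigma,
                              subdiv = 3)
    res <- leave_one_out(
      cohort,
      builder = function(train) mean_map(lapply(train, function(cs) cs$maps$femoral)),
      predictor = function(model, case) {
        scl <- case$femoral_length / model$reference_length
        thickness_map(model$bone_label, model$region, model$values * scl,
                      reference_length = case$femoral_length)
      },
      comparator = function(pred, case) compare_thickness_maps(pred, case$maps$femoral))
    rmses <- c(rmses, vapply(res$per_case, `[[`, numeric(1), "rmse"))
  }
  expected <- sigma * sqrt(n / (n - 1))
  expect_lt(abs(mean(rmses) - expected) / expected, 0.1)
})

test_that("pointwise error maps average magnitudes across cases", {
  expect_equal(pointwise_error_map(list(c(1, 2), c(3, 0))), c(2, 1))
  expect_equal(pointwise_error_map(list(c(1, 2))), c(1, 2))
  e <- list(a = c(1, 5), b = c(3, 1), c = c(2, 3))
  expect_equal(pointwise_error_map(e), pointwise_error_map(rev(e)))
  expect_error(pointwise_error_map(list(1:2, 1:3)), "length")
})
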