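test_that("growth fit recovers exact logarithmic data to machine precision", {
  age <- c(1, 2, 3, 5, 8)
  pts <- data.frame(age_months = age, volume_mm3 = 500 + 300 * log(age + 1))
  g <- fit_growth_curve(pts)
  expect_equal(g$a, 500, tolerance = 1e-12)
  expect_equal(g$b, 300, tolerance = 1e-12)
  expect_equal(g$r_squared, 1, tolerance = 1e-12)
})

test_that("two cohort endpoint volumes give the implied growth rate", {
  # volumes 640 mm^3 at 1.7 months and 1184 mm^3 at 7.2 months
  pts <- data.frame(age_months = c(1.7, 7.2), volume_mm3 = c(640, 1184))
  g <- fit_growth_curve(pts)
  expect_equal(g$b, 544 / (log(8.2) - log(2.7)), tolerance = 1e-12)
  expect_equal(g$r_squared, 1)
})

test_that("degenerate growth inputs are handled per the documented conventions", {
  # constant volumes: zero growth rate, r^2 = 1 by convention
  g <- fit_growth_curve(data.frame(age_months = c(1, 4, 6), volume_mm3 = c(7, 7, 7)))
  expect_equal(g$b, 0)
  expect_equal(g$r_squared, 1)
  expect_error(fit_growth_curve(data.frame(age_months = 1, volume_mm3 = 5)),
               "at least 2")
  expect_error(fit_growth_curve(data.frame(age_months = c(3, 3), volume_mm3 = c(1, 2))),
               "singular")
  expect_error(fit_growth_curve(data.frame(age_months = c(-1, 3), volume_mm3 = c(1, 2))),
               "non-negative")
})

test_that("volume rescaling: identity, direct arithmetic and monotonicity", {
  g <- growth_model(a = 100, b = 300)
  expect_identical(rescale_volume(g, 800, 3, 3), 800)
  expect_equal(rescale_volume(g, 800, 3, 6), 800 + 300 * log(7 / 4),
               tolerance = 1e-12)
  expect_equal(800 + 300 * log(7 / 4), 967.8724, tolerance = 1e-4)
  expect_lt(rescale_volume(g, 800, 5, 2), 800)
})

test_that("volume rescaling is exactly transitive", {
  g <- growth_model(a = 154, b = 489.7)
  set.seed(31)
  for (i in 1:20) {
    ages <- sort(runif(3, 0, 10))
    V1 <- runif(1, 500, 1200)
    via <- rescale_volume(g, rescale_volume(g, V1, ages[1], ages[2]), ages[2], ages[3])
    direct <- rescale_volume(g, V1, ages[1], ages[3])
    expect_equal(via, direct, tolerance = 1e-12)
  }
})

test_that("mesh rescaling scales the enclosed control volume exactly", {
  m <- generate_calvarium()
  v0 <- surface_enclosed_volume(mesh_surface(m))
  expect_identical(rescale_mesh(m, 900, 900)$nodes, m$nodes)
  doubled <- rescale_mesh(m, 100, 800)           # volume ratio 8 -> dims x2
  expect_equal(max(doubled$nodes[, 3]), 2 * max(m$nodes[, 3]), tolerance = 1e-12)
  r <- rescale_mesh(m, 912, 1071)
  expect_equal(surface_enclosed_volume(mesh_surface(r)) / v0, 1071 / 912,
               tolerance = 1e-9)
  expect_error(rescale_mesh(m, -1, 5), "positive")
})

test_that("noiseless synthetic growth data refit reproduces the generator", {
  truth <- default_growth_model()
  pts <- generate_growth_points(24, truth, volume_sd_mm3 = 0, seed = 5)
  g <- fit_growth_curve(pts)
  expect_equal(g$a, truth$a, tolerance = 1e-9)
  expect_equal(g$b, truth$b, tolerance = 1e-9)
  # predicted volumes reproduce the generated ones to machine precision
  expect_equal(predict_volume(g, pts$age_months), pts$volume_mm3,
               tolerance = 1e-9)
})

test_that("growth refit with cohort noise recovers the growth curve", {
  truth <- default_growth_model()
  pts <- generate_growth_points(24, truth, volume_sd_mm3 = 40, seed = 2)
  g <- fit_growth_curve(pts)
  # the curve itself is recovered within 5% across the cohort age range;
  # the growth rate within the precision the noise level supports
  ages <- seq(2, 8, by = 0.5)
  expect_lt(max(abs(predict_volume(g, ages) / predict_volume(truth, ages) - 1)),
            0.05)
  expect_lt(abs(g$b - truth$b) / truth$b, 0.15)
  expect_gt(g$r_squared, 0.8)
})
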