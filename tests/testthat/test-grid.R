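test_that("grid stack construction validates coordinates and reshapes data", {
  expect_error(make_stack(matrix(1, 2, 2), lon = c(1, 1)), "monotone")
  s <- make_stack(matrix(1:6, 2, 3))
  expect_equal(dim(s$data), c(1, 2, 3))
  expect_output(print(s), "grid_stack")
})

test_that("grid stacks round-trip through long-format CSV", {
  set.seed(5)
  s <- make_stack_t(list(matrix(rnorm(12), 3, 4), matrix(rnorm(12), 3, 4)),
                    var = "temperature", units = "degC")
  s$data[1, 2, 2] <- NA
  f <- tempfile(fileext = ".csv")
  write_grid_csv(s, f)
  back <- read_grid_csv(f)
  expect_equal(back$data, s$data, tolerance = 1e-12)
  expect_identical(back$lon, s$lon)
  expect_identical(back$units, "degC")
  unlink(f)
})

test_that("coastal gap filling averages valid 8-neighbours and is idempotent", {
  m <- matrix(10, 3, 3); m[2, 2] <- NA
  filled <- fill_coastal_gaps(make_stack(m))
  expect_equal(filled$data[1, 2, 2], 10)

  m2 <- matrix(NA_real_, 3, 3); m2[1, 1] <- 1; m2[1, 3] <- 3
  f2 <- fill_coastal_gaps(make_stack(m2))
  expect_equal(f2$data[1, 1, 2], 2)        # mean of the two valid neighbours
  f3 <- fill_coastal_gaps(f2)
  expect_equal(f3$data, f2$data)           # idempotent once filled
  # original valid cells never modified
  expect_equal(f2$data[1, 1, 1], 1)
  expect_warning(fill_coastal_gaps(make_stack(matrix(NA_real_, 2, 2))), "masked")
})

test_that("bilinear refinement reproduces constants and linear ramps exactly", {
  cst <- resample_bilinear(make_stack(matrix(5, 4, 4)))
  expect_true(all(cst$data == 5))
  expect_equal(length(cst$lon), 8)
  expect_equal(mean(diff(cst$lon)), 0.5, tolerance = 1e-12)

  lonv <- seq(0.5, by = 1, length.out = 6)
  ramp <- make_stack(matrix(rep(2 * lonv, each = 4), 4, 6), lon = lonv)
  r <- resample_bilinear(ramp)
  # interior refined centres lie exactly on the ramp; edges clamp
  inner <- r$lon >= min(lonv) & r$lon <= max(lonv)
  expect_equal(matrix(r$data[1, , ], 8, 12)[4, inner], 2 * r$lon[inner],
               tolerance = 1e-12)
  # values stay inside the local hull
  expect_true(all(r$data >= min(ramp$data) - 1e-12 &
                  r$data <= max(ramp$data) + 1e-12))
  irr <- grid_stack("x", "1", c(0, 1, 3), c(0, 1), data.frame(year = 1, month = 1),
                    array(1, dim = c(1, 2, 3)))
  expect_error(resample_bilinear(irr), "irregular")
})

test_that("monthly aggregation gives cell-wise min/mean/max", {
  s <- make_stack_t(list(matrix(1, 2, 2), matrix(2, 2, 2), matrix(3, 2, 2)))
  agg <- aggregate_monthly(s)
  expect_equal(agg$min$data[1, 1, 1], 1)
  expect_equal(agg$mean$data[1, 1, 1], 2)
  expect_equal(agg$max$data[1, 1, 1], 3)
  ident <- aggregate_monthly(make_stack_t(list(matrix(4, 2, 2), matrix(4, 2, 2))))
  expect_equal(ident$min$data, ident$max$data)
  expect_error(aggregate_monthly(s, years = 1999), "no time slices")
})

test_that("phi layers match the scalar oracle and propagate masks", {
  p <- published_params()
  temp <- make_stack(matrix(16, 3, 3), var = "temperature", units = "degC")
  po2 <- make_stack(matrix(18, 3, 3), var = "po2", units = "kPa")
  ph <- compute_phi_layers(p, temp, po2)
  expect_equal(as.vector(ph$data), rep(phi(p, 16, 18), 9), tolerance = 1e-12)
  # po2 equal to predicted demand gives phi = 1 everywhere
  po2c <- make_stack(matrix(po2crit_predict(p, 16), 3, 3))
  expect_true(all(abs(compute_phi_layers(p, temp, po2c)$data - 1) < 1e-12))
  po2$data[1, 2, 2] <- NA
  phm <- compute_phi_layers(p, temp, po2)
  expect_true(is.na(phm$data[1, 2, 2]))
  expect_equal(sum(is.na(phm$data)), 1)
  # coordinate metadata preserved bit-exactly
  expect_identical(phm$lon, temp$lon)
  expect_identical(phm$lat, temp$lat)
})

test_that("depth clipping masks cells outside the window", {
  bathy <- make_stack(matrix(c(5, 50, 120, 80), 2, 2), var = "depth", units = "m")
  mask <- clip_depth_domain(bathy, c(0, 100))
  expect_equal(sum(mask), 3)
  expect_false(mask[1, 2][[1]])  # 120 m cell excluded
  expect_warning(clip_depth_domain(make_stack(matrix(500, 2, 2))), "empty")
  s <- apply_domain_mask(make_stack(matrix(1, 2, 2)), mask)
  expect_true(is.na(s$data[1, 1, 2]))
})

test_that("aerobic scope layers follow the quadratic curves", {
  curves <- aerobic_scope_curves(c(0.3, 0.01, 0.0015), c(1.0, 0.35, -0.007))
  temp <- make_stack(matrix(c(8, 16, 20, 24), 2, 2))
  sc <- aerobic_scope_layers(curves, temp)
  smr <- 0.3 + 0.01 * 16 + 0.0015 * 256
  mmr <- 1.0 + 0.35 * 16 - 0.007 * 256
  expect_equal(sc$aas$data[1, 2, 1], mmr - smr, tolerance = 1e-12)
  expect_equal(sc$fas$data[1, 2, 1], mmr / smr, tolerance = 1e-12)
  # AAS > 0 exactly where FAS > 1
  expect_true(all((sc$aas$data > 0) == (sc$fas$data > 1)))
  # a temperature where MMR = 2 SMR gives FAS 2 and AAS = SMR
  curves2 <- aerobic_scope_curves(c(1, 0, 0), c(2, 0, 0))
  sc2 <- aerobic_scope_layers(curves2, temp)
  expect_true(all(sc2$fas$data == 2))
  expect_true(all(sc2$aas$data == 1))
  # out-of-range temperatures (SMR <= 0 or MMR <= SMR) are masked
  curves3 <- aerobic_scope_curves(c(0.5, 0, 0), c(0.4, 0.01, 0))
  sc3 <- aerobic_scope_layers(curves3, make_stack(matrix(c(5, 30), 1, 2)))
  expect_true(is.na(sc3$fas$data[1, 1, 1]))
})

test_that("curve fitting recovers planted quadratics from cohort estimates", {
  truth <- planted_truth(noise_sd_mr = 0)
  coh <- generate_respirometry_cohort(synthetic_config(), truth)
  est <- data.frame(test_temp = coh$truth_table$test_temp,
                    smr = vapply(coh$trials, estimate_smr, numeric(1)),
                    mmr = vapply(coh$trials, estimate_mmr, numeric(1)))
  curves <- fit_aerobic_scope_curves(est)
  expect_equal(curves$smr, truth$smr_curve, tolerance = 1e-6)
  expect_equal(curves$mmr, truth$mmr_curve, tolerance = 1e-6)
})

test_that("phi computed after input refinement differs from refined phi (nonlinearity)", {
  p <- published_params()
  set.seed(8)
  temp <- make_stack(matrix(runif(16, 10, 24), 4, 4), var = "t", units = "degC")
  po2 <- make_stack(matrix(runif(16, 8, 20), 4, 4), var = "po2", units = "kPa")
  phi_then_resample <- resample_bilinear(compute_phi_layers(p, temp, po2))
  resample_then_phi <- compute_phi_layers(p, resample_bilinear(temp),
                                          resample_bilinear(po2))
  expect_gt(max(abs(phi_then_resample$data - resample_then_phi$data)), 1e-6)
})
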