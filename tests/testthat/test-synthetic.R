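test_that("generation is deterministic given the seed", {
  cfg <- sim_config(seed = 5)
  l1 <- generate_landscape(cfg)
  l2 <- generate_landscape(cfg)
  expect_identical(l1$grid, l2$grid)
  expect_identical(l1$villages, l2$villages)
  t1 <- generate_transects(cfg, l1)
  t2 <- generate_transects(cfg, l2)
  expect_identical(t1, t2)
  s1 <- simulate_survey(l1, t1, cfg, 1)
  s2 <- simulate_survey(l2, t2, cfg, 1)
  expect_identical(s1$observations, s2$observations)

  # byte-identical on disk
  f1 <- tempfile(); f2 <- tempfile()
  write_survey(s1, f1, tempfile())
  write_survey(s2, f2, tempfile())
  expect_identical(readLines(f1), readLines(f2))

  # a different seed changes the draw
  s3 <- simulate_survey(l1, t1, sim_config(seed = 6), 1)
  expect_false(identical(s1$observations, s3$observations))
})

test_that("landscape construction honours its constraints", {
  cfg <- sim_config(seed = 23)
  ls_obj <- generate_landscape(cfg)
  # villages lie within 5 km of some road
  d <- rep(Inf, nrow(ls_obj$villages))
  for (r in ls_obj$roads) {
    d <- pmin(d, dungsurvey:::dist_point_polyline(ls_obj$villages, r))
  }
  expect_true(all(d <= 5))
  # grid totals match the generation ledger
  led <- attr(ls_obj, "ledger")
  expect_equal(sum(ls_obj$grid$nonforest_t1_km2),
               led$total_nonforest_t1)
  expect_equal(sum(deforestation_change(ls_obj$grid)$deforested_km2),
               led$total_deforested)
  # deforested area within cell bounds
  expect_true(all(ls_obj$grid$nonforest_t2_km2 <=
                    ls_obj$grid$cell_km^2))
  # grid covers the 15 km buffer
  expect_lte(min(ls_obj$grid$cx_km - ls_obj$grid$cell_km / 2), -15)
  expect_gte(max(ls_obj$grid$cx_km + ls_obj$grid$cell_km / 2),
             cfg$park_x_km + 15)
})

test_that("transect layout matches the sampling design", {
  cfg <- sim_config(seed = 29)
  ls_obj <- generate_landscape(cfg)
  trs <- generate_transects(cfg, ls_obj)
  expect_equal(nrow(trs), 110)
  expect_equal(length(unique(trs$location_id)), 51)
  per_loc <- table(trs$location_id)
  expect_true(all(per_loc >= 1 & per_loc <= 4))
  expect_true(all(trs$length_km >= 2.5 & trs$length_km <= 5))
  inside <- dungsurvey:::point_in_polygon(
    cbind(trs$x_km, trs$y_km),
    rbind(c(0, 0), c(cfg$park_x_km, 0),
          c(cfg$park_x_km, cfg$park_y_km), c(0, cfg$park_y_km)))
  expect_true(all(inside))
})

test_that("true surface responds to its coefficients as built", {
  cfg <- sim_config(seed = 37)
  ls_obj <- generate_landscape(cfg)
  surf <- density_surface(ls_obj, cfg)

  # flat coefficients give a uniform surface at exp(intercept)
  cfg0 <- sim_config(seed = 37,
                     beta = list(intercept = 1.2, dist_hq = 0,
                                 dist_boundary = 0, dist_road = 0,
                                 dist_town = 0, deforestation = 0,
                                 swamp = 0))
  surf0 <- density_surface(ls_obj, cfg0)
  pts <- cbind(runif(20, 10, 120), runif(20, 10, 95))
  expect_equal(surf0(pts, 1), rep(exp(1.2), 20), tolerance = 1e-10)

  # epoch 2 is epoch 1 scaled by decline/refuge multipliers
  D1 <- surf(pts, 1); D2 <- surf(pts, 2)
  d_hq <- sqrt((pts[, 1] - ls_obj$headquarters[1])^2 +
                 (pts[, 2] - ls_obj$headquarters[2])^2)
  expected <- ifelse(d_hq <= cfg$refuge_radius_km,
                     cfg$decline_factor * cfg$refuge_multiplier,
                     cfg$decline_factor)
  expect_equal(D2 / D1, expected, tolerance = 1e-10)

  # negative deforestation coefficient: density falls toward the
  # deforestation hotspot along a ray approaching a town
  cfg_neg <- sim_config(seed = 37,
                        beta = list(intercept = 1.4, dist_hq = 0,
                                    dist_boundary = 0, dist_road = 0,
                                    dist_town = 0, deforestation = -0.5,
                                    swamp = 0))
  surf_neg <- density_surface(ls_obj, cfg_neg)
  town <- ls_obj$towns[2, ]
  ray <- cbind(seq(20, 120, length.out = 12),
               seq(60, town[2], length.out = 12))
  di <- deforestation_index(ray, ls_obj$grid, "nonforest_t1_km2")
  expect_equal(order(surf_neg(ray, 1)), order(-di))
})

test_that("true park population integrates consistently in the ledger", {
  cfg <- sim_config(seed = 41)
  st <- simulate_study(cfg, grid_step_km = 4)
  surf <- st$surface
  # independent quadrature at a finer resolution
  gx <- seq(1, cfg$park_x_km - 1, by = 2.5)
  gy <- seq(1, cfg$park_y_km - 1, by = 2.5)
  gpts <- as.matrix(expand.grid(gx, gy))
  pop <- sum(surf(gpts, 1)) * 2.5^2 * 100
  expect_lt(abs(pop - st$ledger$true_dung_population[1]) / pop, 0.03)
  expect_equal(st$ledger$true_decline_fraction,
               1 - st$ledger$true_dung_population[2] /
                 st$ledger$true_dung_population[1])
})

test_that("counts are Poisson around expectation when phi = 1, g uniform", {
  cfg <- sim_config(seed = 11, phi = 1,
                    detection = list(family = "uniform"),
                    n_transects = 200)
  ls_obj <- generate_landscape(cfg)
  trs <- generate_transects(cfg, ls_obj)
  ds <- simulate_survey(ls_obj, trs, cfg, 1)
  led <- attr(ds, "ledger")
  nobs <- as.integer(table(factor(ds$observations$transect_id,
                                  levels = trs$transect_id)))
  X2 <- sum((nobs - led$expected_counts)^2 / led$expected_counts)
  p <- pchisq(X2, df = length(nobs), lower.tail = FALSE)
  expect_gt(p, 0.01)
  expect_lt(p, 0.99)
})

test_that("overdispersion shows up when phi > 1", {
  cfg <- sim_config(seed = 43, phi = 3,
                    detection = list(family = "uniform"),
                    n_transects = 204)
  ls_obj <- generate_landscape(cfg)
  trs <- generate_transects(cfg, ls_obj)
  ds <- simulate_survey(ls_obj, trs, cfg, 1)
  led <- attr(ds, "ledger")
  nobs <- as.integer(table(factor(ds$observations$transect_id,
                                  levels = trs$transect_id)))
  disp <- sum((nobs - led$expected_counts)^2 / led$expected_counts) /
    length(nobs)
  expect_gt(disp, 1.8)
})

test_that("a zero surface yields zero observations", {
  cfg <- sim_config(seed = 3,
                    beta = list(intercept = -30, dist_hq = 0,
                                dist_boundary = 0, dist_road = 0,
                                dist_town = 0, deforestation = 0,
                                swamp = 0))
  ls_obj <- generate_landscape(cfg)
  trs <- generate_transects(cfg, ls_obj)
  ds <- simulate_survey(ls_obj, trs, cfg, 1)
  expect_equal(ds$n, 0)
})

test_that("wide detection recovers ESW ~ w_sim and covers true density", {
  cover <- 0L
  for (s in 1:30) {
    cfg <- sim_config(seed = s,
                      detection = list(family = "half-normal",
                                       sigma = 500))
    ls_obj <- generate_landscape(cfg)
    trs <- generate_transects(cfg, ls_obj)
    ds <- simulate_survey(ls_obj, trs, cfg, 1)
    led <- attr(ds, "ledger")
    det <- fit_detection(ds$observations$perpendicular_distance_m,
                         "half-normal", w = cfg$w_sim_m)
    expect_gt(det$esw, 0.9 * cfg$w_sim_m)
    e <- density_estimate(ds, det)
    d_true <- sum(led$expected_counts) /
      sum(2 * (cfg$w_sim_m / 1000) * trs$length_km * 100)
    cover <- cover + (e$ci[1] <= d_true && d_true <= e$ci[2])
  }
  expect_gte(cover, 26)
})
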