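test_that("empirical semivariogram equals an all-pairs oracle", {
  set.seed(21)
  pts <- cbind(runif(40, 0, 50), runif(40, 0, 50))
  v <- rnorm(40)
  emp <- empirical_semivariogram(pts, v, n_bins = 8, max_lag = 30)
  # brute-force oracle: loop over every pair, bin, average
  breaks <- seq(0, 30, length.out = 9)
  acc <- matrix(0, 8, 2)
  for (i in 1:39) for (j in (i + 1):40) {
    h <- sqrt(sum((pts[i, ] - pts[j, ])^2))
    if (h <= 0 || h > 30) next
    b <- findInterval(h, breaks, rightmost.closed = TRUE,
                      left.open = TRUE)
    b <- max(1, b)
    acc[b, 1] <- acc[b, 1] + (v[i] - v[j])^2
    acc[b, 2] <- acc[b, 2] + 1
  }
  keep <- acc[, 2] > 0
  expect_equal(emp$gamma, (acc[keep, 1] / (2 * acc[keep, 2])))
  expect_equal(emp$n_pairs, as.integer(acc[keep, 2]))

  # constant field: gamma identically zero
  emp0 <- empirical_semivariogram(pts, rep(3, 40))
  expect_true(all(emp0$gamma == 0))

  # a bin holding a single pair with values 1 and 3 gives gamma = 2
  pts2 <- rbind(c(0, 0), c(1, 0), c(0.5, 0.5), c(40, 0), c(41.3, 0))
  v2 <- c(0, 0, 0, 1, 3)
  emp2 <- suppressWarnings(
    empirical_semivariogram(pts2, v2, n_bins = 30, max_lag = 2))
  one_pair <- emp2[emp2$n_pairs == 1 & emp2$gamma > 0, ]
  expect_true(any(abs(one_pair$gamma - 2) < 1e-12))

  expect_error(empirical_semivariogram(pts[1:3, ], v[1:3]),
               "at least 5")
})

test_that("variogram fitting recovers simulated structure", {
  # median range estimate over replicate fields within 30% of truth
  ranges <- vapply(1:7, function(s) {
    set.seed(s)
    pts <- cbind(runif(200, 0, 100), runif(200, 0, 100))
    v <- grf_spherical(pts, nugget = 0, partial_sill = 1,
                       range_km = 20, seed = s + 100)
    fit_variogram(empirical_semivariogram(pts, v), "spherical")$range_km
  }, numeric(1))
  expect_lt(abs(median(ranges) - 20) / 20, 0.3)

  # pure nugget: partial sill collapses
  set.seed(6)
  pts <- cbind(runif(200, 0, 100), runif(200, 0, 100))
  vn <- rnorm(200)
  fn <- fit_variogram(empirical_semivariogram(pts, vn), "spherical")
  expect_lt(fn$partial_sill / (fn$partial_sill + fn$nugget), 0.25)

  expect_error(fit_variogram(data.frame(lag = 1, gamma = 1,
                                        n_pairs = 3)),
               "at least 3")
})

test_that("ordinary kriging is exact at data points and unbiased", {
  set.seed(33)
  pts <- cbind(runif(10, 0, 30), runif(10, 0, 30))
  v <- sin(pts[, 1] / 5) + 0.1 * pts[, 2]
  model <- list(family = "spherical", nugget = 0, partial_sill = 1,
                range_km = 15)
  ks <- krige(pts, v, model, pts)
  expect_equal(ks$prediction, v, tolerance = 1e-8)

  grid <- prediction_grid(c(0, 30), c(0, 30), 5)
  ks2 <- krige(pts, v, model, grid)
  expect_true(all(ks2$variance >= 0))
  expect_equal(attr(ks2, "weights_sum"), rep(1, nrow(grid)),
               tolerance = 1e-9)

  # direct linear-solve oracle, node by node
  n <- nrow(pts)
  G <- variogram_gamma(as.matrix(dist(pts)), model)
  for (i in c(1, 7, 20)) {
    h0 <- sqrt((pts[, 1] - grid[i, 1])^2 + (pts[, 2] - grid[i, 2])^2)
    A <- rbind(cbind(G, 1), c(rep(1, n), 0))
    sol <- solve(A, c(variogram_gamma(h0, model), 1))
    expect_equal(ks2$prediction[i], sum(sol[1:n] * v),
                 tolerance = 1e-8)
  }

  # constant field kriges to the constant
  kc <- krige(pts, rep(2.5, 10), model, grid)
  expect_equal(kc$prediction, rep(2.5, nrow(grid)), tolerance = 1e-8)

  expect_error(krige(rbind(pts, pts[1, ]), c(v, v[1]), model, grid),
               "duplicated")
  kd <- krige(rbind(pts, pts[1, ]), c(v, v[1]), model, grid,
              dedup = "mean")
  expect_equal(kd$prediction, ks2$prediction, tolerance = 1e-8)
})

test_that("kriged surface mean tracks the data mean on stationary fields", {
  set.seed(55)
  pts <- cbind(runif(80, 0, 100), runif(80, 0, 100))
  v <- 5 + grf_spherical(pts, nugget = 0.2, partial_sill = 1,
                         range_km = 25, seed = 56)
  emp <- empirical_semivariogram(pts, v)
  model <- fit_variogram(emp, "spherical")
  grid <- prediction_grid(c(0, 100), c(0, 100), 5)
  ks <- krige(pts, v, model, grid)
  expect_lt(abs(mean(ks$prediction) - mean(v)) / abs(mean(v)), 0.15)
})

test_that("Gi* matches a hand-computed oracle and flags extremes", {
  # 5-point configuration, oracle computed term by term
  pts <- rbind(c(0, 0), c(1, 0), c(0, 1), c(10, 10), c(10, 11))
  v <- c(5, 6, 7, 1, 2)
  band <- 2
  gi <- getis_ord_gistar(pts, v, band_km = band)
  n <- 5; xbar <- mean(v); s <- sqrt(mean(v^2) - xbar^2)
  d <- as.matrix(dist(pts))
  for (i in 1:5) {
    w <- as.numeric(d[i, ] <= band)
    zi <- (sum(w * v) - xbar * sum(w)) /
      (s * sqrt((n * sum(w^2) - sum(w)^2) / (n - 1)))
    expect_equal(gi$z[i], zi, tolerance = 1e-10)
  }

  # isolated extreme high value dominates the score
  pts6 <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(0.5, 0.5),
                c(50, 50))
  v6 <- c(1, 1.2, 0.8, 1.1, 0.9, 30)
  gi6 <- getis_ord_gistar(pts6, v6, band_km = 2)
  expect_equal(which.max(abs(gi6$z)), 6L)

  # relabeling symmetry: permuting rows permutes scores identically
  perm <- c(3, 1, 5, 2, 4)
  gi_p <- getis_ord_gistar(pts[perm, ], v[perm], band_km = band)
  expect_equal(gi_p$z, gi$z[perm], tolerance = 1e-12)

  expect_error(getis_ord_gistar(pts, rep(1, 5), band_km = band),
               "constant field")
  expect_error(getis_ord_gistar(pts[1:2, ], v[1:2]), "at least 3")
})

test_that("hot flags follow the 1.96 decision rule", {
  set.seed(77)
  pts <- cbind(runif(60, 0, 40), runif(60, 0, 40))
  v <- rnorm(60)
  v[pts[, 1] < 10 & pts[, 2] < 10] <- v[pts[, 1] < 10 & pts[, 2] < 10] + 4
  gi <- getis_ord_gistar(pts, v, band_km = 8)
  expect_identical(gi$hot, gi$z > 1.96)
  expect_identical(gi$cold, gi$z < -1.96)
  expect_true(all(gi$p[gi$hot] < 0.05))
  hot_block <- gi$hot & gi$x_km < 10 & gi$y_km < 10
  expect_gt(sum(hot_block), 0)
})

test_that("post-decline hotspots concentrate in the protected refuge", {
  # strong-refuge configuration makes the mechanism visible per replicate
  sig <- 0L
  for (s in 1:50) {
    cfg <- sim_config(seed = s, refuge_radius_km = 25,
                      refuge_multiplier = 2.5)
    ls_obj <- generate_landscape(cfg)
    trs <- generate_transects(cfg, ls_obj)
    ds2 <- simulate_survey(ls_obj, trs, cfg, 2)
    det <- fit_detection(ds2$observations$perpendicular_distance_m,
                         "half-normal")
    pooled <- pool_by_location(ds2)
    dens <- vapply(seq_len(nrow(pooled)), function(j) {
      estimate_density(pooled$n_obs[j], pooled$effort_km[j], det$esw)
    }, numeric(1))
    gi <- getis_ord_gistar(as.matrix(pooled[, c("x_km", "y_km")]), dens)
    d_hq <- sqrt((pooled$x_km - ls_obj$headquarters[1])^2 +
                   (pooled$y_km - ls_obj$headquarters[2])^2)
    inref <- d_hq <= cfg$refuge_radius_km
    p <- stats::fisher.test(factor(gi$hot, c(TRUE, FALSE)),
                            factor(inref, c(TRUE, FALSE)),
                            alternative = "greater")$p.value
    sig <- sig + (p < 0.05)
  }
  expect_gte(sig, 0.8 * 50)
})
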