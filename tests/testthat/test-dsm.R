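# de Boor recursion, written directly from the recurrence
deboor_basis <- function(knots, x, j, ord) {
  if (ord == 1) {
    return(as.numeric(knots[j] <= x &
                        (x < knots[j + 1] |
                           (x == knots[length(knots)] &
                              knots[j + 1] == knots[length(knots)]))))
  }
  d1 <- knots[j + ord - 1] - knots[j]
  d2 <- knots[j + ord] - knots[j + 1]
  t1 <- if (d1 > 0) {
    (x - knots[j]) / d1 * deboor_basis(knots, x, j, ord - 1)
  } else 0
  t2 <- if (d2 > 0) {
    (knots[j + ord] - x) / d2 * deboor_basis(knots, x, j + 1, ord - 1)
  } else 0
  t1 + t2
}

test_that("spline basis matches the de Boor recursion oracle", {
  set.seed(2)
  x <- sort(runif(60, 0, 10))
  knots <- dungsurvey:::smooth_knots(x, 6)
  xg <- seq(min(x), max(x), length.out = 100)
  B <- dungsurvey:::eval_basis(knots, xg)
  for (j in seq_len(ncol(B))) {
    expect_equal(B[, j], deboor_basis(knots, xg, j, 4),
                 tolerance = 1e-10)
  }
})

test_that("curvature penalty is PSD with a two-dimensional null space", {
  x <- seq(0, 1, length.out = 40)
  knots <- dungsurvey:::smooth_knots(x, 5)
  S <- dungsurvey:::curvature_penalty(knots)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))
  expect_equal(sum(ev < 1e-8 * max(ev)), 2)
  # constant and linear coefficient vectors are unpenalized
  B <- dungsurvey:::eval_basis(knots, x)
  lin_coef <- qr.solve(B, cbind(1, x))
  expect_lt(max(abs(t(lin_coef) %*% S %*% lin_coef)), 1e-8)
})

test_that("design centres smooths and rejects degenerate input", {
  set.seed(3)
  d <- data.frame(a = runif(50), b = runif(50), flat = 1)
  des <- build_design(d, smooth = "a", linear = "b")
  sm_cols <- des$terms$a$cols
  expect_lt(max(abs(colSums(des$X[, sm_cols, drop = FALSE]))), 1e-9)
  expect_lt(abs(sum(des$X[, des$terms$b$cols])), 1e-9)
  expect_error(build_design(d, smooth = "flat"), "constant")
  expect_error(build_design(d, smooth = "nope"), "not in data")
  d$a[1] <- NA
  expect_error(build_design(d, smooth = "a"), "missing")
})

test_that("unpenalized fit equals the Poisson GLM oracle", {
  set.seed(11)
  n <- 120
  d <- data.frame(u = runif(n), v = rnorm(n))
  off <- log(runif(n, 1, 3))
  y <- rpois(n, exp(off + 0.4 + 0.8 * d$u - 0.5 * d$v))
  des <- build_design(d, linear = c("u", "v"))
  f <- fit_gam(y, off, des, lambda = numeric(0))
  oracle <- glm(y ~ I(u - mean(u)) + I(v - mean(v)), offset = off,
                family = poisson(), data = d)
  expect_equal(unname(f$coefficients), unname(coef(oracle)),
               tolerance = 1e-6)
  expect_equal(f$deviance, deviance(oracle), tolerance = 1e-8)
  # dispersion agrees with the Pearson estimate
  prs <- sum(residuals(oracle, "pearson")^2) / (n - 3)
  expect_equal(f$phi, prs, tolerance = 1e-4)
})

test_that("intercept-only model explains no deviance", {
  set.seed(12)
  y <- rpois(40, 3)
  des <- build_design(data.frame(x = runif(40)))
  f <- fit_gam(y, rep(0, 40), des, numeric(0))
  expect_equal(f$deviance_explained, 0, tolerance = 1e-8)
})

test_that("huge smoothing collapses a smooth to its linear null space", {
  set.seed(13)
  n <- 150
  d <- data.frame(x = runif(n, 0, 1))
  y <- rpois(n, exp(1 + sin(2 * pi * d$x)))
  des <- build_design(d, smooth = "x")
  f <- fit_gam(y, rep(0, n), des, lambda = 1e9)
  expect_equal(f$edf, 2, tolerance = 0.05)
  # fitted linear predictor is a straight line in x
  r <- resid(lm(f$linear_predictor ~ d$x))
  expect_lt(max(abs(r)), 1e-3)
})

test_that("offsets absorb effort exactly", {
  set.seed(14)
  n <- 80
  d <- data.frame(x = runif(n))
  off <- log(runif(n, 1, 4))
  y <- rpois(n, exp(off + 0.5 + 0.7 * d$x))
  des <- build_design(d, smooth = "x")
  f1 <- fit_gam(y, off, des, lambda = 2)
  f2 <- fit_gam(y, off + log(3), des, lambda = 2)
  # only the intercept shifts, by -log(3); the smooth is untouched
  expect_equal(f2$coefficients[1], f1$coefficients[1] - log(3),
               tolerance = 1e-6)
  expect_equal(f2$coefficients[-1], f1$coefficients[-1],
               tolerance = 1e-6)
})

test_that("adding a term never increases deviance at lambda = 0", {
  set.seed(15)
  n <- 90
  d <- data.frame(x = runif(n), z = runif(n))
  y <- rpois(n, exp(1 + d$x))
  d1 <- build_design(d, linear = "x")
  d2 <- build_design(d, linear = c("x", "z"))
  f1 <- fit_gam(y, rep(0, n), d1, numeric(0))
  f2 <- fit_gam(y, rep(0, n), d2, numeric(0))
  expect_lte(f2$deviance, f1$deviance + 1e-8)
})

test_that("GCV selects near-linear fits for linear truth", {
  hits <- 0L
  for (s in 1:50) {
    set.seed(s)
    n <- 100
    d <- data.frame(x = runif(n))
    y <- rpois(n, exp(0.5 + 1.2 * d$x))
    f <- fit_dsm(y, rep(0, n), d, smooth = "x")
    hits <- hits + (f$edf >= 1.7 && f$edf <= 2.8)
  }
  expect_gte(hits, 0.7 * 50)
})

test_that("GCV fit beats the forced-linear fit on sinusoidal truth", {
  set.seed(16)
  n <- 400
  d <- data.frame(x = runif(n))
  y <- rpois(n, exp(0.5 + 1.5 * sin(2 * pi * d$x)))
  fs <- fit_dsm(y, rep(0, n), d, smooth = "x", k = 8)
  fl <- fit_dsm(y, rep(0, n), d, linear = "x")
  expect_gte(fs$deviance_explained, fl$deviance_explained)
  expect_gt(fs$edf, 3)
})

test_that("duplicating every row does not shrink the selected fit", {
  set.seed(17)
  n <- 60
  d <- data.frame(x = runif(n))
  y <- rpois(n, exp(0.3 + sin(2 * pi * d$x)))
  f1 <- fit_dsm(y, rep(0, n), d, smooth = "x")
  d2 <- rbind(d, d)
  f2 <- fit_dsm(c(y, y), rep(0, 2 * n), d2, smooth = "x")
  expect_gte(f2$edf, f1$edf - 0.2)
})

test_that("backward deletion prunes noise and is deterministic", {
  dropped <- 0L
  for (s in 1:50) {
    set.seed(s + 100)
    n <- 80
    d <- data.frame(x = runif(n), z = runif(n))
    y <- rpois(n, exp(0.3 + sin(2 * pi * d$x)))
    bd <- backward_delete(y, rep(0, n), d, smooth = c("x", "z"))
    dropped <- dropped + (!"z" %in% bd$smooth && "x" %in% bd$smooth)
  }
  expect_gte(dropped, 0.8 * 50)

  set.seed(101)
  n <- 80
  d <- data.frame(x = runif(n), z = runif(n))
  y <- rpois(n, exp(0.3 + sin(2 * pi * d$x)))
  b1 <- backward_delete(y, rep(0, n), d, smooth = c("x", "z"))
  b2 <- backward_delete(y, rep(0, n), d, smooth = c("x", "z"))
  expect_identical(b1$trace, b2$trace)

  # a lone informative term is kept
  b3 <- backward_delete(y, rep(0, n), d, smooth = "x")
  expect_equal(b3$smooth, "x")
  expect_equal(nrow(b3$trace), 1L)
})

test_that("fit agrees broadly with an mgcv cross-check", {
  set.seed(18)
  n <- 150
  d <- data.frame(x = runif(n, 0, 1))
  off <- log(runif(n, 1, 3))
  y <- rpois(n, exp(off + 1 + 1.2 * sin(2 * pi * d$x)))
  mine <- fit_dsm(y, off, d, smooth = "x", k = 8)
  mg <- mgcv::gam(y ~ s(x, k = 8, bs = "cr") + offset(off),
                  family = stats::quasipoisson(), data = d)
  dev_mg <- 100 * (1 - mg$deviance / mg$null.deviance)
  expect_lt(abs(mine$deviance_explained - dev_mg), 10)
  expect_lt(abs(mine$phi - summary(mg)$dispersion) /
              summary(mg)$dispersion, 0.3)
})

test_that("model report ranks drivers and flags significance", {
  set.seed(19)
  n <- 100
  d <- data.frame(defor = runif(n, 0, 4), noise = runif(n))
  off <- rep(log(2), n)
  y <- rpois(n, exp(off + 1.5 - 0.8 * d$defor))
  rep1 <- table_gam_report(y, off, d,
                           univariate = list(defor = list(smooth = "defor"),
                                             noise = list(smooth = "noise")))
  expect_equal(rep1$model[1], "defor")
  expect_true(rep1$significant[1])

  # null data: nothing explains anything much
  y0 <- rpois(n, exp(off))
  rep0 <- table_gam_report(y0, off, d,
                           univariate = list(defor = list(smooth = "defor"),
                                             noise = list(smooth = "noise")))
  expect_true(all(rep0$deviance_explained < 10))

  pe <- partial_effect(attr(rep1, "fits")[[1]], "defor", d)
  expect_equal(nrow(pe), 100)
  expect_true(all(pe$se >= 0))
  # strong negative driver: effect decreases across its range
  expect_lt(pe$effect[100], pe$effect[1])
})
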