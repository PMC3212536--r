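#' Semivariance of a variogram model
#'
#' @param h lag distances (km).
#' @param model list with `family` ("spherical" or "exponential"),
#'   `nugget`, `partial_sill`, `range_km`.
#' @return semivariance at each lag (0 at h = 0).
#' @export
variogram_gamma <- function(h, model) {
  family <- match.arg(model$family, c("spherical", "exponential"))
  c0 <- model$nugget; c1 <- model$partial_sill; a <- model$range_km
  g <- switch(family,
    spherical = ifelse(h >= a, c1,
                       c1 * (1.5 * h / a - 0.5 * (h / a)^3)),
    exponential = c1 * (1 - exp(-3 * h / a)))
  out <- c0 + g
  out[h == 0] <- 0
  out
}

#' Empirical (binned) semivariogram
#'
#' gamma_hat(h) = 1/(2 N_h) * sum over point pairs in bin h of
#' (v_i - v_j)^2.
#'
#' @param points two-column matrix (km).
#' @param values numeric vector.
#' @param n_bins number of lag bins (default 12).
#' @param max_lag largest lag considered; default half the maximum
#'   pairwise distance.
#' @return data frame `lag` (bin midpoint-of-pairs mean), `gamma`,
#'   `n_pairs`; empty bins are dropped with a warning.
#' @export
empirical_semivariogram <- function(points, values, n_bins = 12,
                                    max_lag = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 5) stop("need at least 5 points", call. = FALSE)
  d <- as.matrix(stats::dist(points))
  if (is.null(max_lag)) max_lag <- max(d) / 2
  stopifnot(max_lag > 0)
  iu <- upper.tri(d)
  h <- d[iu]
  sq <- outer(values, values, `-`)[iu]^2
  keep <- h > 0 & h <= max_lag
  h <- h[keep]; sq <- sq[keep]
  bins <- cut(h, breaks = seq(0, max_lag, length.out = n_bins + 1),
              include.lowest = TRUE)
  np <- tabulate(bins, nbins = n_bins)
  gam <- tapply(sq, bins, function(s) sum(s) / (2 * length(s)))
  lag <- tapply(h, bins, mean)
  out <- data.frame(lag = as.numeric(lag), gamma = as.numeric(gam),
                    n_pairs = np)
  if (any(np == 0)) {
    warning(sum(np == 0), " empty lag bin(s) dropped")
    out <- out[np > 0, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Fit a variogram model by weighted least squares
#'
#' Minimizes sum of N_h * (gamma_hat(h) - gamma_model(h))^2 over
#' (nugget, partial sill, range) with non-negativity bounds.
#'
#' @param emp empirical semivariogram from
#'   [empirical_semivariogram()].
#' @param family "spherical" (default) or "exponential".
#' @return variogram model list (`family`, `nugget`, `partial_sill`,
#'   `range_km`, `converged`, `at_bound`).
#' @export
fit_variogram <- function(emp, family = c("spherical", "exponential")) {
  family <- match.arg(family)
  if (nrow(emp) < 3) {
    stop("need at least 3 non-empty lag bins", call. = FALSE)
  }
  obj <- function(par) {
    m <- list(family = family, nugget = par[1], partial_sill = par[2],
              range_km = par[3])
    sum(emp$n_pairs * (emp$gamma - variogram_gamma(emp$lag, m))^2)
  }
  sill0 <- max(mean(emp$gamma), 1e-9)
  hi <- max(emp$lag)
  start <- c(0.1 * sill0, 0.9 * sill0, hi / 2)
  lower <- c(0, 1e-12, hi * 1e-3)
  upper <- c(2 * max(emp$gamma) + 1e-9, 3 * max(emp$gamma) + 1e-9, 3 * hi)
  opt <- stats::optim(start, obj, method = "L-BFGS-B",
                      lower = lower, upper = upper)
  at_bound <- any(abs(opt$par[3] - c(lower[3], upper[3])) < 1e-8)
  if (at_bound) warning("variogram range at optimization bound")
  list(family = family, nugget = opt$par[1], partial_sill = opt$par[2],
       range_km = opt$par[3], converged = opt$convergence == 0,
       at_bound = at_bound)
}

#' Ordinary kriging onto a grid
#'
#' Solves the ordinary-kriging system per prediction node: semivariance
#' matrix among data points augmented with the unbiasedness (Lagrange)
#' row, so the weights sum to 1 at every node. With zero nugget the
#' prediction at a data point reproduces its observed value.
#'
#' @param points two-column data matrix (km).
#' @param values observed values at `points`.
#' @param model variogram model (from [fit_variogram()] or hand-built).
#' @param grid two-column matrix of prediction nodes (km).
#' @param dedup how to handle duplicated data points: "fail" (default)
#'   or "mean" (average their values).
#' @return object of class `kriged_surface`: data frame `x_km`, `y_km`,
#'   `prediction`, `variance`, plus attribute `weights_sum` (per-node sum
#'   of kriging weights).
#' @export
krige <- function(points, values, model, grid, dedup = c("fail", "mean")) {
  dedup <- match.arg(dedup)
  points <- as.matrix(points); grid <- as.matrix(grid)
  stopifnot(nrow(grid) >= 1, nrow(points) == length(values))
  key <- paste(points[, 1], points[, 2])
  if (any(duplicated(key))) {
    if (dedup == "fail") {
      stop("duplicated data points; set dedup = \"mean\"", call. = FALSE)
    }
    values <- as.numeric(tapply(values, key, mean)[unique(key)])
    points <- points[!duplicated(key), , drop = FALSE]
  }
  n <- nrow(points)
  G <- variogram_gamma(as.matrix(stats::dist(points)), model)
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  Ai <- solve(A)
  pred <- var_ok <- wsum <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    h0 <- sqrt((points[, 1] - grid[i, 1])^2 +
                 (points[, 2] - grid[i, 2])^2)
    g0 <- c(variogram_gamma(h0, model), 1)
    sol <- Ai %*% g0
    w <- sol[seq_len(n)]
    pred[i] <- sum(w * values)
    # kriging variance w'g0 + mu; clamp tiny negative round-off
    var_ok[i] <- max(0, sum(sol * g0))
    wsum[i] <- sum(w)
  }
  structure(
    data.frame(x_km = grid[, 1], y_km = grid[, 2],
               prediction = pred, variance = var_ok),
    weights_sum = wsum, class = c("kriged_surface", "data.frame"))
}

#' Getis-Ord Gi* local hotspot statistic
#'
#' Gi*(i) = (sum_j w_ij x_j - Xbar W_i) /
#'          (S * sqrt((n sum_j w_ij^2 - W_i^2) / (n - 1)))
#' with binary distance-band weights including the self term
#' (w_ii = 1), Xbar and S the global mean and (population) standard
#' deviation. High positive z flags a hotspot of large values; large
#' negative z a cold spot.
#'
#' @param points two-column matrix (km).
#' @param values numeric vector.
#' @param band_km neighbourhood radius; default twice the median
#'   nearest-neighbour distance.
#' @param z_crit flag threshold (default 1.96).
#' @return data frame `x_km`, `y_km`, `value`, `z`, `p` (two-sided),
#'   `hot`, `cold`.
#' @export
getis_ord_gistar <- function(points, values, band_km = NULL,
                             z_crit = 1.96) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  d <- as.matrix(stats::dist(points))
  if (is.null(band_km)) {
    nn <- apply(d + diag(Inf, n), 1, min)
    band_km <- 2 * stats::median(nn)
  }
  stopifnot(band_km > 0)
  xbar <- mean(values)
  s <- sqrt(mean(values^2) - xbar^2)
  if (s == 0) {
    stop("constant field: Gi* scores undefined", call. = FALSE)
  }
  W <- (d <= band_km) * 1  # includes self (d_ii = 0)
  wi <- rowSums(W)
  num <- as.numeric(W %*% values) - xbar * wi
  den <- s * sqrt((n * wi - wi^2) / (n - 1))  # binary weights: sum w^2 = sum w
  z <- num / den
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  data.frame(x_km = points[, 1], y_km = points[, 2], value = values,
             z = z, p = p, hot = z > z_crit, cold = z < -z_crit)
}

#' Write a kriged surface (and optional hotspot table) to CSV
#' @param surface a `kriged_surface`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_kriged_surface <- function(surface, path) {
  utils::write.csv(as.data.frame(surface), path, row.names = FALSE)
  invisible(path)
}

#' Build a rectangular prediction grid over a bounding box
#' @param xlim,ylim extents (km).
#' @param step grid spacing (km).
#' @return two-column matrix of node coordinates.
#' @export
prediction_grid <- function(xlim, ylim, step) {
  as.matrix(expand.grid(x_km = seq(xlim[1], xlim[2], by = step),
                        y_km = seq(ylim[1], ylim[2], by = step)))
}
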