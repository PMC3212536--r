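#' Simulation configuration for synthetic surveys
#'
#' Defaults emulate the study design the package targets: a ~13,700 km^2
#' rectangular forest reserve, 51 sampling locations holding 110
#' transects of 2.5--5 km, a pooled half-normal detection function with
#' sigma = 2 m, negative-binomial overdispersion (phi = 2), a 50%
#' density decline in the second epoch, and a modest refuge effect
#' around the headquarters where the decline is buffered.
#'
#' @param seed integer seed; every random draw derives from it.
#' @param park_x_km,park_y_km park rectangle dimensions (km).
#' @param n_locations number of sampling locations (default 51).
#' @param n_transects total transects across locations (default 110;
#'   each location holds 1--4).
#' @param length_range_km transect length range (default 2.5--5).
#' @param detection list: `family`, `sigma` (m) and, for hazard-rate,
#'   `b`.
#' @param w_sim_m simulation half-width within which dung is laid out
#'   (m).
#' @param beta named list of true log-density coefficients. `intercept`
#'   is the log of the typical density in piles per ha; the remaining
#'   entries (`dist_hq`, `dist_boundary`, `dist_road`, `dist_town`,
#'   `deforestation`, `swamp`) act per standard deviation of the
#'   corresponding covariate over the park (swamp is a 0/1 bump).
#' @param decline_factor epoch-2 multiplier on density (default 0.5).
#' @param refuge_radius_km,refuge_multiplier epoch-2 refuge around the
#'   headquarters: within the radius the epoch-2 density is additionally
#'   multiplied by `refuge_multiplier`.
#' @param phi overdispersion: count variance = phi * mean (default 2).
#' @param cell_km deforestation grid cell size (default 10).
#' @param buffer_km grid buffer beyond the boundary (default 15).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       park_x_km = 130, park_y_km = 105.4,
                       n_locations = 51, n_transects = 110,
                       length_range_km = c(2.5, 5),
                       detection = list(family = "half-normal",
                                        sigma = 2),
                       w_sim_m = 10,
                       beta = list(intercept = 1.4, dist_hq = -0.3,
                                   dist_boundary = 0.25, dist_road = 0,
                                   dist_town = 0, deforestation = -0.4,
                                   swamp = 0),
                       decline_factor = 0.5,
                       refuge_radius_km = 15, refuge_multiplier = 1.5,
                       phi = 2, cell_km = 10, buffer_km = 15) {
  stopifnot(decline_factor > 0, decline_factor <= 1, phi >= 1,
            park_x_km > 0, park_y_km > 0,
            n_locations <= n_transects, n_transects <= 4 * n_locations)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic landscape
#'
#' A rectangular park with a bisecting east--west road through its
#' southern half, roads along the eastern and beyond the western
#' boundary, villages strung within 5 km of the roads, four towns
#' outside the boundary, headquarters on the central road, a
#' deforestation grid (non-forested area decaying with distance to
#' towns and roads, growing between epochs), and slope/habitat lattices.
#'
#' @param config a [sim_config()].
#' @return a [landscape()]; attribute `ledger` carries the grid totals.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  X <- config$park_x_km; Y <- config$park_y_km
  buf <- config$buffer_km
  boundary <- rbind(c(0, 0), c(X, 0), c(X, Y), c(0, Y))
  y_rn4 <- 0.35 * Y
  roads <- list(
    central = cbind(seq(-buf, X + buf, length.out = 30),
                    y_rn4 + 3 * sin(seq(0, 3 * pi, length.out = 30))),
    eastern = cbind(rep(X + 1, 2), c(-buf, Y + buf)),
    western = cbind(rep(-10, 2), c(-buf, Y + buf)))
  villages <- do.call(rbind, lapply(roads, function(r) {
    n <- 12
    idx <- sort(stats::runif(n))
    # arc-length parameterization is overkill; vertices are near-even
    vi <- pmax(1, ceiling(idx * (nrow(r) - 1)))
    base <- r[vi, , drop = FALSE]
    base + matrix(stats::runif(2 * n, -3.5, 3.5), ncol = 2)
  }))
  towns <- rbind(c(0.25 * X, -8), c(X + 8, 0.6 * Y),
                 c(0.7 * X, Y + 8), c(-8, 0.2 * Y))
  hq <- c(X / 2, y_rn4)  # headquarters on the central road axis

  cell <- config$cell_km
  cx <- seq(-buf + cell / 2, X + buf, by = cell)
  cy <- seq(-buf + cell / 2, Y + buf, by = cell)
  grid <- expand.grid(cx_km = cx, cy_km = cy)
  grid$cell_km <- cell
  centers <- as.matrix(grid[, 1:2])
  d_town <- dist_point_points(centers, towns)
  d_road <- rep(Inf, nrow(centers))
  for (r in roads) d_road <- pmin(d_road, dist_point_polyline(centers, r))
  cell_area <- cell^2
  frac1 <- 0.35 * exp(-d_town / 20) + 0.15 * exp(-d_road / 8)
  frac1 <- frac1 * exp(stats::rnorm(nrow(grid), 0, 0.3))
  grid$nonforest_t1_km2 <- pmin(cell_area, frac1 * cell_area)
  growth <- 0.12 * exp(-d_town / 25) * stats::runif(nrow(grid), 0.3, 1)
  grid$nonforest_t2_km2 <- pmin(cell_area,
                                grid$nonforest_t1_km2 +
                                  growth * cell_area)

  sx <- seq(-buf, X + buf, by = 5); sy <- seq(-buf, Y + buf, by = 5)
  sl <- expand.grid(x_km = sx, y_km = sy)
  sl$slope_deg <- pmax(0, 5 + 4 * sin(sl$x_km / 19) +
                         4 * cos(sl$y_km / 23) +
                         stats::rnorm(nrow(sl), 0, 1))
  hb <- expand.grid(x_km = sx, y_km = sy)
  u <- sin(hb$x_km / 31) + cos(hb$y_km / 27) +
    stats::rnorm(nrow(hb), 0, 0.5)
  qs <- stats::quantile(u, c(0.55, 0.85, 0.93))
  hb$habitat <- cut(u, breaks = c(-Inf, qs, Inf),
                    labels = c("mixed_forest", "mbau_forest",
                               "swamp_forest", "hill_forest"))
  hb$habitat <- as.character(hb$habitat)

  out <- landscape(boundary = boundary, roads = roads,
                   villages = villages, towns = towns,
                   headquarters = hq, grid = grid,
                   slope_grid = sl, habitat_grid = hb)
  attr(out, "ledger") <- list(
    seed = config$seed,
    total_nonforest_t1 = sum(grid$nonforest_t1_km2),
    total_nonforest_t2 = sum(grid$nonforest_t2_km2),
    total_deforested = sum(pmax(0, grid$nonforest_t2_km2 -
                                  grid$nonforest_t1_km2)))
  out
}

#' Generate the transect layout
#'
#' Sampling locations are placed uniformly in the park interior with a
#' minimum separation; each holds 1--4 transects (totalling
#' `n_transects`) radiating on random bearings from the shared
#' departure point.
#'
#' @param config a [sim_config()].
#' @param ls_obj the landscape (used for the park frame only).
#' @return transect table consumable by [survey_dataset()].
#' @export
generate_transects <- function(config, ls_obj) {
  set.seed(config$seed + 1L)
  X <- config$park_x_km; Y <- config$park_y_km
  k <- config$n_locations
  pts <- matrix(NA_real_, 0, 2)
  min_sep <- 0.6 * sqrt(X * Y / k)
  tries <- 0
  while (nrow(pts) < k && tries < 20000) {
    cand <- c(stats::runif(1, 6, X - 6), stats::runif(1, 6, Y - 6))
    if (nrow(pts) == 0 ||
        min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) >
          min_sep) {
      pts <- rbind(pts, cand)
    }
    tries <- tries + 1
  }
  if (nrow(pts) < k) stop("could not place sampling locations")
  per_loc <- rep(max(1L, config$n_transects %/% k), k)
  extra <- config$n_transects - sum(per_loc)
  if (extra > 0) {
    bump <- sample.int(k, extra)
    per_loc[bump] <- per_loc[bump] + 1L
  } else if (extra < 0) {
    cut <- sample(which(per_loc > 1), -extra)
    per_loc[cut] <- per_loc[cut] - 1L
  }
  stopifnot(all(per_loc >= 1), all(per_loc <= 4))
  rows <- list()
  tid <- 0L
  for (i in seq_len(k)) {
    bearings <- stats::runif(per_loc[i], 0, 360)
    lens <- stats::runif(per_loc[i], config$length_range_km[1],
                         config$length_range_km[2])
    for (j in seq_len(per_loc[i])) {
      tid <- tid + 1L
      rows[[tid]] <- data.frame(
        transect_id = sprintf("T%03d", tid),
        location_id = sprintf("L%02d", i),
        x_km = pts[i, 1], y_km = pts[i, 2],
        bearing_deg = bearings[j], length_km = lens[j],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' True dung-density surface
#'
#' log D(s) (dung piles per ha) is linear in standardized landscape
#' covariates at s: distance to headquarters, to the boundary, to roads
#' and towns, the pre-epoch deforestation index, and a swamp-habitat
#' bump. Covariates are z-scored against a fixed reference lattice over
#' the park, so each coefficient is a per-standard-deviation effect on
#' log density and the intercept is the log of the typical density.
#' Epoch 2 is the epoch-1 surface multiplied by the decline factor,
#' except within the refuge radius of the headquarters where the
#' refuge multiplier is applied on top.
#'
#' @param ls_obj a [landscape()].
#' @param config a [sim_config()].
#' @return function `(points, epoch)` returning density per ha at the
#'   given points; `epoch` is 1 or 2.
#' @export
density_surface <- function(ls_obj, config) {
  b <- config$beta
  force(ls_obj)
  raw_covs <- function(points) {
    points <- matrix(points, ncol = 2)
    d_road <- rep(Inf, nrow(points))
    for (r in ls_obj$roads) {
      d_road <- pmin(d_road, dist_point_polyline(points, r))
    }
    swamp <- 0
    if (!is.null(ls_obj$habitat_grid)) {
      hg <- ls_obj$habitat_grid
      swamp <- vapply(seq_len(nrow(points)), function(i) {
        j <- which.min((hg$x_km - points[i, 1])^2 +
                         (hg$y_km - points[i, 2])^2)
        as.numeric(hg$habitat[j] == "swamp_forest")
      }, numeric(1))
    }
    cbind(
      dist_hq = sqrt((points[, 1] - ls_obj$headquarters[1])^2 +
                       (points[, 2] - ls_obj$headquarters[2])^2),
      dist_boundary = dist_point_polyline(points, ls_obj$boundary,
                                          closed = TRUE),
      dist_road = d_road,
      dist_town = dist_point_points(points, ls_obj$towns),
      deforestation = deforestation_index(points, ls_obj$grid,
                                          "nonforest_t1_km2"),
      swamp = swamp)
  }
  # reference lattice over the park fixes the standardization
  ref <- as.matrix(expand.grid(
    seq(4, config$park_x_km - 4, length.out = 18),
    seq(4, config$park_y_km - 4, length.out = 15)))
  refc <- raw_covs(ref)
  ctr <- colMeans(refc)
  scl <- apply(refc, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  ctr["swamp"] <- 0; scl["swamp"] <- 1  # indicator left unscaled
  coef <- c(dist_hq = b$dist_hq, dist_boundary = b$dist_boundary,
            dist_road = b$dist_road, dist_town = b$dist_town,
            deforestation = b$deforestation, swamp = b$swamp)
  function(points, epoch = 1) {
    z <- sweep(sweep(raw_covs(points), 2, ctr), 2, scl, "/")
    D <- exp(b$intercept + drop(z %*% coef[colnames(z)]))
    if (epoch == 2) {
      d_hq_raw <- z[, "dist_hq"] * scl["dist_hq"] + ctr["dist_hq"]
      mult <- ifelse(d_hq_raw <= config$refuge_radius_km,
                     config$decline_factor * config$refuge_multiplier,
                     config$decline_factor)
      D <- D * mult
    }
    D
  }
}

#' Simulate a line-transect dung survey for one epoch
#'
#' Per transect, the expected pile count over the simulation strip is
#' mu_i = D(midpoint) * 2 * w_sim * l_i (in consistent units); realized
#' counts are negative binomial with mean mu_i and variance phi * mu_i
#' (Poisson when phi = 1). Each pile gets a uniform perpendicular
#' distance on [0, w_sim] and is detected with probability g(x), so
#' observed distances follow the detection density g(x)/ESW.
#'
#' @param ls_obj landscape; `transects` the layout from
#'   [generate_transects()]; `config` a [sim_config()]; `epoch` 1 or 2;
#'   `epoch_label` the label stamped on observations.
#' @param transects transect table shared between epochs.
#' @param config a [sim_config()].
#' @param epoch 1 or 2.
#' @param epoch_label label for the dataset (defaults to "1995"/"2006").
#' @return a [survey_dataset()] with attribute `ledger` (true density,
#'   expected counts, realized pile counts, seeds).
#' @export
simulate_survey <- function(ls_obj, transects, config, epoch,
                            epoch_label = NULL) {
  if (is.null(epoch_label)) {
    epoch_label <- if (epoch == 1) "1995" else "2006"
  }
  set.seed(config$seed + 1000L * as.integer(epoch) + 7L)
  surf <- density_surface(ls_obj, config)
  mid <- transect_midpoints(transects)
  D <- surf(mid, epoch)   # per ha
  w_km <- config$w_sim_m / 1000
  area_ha <- 2 * w_km * transects$length_km * 100
  mu <- D * area_ha
  counts <- if (config$phi > 1) {
    stats::rnbinom(length(mu), mu = mu, size = mu / (config$phi - 1))
  } else {
    stats::rpois(length(mu), mu)
  }
  g <- detection_g(config$detection$family,
                   unlist(config$detection[-1]))
  obs <- list()
  for (i in seq_along(counts)) {
    if (counts[i] == 0) next
    x <- stats::runif(counts[i], 0, config$w_sim_m)
    keep <- stats::runif(counts[i]) < g(x)
    if (!any(keep)) next
    obs[[length(obs) + 1]] <- data.frame(
      transect_id = transects$transect_id[i],
      epoch = epoch_label,
      perpendicular_distance_m = round(x[keep], 2),
      stringsAsFactors = FALSE)
  }
  obs <- if (length(obs) > 0) {
    do.call(rbind, obs)
  } else {
    data.frame(transect_id = character(0), epoch = character(0),
               perpendicular_distance_m = numeric(0))
  }
  ds <- survey_dataset(epoch_label, obs, transects)
  attr(ds, "ledger") <- list(
    seed = config$seed, epoch = epoch,
    true_density_per_ha = D, expected_counts = mu,
    realized_piles = counts, w_sim_m = config$w_sim_m)
  ds
}

#' Simulate a complete two-epoch study
#'
#' Landscape, shared transect layout, and one survey per epoch, plus a
#' truth ledger (true densities at transect midpoints, the park-wide
#' true dung population per epoch by numerical integration, and the
#' realized decline).
#'
#' @param config a [sim_config()].
#' @param grid_step_km integration step for the true dung population.
#' @return list `landscape`, `transects`, `surveys` (list of two
#'   [survey_dataset()]s), `surface` (the density function), `ledger`.
#' @export
simulate_study <- function(config = sim_config(), grid_step_km = 4) {
  ls_obj <- generate_landscape(config)
  transects <- generate_transects(config, ls_obj)
  surf <- density_surface(ls_obj, config)
  ds1 <- simulate_survey(ls_obj, transects, config, 1)
  ds2 <- simulate_survey(ls_obj, transects, config, 2)
  gx <- seq(grid_step_km / 2, config$park_x_km, by = grid_step_km)
  gy <- seq(grid_step_km / 2, config$park_y_km, by = grid_step_km)
  gpts <- as.matrix(expand.grid(gx, gy))
  cell_ha <- grid_step_km^2 * 100
  pop <- vapply(1:2, function(e) sum(surf(gpts, e)) * cell_ha,
                numeric(1))
  ledger <- list(
    seed = config$seed,
    true_dung_population = pop,
    true_decline_fraction = 1 - pop[2] / pop[1],
    epoch1 = attr(ds1, "ledger"), epoch2 = attr(ds2, "ledger"))
  list(landscape = ls_obj, transects = transects,
       surveys = list(ds1, ds2), surface = surf, ledger = ledger)
}

#' Write a truth ledger as JSON
#' @param ledger ledger list from [simulate_study()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  jsonlite::write_json(ledger, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
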