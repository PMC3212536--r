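# shared fixtures, built in code

# tiny hand-checkable survey: 2 locations, 3 transects, 7 observations
toy_survey <- function(epoch = "1995") {
  transects <- data.frame(
    transect_id = c("T1", "T2", "T3"),
    location_id = c("L1", "L1", "L2"),
    x_km = c(10, 10, 40), y_km = c(10, 10, 25),
    bearing_deg = c(0, 90, 180),
    length_km = c(3, 4, 5),
    stringsAsFactors = FALSE)
  observations <- data.frame(
    transect_id = c("T1", "T1", "T2", "T2", "T2", "T2", "T2"),
    epoch = epoch,
    perpendicular_distance_m = c(0.5, 1.2, 0.1, 2.4, 0.9, 1.7, 3),
    stringsAsFactors = FALSE)
  survey_dataset(epoch, observations, transects)
}

# published-style two-epoch survey summaries (effort 280 km, 51 units)
table_estimates <- function() {
  list(
    d1 = density_estimate_from_summary("1995", n = 460, L = 280,
                                       esw = 2.01, k = 51,
                                       cv_encounter = 0.1863,
                                       cv_density = 0.1907),
    d2 = density_estimate_from_summary("2006", n = 286, L = 280,
                                       esw = 2.40, k = 51,
                                       cv_encounter = 0.2808,
                                       cv_density = 0.2870))
}

# simulate a spherical Gaussian random field at given points
grf_spherical <- function(pts, nugget, partial_sill, range_km, seed) {
  set.seed(seed)
  model <- list(family = "spherical", nugget = nugget,
                partial_sill = partial_sill, range_km = range_km)
  h <- as.matrix(stats::dist(pts))
  sill <- nugget + partial_sill
  C <- sill - variogram_gamma(h, model)
  diag(C) <- sill
  drop(t(chol(C + diag(1e-8, nrow(pts)))) %*% stats::rnorm(nrow(pts)))
}
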