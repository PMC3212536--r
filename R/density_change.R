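#' Dung density from counts, effort and effective strip width
#'
#' D = n / (2 * ESW * L), the standard line-transect estimator: n
#' detections over a surveyed strip of effective area 2 * ESW * L.
#' Returned per hectare.
#'
#' @param n number of observations (dung piles).
#' @param L total effort in km.
#' @param esw effective strip width in meters.
#' @return density in dung piles per hectare.
#' @export
estimate_density <- function(n, L, esw) {
  if (L <= 0) stop("effort L must be > 0", call. = FALSE)
  if (esw <= 0) stop("esw must be > 0", call. = FALSE)
  if (n < 0) stop("n must be >= 0", call. = FALSE)
  # effective area: 2 * (esw m -> km) * L km = km^2; 1 km^2 = 100 ha
  n / (2 * (esw / 1000) * L) / 100
}

#' Encounter rate and its coefficient of variation
#'
#' Rate n/L with the classical effort-weighted between-unit variance
#' estimator over k independent sampling units (locations):
#' var(n/L) = k / (L^2 (k-1)) * sum l_i^2 (n_i/l_i - n/L)^2.
#'
#' @param pooled per-location table from [pool_by_location()] (or any
#'   data frame with `effort_km` and `n_obs`).
#' @return list with `rate` (per km), `cv` (fraction; `NA` with an error
#'   attribute if k < 2), `n`, `L`, `k`.
#' @export
encounter_rate <- function(pooled) {
  l <- pooled$effort_km
  ni <- pooled$n_obs
  k <- length(l)
  L <- sum(l)
  n <- sum(ni)
  rate <- n / L
  if (k < 2) {
    stop("need at least 2 sampling units for an encounter-rate CV",
         call. = FALSE)
  }
  v <- k / (L^2 * (k - 1)) * sum(l^2 * (ni / l - rate)^2)
  cv <- if (rate > 0) sqrt(v) / rate else NA_real_
  list(rate = rate, cv = cv, n = n, L = L, k = k)
}

#' Log-normal confidence interval for a density estimate
#'
#' (D / C, D * C) with C = exp(z * sqrt(log(1 + CV^2))), the conventional
#' interval for a positively skewed density estimate.
#'
#' @param D density (any unit).
#' @param cv coefficient of variation as a fraction.
#' @param alpha two-sided error rate (default 0.05 -> 95% interval).
#' @return numeric length-2 `c(low, high)`.
#' @export
density_interval <- function(D, cv, alpha = 0.05) {
  stopifnot(D >= 0, cv >= 0)
  z <- stats::qnorm(1 - alpha / 2)
  C <- exp(z * sqrt(log(1 + cv^2)))
  c(low = D / C, high = D * C)
}

#' Per-epoch density estimate from a survey dataset and detection model
#'
#' Combines the pooled encounter rate, the ESW and the variance
#' decomposition CV(D)^2 = CV(n/L)^2 + CV(ESW)^2 into a Table-style
#' density estimate with a log-normal CI.
#'
#' @param ds a [survey_dataset()].
#' @param detection a `detection_model` (its `esw`, `cv_esw` are used).
#' @param alpha CI error rate.
#' @return object of class `density_estimate`: `epoch`, `n`, `L`, `k`,
#'   `encounter_rate`, `cv_encounter`, `esw`, `cv_esw`, `density`
#'   (per ha), `cv_density` (fractions throughout), `ci`.
#' @export
density_estimate <- function(ds, detection, alpha = 0.05) {
  pooled <- pool_by_location(ds)
  er <- encounter_rate(pooled)
  D <- estimate_density(er$n, er$L, detection$esw)
  cv_d <- sqrt(er$cv^2 + detection$cv_esw^2)
  structure(
    list(epoch = ds$epoch, n = er$n, L = er$L, k = er$k,
         encounter_rate = er$rate, cv_encounter = er$cv,
         esw = detection$esw, cv_esw = detection$cv_esw,
         density = D, cv_density = cv_d,
         ci = density_interval(D, cv_d, alpha)),
    class = "density_estimate")
}

#' Assemble a density estimate from summary numbers
#'
#' For working from published survey summaries (counts, effort, ESW and
#' CVs) rather than raw observations.
#'
#' @param epoch label.
#' @param n,L,k counts, effort (km), sampling units.
#' @param esw effective strip width (m); `cv_esw` as a fraction.
#' @param cv_encounter encounter-rate CV as a fraction (optional if
#'   `cv_density` given).
#' @param cv_density density CV as a fraction; defaults to the
#'   decomposition `sqrt(cv_encounter^2 + cv_esw^2)`.
#' @param alpha CI error rate.
#' @return a `density_estimate`.
#' @export
density_estimate_from_summary <- function(epoch, n, L, esw, k = NA,
                                          cv_encounter = NA,
                                          cv_esw = NA,
                                          cv_density = NULL,
                                          alpha = 0.05) {
  D <- estimate_density(n, L, esw)
  if (is.null(cv_density)) {
    cv_density <- sqrt(cv_encounter^2 + cv_esw^2)
  }
  structure(
    list(epoch = as.character(epoch), n = n, L = L, k = k,
         encounter_rate = n / L, cv_encounter = cv_encounter,
         esw = esw, cv_esw = cv_esw, density = D,
         cv_density = cv_density,
         ci = density_interval(D, cv_density, alpha)),
    class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf("Density estimate, epoch %s\n", x$epoch))
  cat(sprintf("  n = %d, L = %.1f km, k = %s, n/L = %.3f /km (CV %.1f%%)\n",
              x$n, x$L, as.character(x$k), x$encounter_rate,
              100 * x$cv_encounter))
  cat(sprintf("  ESW = %.3f m (CV %.1f%%)\n", x$esw, 100 * x$cv_esw))
  cat(sprintf("  D = %.3f /ha (CV %.1f%%), 95%% CI %.2f-%.2f\n",
              x$density, 100 * x$cv_density, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Two-survey z-test for a change in density
#'
#' Tests the null that the difference between two density estimates is
#' zero: z = (D1 - D2) / sqrt(se1^2 + se2^2), with se = D * CV. The
#' default p-value is one-sided (upper tail: a decline from survey 1 to
#' survey 2).
#'
#' @param d1,d2 `density_estimate` objects (epoch 1, epoch 2).
#' @param two_sided report a two-sided p instead.
#' @return list with `z`, `p`, `percent_change` (100 * (D1 - D2)/D1;
#'   positive is a decline), `d1`, `d2`.
#' @export
ztest_change <- function(d1, d2, two_sided = FALSE) {
  se1 <- d1$density * d1$cv_density
  se2 <- d2$density * d2$cv_density
  if (se1 == 0 && se2 == 0) {
    stop("both standard errors are zero; z undefined", call. = FALSE)
  }
  z <- (d1$density - d2$density) / sqrt(se1^2 + se2^2)
  p <- stats::pnorm(z, lower.tail = FALSE)
  if (two_sided) p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  list(z = z, p = p,
       percent_change = 100 * (d1$density - d2$density) / d1$density,
       d1 = d1, d2 = d2)
}

#' Classify per-location density changes and test against random change
#'
#' Each paired location is classified as declined / same / increased by
#' comparing the change in density to a tolerance `epsilon`; the three
#' counts are tested against equal expected frequencies with a
#' chi-square goodness-of-fit test (df = 2).
#'
#' @param d1_loc,d2_loc per-location densities (same order/length), any
#'   common unit.
#' @param epsilon half-width of the "same" band, in the density unit of
#'   the inputs (default 0.1).
#' @return list with `counts` (declined, same, increased), `chi_square`,
#'   `p`, `deltas`.
#' @export
classify_changes <- function(d1_loc, d2_loc, epsilon = 0.1) {
  if (length(d1_loc) != length(d2_loc) || length(d1_loc) == 0) {
    stop("need paired, non-empty density vectors", call. = FALSE)
  }
  stopifnot(epsilon >= 0)
  delta <- d2_loc - d1_loc
  cls <- ifelse(abs(delta) <= epsilon, "same",
                ifelse(delta < 0, "declined", "increased"))
  counts <- c(declined = sum(cls == "declined"),
              same = sum(cls == "same"),
              increased = sum(cls == "increased"))
  gof <- change_gof(counts)
  list(counts = counts, chi_square = gof$chi_square, p = gof$p,
       deltas = delta, classes = cls)
}

#' Chi-square goodness of fit of change counts against uniformity
#'
#' @param counts length-3 vector (declined, same, increased).
#' @return list with `chi_square` and `p` (df = 2).
#' @export
change_gof <- function(counts) {
  stopifnot(length(counts) == 3, all(counts >= 0))
  E <- sum(counts) / 3
  chi <- sum((counts - E)^2 / E)
  list(chi_square = chi,
       p = stats::pchisq(chi, df = 2, lower.tail = FALSE))
}

#' Convert dung density to elephant density
#'
#' E = (D_dung * 100) / (decay_days * defecation_rate): dung piles/ha
#' scaled to km^2 and divided by the steady-state dung production per
#' elephant (piles per day times mean pile survival in days).
#'
#' @param d_dung_per_ha dung density, piles per hectare.
#' @param defecation_rate dung piles per elephant per day (default
#'   19.77).
#' @param decay_days mean dung survival in days (default 44).
#' @return elephants per km^2.
#' @export
dung_to_elephants <- function(d_dung_per_ha, defecation_rate = 19.77,
                              decay_days = 44) {
  stopifnot(defecation_rate > 0, decay_days > 0, d_dung_per_ha >= 0)
  (d_dung_per_ha * 100) / (decay_days * defecation_rate)
}

#' Extrapolate an elephant density to a population size
#'
#' The density is rounded to 2 decimals before multiplying by the area,
#' and the product is rounded to a whole count — matching how reserve
#' totals are conventionally reported from a rounded density.
#'
#' @param e_per_km2 elephants per km^2.
#' @param area_km2 reserve area (default 13700).
#' @param digits decimals the density is rounded to first (default 2).
#' @return integer population size.
#' @export
extrapolate_population <- function(e_per_km2, area_km2 = 13700,
                                   digits = 2) {
  stopifnot(e_per_km2 >= 0, area_km2 > 0)
  round(round(e_per_km2, digits) * area_km2)
}

#' Convert an ivory mass to an elephant count
#'
#' total_kg / kg_per_elephant, rounded to a whole number of animals.
#' Note 23687 / 6.9 = 3433.0 exactly; this function returns 3433 for
#' that input (published roundings of the same arithmetic sometimes
#' differ by one animal).
#'
#' @param total_kg ivory mass in kg.
#' @param kg_per_elephant mean ivory per elephant (default 6.9 kg).
#' @return integer count.
#' @export
ivory_to_elephants <- function(total_kg, kg_per_elephant = 6.9) {
  stopifnot(total_kg > 0, kg_per_elephant > 0)
  round(total_kg / kg_per_elephant)
}

#' Full before/after change report
#'
#' z-test on the two density estimates, per-location change
#' classification with chi-square, dung-to-elephant conversion and
#' population extrapolation.
#'
#' @param d1,d2 `density_estimate` objects.
#' @param d1_loc,d2_loc optional per-location densities for the
#'   classification stage (skipped if `NULL`).
#' @param conversion list with `defecation_rate`, `decay_days`,
#'   `area_km2` (defaults 19.77, 44, 13700).
#' @param epsilon "same" tolerance for [classify_changes()].
#' @return object of class `change_report`.
#' @export
change_report <- function(d1, d2, d1_loc = NULL, d2_loc = NULL,
                          conversion = list(), epsilon = 0.1) {
  cv <- utils::modifyList(
    list(defecation_rate = 19.77, decay_days = 44, area_km2 = 13700),
    conversion)
  zt <- ztest_change(d1, d2)
  e1 <- dung_to_elephants(d1$density, cv$defecation_rate, cv$decay_days)
  e2 <- dung_to_elephants(d2$density, cv$defecation_rate, cv$decay_days)
  p1 <- extrapolate_population(e1, cv$area_km2)
  p2 <- extrapolate_population(e2, cv$area_km2)
  cls <- if (!is.null(d1_loc)) classify_changes(d1_loc, d2_loc, epsilon)
  structure(
    list(d1 = d1, d2 = d2, z = zt$z, p = zt$p,
         percent_decline = zt$percent_change,
         elephants_km2 = c(e1, e2),
         population = c(p1, p2), loss = p1 - p2,
         classification = cls, conversion = cv),
    class = "change_report")
}

#' @export
print.change_report <- function(x, ...) {
  cat(sprintf("Change %s -> %s: D %.2f -> %.2f /ha (%.0f%% decline)\n",
              x$d1$epoch, x$d2$epoch, x$d1$density, x$d2$density,
              x$percent_decline))
  cat(sprintf("  z = %.3f, one-sided p = %.4f\n", x$z, x$p))
  cat(sprintf("  elephants/km2 %.2f -> %.2f; population %d -> %d (loss %d)\n",
              x$elephants_km2[1], x$elephants_km2[2],
              x$population[1], x$population[2], x$loss))
  if (!is.null(x$classification)) {
    cc <- x$classification
    cat(sprintf("  locations declined/same/increased: %d/%d/%d (chi2 %.4f, p %.3f)\n",
                cc$counts[1], cc$counts[2], cc$counts[3],
                cc$chi_square, cc$p))
  }
  invisible(x)
}

#' Survey summary table (effort, encounter rate, ESW, density, CI)
#'
#' One row per `density_estimate`, in the conventional reporting layout:
#' Samples, Total effort (km), No obs., n/L (per km), CV(n/L) %, ESW (m),
#' D (per ha), CV(D) %, CI.
#'
#' @param estimates list of `density_estimate` objects.
#' @return data frame.
#' @export
density_table <- function(estimates) {
  rows <- lapply(estimates, function(e) {
    data.frame(
      Survey = e$epoch, Samples = e$k, Total_effort_km = e$L,
      No_obs = e$n, n_per_km = round(e$encounter_rate, 2),
      CV_n_per_km = round(100 * e$cv_encounter, 2),
      ESW_m = round(e$esw, 2), D_per_ha = round(e$density, 2),
      CV_D = round(100 * e$cv_density, 2),
      CI = sprintf("%.2f-%.2f", e$ci[1], e$ci[2]),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
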