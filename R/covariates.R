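#' Distance covariates for transect midpoints
#'
#' Euclidean distances (km) from each transect midpoint to the nearest
#' road, village, town, the park boundary and the headquarters.
#' Midpoints outside the park polygon are flagged (`inside_park`), with
#' distances still computed.
#'
#' @param transects transect table (`transect_id`, `x_km`, `y_km`,
#'   `bearing_deg`, `length_km`).
#' @param ls_obj a [landscape()].
#' @return data frame keyed by `transect_id` with `dist_road`,
#'   `dist_village`, `dist_town`, `dist_boundary`, `dist_hq` (km) and
#'   `inside_park`.
#' @export
distance_covariates <- function(transects, ls_obj) {
  stopifnot(inherits(ls_obj, "landscape"))
  mid <- transect_midpoints(transects)
  droad <- rep(Inf, nrow(mid))
  for (r in ls_obj$roads) droad <- pmin(droad, dist_point_polyline(mid, r))
  out <- data.frame(
    transect_id = transects$transect_id,
    dist_road = droad,
    dist_village = dist_point_points(mid, ls_obj$villages),
    dist_town = dist_point_points(mid, ls_obj$towns),
    dist_boundary = dist_point_polyline(mid, ls_obj$boundary,
                                        closed = TRUE),
    dist_hq = sqrt((mid[, 1] - ls_obj$headquarters[1])^2 +
                     (mid[, 2] - ls_obj$headquarters[2])^2),
    inside_park = point_in_polygon(mid, ls_obj$boundary),
    stringsAsFactors = FALSE)
  if (any(!out$inside_park)) {
    warning(sum(!out$inside_park),
            " transect midpoint(s) fall outside the park boundary")
  }
  out
}

#' Per-cell deforested area between two epochs
#'
#' Delta a_j = max(0, nonforest_t2 - nonforest_t1): forest regrowth is
#' clamped to zero so the index responds to deforestation only.
#'
#' @param grid deforestation grid (`nonforest_t1_km2`,
#'   `nonforest_t2_km2`).
#' @return the grid with a `deforested_km2` column appended.
#' @export
deforestation_change <- function(grid) {
  stopifnot(all(c("nonforest_t1_km2", "nonforest_t2_km2") %in%
                  names(grid)))
  grid$deforested_km2 <- pmax(0, grid$nonforest_t2_km2 -
                                grid$nonforest_t1_km2)
  grid
}

#' Composite deforestation index at a point
#'
#' I = sum over grid cells of a_j / d_j^exponent, with a_j the relevant
#' non-forested (or deforested) area of cell j and d_j the distance from
#' the point to the cell centre. High values mean large areas of
#' deforestation close to the point — a proxy for the intensity and
#' proximity of human activity. Distances are floored at half the cell
#' size so a point on a cell centre cannot blow up the sum.
#'
#' @param points two-column matrix of points (km), e.g. transect
#'   midpoints.
#' @param grid deforestation grid.
#' @param area_col which per-cell area drives the index:
#'   `"nonforest_t1_km2"`, `"nonforest_t2_km2"` or `"deforested_km2"`.
#' @param exponent inverse-distance power (default 1).
#' @return numeric index per point (dimensionless up to the km units).
#' @export
deforestation_index <- function(points, grid,
                                area_col = "nonforest_t1_km2",
                                exponent = 1) {
  points <- matrix(points, ncol = 2)
  if (is.null(grid) || nrow(grid) == 0) {
    warning("empty deforestation grid; index is zero")
    return(rep(0, nrow(points)))
  }
  stopifnot(area_col %in% names(grid), exponent > 0)
  a <- grid[[area_col]]
  floor_d <- grid$cell_km / 2
  vapply(seq_len(nrow(points)), function(i) {
    d <- sqrt((grid$cx_km - points[i, 1])^2 +
                (grid$cy_km - points[i, 2])^2)
    d <- pmax(d, floor_d)
    sum(a / d^exponent)
  }, numeric(1))
}

#' Assemble the full per-transect covariate table
#'
#' Distance covariates, the epoch-appropriate deforestation index, and
#' (when the landscape carries them) slope and habitat from
#' nearest-neighbour grid lookup.
#'
#' @param transects transect table.
#' @param ls_obj a [landscape()].
#' @param epoch_area column of the deforestation grid to use for the
#'   index (see [deforestation_index()]).
#' @param exponent inverse-distance power for the index.
#' @return data frame keyed by `transect_id`.
#' @export
covariate_table <- function(transects, ls_obj,
                            epoch_area = "nonforest_t1_km2",
                            exponent = 1) {
  out <- distance_covariates(transects, ls_obj)
  mid <- transect_midpoints(transects)
  out$deforestation_index <- deforestation_index(mid, ls_obj$grid,
                                                 epoch_area, exponent)
  nn_lookup <- function(g, col) {
    vapply(seq_len(nrow(mid)), function(i) {
      j <- which.min((g$x_km - mid[i, 1])^2 + (g$y_km - mid[i, 2])^2)
      g[[col]][j]
    }, g[[col]][1])
  }
  if (!is.null(ls_obj$slope_grid)) {
    out$slope <- nn_lookup(ls_obj$slope_grid, "slope_deg")
  }
  if (!is.null(ls_obj$habitat_grid)) {
    hg <- ls_obj$habitat_grid
    out$habitat <- nn_lookup(hg, "habitat")
    # proportion of the transect in each habitat class, from 11 points
    # sampled along the line (nearest-cell lookup per point)
    theta <- transects$bearing_deg * pi / 180
    fr <- seq(0, 1, length.out = 11)
    classes <- sort(unique(hg$habitat))
    props <- matrix(0, nrow(transects), length(classes),
                    dimnames = list(NULL, classes))
    for (i in seq_len(nrow(transects))) {
      px <- transects$x_km[i] + fr * transects$length_km[i] *
        sin(theta[i])
      py <- transects$y_km[i] + fr * transects$length_km[i] *
        cos(theta[i])
      cls <- vapply(seq_along(px), function(j) {
        hg$habitat[which.min((hg$x_km - px[j])^2 + (hg$y_km - py[j])^2)]
      }, character(1))
      props[i, ] <- tabulate(factor(cls, levels = classes),
                             nbins = length(classes)) / length(cls)
    }
    colnames(props) <- paste0("hab_", classes)
    out <- cbind(out, as.data.frame(props))
  }
  out
}

#' Screen covariates for collinearity
#'
#' Pairwise Pearson correlations among numeric covariates; whenever a
#' pair reaches `|r| >= r_max`, the lower-priority member is dropped.
#' Processing is deterministic: pairs are visited in priority order, and
#' a covariate already dropped no longer eliminates others.
#'
#' @param tab covariate data frame (non-numeric columns and
#'   `transect_id` are ignored by the screen and always retained).
#' @param r_max correlation threshold (default 0.6).
#' @param priority character vector, most important first; defaults to
#'   the column order of `tab`.
#' @return list with `retained` (character), `dropped` (named character
#'   vector: dropped -> offending partner), `correlations` (matrix).
#' @export
collinearity_screen <- function(tab, r_max = 0.6, priority = NULL) {
  num <- names(tab)[vapply(tab, is.numeric, TRUE)]
  num <- setdiff(num, "transect_id")
  if (nrow(tab) < 3) stop("need at least 3 transects", call. = FALSE)
  const <- num[vapply(num, function(v) stats::sd(tab[[v]]) == 0, TRUE)]
  if (length(const) > 0) {
    warning("constant column(s) dropped: ", paste(const, collapse = ", "))
    num <- setdiff(num, const)
  }
  if (is.null(priority)) priority <- num
  ord <- c(intersect(priority, num), setdiff(num, priority))
  R <- stats::cor(tab[, ord, drop = FALSE])
  retained <- character(0)
  dropped <- character(0)
  partner <- character(0)
  for (v in ord) {
    clash <- retained[abs(R[v, retained]) >= r_max]
    if (length(clash) == 0) {
      retained <- c(retained, v)
    } else {
      dropped <- c(dropped, v)
      partner <- c(partner, clash[1])
    }
  }
  names(partner) <- dropped
  list(retained = retained, dropped = partner, correlations = R)
}
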