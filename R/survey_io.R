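#' Construct a validated line-transect survey dataset
#'
#' Bundles per-observation perpendicular distances, per-transect geometry
#' and effort, and the sampling locations they belong to, for one survey
#' epoch. Transects are grouped into sampling locations (1--4 transects
#' radiating from a shared departure point); locations are the independent
#' sampling units for variance estimation.
#'
#' @param epoch survey label, e.g. `"1995"`.
#' @param observations data frame with columns `transect_id`, `epoch`,
#'   `perpendicular_distance_m` (meters, >= 0). One row per detected dung
#'   pile.
#' @param transects data frame with columns `transect_id`, `location_id`,
#'   `x_km`, `y_km` (planar origin, km), `bearing_deg`, `length_km`.
#' @return An object of class `survey_dataset`: a list with elements
#'   `epoch`, `observations`, `transects`, `locations` (one row per
#'   sampling location with its origin point and member transects), and
#'   summary fields `n` (total observations), `L` (total effort, km) and
#'   `k` (number of sampling locations).
#' @export
survey_dataset <- function(epoch, observations, transects) {
  obs_cols <- c("transect_id", "epoch", "perpendicular_distance_m")
  tr_cols <- c("transect_id", "location_id", "x_km", "y_km",
               "bearing_deg", "length_km")
  miss <- setdiff(obs_cols, names(observations))
  if (length(miss) > 0) {
    stop("observation table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  miss <- setdiff(tr_cols, names(transects))
  if (length(miss) > 0) {
    stop("transect table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  observations <- observations[observations$epoch == epoch, , drop = FALSE]
  observations$perpendicular_distance_m <-
    as.double(observations$perpendicular_distance_m)
  for (col in c("x_km", "y_km", "bearing_deg", "length_km")) {
    transects[[col]] <- as.double(transects[[col]])
  }
  d <- observations$perpendicular_distance_m
  if (anyNA(d) || any(!is.finite(d))) {
    stop("perpendicular distances must be finite", call. = FALSE)
  }
  if (any(d < 0)) {
    stop("perpendicular distances must be >= 0", call. = FALSE)
  }
  if (any(duplicated(transects$transect_id))) {
    stop("duplicated transect_id in transect table", call. = FALSE)
  }
  orphans <- setdiff(observations$transect_id, transects$transect_id)
  if (length(orphans) > 0) {
    stop("observations reference unknown transect(s): ",
         paste(utils::head(orphans, 5), collapse = ", "), call. = FALSE)
  }
  if (any(transects$length_km <= 0)) {
    stop("transect lengths must be > 0", call. = FALSE)
  }
  n_per_loc <- table(transects$location_id)
  if (any(n_per_loc > 4)) {
    stop("a sampling location may hold at most 4 transects", call. = FALSE)
  }

  locs <- unique(transects[, c("location_id", "x_km", "y_km")])
  if (any(duplicated(locs$location_id))) {
    stop("transects at one location must share a departure point",
         call. = FALSE)
  }
  locs <- locs[order(locs$location_id), , drop = FALSE]
  rownames(locs) <- NULL

  structure(
    list(
      epoch = as.character(epoch),
      observations = observations,
      transects = transects,
      locations = locs,
      n = nrow(observations),
      L = sum(transects$length_km),
      k = nrow(locs)
    ),
    class = "survey_dataset"
  )
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("Line-transect survey dataset, epoch", x$epoch, "\n")
  cat(sprintf("  %d observations on %d transects at %d locations\n",
              x$n, nrow(x$transects), x$k))
  cat(sprintf("  total effort %.2f km\n", x$L))
  invisible(x)
}

#' Read a survey dataset from CSV tables
#'
#' @param observations_csv path to the observation table (columns
#'   `transect_id`, `epoch`, `perpendicular_distance_m`).
#' @param transects_csv path to the transect table (columns `transect_id`,
#'   `location_id`, `x_km`, `y_km`, `bearing_deg`, `length_km`).
#' @param epoch epoch label to extract; defaults to the single epoch
#'   present in the observation table (an error if there are several).
#' @return a [survey_dataset()].
#' @export
read_survey <- function(observations_csv, transects_csv, epoch = NULL) {
  obs <- utils::read.csv(observations_csv, stringsAsFactors = FALSE,
                         colClasses = NA)
  trs <- utils::read.csv(transects_csv, stringsAsFactors = FALSE)
  if (!"perpendicular_distance_m" %in% names(obs)) {
    stop("observation table is missing column(s): perpendicular_distance_m",
         call. = FALSE)
  }
  if (!is.numeric(obs$perpendicular_distance_m)) {
    stop("perpendicular_distance_m does not parse as numeric", call. = FALSE)
  }
  obs$epoch <- as.character(obs$epoch)
  if (is.null(epoch)) {
    epochs <- unique(obs$epoch)
    if (length(epochs) != 1) {
      stop("observation table holds epochs ",
           paste(epochs, collapse = ", "),
           "; pass `epoch` to choose one", call. = FALSE)
    }
    epoch <- epochs
  }
  survey_dataset(epoch, obs, trs)
}

#' Write a survey dataset to CSV tables
#'
#' Numeric fields are written at fixed precision (10 significant digits)
#' so that a write/read round trip reproduces distances, lengths and
#' counts exactly for data recorded at field precision (cm distances,
#' metre-scale transect lengths).
#'
#' @param ds a [survey_dataset()].
#' @param observations_csv,transects_csv output paths.
#' @return invisibly, the two paths.
#' @export
write_survey <- function(ds, observations_csv, transects_csv) {
  stopifnot(inherits(ds, "survey_dataset"))
  fmt <- function(x) if (is.numeric(x)) sprintf("%.10g", x) else x
  obs <- as.data.frame(lapply(ds$observations, fmt),
                       stringsAsFactors = FALSE)
  trs <- as.data.frame(lapply(ds$transects, fmt), stringsAsFactors = FALSE)
  utils::write.csv(obs, observations_csv, row.names = FALSE, quote = FALSE)
  utils::write.csv(trs, transects_csv, row.names = FALSE, quote = FALSE)
  invisible(c(observations_csv, transects_csv))
}

#' Pool observations and effort by sampling location
#'
#' Transects within a sampling location share a departure point and are
#' not independent; pooling them yields the independent sampling units
#' used for encounter-rate variance. Pooling conserves totals:
#' `sum(effort_km) == ds$L` and `sum(n_obs) == ds$n`.
#'
#' @param ds a [survey_dataset()].
#' @return data frame with one row per location: `location_id`, `x_km`,
#'   `y_km`, `effort_km` (summed member lengths), `n_obs` (summed member
#'   counts), `rate_per_km`.
#' @export
pool_by_location <- function(ds) {
  stopifnot(inherits(ds, "survey_dataset"))
  trs <- ds$transects
  eff <- tapply(trs$length_km, trs$location_id, sum)
  counts_by_tr <- table(factor(ds$observations$transect_id,
                               levels = trs$transect_id))
  loc_of <- trs$location_id[match(names(counts_by_tr), trs$transect_id)]
  cnt <- tapply(as.integer(counts_by_tr), loc_of, sum)
  out <- ds$locations
  out$effort_km <- as.numeric(eff[as.character(out$location_id)])
  out$n_obs <- as.integer(cnt[as.character(out$location_id)])
  out$n_obs[is.na(out$n_obs)] <- 0L
  out$rate_per_km <- out$n_obs / out$effort_km
  rownames(out) <- NULL
  out
}
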