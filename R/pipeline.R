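#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis. In simulate mode the
#' data come from [simulate_study()]; otherwise observation/transect
#' CSVs and a landscape GeoJSON + grid CSV are read.
#'
#' @param simulate a [sim_config()] for simulate mode, or `NULL`.
#' @param observations_csv,transects_csv,landscape_geojson,grid_csv
#'   input paths for non-simulate mode.
#' @param epochs two epoch labels, oldest first.
#' @param w truncation distance (m) for detection fits; `NULL` = max
#'   observed.
#' @param families detection families to fit and compare by AIC.
#' @param conversion list: `defecation_rate`, `decay_days`, `area_km2`.
#' @param epsilon "same" tolerance for change classification (density
#'   per ha).
#' @param krige_step_km kriging prediction grid spacing.
#' @param gi_band_km Gi* distance band; `NULL` = 2x median
#'   nearest-neighbour distance.
#' @param gam_smooth,gam_linear candidate GAM terms (screened for
#'   collinearity before fitting).
#' @param r_max collinearity threshold.
#' @param k_basis smooth basis dimension.
#' @param out_dir output directory.
#' @param seed integer seed (forwarded to simulate mode).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = sim_config(),
                            observations_csv = NULL,
                            transects_csv = NULL,
                            landscape_geojson = NULL, grid_csv = NULL,
                            epochs = c("1995", "2006"),
                            w = NULL,
                            families = c("uniform", "half-normal",
                                         "hazard-rate"),
                            conversion = list(defecation_rate = 19.77,
                                              decay_days = 44,
                                              area_km2 = 13700),
                            epsilon = 0.1,
                            krige_step_km = 5, gi_band_km = NULL,
                            gam_smooth = c("dist_hq", "dist_boundary",
                                           "dist_town", "dist_road",
                                           "deforestation_index"),
                            gam_linear = c("slope", "hab_swamp_forest"),
                            r_max = 0.6, k_basis = 5,
                            out_dir = tempfile("pipeline_"),
                            seed = 1) {
  if (is.null(simulate)) {
    paths <- c(observations_csv, transects_csv, landscape_geojson)
    if (any(!file.exists(paths))) {
      stop("input path(s) missing in non-simulate mode", call. = FALSE)
    }
  } else {
    simulate$seed <- seed
  }
  structure(as.list(environment()), class = "pipeline_config")
}

config_hash <- function(txt) {
  h <- 5381
  for (b in utf8ToInt(txt)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full before/after survey analysis
#'
#' Stages, in order: data acquisition (simulate or read), per-epoch
#' detection-function fitting with AIC selection, per-epoch density
#' estimation, change inference (z-test, per-location classification,
#' conversions, population extrapolation), ordinary kriging and Gi*
#' hotspots per epoch, covariate construction with collinearity
#' screening, and per-epoch density-surface GAMs (univariate table,
#' human-only and human+habitat composites, partial effects). Every
#' stage writes its artifact under `config$out_dir`; a failing stage
#' aborts with the stage name after writing a failure marker.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory results and the paths
#'   written (`$paths`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  add_path <- function(p) paths[[length(paths) + 1]] <<- p
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0(name, ": ", conditionMessage(e)),
                 file.path(out, paste0("FAILED_", name, ".txt")))
      stop("pipeline stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE)
    })
  }

  dat <- stage("data", {
    if (!is.null(config$simulate)) {
      simulate_study(config$simulate)
    } else {
      ls_obj <- read_landscape(config$landscape_geojson,
                               config$grid_csv)
      trs <- utils::read.csv(config$transects_csv,
                             stringsAsFactors = FALSE)
      surveys <- lapply(config$epochs, function(e) {
        read_survey(config$observations_csv, config$transects_csv,
                    epoch = e)
      })
      list(landscape = ls_obj, transects = trs, surveys = surveys,
           ledger = NULL)
    }
  })

  detections <- stage("detection", {
    lapply(dat$surveys, function(ds) {
      fits <- lapply(config$families, function(fam) {
        fit_detection(ds$observations$perpendicular_distance_m,
                      family = fam, w = config$w)
      })
      best <- select_model(fits)
      p <- file.path(out, paste0("detection_", ds$epoch, ".json"))
      detection_to_json(best, p)
      add_path(p)
      best
    })
  })

  densities <- stage("density", {
    ests <- Map(density_estimate, dat$surveys, detections)
    p <- file.path(out, "density_table.csv")
    utils::write.csv(density_table(ests), p, row.names = FALSE)
    add_path(p)
    ests
  })

  loc_density <- stage("per_location_density", {
    lapply(seq_along(dat$surveys), function(i) {
      pooled <- pool_by_location(dat$surveys[[i]])
      pooled$density_per_ha <- vapply(seq_len(nrow(pooled)), function(j) {
        estimate_density(pooled$n_obs[j], pooled$effort_km[j],
                         detections[[i]]$esw)
      }, numeric(1))
      pooled
    })
  })

  change <- stage("change", {
    rep <- change_report(densities[[1]], densities[[2]],
                         loc_density[[1]]$density_per_ha,
                         loc_density[[2]]$density_per_ha,
                         conversion = config$conversion,
                         epsilon = config$epsilon)
    p <- file.path(out, "change_report.json")
    jsonlite::write_json(
      list(z = rep$z, p = rep$p,
           percent_decline = rep$percent_decline,
           elephants_km2 = rep$elephants_km2,
           population = rep$population, loss = rep$loss,
           counts = as.list(rep$classification$counts),
           chi_square = rep$classification$chi_square,
           p_chi = rep$classification$p),
      p, auto_unbox = TRUE, digits = NA)
    add_path(p)
    rep
  })

  spatial <- stage("spatial", {
    lapply(seq_along(loc_density), function(i) {
      ld <- loc_density[[i]]
      pts <- as.matrix(ld[, c("x_km", "y_km")])
      ep <- dat$surveys[[i]]$epoch
      emp <- empirical_semivariogram(pts, ld$density_per_ha)
      vg <- tryCatch(suppressWarnings(fit_variogram(emp, "spherical")),
                     error = function(e) NULL)
      surf <- NULL
      if (!is.null(vg)) {
        grid <- prediction_grid(range(pts[, 1]), range(pts[, 2]),
                                config$krige_step_km)
        surf <- krige(pts, ld$density_per_ha, vg, grid)
        p1 <- file.path(out, paste0("kriged_", ep, ".csv"))
        write_kriged_surface(surf, p1)
        add_path(p1)
      }
      hs <- getis_ord_gistar(pts, ld$density_per_ha,
                             band_km = config$gi_band_km)
      hs <- cbind(location_id = ld$location_id, hs)
      p2 <- file.path(out, paste0("hotspots_", ep, ".csv"))
      utils::write.csv(hs, p2, row.names = FALSE)
      add_path(p2)
      list(variogram = vg, surface = surf, hotspots = hs)
    })
  })

  covars <- stage("covariates", {
    lapply(seq_along(dat$surveys), function(i) {
      acol <- if (i == 1) "nonforest_t1_km2" else "nonforest_t2_km2"
      tab <- covariate_table(dat$transects, dat$landscape, acol)
      p <- file.path(out, paste0("covariates_",
                                 dat$surveys[[i]]$epoch, ".csv"))
      utils::write.csv(tab, p, row.names = FALSE)
      add_path(p)
      tab
    })
  })

  gams <- stage("dsm", {
    lapply(seq_along(dat$surveys), function(i) {
      ds <- dat$surveys[[i]]
      tab <- covars[[i]]
      counts <- table(factor(ds$observations$transect_id,
                             levels = dat$transects$transect_id))
      y <- as.integer(counts)
      off <- effort_offset(dat$transects$length_km,
                           detections[[i]]$esw)
      cand <- intersect(c(config$gam_smooth, config$gam_linear),
                        names(tab))
      prio <- c("dist_road", "dist_village", "dist_town",
                "dist_boundary", "dist_hq", "deforestation_index",
                "slope")
      scr <- collinearity_screen(tab[, c("transect_id", cand)],
                                 r_max = config$r_max,
                                 priority = c(intersect(prio, cand),
                                              setdiff(cand, prio)))
      sm <- intersect(config$gam_smooth, scr$retained)
      ln <- intersect(config$gam_linear, scr$retained)
      uni <- c(
        stats::setNames(lapply(sm, function(v) list(smooth = v)), sm),
        stats::setNames(lapply(ln, function(v) list(linear = v)), ln))
      comp <- list(
        "human covariates only" = list(smooth = sm),
        "human + habitat" = list(smooth = sm, linear = ln))
      rep <- table_gam_report(y, off, tab, uni, comp,
                              k = config$k_basis)
      p <- file.path(out, paste0("gam_report_", ds$epoch, ".csv"))
      utils::write.csv(rep, p, row.names = FALSE)
      add_path(p)
      fits <- attr(rep, "fits")
      full <- fits[["human + habitat"]]
      pe <- do.call(rbind, lapply(sm, function(v) {
        cbind(covariate = v, partial_effect(full, v, tab))
      }))
      p2 <- file.path(out, paste0("partial_effects_", ds$epoch, ".csv"))
      utils::write.csv(pe, p2, row.names = FALSE)
      add_path(p2)
      list(report = rep, screen = scr, full = full)
    })
  })

  manifest <- stage("manifest", {
    cfg_json <- jsonlite::toJSON(
      config[setdiff(names(config), "out_dir")],
      auto_unbox = TRUE, force = TRUE, digits = NA)
    m <- list(package = "dungsurvey",
              version = as.character(utils::packageVersion("dungsurvey")),
              seed = config$seed, config_hash = config_hash(cfg_json),
              r_version = paste(R.version$major, R.version$minor,
                                sep = "."))
    p <- file.path(out, "manifest.json")
    jsonlite::write_json(m, p, auto_unbox = TRUE, digits = NA)
    add_path(p)
    m
  })

  invisible(list(data = dat, detections = detections,
                 densities = densities, loc_density = loc_density,
                 change = change, spatial = spatial,
                 covariates = covars, gams = gams,
                 manifest = manifest, paths = paths))
}
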