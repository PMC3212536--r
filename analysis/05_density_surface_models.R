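#!/usr/bin/env Rscript
# Stage 5: density-surface GAMs. Per epoch: build the per-transect
# covariate table (distances, deforestation index, slope, habitat),
# screen collinearity at |r| >= 0.6, fit univariate quasipoisson GAMs
# with the effort offset, then the composite "human only" and
# "human + habitat" models, and run backward deletion from the full
# human set.

suppressPackageStartupMessages(library(dungsurvey))

dat <- "results/data"
out <- "results/gam"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ls_obj <- read_landscape(file.path(dat, "landscape.geojson"),
                         file.path(dat, "deforestation_grid.csv"))
# habitat/slope lattices are not serialized; regenerate them from the
# same configuration used in stage 1
cfg <- sim_config(seed = 20260927)
ls_full <- generate_landscape(cfg)

trs <- utils::read.csv(file.path(dat, "transects.csv"))

for (i in 1:2) {
  epoch <- c("1995", "2006")[i]
  acol <- c("nonforest_t1_km2", "nonforest_t2_km2")[i]
  ds <- read_survey(file.path(dat, "observations.csv"),
                    file.path(dat, "transects.csv"), epoch = epoch)
  det <- detection_from_json(
    file.path("results/density", paste0("detection_", epoch, ".json")))
  tab <- covariate_table(trs, ls_full, acol)
  y <- as.integer(table(factor(ds$observations$transect_id,
                               levels = trs$transect_id)))
  off <- effort_offset(trs$length_km, det$esw)

  human_cand <- c("dist_road", "dist_village", "dist_town",
                  "dist_boundary", "dist_hq", "deforestation_index")
  scr <- collinearity_screen(tab[, c("transect_id", human_cand,
                                     "slope")],
                             priority = c(human_cand, "slope"))
  cat(sprintf("%s screen dropped: %s\n", epoch,
              paste(names(scr$dropped), collapse = ", ")))
  human <- intersect(human_cand, scr$retained)
  hab <- intersect(c("slope", "hab_swamp_forest", "hab_hill_forest"),
                   names(tab))
  hab <- hab[vapply(hab, function(v) sd(tab[[v]]) > 0, TRUE)]

  uni <- c(
    stats::setNames(lapply(human, function(v) list(smooth = v)), human),
    stats::setNames(lapply(hab, function(v) list(linear = v)), hab))
  comp <- list("human covariates only" = list(smooth = human),
               "human + habitat" = list(smooth = human, linear = hab))
  rep <- table_gam_report(y, off, tab, uni, comp)
  print(rep)
  utils::write.csv(rep, file.path(out, paste0("gam_report_", epoch,
                                              ".csv")),
                   row.names = FALSE)

  bd <- backward_delete(y, off, tab, smooth = human, linear = hab)
  cat(sprintf("%s minimal adequate model keeps: %s (GCV %.3f)\n",
              epoch, paste(c(bd$smooth, bd$linear), collapse = ", "),
              bd$fit$gcv))
  utils::write.csv(bd$trace, file.path(out, paste0("backward_trace_",
                                                   epoch, ".csv")),
                   row.names = FALSE)

  full <- attr(rep, "fits")[["human + habitat"]]
  pe <- do.call(rbind, lapply(human, function(v) {
    cbind(covariate = v, partial_effect(full, v, tab))
  }))
  utils::write.csv(pe, file.path(out, paste0("partial_effects_", epoch,
                                             ".csv")),
                   row.names = FALSE)
}
cat("wrote GAM reports, backward-deletion traces and partial effects",
    "under", out, "\n")
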