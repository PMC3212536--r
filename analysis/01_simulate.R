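#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study -- a ~13,700 km^2 reserve, 110
# transects at 51 sampling locations, and two survey epochs with a true
# 50% density decline buffered inside a refuge around the headquarters.
# Writes the raw survey tables, landscape and truth ledger that the
# later stages consume.

suppressPackageStartupMessages(library(dungsurvey))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 20260927)
st <- simulate_study(cfg)

write_survey(st$surveys[[1]], file.path(out, "observations_1995.csv"),
             file.path(out, "transects.csv"))
obs2 <- st$surveys[[2]]$observations
all_obs <- rbind(st$surveys[[1]]$observations, obs2)
utils::write.csv(all_obs, file.path(out, "observations.csv"),
                 row.names = FALSE)
write_landscape(st$landscape, file.path(out, "landscape.geojson"),
                file.path(out, "deforestation_grid.csv"))
write_ledger(st$ledger, file.path(out, "truth_ledger.json"))

cat(sprintf("epoch 1: %d observations over %.0f km\n",
            st$surveys[[1]]$n, st$surveys[[1]]$L))
cat(sprintf("epoch 2: %d observations over %.0f km\n",
            st$surveys[[2]]$n, st$surveys[[2]]$L))
cat(sprintf("true park-wide dung decline: %.1f%%\n",
            100 * st$ledger$true_decline_fraction))
cat("wrote survey tables, landscape and ledger under", out, "\n")
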