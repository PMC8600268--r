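#!/usr/bin/env Rscript
# Stage 4: adult phenology from field surveys.
#
# Computes the development index (DI, count-weighted mean stage, 1 = all
# first instars to 6 = all adults) from the weekly stage counts, smooths
# DI against day of year and against cumulative degree-days with a
# GCV-tuned cubic spline, and estimates adult timing as the first upward
# crossing of DI = 5.5. Contrasts the warm and cool season: calendar
# timing shifts, degree-day timing barely moves.

suppressPackageStartupMessages({
  library(hopperdev)
  library(dplyr)
  library(tidyr)
})

surveys <- read_survey_csv("results/data/surveys.csv")
gdd <- readr::read_csv("results/gdd.csv", show_col_types = FALSE)

di <- di_series(surveys, gdd = gdd)
write_table(di, "results/di_series.csv")

timing <- adult_timing_table(di, threshold = 5.5)
write_table(timing, "results/adult_timing.csv")

cat("Adult timing (DI = 5.5 crossing) per site and year:\n")
print(as.data.frame(timing), digits = 5)

wide <- timing |>
  filter(status == "estimated") |>
  pivot_wider(id_cols = site, names_from = year,
              values_from = c(doy_at_threshold, gdd_at_threshold))
doy_shift <- wide[[2]] - wide[[3]]
gdd_shift <- wide[[4]] - wide[[5]]
cat(sprintf(
  "\nWarm-minus-cool shifts: %.1f to %.1f days earlier on the calendar axis,\nbut only %.0f to %.0f degree-days apart on the physiological axis —\nadult timing is conserved in GDD while day-of-year responds to warmth.\nWrote results/di_series.csv and results/adult_timing.csv\n",
  min(doy_shift), max(doy_shift), min(abs(gdd_shift)), max(abs(gdd_shift))
))
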