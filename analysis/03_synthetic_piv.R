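#!/usr/bin/env Rscript
# Synthetic LED-PIV acquisition and processing for the high-amplitude case:
# renders one phase-locked cycle (25 double-exposure pairs) of Womersley
# flow in the straight inlet region, runs the full preprocessing +
# three-pass correlation + validation chain, and derives axial profiles,
# vorticity, and the axisymmetric flow-rate reconstruction.
#
# Writes: results/tables/{invalid_rates.csv, flow_rate_FH.csv,
#         profile_peak_FH.csv}; results/figures/{profiles_FH.png,
#         flowrate_FH.png, example_pair.png}

suppressPackageStartupMessages({
  library(aaapiv)
  library(ggplot2)
})
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

cfg <- default_run_config("FH", "C4", seed = 1)
st <- run_pipeline(cfg, stages = c("generate", "piv", "metrics"),
                   out_dir = "results/run_FH")

rates <- vapply(st$fields, function(f) attr(f, "invalid_rate"), 0)
write.csv(data.frame(phase = st$dataset$phase,
                     t_s = st$dataset$phase_t[st$dataset$phase],
                     invalid_rate = rates),
          "results/tables/invalid_rates.csv", row.names = FALSE)
message(sprintf("Invalid-vector rate: mean %.2f%%, range %.2f-%.2f%% (inside the 0.5-3%% benchmark band for idealized-phantom
  acquisitions).",
  100 * mean(rates), 100 * min(rates), 100 * max(rates)))

# save one rendered pair as 16-bit TIFF for inspection
write_pair_tiff(st$dataset$pairs[[5]], "results", cycle = 1, phase = 5)

# axial velocity profile at peak systole vs the analytic solution
ds <- st$dataset
i_pk <- which.min(abs(ds$phase_t - 0.124))
f <- st$fields[[i_pk]]
fld <- shift_field_origin(f, 0, -cfg$roi$height_px / 2 / ds$camera$scale)
band <- fld$x_mm >= 8 & fld$x_mm <= 12
u_prof <- rowMeans(fld$u_ms[, band], na.rm = TRUE)
r_mm <- fld$y_mm
ana <- womersley_profile(ds$waveform, ds$d, ds$fluid,
                         r = pmin(abs(r_mm), 10) / 1000,
                         t = ds$phase_t[i_pk])
prof <- data.frame(r_mm = r_mm, u_piv = u_prof, u_womersley = ana)
write.csv(prof, "results/tables/profile_peak_FH.csv", row.names = FALSE)
gg <- ggplot(prof, aes(r_mm)) +
  geom_line(aes(y = u_womersley), linetype = 3) +
  geom_point(aes(y = u_piv), size = 1.2, colour = "steelblue") +
  coord_flip() +
  labs(x = "transverse position [mm]", y = "axial velocity [m/s]",
       title = "FH peak systole: PIV (points) vs Womersley (dotted)") +
  theme_minimal()
ggsave("results/figures/profiles_FH.png", gg, width = 5, height = 6,
       dpi = 150)

# flow-rate reconstruction across the cycle
m <- st$metrics
write.csv(m, "results/tables/flow_rate_FH.csv", row.names = FALSE)
gg2 <- ggplot(m, aes(t_s)) +
  geom_line(aes(y = q_ref_lmin), linetype = 2) +
  geom_point(aes(y = q_piv_lmin), colour = "firebrick") +
  labs(x = "phase [s]", y = "flow [L/min]",
       title = "PIV-derived flow rate (points) vs reference (dashed)") +
  theme_minimal()
ggsave("results/figures/flowrate_FH.png", gg2, width = 7, height = 4,
       dpi = 150)
message(sprintf("Flow-rate reconstruction: max |error| = %.2f L/min (benchmark: < 2 L/min).", max(abs(m$q_piv_lmin - m$q_ref_lmin))))

# vorticity at peak systole (interior check: shear layers at the walls)
w <- vorticity(f)
message(sprintf("Peak-systole vorticity spans %.0f to %.0f 1/s across the
  inlet window.", min(w, na.rm = TRUE), max(w, na.rm = TRUE)))
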