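#!/usr/bin/env Rscript
# Step 1: generate the synthetic inputs used by the rest of the workflow —
# a vessel phantom stack with analytic ground truth, line scans at known
# velocities, a 162-track longitudinal fate table, and two-channel
# coverage fixtures. Everything downstream reads from results/.

suppressPackageStartupMessages(library(capfate))
dir.create("results/inputs", showWarnings = FALSE, recursive = TRUE)
set.seed(1000)

## 12 near-axial capillary phantoms (r = 2 um, L = 75 um each)
cfg <- synth_config(dims = c(160L, 160L, 44L), blur_sigma_um = 0.2,
                    read_noise_sd = 5, seed = 11)
ang <- runif(12, 0, 2 * pi)
tilt <- runif(12, 0, 3) * pi / 180
specs <- lapply(seq_len(12), function(i) {
  gx <- 14 + ((i - 1) %% 4) * 25
  gy <- 14 + ((i - 1) %/% 4) * 28
  cylinder_spec(c(gx, gy, 4),
                c(gx + 75 * sin(tilt[i]) * cos(ang[i]),
                  gy + 75 * sin(tilt[i]) * sin(ang[i]),
                  4 + 75 * cos(tilt[i])), 2)
})
phantom <- generate_vessel_stack(specs, cfg)
write_stack_text(phantom$stack, "results/inputs/phantom_stack.csv")
write_phantom_truth(phantom$truth, "results/inputs/phantom_truth.json")
cat(sprintf("phantom: %d vessels, analytic volume %.1f um^3 (count %.1f)\n",
            phantom$truth$n_vessels, phantom$truth$total_volume,
            phantom$truth$total_volume / capillary_volume()))

## line scans at known velocities (um/s)
velocities <- c(200, 500, 800, 1200)
for (v in velocities) {
  ls <- generate_linescan(v, line_period_ms = 1, pixel_pitch_um = 2,
                          noise_sd = 6, seed = v)
  write_linescan_text(ls, sprintf("results/inputs/linescan_v%d.csv", v))
}
cat("line scans written for velocities:", paste(velocities, collapse = ", "),
    "um/s\n")

## longitudinal fate table: the 21-day microsphere cohort's stated world
fates <- generate_fate_table(seed = 2000)
write_fate_table(fates, "results/inputs/fate_table.csv")
cat(sprintf("fate table: %d tracks x %d timepoints\n",
            length(unique(fates$track)), length(unique(fates$time_day))))

## coverage fixtures spanning the observed pVEGF-R2 range
for (cov in c(4, 13, 25, 60)) {
  p <- generate_coloc_projection(0.35, cov, seed = cov, dims = c(101, 101))
  utils::write.csv(which(p$vessel_mask, arr.ind = TRUE),
                   sprintf("results/inputs/coloc_vessel_%02d.csv", cov),
                   row.names = FALSE)
  utils::write.csv(which(p$signal_mask, arr.ind = TRUE),
                   sprintf("results/inputs/coloc_signal_%02d.csv", cov),
                   row.names = FALSE)
}
cat("coverage fixtures written (4, 13, 25, 60 % quotas)\n")
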