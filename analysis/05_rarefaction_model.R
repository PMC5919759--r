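#!/usr/bin/env Rscript
# Step 5: the capillary-loss model. 100,000 theoretical capillaries, 2-hr
# cycles, per-branch-order obstruction risks summing to 0.118%/day, 30%
# pruning of obstructed vessels. Expected-value and Monte-Carlo modes;
# headline predictions at 365 and 405 days.

suppressPackageStartupMessages(library(capfate))
dir.create("results", showWarnings = FALSE)

## one year, homogeneous risk: the back-of-envelope prediction
cfg365 <- rarefaction_config(daily_rate = 0.00118, p_prune = 0.30,
                             duration_days = 365)
red <- (1 - predicted_remaining(cfg365, 365)) * 100
cat(sprintf("365 days, homogeneous risk: %.2f%% density reduction (~12%%)\n",
            red))

## 405 days (~13.5 months) with branch-order structure
bt <- default_branch_order_table()
cfg405 <- rarefaction_config(n_capillaries = 100000, duration_days = 405,
                             branch_table = bt, seed = 99)
exp_traj <- simulate_expected(cfg405)
mc_traj <- simulate_monte_carlo(cfg405)
cat(sprintf("405 days: expected %.2f%%, Monte-Carlo %.2f%% remaining\n",
            100 * exp_traj$remaining[nrow(exp_traj)],
            100 * mc_traj$remaining[nrow(mc_traj)]))
hom405 <- predicted_remaining(rarefaction_config(duration_days = 405), 405)
cat(sprintf("Jensen bracket: homogeneous floor %.2f%% <= structured <= ~89%%\n",
            100 * hom405))

## daily-resolution trajectory table
keep <- exp_traj$day %% 1 == 0
write.csv(data.frame(day = exp_traj$day[keep],
                     remaining_expected = exp_traj$remaining[keep],
                     remaining_mc = mc_traj$remaining[keep]),
          "results/rarefaction_trajectory.csv", row.names = FALSE)
cat("trajectory written to results/rarefaction_trajectory.csv\n")
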