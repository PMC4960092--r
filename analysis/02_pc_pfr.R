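#!/usr/bin/env Rscript
# PC pathway: decode the velocity maps, build ROI flow curves, and apply the
# three-phase peak rule to both PC acquisitions. Finds that the 43.2 ms
# acquisition underestimates the true peak by a few percent while the
# 100.8 ms acquisition loses ~16 %, reproducing the temporal-vs-spatial
# ordering. Writes results/pc_flow_curves.csv and results/pc_pfr.json.

suppressPackageStartupMessages(library(pfrkit))

if (!dir.exists("scratch/phantom"))
  stop("run analysis/01_simulate_phantom.R first")
truth <- jsonlite::read_json("results/phantom_truth.json",
                             simplifyVector = TRUE)$true_pfr

res <- list()
curves <- NULL
for (method in c("temporal_pc", "spatial_pc")) {
  series <- read_series("scratch/phantom", prefix = method)
  fc <- flow_curve(series)
  fc$method <- method
  curves <- rbind(curves, fc)
  k <- find_visual_peak(series)
  pfr <- pfr_from_three_phases(series, visual_peak_index = k)
  res[[method]] <- c(unclass(pfr)[c("pfr", "peak_filling_time", "method")],
                     list(visual_peak_index = k,
                          deficit_pct = 100 * (1 - pfr$pfr / truth)))
  cat(sprintf("%-11s peak phase %2d: PFR %.1f mL/s (%.1f %% below truth)\n",
              method, k, pfr$pfr, 100 * (1 - pfr$pfr / truth)))
}

write.csv(curves, "results/pc_flow_curves.csv", row.names = FALSE)
jsonlite::write_json(res, "results/pc_pfr.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
cat("Wrote results/pc_flow_curves.csv and results/pc_pfr.json\n")
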