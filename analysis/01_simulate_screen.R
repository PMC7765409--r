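#!/usr/bin/env Rscript
# Simulate the full primary-screen campaign in summary mode: 4 x 384-well
# plates, stimulator controls in column 11, neutral controls in column 12,
# 1.2% planted true actives and 0.8% cytotoxic wells, then run the whole
# chain (QC -> hit calling -> retest -> dose-response -> clustering ->
# profiling) through run_screen(). Outputs land in results/campaign/.

library(steatoscreen)

cfg <- run_config(seed = 2026L, out_dir = file.path("results", "campaign"))
manifest <- run_screen(cfg)

cat("Campaign complete.\n")
cat(sprintf("  wells simulated:    %d\n", manifest$counts$wells))
cat(sprintf("  planted actives:    %d (%.2f%% of compound wells)\n",
            manifest$counts$planted_actives,
            100 * manifest$counts$planted_actives / (manifest$counts$wells -
                                                       4 * 32)))
cat(sprintf("  planted cytotoxic:  %d\n", manifest$counts$planted_cytotoxic))
cat(sprintf("  primary hits:       %d\n", manifest$counts$hits))
cat(sprintf("  cytotoxic calls:    %d\n", manifest$counts$cytotoxic))
cat(sprintf("  confirmed (2-dose): %d\n", manifest$counts$confirmed))
cat(sprintf("  dose-dependent:     %d\n", manifest$counts$dose_dependent))
cat(sprintf("  clusters at k=3:    %d\n", manifest$counts$clusters))
cat("Manifest written to results/campaign/manifest.json\n")
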