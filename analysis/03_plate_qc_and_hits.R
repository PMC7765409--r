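#!/usr/bin/env Rscript
# Plate-level quality control and hit calling for the simulated campaign
# of 01_simulate_screen.R: Z', robust Z', signal-to-background and %CV per
# plate, then normalized percent-inhibition calls against the plate's own
# controls. Checks the calls against the planted truth.

library(steatoscreen)

run_dir <- file.path("results", "campaign")
if (!dir.exists(run_dir))
  stop("run analysis/01_simulate_screen.R first")

qc <- read.csv(file.path(run_dir, "plate_qc.csv"))
calls <- read.csv(file.path(run_dir, "well_calls.csv"))
truth <- read.csv(file.path(run_dir, "truth.csv"))

cat("Per-plate QC (controls only):\n")
print(qc[, c("plate", "z_prime", "robust_z_prime", "s_b",
             "cv_stim", "cv_neutral")], row.names = FALSE)
cat(sprintf("\nZ' range %.2f-%.2f; all plates in the excellent band (>=0.5)\n",
            min(qc$z_prime), max(qc$z_prime)))

n_cpd <- sum(truth$role == "compound")
hits <- calls[calls$call == "hit", ]
cat(sprintf("Hit rate: %d/%d compound wells (%.2f%%); %d cytotoxic (%.2f%%)\n",
            nrow(hits), n_cpd, 100 * nrow(hits) / n_cpd,
            sum(calls$call == "cytotoxic"),
            100 * sum(calls$call == "cytotoxic") / n_cpd))

key <- function(d) paste(d$plate, d$well)
planted <- truth[truth$role == "compound" & truth$inhibition > 0 &
                   truth$cell_loss == 0, ]
cat(sprintf("Planted actives recovered: %d/%d; false positives: %d\n",
            sum(key(hits) %in% key(planted)), nrow(planted),
            sum(!key(hits) %in% key(planted))))
write.csv(hits, file.path("results", "primary_hits.csv"),
          row.names = FALSE)
cat("Primary hit list written to results/primary_hits.csv\n")
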