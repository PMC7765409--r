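#!/usr/bin/env Rscript
# Dose-response confirmation. First a positive-control check: a 10-point
# curve generated at the potency of the pharmacological control (obeticholic
# acid, true IC50 0.63 uM) is refitted and must come back at pIC50 6.2.
# Then the campaign's confirmed hits (from 01) are summarized: fitted
# IC50/pIC50, censoring, activity at the 10 uM threshold and five-fold
# viability selectivity.

library(steatoscreen)

dir.create("results", showWarnings = FALSE)

oca <- generate_dose_series(dose_series_spec(
  top = 100, bottom = 0, ic50 = 0.63e-6, hill = 1,
  concentrations = conc_series("10pt"), n_replicates = 3, cv = 0.1,
  seed = 2026))
f <- fit_4pl(oca$concentration, oca$response)
cat(sprintf("OCA control: fitted IC50 %.2f uM, pIC50 %.1f (true 0.63 uM / 6.2)\n",
            f$ic50 * 1e6, f$pic50))

# triage pattern of the three prioritized CDK-inhibitor hits: activity
# IC50s 45 nM / 4.6 uM / 0.32 uM against viability 17.8 / 16.6 / >30 uM
panel <- data.frame(compound = c("C1", "C16", "C3"),
                    act = c(45e-9, 4.6e-6, 0.32e-6),
                    via = c(17.8e-6, 16.6e-6, 1e-3))
x <- conc_series("10pt")
tri <- do.call(rbind, lapply(seq_len(nrow(panel)), function(i) {
  af <- fit_4pl(x, fourpl(x, 100, 0, panel$act[i], 1))
  vf <- fit_4pl(x, fourpl(x, 100, 0, panel$via[i], 1))
  cbind(compound = panel$compound[i], triage(af, vf))
}))
cat("\nPrioritized-compound triage (activity <= 10 uM, selectivity >= 5x):\n")
print(tri[, c("compound", "activity_ic50", "viability_ic50",
              "viability_censored", "active", "selective")],
      row.names = FALSE)

run_dr <- file.path("results", "campaign", "dose_response.csv")
if (file.exists(run_dr)) {
  dr <- read.csv(run_dr)
  cat(sprintf("\nCampaign: %d/%d confirmed hits are dose-dependent (IC50 <= 10 uM)\n",
              sum(dr$active), nrow(dr)))
  cat(sprintf("Fitted pIC50 range: %.2f-%.2f\n",
              min(dr$pic50), max(dr$pic50)))
  write.csv(dr[, c("compound", "ic50", "pic50", "hill", "active",
                   "ic50_censored")],
            file.path("results", "confirmed_fits.csv"), row.names = FALSE)
  cat("Confirmed-hit fits written to results/confirmed_fits.csv\n")
}
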