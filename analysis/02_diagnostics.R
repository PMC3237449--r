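#!/usr/bin/env Rscript
# S-system diagnostics of the flux-balanced SL-E model: consistency of the
# aggregation, eigenvalue stability, logarithmic gains and rate-constant
# sensitivities, and the ranking of pools by summed large log gains.

suppressMessages(library(sleBST))
dir.create("results", showWarnings = FALSE)

m <- sle_model("balanced")
ss <- as_ssystem(m)
cat(sprintf("aggregation consistency: max |Vin - Vout|/Vin = %.2e\n",
            max(abs(ss$Vin - ss$Vout) / ss$Vin)))

ev <- stability_eigenvalues(ss)
cat(sprintf("eigenvalues: %d total, %d with negative real part, %d complex\n",
            length(ev), sum(Re(ev) < 0), sum(Im(ev) != 0)))
cat(sprintf("slowest mode: Re = %.4g /min (t1/2 ~ %.0f min); fastest: %.3g\n",
            max(Re(ev)), log(2) / abs(max(Re(ev))), min(Re(ev))))
write.csv(data.frame(re = Re(ev), im = Im(ev)),
          "results/02_eigenvalues.csv", row.names = FALSE)

rep <- sensitivity_report(ss)
cat(sprintf("sensitivities: %d entries, %.1f%% below 1 in magnitude (max %.2f)\n",
            rep$summary$n_entries, 100 * rep$summary$fraction_below_one,
            rep$summary$max_magnitude))
write_sensitivity_report(rep, "results/02_sensitivity_report")

rk <- top_loggain_ranking(rep, 10)
cat("\npools ranked by summed log-gain magnitudes above 1:\n")
print(data.frame(pool = as.character(rk), score = attr(rk, "scores")),
      row.names = FALSE)
cat("\nMost perturbations are attenuated (majority of magnitudes < 1); the\n")
cat("largest gains sit on the low-concentration intermediates whose levels\n")
cat("are set by pathways outside the model boundary.\n")
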