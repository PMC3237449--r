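#!/usr/bin/env Rscript
# Regenerates the shipped plain-text copies of the synthetic SL-E model
# (inst/extdata/*.plas, labeling map, pool definitions) from the in-code
# constructors. Run from the repository root after changing the model.

suppressMessages(devtools::load_all(".", quiet = TRUE))

hdr <- function(variant) c(
  "Synthetic reconstruction of the integrated sphingolipid-ergosterol (SL-E)",
  "network of S. cerevisiae in GMA power-law form.",
  sprintf("Variant: %s.", variant),
  "Generated by scripts/make_sle_data.R; edit the flux table in",
  "R/sle-model.R, not this file.",
  "Units: uM for metabolites, mol% for sphingolipid classes, % of the",
  "wild-type total sterol amount for sterol pools; time in minutes.")

write_plas(sle_model("dynamic"), "inst/extdata/sle_synthetic_dynamic.plas",
           header = hdr("dynamic (tracer simulations)"))
write_plas(sle_model("balanced"), "inst/extdata/sle_synthetic_balanced.plas",
           header = hdr("flux balanced (total-mass experiments, diagnostics)"))
write_labeling_yaml(sle_labeling(sle_model("dynamic")),
                    "inst/extdata/sle_labeling.yaml")
yaml::write_yaml(sle_pools(), "inst/extdata/sle_pools.yaml")
cat("wrote inst/extdata files\n")
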