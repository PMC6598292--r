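#!/usr/bin/env Rscript
# Build the synthetic C4 core model, verify its construction guarantees and
# export it in both interchange formats. Downstream drivers re-generate the
# model from the same seed rather than reading these files, so the exports
# are purely for inspection and external tools.

suppressPackageStartupMessages(library(c4balance))
dir.create("results", showWarnings = FALSE)

cfg <- core_config(seed = 1L, n_filler = 20L)
core <- generate_core_model(cfg)
print(core)

write_sbml(core, "results/core_model.xml")
write_model_tables(core, "results/core_reactions.csv",
                   "results/core_metabolites.csv")

bal <- check_model_balance(core)
cat("balance verdicts:\n")
print(table(bal$verdict))
stopifnot(all(bal$verdict %in% c("balanced", "boundary_exempt")))

cat("\nThe generated core is elementally and charge balanced in every",
    "internal reaction; boundary pseudo-reactions (exchanges, biomass",
    "sinks) are exempt by construction.\n")
cat("Analytic NH4+:NO3- co-uptake ratio for this configuration:",
    round(expected_n_ratio(cfg), 4), "\n")
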