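#!/usr/bin/env Rscript
# Stem lignocellulose production on the wired multi-tissue model: per-gram
# photon and sucrose fluxes for the three cell-wall polymers under proton
# balance, the proton-balance dependence of the triose-phosphate shuttle,
# and the three-way partition of stem reaction/gene sets.

suppressPackageStartupMessages(library(c4balance))
dir.create("results", showWarnings = FALSE)

core <- generate_core_model(core_config(seed = 1L, n_filler = 5L))
tm_pb <- wire_c4(replicate_tissues(core), wiring_config(proton_policy = "PB"))
tm_rel <- wire_c4(replicate_tissues(core),
                  wiring_config(proton_policy = "relaxed"))

comps <- c("cellulose", "hemicellulose", "lignin")
runs <- lapply(comps, function(cc) scenario_lignocellulose(tm_pb, cc, 1))
names(runs) <- comps

tab <- do.call(rbind, lapply(comps, function(cc) {
  s <- runs[[cc]]$summary
  data.frame(component = cc, photon_MP = s[["photon_MP"]],
             photon_BS = s[["photon_BS"]],
             photon_total = s[["photon_total"]],
             sucrose_bs_st = s[["suc_bs_st"]],
             shuttle_triose = s[["shuttle_triose"]])
}))
print(tab, digits = 4)
utils::write.csv(tab, "results/lignocellulose_fluxes.csv", row.names = FALSE)
cat("\nLignin is the photon-costliest polymer per gram; sucrose from the",
    "bundle sheath is the stem's sole carbon and energy source in every",
    "run.\n\n")

## shuttle behaviour: proton balance vs relaxed external H+
rel <- scenario_lignocellulose(tm_rel, "cellulose", 1, psii_asymmetry = 1)
cat(sprintf("Triose shuttle flux: P_B %.4f vs relaxed %.4f\n",
            runs$cellulose$summary[["shuttle_triose"]],
            rel$summary[["shuttle_triose"]]))
cat(sprintf("O2 between cell types: P_B %.4f vs relaxed %.4f\n",
            runs$cellulose$summary[["o2_mp_bs"]], rel$summary[["o2_mp_bs"]]))
cat("Opening external H+ exchange deactivates the 3-PGA/DHAP shuttle and",
    "activates O2 movement from bundle sheath to mesophyll; photon demand",
    "shifts from the mesophyll to the bundle sheath.\n\n")

## stem reaction/gene set partition across the three polymers
sets <- lapply(runs, function(r) active_sets(r$solution, tm_pb,
                                             tissue = "ST"))
pr <- venn3(sets[[1]], sets[[2]], sets[[3]], names = comps)
pg <- venn3(sets[[1]], sets[[2]], sets[[3]], names = comps, what = "genes")
cat("stem reaction-set partition:\n")
print(pr[, c("region", "count")])
pr$ids <- vapply(pr$ids, paste, "", collapse = ";")
pg$ids <- vapply(pg$ids, paste, "", collapse = ";")
utils::write.csv(pr, "results/venn_stem_reactions.csv", row.names = FALSE)
utils::write.csv(pg, "results/venn_stem_genes.csv", row.names = FALSE)
cat("\nThe common region is sucrose import and degradation (shared energy",
    "and carbon backbone); each polymer keeps a unique terminal branch.\n")
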