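#!/usr/bin/env Rscript
# Step 4 — simulate the consortium experiment: 176 background communities of
# 2-6 members from a 10-strain pool (balanced prevalence), each measured
# alone and with each of two focal fermenter strains added (528 background
# assays), plus 12 monocultures and all 66 pairwise co-cultures — the
# 606-assay bookkeeping — in biological triplicate, with a held-out
# validation set of 131 never-measured communities on the same ground-truth
# landscape. Outputs under results/communities/.

suppressMessages(library(winescape))
seed <- as.integer(Sys.getenv("ANALYSIS_SEED", "1"))
out <- "results/communities"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

e <- simulate_community_experiment(seed = seed)

write_community_measurements(e$dataset, file.path(out, "measurements.csv"))
write.csv(e$validation, file.path(out, "validation.csv"), row.names = FALSE)
jsonlite::write_json(list(params = e$truth$params, tau = e$truth$tau,
                          eps = e$truth$eps, seed = e$truth$seed),
                     file.path(out, "truth.json"),
                     auto_unbox = TRUE, digits = NA)
write.csv(e$truth$landscape, file.path(out, "landscape.csv"),
          row.names = FALSE)

dc <- design_counts(e$design$n_backgrounds, e$design$n_schemes,
                    e$design$n_strains)
cat(sprintf("design: %d backgrounds x %d schemes = %d background assays\n",
            e$design$n_backgrounds, e$design$n_schemes, dc$background_assays))
cat(sprintf("plus %d monocultures and %d pairwise co-cultures: %d assays\n",
            dc$monocultures, dc$pairwise, dc$total))
cat(sprintf("measured compositions: %d (x3 replicates = %d measurements)\n",
            e$design$n_compositions, nrow(e$dataset)))
cat(sprintf("held-out validation communities: %d\n", nrow(e$validation)))
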