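#!/usr/bin/env Rscript
# Step 1 — simulate the strain collection that stands in for the wine-yeast
# panel: a 60-tip ultrametric phylogeny (with a few identical-marker strain
# pairs), 43 quantitative traits with per-trait phylogenetic signal drawn
# from 0..1, and a taxonomy table (marker group / species / genus).
# Outputs under results/collection/.

suppressMessages(library(winescape))
seed <- as.integer(Sys.getenv("ANALYSIS_SEED", "1"))
out <- "results/collection"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

col <- simulate_collection(n_strains = 60, n_traits = 43,
                           lambda_grid = seq(0, 1, by = 0.1), seed = seed)

ape::write.tree(col$tree, file.path(out, "tree.nwk"))
write_trait_table(col$traits, file.path(out, "traits.tsv"))
write.table(col$metadata, file.path(out, "metadata.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(col$truth, file.path(out, "truth.json"),
                     auto_unbox = TRUE, digits = NA)

cat(sprintf("collection: %d strains, %d traits, %d species, %d genera\n",
            length(col$tree$tip.label), ncol(col$traits),
            length(unique(col$metadata$species)),
            length(unique(col$metadata$genus))))
cat(sprintf("identical-marker strains: %d\n",
            sum(duplicated(col$metadata$marker_group))))
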