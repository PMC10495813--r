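#!/usr/bin/env Rscript
# Step 5 — the community-function landscape: fit each strain's functional
# effect equation (dF_i(B) = a_i + b_i F(B) + theta_i(B)), predict the
# held-out communities by concatenating FEEs over the subset lattice
# (weighted least squares), and compare against the additive baseline
# (monoculture function plus summed pairwise effects), overall and by
# community richness. Reads results/communities/, writes results/landscape/.

suppressMessages(library(winescape))
out <- "results/landscape"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

dataset <- read_community_measurements("results/communities/measurements.csv")
validation <- read.csv("results/communities/validation.csv",
                       colClasses = c(community_id = "character"))

res <- run_landscape_workflow(
  dataset,
  targets = validation$community_id,
  observations = data.frame(community_id = validation$community_id,
                            F_obs = validation$F_true),
  focal = "Sc5",
  out_dir = out)

tab <- attr(res$fees, "fee_table")
cat("fitted functional effect equations:\n")
print(tab[order(tab$strain_id), c("strain_id", "a", "b", "r2", "n_points")],
      row.names = FALSE, digits = 3)

ev <- res$metrics$fee$overall
cat(sprintf("\nFEE lattice predictor, %d held-out communities: r = %.3f, RMSE = %.3f\n",
            ev$n, ev$r, ev$rmse))
if (!is.null(res$metrics$additive)) {
  ea <- res$metrics$additive$overall
  cat(sprintf("additive baseline (focal-containing subset, n = %d): r = %.3f, RMSE = %.3f\n",
              ea$n, ea$r, ea$rmse))
  cat("additive RMSE by community richness:\n")
  print(res$metrics$additive$per_richness, row.names = FALSE, digits = 3)
}
write.csv(res$metrics$fee$per_community,
          file.path(out, "per_community_errors.csv"), row.names = FALSE)
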