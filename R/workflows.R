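#' Write a strain-by-trait table as TSV
#'
#' @param traits Matrix with strain rownames.
#' @param path Output path.
#' @export
write_trait_table <- function(traits, path) {
  df <- data.frame(strain_id = rownames(traits), as.data.frame(traits),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write community measurements as CSV
#' @param dataset Measurement data frame.
#' @param path Output path.
#' @export
write_community_measurements <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.as_tree <- function(tree) if (is.character(tree)) read_newick(tree) else tree
.as_traits <- function(traits)
  if (is.character(traits)) read_trait_table(traits) else as.matrix(traits)
.as_measurements <- function(x)
  if (is.character(x)) read_community_measurements(x) else x

#' Phylogenetic-signal workflow
#'
#' Scales the trait table, runs the per-trait Pagel's lambda estimate with
#' its permutation test, and (optionally) writes a TSV with columns trait,
#' lambda, loglik, p_value, significant. Deterministic for a fixed seed:
#' reruns produce byte-identical output.
#'
#' @param tree `phylo` object or newick path.
#' @param traits Trait matrix or TSV path.
#' @param n_perm Permutations per trait (default 1000).
#' @param seed Root seed.
#' @param out Optional output TSV path.
#' @return The signal table (invisibly if `out` is given).
#' @export
run_signal_workflow <- function(tree, traits, n_perm = 1000L, seed = 1L,
                                out = NULL) {
  tree <- .as_tree(tree)
  traits <- .as_traits(traits)
  scaled <- scale_traits(traits)
  tab <- signal_table(scaled, tree, n_perm = n_perm, seed = seed)
  if (!is.null(out)) {
    utils::write.table(format(tab, digits = 10, trim = TRUE), out, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Imputation workflow
#'
#' Leave-one-out cross-validated phylogenetic imputation at a taxonomic
#' exclusion level; optionally writes the prediction and variance tables and
#' a per-trait summary.
#'
#' @param tree `phylo` object or newick path.
#' @param traits Trait matrix or TSV path.
#' @param metadata Metadata data frame or TSV path (`NULL` allowed for
#'   `exclusion = "strain"`).
#' @param exclusion One of strain, marker, species, genus.
#' @param out_dir Optional output directory (`predictions.tsv`,
#'   `variances.tsv`, `per_trait.tsv`).
#' @return The [loocv_impute()] result.
#' @export
run_impute_workflow <- function(tree, traits, metadata = NULL,
                                exclusion = "strain", out_dir = NULL) {
  tree <- .as_tree(tree)
  traits <- .as_traits(traits)
  if (is.character(metadata)) metadata <- read_strain_metadata(metadata)
  res <- loocv_impute(tree, traits, metadata, exclusion = exclusion)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trait_table(res$predictions, file.path(out_dir, "predictions.tsv"))
    write_trait_table(res$variances, file.path(out_dir, "variances.tsv"))
    per_trait <- data.frame(trait = names(res$per_trait_r),
                            r = unname(res$per_trait_r))
    utils::write.table(format(per_trait, digits = 10, trim = TRUE),
                       file.path(out_dir, "per_trait.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}

#' Community-function landscape workflow
#'
#' Fits the per-strain functional effect equations, predicts every target
#' community with the subset-lattice predictor and, when a focal strain is
#' given, with the additive baseline; evaluates both against observations
#' when available. Unfittable strains are reported with a warning and the
#' run continues.
#'
#' @param measurements Measurement data frame or CSV path (training data).
#' @param targets Character vector of canonical community ids to predict
#'   (default: every measured community, i.e. in-sample check).
#' @param observations Optional data frame `community_id`, `F_obs` (or a
#'   measurement table) the predictions are scored against.
#' @param focal Optional focal strain id for the additive baseline (targets
#'   must contain it).
#' @param scope Lattice scope, `"interval"` or `"powerset"`.
#' @param sigma2_floor Residual-variance floor for the FEE fits.
#' @param out_dir Optional output directory (`fees.json`, `predictions.csv`,
#'   `metrics.csv`).
#' @return List: `fees`, `predictions`, `additive` (or `NULL`), `metrics`.
#' @export
run_landscape_workflow <- function(measurements, targets = NULL,
                                   observations = NULL, focal = NULL,
                                   scope = "interval", sigma2_floor = 1e-4,
                                   out_dir = NULL) {
  dataset <- .as_measurements(measurements)
  fees <- fit_all_fees(dataset, sigma2_floor = sigma2_floor)
  if (is.null(targets)) targets <- setdiff(unique(dataset$community_id), "")
  pred <- predict_many(targets, dataset, fees, scope = scope)
  additive <- NULL
  if (!is.null(focal)) {
    eff <- additive_effects(dataset, focal)
    f_sc <- attr(eff, "monoculture_F")
    rows <- lapply(targets, function(id) {
      mem <- community_members(id)
      if (!focal %in% mem) return(NULL)
      p <- additive_predict(setdiff(mem, focal), f_sc, eff)
      data.frame(community_id = id, F_pred = p$F_pred,
                 F_pred_raw = p$F_pred_raw, clipped = p$clipped)
    })
    additive <- do.call(rbind, rows)
  }
  metrics <- NULL
  if (!is.null(observations)) {
    metrics <- list(fee = evaluate_predictions(pred, observations))
    if (!is.null(additive) && nrow(additive) > 0)
      metrics$additive <- evaluate_predictions(additive, observations)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fees_json(fees, file.path(out_dir, "fees.json"))
    utils::write.csv(pred, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(metrics)) {
      mrows <- lapply(names(metrics), function(nm)
        cbind(model = nm, metrics[[nm]]$overall))
      utils::write.csv(do.call(rbind, mrows), file.path(out_dir, "metrics.csv"),
                       row.names = FALSE, quote = FALSE)
    }
  }
  list(fees = fees, predictions = pred, additive = additive, metrics = metrics)
}
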