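#' Impute missing tip traits under Brownian motion
#'
#' Conditional-Gaussian prediction: with observed tips `o`, missing tips `m`,
#' phylogenetic covariance `C` and GLS root estimate
#' `mu_hat = (1' Coo^-1 x_o) / (1' Coo^-1 1)`, the point estimate is
#' `x_m = mu_hat + Cmo Coo^-1 (x_o - mu_hat)` and the predictive variance is
#' `sigma2_hat * (Cmm - Cmo Coo^-1 Com)` plus the propagated uncertainty of
#' the estimated mean. This equals rerooting the phylogeny at the missing
#' tip's attachment point and running maximum-likelihood ancestral state
#' reconstruction on the observed tips.
#'
#' @param tree A `phylo` object.
#' @param x Named trait vector over (a subset of) tips; tips absent from `x`
#'   or with `NA` are imputed.
#' @param lambda Optional Pagel's lambda applied to the covariance before
#'   conditioning (default 1, pure Brownian motion).
#' @return List with `estimate` and `variance`, named numeric vectors over the
#'   imputed tips, plus `mu_hat` and `sigma2_hat`.
#' @export
impute_tips <- function(tree, x, lambda = 1) {
  C <- lambda_transform(bm_covariance(tree), lambda)
  tips <- rownames(C)
  obs <- intersect(names(x)[!is.na(x)], tips)
  mis <- setdiff(tips, obs)
  # a single observation still defines the GLS mean (and hence a prediction),
  # with zero estimated rate
  if (length(obs) < 1) stop("need at least 1 observed tip")
  if (length(mis) == 0)
    return(list(estimate = numeric(0), variance = numeric(0),
                mu_hat = NA_real_, sigma2_hat = NA_real_))
  xo <- x[obs]
  Coo <- C[obs, obs, drop = FALSE]
  Cmo <- C[mis, obs, drop = FALSE]
  ch <- tryCatch(chol(Coo), error = function(e) NULL)
  if (is.null(ch)) {
    ridge <- 1e-10 * max(diag(C))
    warning("near-singular observed covariance; adding ridge ", signif(ridge, 3))
    ch <- chol(Coo + diag(ridge, length(obs)))
  }
  one <- rep(1, length(obs))
  Ki_x <- backsolve(ch, backsolve(ch, xo, transpose = TRUE))
  Ki_1 <- backsolve(ch, backsolve(ch, one, transpose = TRUE))
  s11 <- sum(Ki_1)                      # 1' Coo^-1 1
  mu <- sum(Ki_x) / s11
  resid <- xo - mu
  Ki_r <- Ki_x - mu * Ki_1
  n <- length(obs)
  sigma2 <- sum(resid * Ki_r) / n
  est <- mu + drop(Cmo %*% Ki_r)
  # conditional variance + GLS mean-uncertainty term
  Z <- backsolve(ch, t(Cmo), transpose = TRUE)    # Coo^{-1/2} Com
  cond <- diag(C)[mis] - colSums(Z^2)
  a <- 1 - drop(Cmo %*% Ki_1)                      # sensitivity to mu_hat
  v <- sigma2 * (pmax(cond, 0) + a^2 / s11)
  names(est) <- names(v) <- mis
  list(estimate = est, variance = v, mu_hat = mu, sigma2_hat = sigma2)
}

.exclusion_sets <- function(focal, level, metadata, marker_groups) {
  switch(level,
    strain = focal,
    marker = {
      g <- marker_groups[[focal]]
      names(marker_groups)[marker_groups == g]
    },
    species = {
      sp <- metadata$species[metadata$strain_id == focal]
      metadata$strain_id[metadata$species == sp]
    },
    genus = {
      ge <- metadata$genus[metadata$strain_id == focal]
      metadata$strain_id[metadata$genus == ge]
    },
    stop("unknown exclusion level: ", level))
}

#' Leave-one-out cross-validated imputation with taxonomic exclusion
#'
#' For each focal strain with an observed value, all trait values of the
#' excluded set are removed before imputation: the focal strain itself
#' (`strain`), its identical-marker group (`marker`), its species
#' (`species`), or its whole genus (`genus`). Per-trait accuracy is the
#' Pearson correlation between predicted and observed values on the original
#' trait scale; per-strain error is the mean absolute error on scaled traits.
#'
#' @param tree A `phylo` object.
#' @param traits Strain-by-trait matrix.
#' @param metadata Data frame with `strain_id`, `species`, `genus` (and
#'   optionally `marker_group`); may be `NULL` when `exclusion = "strain"`.
#' @param exclusion One of `"strain"`, `"marker"`, `"species"`, `"genus"`.
#' @param lambda Lambda passed to [impute_tips()].
#' @return List with `predictions`, `variances` (matrices matching `traits`),
#'   `per_trait_r`, `per_strain_error`, `exclusion`.
#' @export
loocv_impute <- function(tree, traits, metadata = NULL,
                         exclusion = c("strain", "marker", "species", "genus"),
                         lambda = 1) {
  exclusion <- match.arg(exclusion)
  traits <- as.matrix(traits)
  strains <- intersect(rownames(traits), tree$tip.label)
  if (exclusion != "strain" && is.null(metadata))
    stop("metadata required for exclusion level ", exclusion)
  marker_groups <- NULL
  if (exclusion == "marker") {
    if (!is.null(metadata) && "marker_group" %in% names(metadata)) {
      marker_groups <- stats::setNames(metadata$marker_group, metadata$strain_id)
    } else {
      marker_groups <- derive_marker_groups(tree)
    }
  }
  pred <- var_ <- matrix(NA_real_, nrow(traits), ncol(traits),
                         dimnames = dimnames(traits))
  dropped <- character(0)
  singles <- character(0)
  for (focal in strains) {
    excl <- .exclusion_sets(focal, exclusion, metadata, marker_groups)
    for (j in seq_len(ncol(traits))) {
      x <- traits[, j]
      names(x) <- rownames(traits)
      if (is.na(x[focal])) next
      x[names(x) %in% excl] <- NA
      x[focal] <- NA
      n_obs <- sum(!is.na(x))
      if (n_obs < 1) {
        dropped <- c(dropped, focal)
        next
      }
      if (n_obs == 1) singles <- c(singles, focal)
      imp <- impute_tips(tree, x, lambda = lambda)
      pred[focal, j] <- imp$estimate[focal]
      var_[focal, j] <- imp$variance[focal]
    }
  }
  if (length(dropped))
    warning("exclusion left no observed strains for: ",
            paste(unique(dropped), collapse = ", "))
  if (length(singles))
    warning("predictions based on a single observed strain for: ",
            paste(unique(singles), collapse = ", "))
  per_trait_r <- vapply(seq_len(ncol(traits)), function(j) {
    ok <- !is.na(pred[, j]) & !is.na(traits[, j])
    if (sum(ok) < 3 || stats::sd(traits[ok, j]) == 0 || stats::sd(pred[ok, j]) == 0)
      return(NA_real_)
    stats::cor(pred[ok, j], traits[ok, j])
  }, numeric(1))
  names(per_trait_r) <- colnames(traits)
  sds <- apply(traits, 2, stats::sd, na.rm = TRUE)
  err <- abs(sweep(pred - traits, 2, pmax(sds, .Machine$double.eps), "/"))
  per_strain_error <- rowMeans(err, na.rm = TRUE)
  list(predictions = pred, variances = var_, per_trait_r = per_trait_r,
       per_strain_error = per_strain_error, exclusion = exclusion)
}

#' Pair imputation accuracy with phylogenetic signal
#'
#' Joins per-trait lambda estimates with per-trait imputation correlations
#' and reports their Pearson correlation; analogously pairs each strain's
#' phylogenetic nearest-neighbour distance (PNND) with its mean imputation
#' error.
#'
#' @param signal Data frame from [signal_table()] (columns `trait`, `lambda`).
#' @param imputation Result of [loocv_impute()].
#' @param tree Optional `phylo`; when given, the per-strain PNND pairing is
#'   included.
#' @return List with `trait_pairs` (trait, lambda, r), `r_lambda_accuracy`,
#'   and when `tree` is given `strain_pairs` (strain, pnnd, error) and
#'   `r_pnnd_error`.
#' @export
accuracy_vs_signal <- function(signal, imputation, tree = NULL) {
  common <- intersect(signal$trait, names(imputation$per_trait_r))
  if (length(common) == 0) stop("signal and imputation share no traits")
  if (length(common) < 2) stop("need at least 2 shared traits for a correlation")
  tp <- data.frame(trait = common,
                   lambda = signal$lambda[match(common, signal$trait)],
                   r = unname(imputation$per_trait_r[common]))
  ok <- stats::complete.cases(tp$lambda, tp$r)
  r_la <- if (sum(ok) >= 3 && stats::sd(tp$lambda[ok]) > 0 && stats::sd(tp$r[ok]) > 0)
    stats::cor(tp$lambda[ok], tp$r[ok]) else NA_real_
  out <- list(trait_pairs = tp, r_lambda_accuracy = r_la)
  if (!is.null(tree)) {
    nn <- pnnd(tree)
    strains <- intersect(names(nn), names(imputation$per_strain_error))
    sp <- data.frame(strain = strains, pnnd = unname(nn[strains]),
                     error = unname(imputation$per_strain_error[strains]))
    ok <- stats::complete.cases(sp$pnnd, sp$error)
    out$strain_pairs <- sp
    out$r_pnnd_error <- if (sum(ok) >= 3 && stats::sd(sp$pnnd[ok]) > 0)
      stats::cor(sp$pnnd[ok], sp$error[ok]) else NA_real_
  }
  out
}
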