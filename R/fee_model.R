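#' Canonical community identifier
#'
#' Communities are unordered strain sets; the canonical identity is the
#' sorted member tuple joined by `";"`. The empty string denotes the empty
#' community (un-inoculated medium, function 0 by definition).
#'
#' @param members Character vector of strain ids (duplicates forbidden).
#' @return Single string id.
#' @export
community_id <- function(members) {
  members <- members[nzchar(members)]
  if (anyDuplicated(members)) stop("duplicate members in community: ",
                                   paste(members, collapse = ";"))
  paste(sort(members), collapse = ";")
}

#' Split a community id back into its member set
#' @param id Canonical id from [community_id()].
#' @return Character vector (length 0 for the empty community).
#' @export
community_members <- function(id) {
  if (is.na(id) || !nzchar(id)) return(character(0))
  strsplit(id, ";", fixed = TRUE)[[1]]
}

#' Fraction of sugars consumed
#'
#' `F = (initial - residual) / initial`, clipped to `[0, 1]`. A residual
#' above `initial * 1.05` indicates an assay inconsistency and errors; small
#' overshoots (measurement noise) clip to 0 with a warning.
#'
#' @param initial_sugars Initial sugar concentration (g/l; 200 in synthetic
#'   grape must).
#' @param residual_sugars Final residual sugar concentration (g/l).
#' @return Fraction in `[0, 1]`.
#' @export
community_function <- function(initial_sugars, residual_sugars) {
  if (any(initial_sugars <= 0)) stop("initial sugars must be positive")
  if (any(residual_sugars < 0)) stop("negative residual sugars")
  if (any(residual_sugars > initial_sugars * 1.05))
    stop("residual sugars exceed initial by more than 5%: assay inconsistency")
  f <- (initial_sugars - residual_sugars) / initial_sugars
  if (any(f < 0)) warning("residual slightly above initial; clipping F to 0")
  pmin(pmax(f, 0), 1)
}

#' Read community measurements from CSV
#'
#' Columns: `community_id`, `members` (semicolon-joined strain ids, empty
#' string = empty community), `replicate`, `F`. Member strings are
#' canonicalised on read.
#'
#' @param path CSV path.
#' @return Data frame with canonical `community_id`.
#' @export
read_community_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(members = "character"))
  need <- c("members", "replicate", "F")
  if (!all(need %in% names(df)))
    stop("measurements need columns: ", paste(need, collapse = ", "))
  if (any(df$F < -1e-9 | df$F > 1 + 1e-9)) stop("function values outside [0, 1]")
  df$F <- pmin(pmax(df$F, 0), 1)
  df$members[is.na(df$members)] <- ""
  df$community_id <- vapply(df$members,
                            function(m) community_id(community_members(m)),
                            character(1), USE.NAMES = FALSE)
  df$members <- df$community_id
  df[, c("community_id", "members", "replicate", "F")]
}

#' Replicate means per community
#'
#' Aggregates replicate measurements to mean and sd per canonical community.
#' The empty community is always present with `F = 0` (hard anchor:
#' un-inoculated medium consumes nothing).
#'
#' @param dataset Measurement data frame (see
#'   [read_community_measurements()]).
#' @return Data frame: `community_id`, `richness`, `n_rep`, `F_mean`, `F_sd`.
#' @export
community_means <- function(dataset) {
  sp <- split(dataset$F, dataset$community_id)
  out <- data.frame(
    community_id = names(sp),
    richness = vapply(names(sp), function(id) length(community_members(id)),
                      integer(1), USE.NAMES = FALSE),
    n_rep = vapply(sp, length, integer(1), USE.NAMES = FALSE),
    F_mean = vapply(sp, mean, numeric(1), USE.NAMES = FALSE),
    F_sd = vapply(sp, function(v) if (length(v) > 1) stats::sd(v) else 0,
                  numeric(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  if (!"" %in% out$community_id) {
    out <- rbind(data.frame(community_id = "", richness = 0L, n_rep = 1L,
                            F_mean = 0, F_sd = 0), out)
  } else {
    out$F_mean[out$community_id == ""] <- 0
  }
  rownames(out) <- out$community_id
  out[order(out$richness, out$community_id), ]
}

#' Functional effect of adding a strain to a background
#'
#' `dF_i(B) = F(B + i) - F(B)` on replicate means; the sd is propagated from
#' the two (independent) replicate sets as `sqrt(sd_B^2 + sd_{B+i}^2)`.
#'
#' @param dataset Measurement data frame.
#' @param strain Focal strain id.
#' @param background Character vector of background members (may be empty:
#'   `F(empty) = 0`, so the effect equals the monoculture function).
#' @return List with `delta_F`, `sd`, `F_background`, `F_with`.
#' @export
functional_effect <- function(dataset, strain, background = character(0)) {
  if (strain %in% background) stop("strain already in background")
  mn <- community_means(dataset)
  idB <- community_id(background)
  idBi <- community_id(c(background, strain))
  if (!idB %in% mn$community_id) stop("background not measured: '", idB, "'")
  if (!idBi %in% mn$community_id) stop("community not measured: '", idBi, "'")
  fB <- mn[match(idB, mn$community_id), ]
  fBi <- mn[match(idBi, mn$community_id), ]
  list(delta_F = fBi$F_mean - fB$F_mean,
       sd = sqrt(fB$F_sd^2 + fBi$F_sd^2),
       F_background = fB$F_mean, F_with = fBi$F_mean)
}

.fee_pairs <- function(means, strain) {
  ids <- means$community_id
  with_i <- vapply(ids, function(id) strain %in% community_members(id),
                   logical(1), USE.NAMES = FALSE)
  pairs <- lapply(ids[!with_i], function(idB) {
    idBi <- community_id(c(community_members(idB), strain))
    if (!idBi %in% ids) return(NULL)
    fB <- means$F_mean[match(idB, ids)]
    data.frame(background = idB, F_B = fB,
               delta_F = means$F_mean[match(idBi, ids)] - fB)
  })
  do.call(rbind, pairs)
}

#' Fit a strain's functional effect equation
#'
#' Ordinary least squares of the functional effect `dF_i(B)` on the
#' background function `F(B)` over every measured `(B, B + i)` pair:
#' `dF_i(B) = a_i + b_i F(B) + theta_i(B)`. The residual variance
#' `sigma2 = SSR / (n - 2)` is floored at `1e-4` (function-scale units) so
#' perfect fits cannot produce infinite lattice edge weights.
#'
#' @param dataset Measurement data frame.
#' @param strain Strain id.
#' @param sigma2_floor Residual-variance floor.
#' @return List of class `fee`: `strain_id`, `a`, `b`, `sigma2`, `n_points`,
#'   `r2`, plus the pair table with residuals.
#' @export
fit_fee <- function(dataset, strain, sigma2_floor = 1e-4) {
  mn <- community_means(dataset)
  pairs <- .fee_pairs(mn, strain)
  if (is.null(pairs) || nrow(pairs) < 3)
    stop("strain '", strain, "' has fewer than 3 measured (B, B+i) pairs")
  if (stats::sd(pairs$F_B) == 0)
    stop("degenerate design for strain '", strain,
         "': no variance in background function")
  fit <- stats::lm(delta_F ~ F_B, data = pairs)
  co <- stats::coef(fit)
  n <- nrow(pairs)
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((pairs$delta_F - mean(pairs$delta_F))^2)
  pairs$residual <- stats::residuals(fit)
  structure(list(strain_id = strain, a = unname(co[1]), b = unname(co[2]),
                 sigma2 = max(ssr / (n - 2), sigma2_floor),
                 n_points = n,
                 r2 = if (sst > 0) 1 - ssr / sst else NA_real_,
                 pairs = pairs),
            class = "fee")
}

#' Fit FEEs for all (or selected) strains in a dataset
#'
#' Strains with fewer than 3 usable pairs (e.g. strains only ever seen inside
#' backgrounds) are skipped with a warning naming them; fitting continues for
#' the rest.
#'
#' @param dataset Measurement data frame.
#' @param strains Strain ids (default: every strain appearing in any
#'   community).
#' @param sigma2_floor Residual-variance floor (see [fit_fee()]).
#' @return Named list of `fee` objects, with a `fee_table` data-frame
#'   attribute (`strain_id`, `a`, `b`, `sigma2`, `n_points`, `r2`).
#' @export
fit_all_fees <- function(dataset, strains = NULL, sigma2_floor = 1e-4) {
  if (is.null(strains)) {
    strains <- sort(unique(unlist(lapply(unique(dataset$community_id),
                                         community_members))))
  }
  fees <- list()
  skipped <- character(0)
  for (s in strains) {
    f <- tryCatch(fit_fee(dataset, s, sigma2_floor = sigma2_floor),
                  error = function(e) e$message)
    if (inherits(f, "fee")) fees[[s]] <- f else skipped <- c(skipped, s)
  }
  if (length(skipped))
    warning("no FEE fitted for: ", paste(skipped, collapse = ", "))
  attr(fees, "fee_table") <- do.call(rbind, lapply(fees, function(f)
    data.frame(strain_id = f$strain_id, a = f$a, b = f$b, sigma2 = f$sigma2,
               n_points = f$n_points, r2 = f$r2)))
  fees
}

#' Serialize fitted FEEs to JSON
#' @param fees Result of [fit_all_fees()].
#' @param path Output JSON path.
#' @export
write_fees_json <- function(fees, path) {
  tab <- lapply(unname(fees), function(f)
    f[c("strain_id", "a", "b", "sigma2", "n_points", "r2")])
  jsonlite::write_json(tab, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read FEEs back from JSON
#' @param path JSON path written by [write_fees_json()].
#' @return Named list of `fee` objects (without pair tables).
#' @export
read_fees_json <- function(path) {
  tab <- jsonlite::read_json(path, simplifyVector = FALSE)
  fees <- list()
  for (f in tab)
    fees[[f$strain_id]] <- structure(f, class = "fee")
  attr(fees, "fee_table") <- do.call(rbind, lapply(fees, function(f)
    data.frame(strain_id = f$strain_id, a = f$a, b = f$b, sigma2 = f$sigma2,
               n_points = f$n_points, r2 = f$r2)))
  fees
}

.subsets_of <- function(members) {
  k <- length(members)
  if (k == 0) return(list(character(0)))
  lapply(seq_len(2^k) - 1L, function(mask)
    members[bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L])
}

#' Predict the function of a target community by FEE concatenation
#'
#' Builds the subset lattice between the largest observed sub-community
#' `c0` and the target, fixes every observed node at its replicate mean
#' (the empty community is anchored at 0), and solves for the latent node
#' values by weighted least squares over the single-strain-addition edges:
#' each edge `(S, S + i)` contributes
#' `(F_{S+i} - (1 + b_i) F_S - a_i)^2 / sigma_i^2`. The solution is the
#' maximum-likelihood estimate of the latent functions under Gaussian FEE
#' residuals, is invariant to the order in which member strains are listed or
#' nodes enumerated, and reduces to the closed-form single-addition
#' concatenation `F(c0) + a_C + b_C F(c0)` offset from `F(c0)` when exactly
#' one species is missing.
#'
#' @param target Character vector of target community members (or canonical
#'   id string).
#' @param dataset Measurement data frame (training data).
#' @param fees Named list of `fee` objects from [fit_all_fees()].
#' @param scope `"interval"` (default; lattice between `c0` and target, plus
#'   any other observed subsets of the target) or `"powerset"` (every subset
#'   of the target).
#' @return List: `community_id`, `F_pred` (clipped to `[0, 1]`),
#'   `F_pred_raw`, `lattice_nodes`, `anchors` (observed sub-communities
#'   used), `clipped`, `in_sample`.
#' @export
predict_function <- function(target, dataset, fees,
                             scope = c("interval", "powerset")) {
  scope <- match.arg(scope)
  if (length(target) == 1 && grepl(";", target, fixed = TRUE))
    target <- community_members(target)
  tid <- community_id(target)
  target <- community_members(tid)
  mn <- community_means(dataset)
  if (tid %in% mn$community_id) {
    f <- mn$F_mean[match(tid, mn$community_id)]
    return(list(community_id = tid, F_pred = f, F_pred_raw = f,
                lattice_nodes = 1L, anchors = tid, clipped = FALSE,
                in_sample = TRUE))
  }
  is_sub <- vapply(mn$community_id, function(id)
    all(community_members(id) %in% target), logical(1), USE.NAMES = FALSE)
  obs <- mn[is_sub, , drop = FALSE]
  # c0: largest observed subset; ties -> more replicates, then lexicographic
  ord <- order(-obs$richness, -obs$n_rep, obs$community_id)
  c0_id <- obs$community_id[ord[1]]
  c0 <- community_members(c0_id)
  add <- setdiff(target, c0)
  no_fee <- setdiff(add, names(fees))
  if (length(no_fee))
    stop("no fitted FEE for strain(s) needed above c0: ",
         paste(no_fee, collapse = ", "))
  nodes <- vapply(.subsets_of(add), function(s) community_id(c(c0, s)),
                  character(1))
  if (scope == "powerset") {
    nodes <- vapply(.subsets_of(target), community_id, character(1))
  }
  nodes <- sort(unique(c(nodes, obs$community_id)))
  observed_ids <- intersect(nodes, obs$community_id)
  latent_ids <- setdiff(nodes, observed_ids)
  # note: name-based lookup cannot be used here, the empty community's id
  # is the empty string which named vectors will not match
  fixed_vals <- obs$F_mean[match(observed_ids, obs$community_id)]
  fixed <- function(id) fixed_vals[match(id, observed_ids)]
  # edges: S -> S + i within the node set, strain i must carry an FEE
  rows <- list()
  for (sid in nodes) {
    S <- community_members(sid)
    for (i in setdiff(target, S)) {
      if (!i %in% names(fees)) next
      sid2 <- community_id(c(S, i))
      if (!sid2 %in% nodes) next
      rows[[length(rows) + 1L]] <- list(from = sid, to = sid2, strain = i)
    }
  }
  if (!length(latent_ids)) {  # only possible in degenerate scopes
    f <- fixed(tid)
    return(list(community_id = tid, F_pred = min(max(f, 0), 1),
                F_pred_raw = f, lattice_nodes = length(nodes),
                anchors = observed_ids, clipped = f < 0 || f > 1,
                in_sample = FALSE))
  }
  p <- length(latent_ids)
  idx <- stats::setNames(seq_len(p), latent_ids)
  A <- matrix(0, length(rows), p)
  rhs <- numeric(length(rows))
  w <- numeric(length(rows))
  for (e in seq_along(rows)) {
    r <- rows[[e]]
    fee <- fees[[r$strain]]
    w[e] <- 1 / fee$sigma2
    rhs[e] <- fee$a
    # F_to - (1 + b) F_from = a
    if (r$to %in% latent_ids) A[e, idx[r$to]] <- A[e, idx[r$to]] + 1
    else rhs[e] <- rhs[e] - fixed(r$to)
    cf <- -(1 + fee$b)
    if (r$from %in% latent_ids) A[e, idx[r$from]] <- A[e, idx[r$from]] + cf
    else rhs[e] <- rhs[e] - cf * fixed(r$from)
  }
  sw <- sqrt(w)
  sol <- qr.solve(A * sw, rhs * sw)
  f_raw <- unname(sol[idx[tid]])
  f <- min(max(f_raw, 0), 1)
  list(community_id = tid, F_pred = f, F_pred_raw = f_raw,
       lattice_nodes = length(nodes), anchors = observed_ids,
       clipped = f != f_raw, in_sample = FALSE)
}

#' Predict many target communities
#'
#' @param targets Character vector of canonical ids, or list of member
#'   vectors.
#' @param dataset,fees,scope As in [predict_function()].
#' @return Data frame: `community_id`, `members`, `F_pred`, `F_pred_raw`,
#'   `lattice_nodes`, `anchors`, `clipped`, `in_sample`.
#' @export
predict_many <- function(targets, dataset, fees,
                         scope = c("interval", "powerset")) {
  scope <- match.arg(scope)
  if (!is.list(targets)) targets <- lapply(targets, community_members)
  rows <- lapply(targets, function(t) {
    p <- predict_function(t, dataset, fees, scope = scope)
    data.frame(community_id = p$community_id, members = p$community_id,
               F_pred = p$F_pred, F_pred_raw = p$F_pred_raw,
               lattice_nodes = p$lattice_nodes,
               anchors = paste(p$anchors, collapse = "|"),
               clipped = p$clipped, in_sample = p$in_sample)
  })
  do.call(rbind, rows)
}

#' Additive baseline prediction
#'
#' Predicts a community containing a focal strain as the focal monoculture
#' function plus the sum of the pairwise functional effects of every other
#' member: `F_A = F_focal + sum(dF_i)`, ignoring all higher-order
#' interactions. Clipped to `[0, 1]` with the raw value retained.
#'
#' @param add_members Strains added to the focal strain.
#' @param monoculture_F Focal strain's monoculture function.
#' @param pairwise_effects Named vector of pairwise effects `dF_i` (from
#'   co-culture with the focal strain, e.g. via [additive_effects()]).
#' @return List with `F_pred`, `F_pred_raw`, `clipped`.
#' @export
additive_predict <- function(add_members, monoculture_F, pairwise_effects) {
  missing_eff <- setdiff(add_members, names(pairwise_effects))
  if (length(missing_eff))
    stop("no pairwise effect for: ", paste(missing_eff, collapse = ", "))
  raw <- monoculture_F + sum(pairwise_effects[add_members])
  f <- min(max(raw, 0), 1)
  list(F_pred = f, F_pred_raw = raw, clipped = f != raw)
}

#' Pairwise functional effects against a focal strain
#'
#' `dF_i = F({i, focal}) - F({focal})` for every strain with a measured
#' co-culture with the focal strain.
#'
#' @param dataset Measurement data frame.
#' @param focal Focal strain id.
#' @return Named numeric vector of effects; the focal monoculture function is
#'   attached as the `monoculture_F` attribute.
#' @export
additive_effects <- function(dataset, focal) {
  mn <- community_means(dataset)
  fid <- community_id(focal)
  if (!fid %in% mn$community_id) stop("focal monoculture not measured")
  f_sc <- mn$F_mean[match(fid, mn$community_id)]
  others <- setdiff(unique(unlist(lapply(mn$community_id, community_members))),
                    focal)
  eff <- vapply(others, function(i) {
    id2 <- community_id(c(focal, i))
    if (id2 %in% mn$community_id)
      mn$F_mean[match(id2, mn$community_id)] - f_sc
    else NA_real_
  }, numeric(1))
  eff <- eff[!is.na(eff)]
  attr(eff, "monoculture_F") <- f_sc
  eff
}

#' Evaluate predictions against observations
#'
#' @param predictions Data frame with `community_id` and `F_pred`.
#' @param observations Measurement data frame (replicates aggregated to
#'   means) or a data frame with `community_id` and `F_obs`.
#' @param by_richness Also report RMSE per community richness.
#' @return List: `overall` (data frame with `r`, `rmse`, `mae`, `n`),
#'   `per_richness` (richness, rmse, n), `per_community`
#'   (community_id, richness, F_pred, F_obs, sq_error, abs_error).
#' @export
evaluate_predictions <- function(predictions, observations, by_richness = TRUE) {
  if ("F_obs" %in% names(observations)) {
    obs <- observations[, c("community_id", "F_obs")]
  } else {
    mn <- community_means(observations)
    obs <- data.frame(community_id = mn$community_id, F_obs = mn$F_mean)
  }
  m <- merge(predictions[, c("community_id", "F_pred")], obs,
             by = "community_id")
  if (nrow(m) == 0) stop("no communities shared between predictions and observations")
  m$richness <- vapply(m$community_id,
                       function(id) length(community_members(id)),
                       integer(1), USE.NAMES = FALSE)
  m$sq_error <- (m$F_pred - m$F_obs)^2
  m$abs_error <- abs(m$F_pred - m$F_obs)
  r <- if (nrow(m) >= 3 && stats::sd(m$F_pred) > 0 && stats::sd(m$F_obs) > 0)
    stats::cor(m$F_pred, m$F_obs) else NA_real_
  overall <- data.frame(r = r, rmse = sqrt(mean(m$sq_error)),
                        mae = mean(m$abs_error), n = nrow(m))
  out <- list(overall = overall,
              per_community = m[order(m$richness, m$community_id), ])
  if (by_richness) {
    sp <- split(m$sq_error, m$richness)
    out$per_richness <- data.frame(
      richness = as.integer(names(sp)),
      rmse = vapply(sp, function(v) sqrt(mean(v)), numeric(1), USE.NAMES = FALSE),
      n = vapply(sp, length, integer(1), USE.NAMES = FALSE))
  }
  out
}
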