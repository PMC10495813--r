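#' Simulate an ultrametric pure-birth (Yule) tree
#'
#' Pure-birth tree with the stated number of tips, rescaled to total height 1
#' (arbitrary time units). Deterministic given the seed.
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Integer seed.
#' @return A `phylo` object with tips `t1 ... tn`.
#' @export
simulate_yule_tree <- function(n_tips, seed = 1L) {
  if (n_tips < 2) stop("need at least 2 tips")
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  h <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / h
  validate_phylogeny(tree)
}

#' Simulate traits with tunable phylogenetic signal
#'
#' Draws each trait from a multivariate normal with mean `mu` and covariance
#' `sigma2 * C(lam)`, where `C(lam)` is the Pagel's-lambda transform of the
#' tree's Brownian covariance: `lam = 1` gives Brownian evolution along the
#' tree, `lam = 0` independent tips.
#'
#' @param tree A `phylo` object.
#' @param lam Lambda in `[0, 1]` (recycled over traits).
#' @param sigma2 Brownian rate (variance per unit height).
#' @param mu Root state.
#' @param n_traits Number of traits.
#' @param seed Integer seed.
#' @return Tip-by-trait matrix; generating lambdas in the `lambda` attribute.
#' @export
simulate_bm_traits <- function(tree, lam, sigma2 = 1, mu = 0, n_traits = 1,
                               seed = 1L) {
  lam <- rep_len(lam, n_traits)
  if (any(lam < 0 | lam > 1)) stop("lambda must lie in [0, 1]")
  set.seed(seed)
  C <- bm_covariance(tree)
  n <- nrow(C)
  X <- matrix(NA_real_, n, n_traits,
              dimnames = list(rownames(C), paste0("trait", seq_len(n_traits))))
  for (j in seq_len(n_traits)) {
    if (sigma2 == 0) {
      X[, j] <- mu
    } else {
      V <- sigma2 * lambda_transform(C, lam[j])
      ch <- chol(V + diag(1e-12 * max(diag(V)), n))
      X[, j] <- mu + drop(crossprod(ch, stats::rnorm(n)))
    }
  }
  attr(X, "lambda") <- lam
  X
}

# Collapse n_pairs cherries to zero terminal length (moving the length onto
# the cherry stem so the tree stays ultrametric); emulates strains with
# identical marker sequences.
.collapse_cherries <- function(tree, n_pairs) {
  if (n_pairs <= 0) return(tree)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  done <- 0L
  for (node in sort(unique(tree$edge[, 1]), decreasing = TRUE)) {
    if (done >= n_pairs || node == root) next
    kids <- which(tree$edge[, 1] == node)
    if (length(kids) == 2 && all(tree$edge[kids, 2] <= n_tip)) {
      t_len <- tree$edge.length[kids[1]]
      stem <- which(tree$edge[, 2] == node)
      tree$edge.length[kids] <- 0
      tree$edge.length[stem] <- tree$edge.length[stem] + t_len
      done <- done + 1L
    }
  }
  tree
}

#' Simulate a strain collection: tree, traits and taxonomy metadata
#'
#' Emulates a wine-yeast collection: an ultrametric tree over `n_strains`
#' tips (with a few zero-length cherries standing in for strains with
#' identical marker sequences), `n_traits` traits whose phylogenetic signal
#' is drawn per trait from `lambda_grid`, and a metadata table assigning
#' marker group, species and genus by cutting the tree at fixed depth
#' thresholds (so the three partitions are nested: marker within species
#' within genus).
#'
#' @param n_strains Number of strains (default 60).
#' @param n_traits Number of traits (default 43).
#' @param lambda_grid Values the per-trait generating lambda is drawn from.
#' @param n_marker_pairs Cherries collapsed to identical-marker pairs.
#' @param species_h,genus_h Cophenetic-distance thresholds (tree height 1)
#'   defining species and genus clades.
#' @param seed Integer seed.
#' @return List: `tree`, `traits`, `metadata`, `truth` (generating
#'   parameters, for recovery tests).
#' @export
simulate_collection <- function(n_strains = 60, n_traits = 43,
                                lambda_grid = seq(0, 1, by = 0.1),
                                n_marker_pairs = 5,
                                species_h = 0.35, genus_h = 0.8,
                                seed = 1L) {
  if (n_strains < 2 || n_traits < 1) stop("sizes too small")
  tree <- simulate_yule_tree(n_strains, seed = seed)
  tree <- .collapse_cherries(tree, n_marker_pairs)
  tree <- validate_phylogeny(tree)
  set.seed(seed + 1L)
  lam <- sample(lambda_grid, n_traits, replace = TRUE)
  traits <- simulate_bm_traits(tree, lam, sigma2 = 1, mu = 0,
                               n_traits = n_traits, seed = seed + 2L)
  d <- cophenetic_matrix(tree)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  species <- stats::cutree(hc, h = species_h)
  genus <- stats::cutree(hc, h = genus_h)
  metadata <- data.frame(
    strain_id = tree$tip.label,
    species = paste0("sp", species[tree$tip.label]),
    genus = paste0("g", genus[tree$tip.label]),
    marker_group = unname(derive_marker_groups(tree)[tree$tip.label]),
    stringsAsFactors = FALSE)
  list(tree = tree, traits = traits, metadata = metadata,
       truth = list(lambda = stats::setNames(lam, colnames(traits)),
                    sigma2 = 1, mu = 0, seed = seed,
                    species_h = species_h, genus_h = genus_h))
}

#' Default ground-truth FEE parameters for a strain panel
#'
#' Intercepts, slopes and residual scales spanning the qualitative strain
#' classes seen in wine consortia: focal fermenters get a high intercept and
#' a slope near -1 (they push any community towards near-complete sugar
#' consumption), the rest span near-neutral to strongly negative effects.
#'
#' @param background_strains,focal_strains Strain id vectors.
#' @param seed Integer seed.
#' @return Data frame: `strain_id`, `a`, `b`, `sigma`.
#' @export
default_fee_truth <- function(background_strains, focal_strains, seed = 1L) {
  set.seed(seed)
  nb <- length(background_strains)
  nf <- length(focal_strains)
  data.frame(
    strain_id = c(background_strains, focal_strains),
    a = c(stats::runif(nb, -0.1, 1.0), stats::runif(nf, 0.85, 0.95)),
    b = c(stats::runif(nb, -1.2, 0.2), stats::runif(nf, -1.05, -0.85)),
    sigma = stats::runif(nb + nf, 0.01, 0.1),
    stringsAsFactors = FALSE)
}

# Sample n unique strain sets with sizes drawn from `sizes`, steering
# per-strain prevalence towards balance by inverse-frequency weighting.
# `init_counts` seeds the prevalence tally (sets already in the design);
# when `max_spread` is finite the relative prevalence spread
# (max - min) / mean of the final tally must not exceed it.
.sample_balanced_sets <- function(pool, n, sizes, max_spread = Inf,
                                  exclude = character(0),
                                  init_counts = NULL, max_try = 200L) {
  if (max(sizes) > length(pool)) stop("infeasible design: sets larger than pool")
  if (is.null(init_counts)) init_counts <- stats::setNames(numeric(length(pool)), pool)
  for (attempt in seq_len(max_try)) {
    counts <- init_counts
    sets <- list()
    seen <- exclude
    guard <- 0L
    while (length(sets) < n && guard < 50L * n) {
      guard <- guard + 1L
      s <- if (length(sizes) == 1) sizes else sample(sizes, 1)
      w <- 1 / (counts[pool] + 1)
      mem <- sample(pool, s, prob = w)
      id <- community_id(mem)
      if (id %in% seen) next
      seen <- c(seen, id)
      sets[[length(sets) + 1L]] <- sort(mem)
      counts[mem] <- counts[mem] + 1
    }
    if (length(sets) < n) next
    spread <- (max(counts) - min(counts)) / mean(counts)
    if (spread <= max_spread) return(sets)
  }
  stop("infeasible design: could not balance strain prevalence")
}

#' Simulate a ground-truth community-function experiment
#'
#' Builds a synthetic consortium experiment with the structure of the wine
#' yeast assays: background communities of 2-6 members drawn from a
#' 10-strain pool (balanced prevalence), each measured alone and with each
#' focal strain added; plus all monocultures and all pairwise co-cultures of
#' the full panel; everything in biological triplicate.
#'
#' The ground-truth function landscape is generated bottom-up from per-strain
#' FEE parameters: `F*(empty) = 0` and, for every community `S`,
#' `F*(S) = clip(mean over i in S of [(1 + b_i) F*(S - i) + a_i] + N(0, tau^2))`.
#' Averaging the recursion over all removal parents makes the truth
#' permutation-symmetric by construction. Replicate observations add
#' measurement noise: `clip(F*(S) + N(0, eps^2))`.
#'
#' A validation set of additional, never-measured communities (mirroring the
#' held-out consortia used to test the predictor) is generated on the same
#' landscape and returned with its true function values.
#'
#' @param background_strains Pool the backgrounds are drawn from (default 10
#'   strains `ns1 ... ns10`).
#' @param focal_strains Strains added to every background (default `Sc5`,
#'   `Sc8`).
#' @param truth Data frame `strain_id`, `a`, `b`, `sigma` of generating FEE
#'   parameters; default [default_fee_truth()]. Slopes must exceed -2.
#' @param n_backgrounds Number of background communities (default 176).
#' @param background_sizes Background richness range (default `2:6`).
#' @param n_base Base communities to which every absent pool strain is also
#'   added (mirrors the assembly scheme that guarantees `(B, B + i)` pairs
#'   for every pool strain; default 16, sizes 3-6).
#' @param tau Landscape (lattice) noise sd (default 0.01).
#' @param eps Measurement noise sd (default 0.01).
#' @param n_replicates Replicates per composition (default 3, biological
#'   triplicates).
#' @param n_validation Held-out communities generated on the same landscape
#'   (default 131).
#' @param max_spread Similar-prevalence constraint: maximum relative spread
#'   (max - min) / mean of per-strain background counts (default 0.2; small
#'   toy designs may need a looser bound).
#' @param seed Integer seed.
#' @return List: `dataset` (replicate-level measurements), `validation`
#'   (data frame `community_id`, `richness`, `F_true`, `F_obs`), `truth`
#'   (generating parameters plus the realised landscape `F_star`),
#'   `design` (composition bookkeeping).
#' @export
simulate_community_experiment <- function(background_strains = paste0("ns", 1:10),
                                          focal_strains = c("Sc5", "Sc8"),
                                          truth = NULL,
                                          n_backgrounds = 176,
                                          background_sizes = 2:6,
                                          n_base = 16,
                                          tau = 0.01, eps = 0.01,
                                          n_replicates = 3,
                                          n_validation = 131,
                                          max_spread = 0.2,
                                          seed = 1L) {
  strains <- c(background_strains, focal_strains)
  if (is.null(truth))
    truth <- default_fee_truth(background_strains, focal_strains, seed = seed)
  if (!all(strains %in% truth$strain_id)) stop("truth must cover every strain")
  if (any(truth$b <= -2)) stop("unstable truth: slopes must exceed -2")
  a <- stats::setNames(truth$a, truth$strain_id)
  b <- stats::setNames(truth$b, truth$strain_id)

  set.seed(seed + 10L)
  # base communities plus single-strain additions (the assembly scheme,
  # which guarantees (B, B + i) pairs for every pool strain), topped up with
  # random backgrounds; the similar-prevalence constraint (relative spread
  # of per-strain background counts <= 20%) is enforced on the full design
  base_sizes <- intersect(3:6, background_sizes)
  if (!length(base_sizes)) base_sizes <- background_sizes
  for (attempt in seq_len(100L)) {
    base <- .sample_balanced_sets(background_strains, n_base, sizes = base_sizes)
    backgrounds <- list()
    seen <- character(0)
    for (B in base) {
      for (S in c(list(B), lapply(setdiff(background_strains, B),
                                  function(i) sort(c(B, i))))) {
        id <- community_id(S)
        if (!id %in% seen) {
          seen <- c(seen, id)
          backgrounds[[length(backgrounds) + 1L]] <- S
        }
      }
    }
    if (length(backgrounds) > n_backgrounds)
      backgrounds <- backgrounds[seq_len(n_backgrounds)]
    counts <- stats::setNames(numeric(length(background_strains)),
                              background_strains)
    for (B in backgrounds) counts[B] <- counts[B] + 1
    if (length(backgrounds) < n_backgrounds) {
      extra <- tryCatch(
        .sample_balanced_sets(background_strains,
                              n_backgrounds - length(backgrounds),
                              sizes = background_sizes, exclude = seen,
                              init_counts = counts, max_try = 20L),
        error = function(e) NULL)
      if (is.null(extra)) next
      backgrounds <- c(backgrounds, extra)
      for (B in extra) counts[B] <- counts[B] + 1
    }
    spread <- (max(counts) - min(counts)) / mean(counts)
    if (spread <= max_spread) break
    if (attempt == 100L) stop("infeasible design: could not balance strain prevalence")
  }

  compositions <- backgrounds
  for (f in focal_strains)
    compositions <- c(compositions, lapply(backgrounds, function(B) sort(c(B, f))))
  compositions <- c(compositions,
                    lapply(strains, identity),
                    utils::combn(strains, 2, simplify = FALSE))
  ids <- vapply(compositions, community_id, character(1))
  keep <- !duplicated(ids)
  compositions <- compositions[keep]
  ids <- ids[keep]

  # ground-truth landscape, memoised bottom-up over the subset closure
  # (environments cannot hold an empty-string name, hence the "{}" key)
  f_star <- new.env(parent = emptyenv())
  key <- function(id) if (nzchar(id)) id else "{}"
  assign("{}", 0, envir = f_star)
  eval_f <- function(members) {
    id <- community_id(members)
    got <- get0(key(id), envir = f_star, ifnotfound = NULL)
    if (!is.null(got)) return(got)
    parents <- vapply(seq_along(members), function(k)
      eval_f(members[-k]), numeric(1))
    val <- mean((1 + b[members]) * parents + a[members])
    if (tau > 0) val <- val + stats::rnorm(1, 0, tau)
    val <- min(max(val, 0), 1)
    assign(key(id), val, envir = f_star)
    val
  }
  ord <- order(lengths(compositions), ids)  # deterministic traversal
  for (k in ord) eval_f(compositions[[k]])

  dataset <- do.call(rbind, lapply(ord, function(k) {
    id <- ids[k]
    fs <- f_star[[key(id)]]
    data.frame(community_id = id, members = id,
               replicate = seq_len(n_replicates),
               F = pmin(pmax(fs + stats::rnorm(n_replicates, 0, eps), 0), 1))
  }))
  rownames(dataset) <- NULL

  validation <- NULL
  if (n_validation > 0) {
    val_sizes <- seq(min(background_sizes),
                     min(max(background_sizes) + 1, length(strains)))
    val_sets <- .sample_balanced_sets(strains, n_validation,
                                      sizes = val_sizes, exclude = ids,
                                      max_spread = 0.5)
    vids <- vapply(val_sets, community_id, character(1))
    vord <- order(lengths(val_sets), vids)
    f_true <- f_obs <- numeric(length(val_sets))
    for (k in vord) {
      f_true[k] <- eval_f(val_sets[[k]])
      f_obs[k] <- mean(pmin(pmax(f_true[k] + stats::rnorm(n_replicates, 0, eps),
                                 0), 1))
    }
    validation <- data.frame(community_id = vids,
                             richness = lengths(val_sets),
                             F_true = f_true, F_obs = f_obs)
  }

  keys <- ls(f_star, all.names = TRUE)
  landscape <- data.frame(community_id = ifelse(keys == "{}", "", keys),
                          stringsAsFactors = FALSE)
  landscape$F_star <- vapply(keys, function(k) f_star[[k]], numeric(1),
                             USE.NAMES = FALSE)
  list(dataset = dataset,
       validation = validation,
       truth = list(params = truth, tau = tau, eps = eps,
                    n_replicates = n_replicates, seed = seed,
                    landscape = landscape),
       design = list(n_backgrounds = length(backgrounds),
                     n_schemes = 1 + length(focal_strains),
                     n_strains = length(strains),
                     n_compositions = length(compositions)))
}

#' Experiment-design bookkeeping
#'
#' Reports the assay counts of a background-plus-inoculation design:
#' backgrounds times inoculation schemes, monocultures, pairwise co-cultures
#' `n (n - 1) / 2`, their total, and the number of possible non-empty
#' communities `2^k - 1` assemblable from a `k`-strain library.
#'
#' @param n_backgrounds Number of background communities.
#' @param n_schemes Number of inoculation schemes per background (background
#'   alone counts as one scheme).
#' @param n_strains Panel size for monocultures and pairwise co-cultures.
#' @param library_size Library size `k` for the `2^k - 1` bound (default
#'   `n_strains`).
#' @return List: `background_assays`, `monocultures`, `pairwise`, `total`,
#'   `possible_communities`.
#' @export
design_counts <- function(n_backgrounds, n_schemes, n_strains,
                          library_size = n_strains) {
  if (any(c(n_backgrounds, n_schemes, n_strains) < 0))
    stop("counts must be non-negative")
  bg <- n_backgrounds * n_schemes
  mono <- n_strains
  pair <- n_strains * (n_strains - 1) / 2
  list(background_assays = bg, monocultures = mono, pairwise = pair,
       total = bg + mono + pair,
       possible_communities = 2^library_size - 1)
}

#' Number of distinct communities of given sizes from a strain pool
#'
#' @param k Pool size.
#' @param sizes Community sizes.
#' @return `sum(choose(k, sizes))`.
#' @export
n_compositions <- function(k, sizes) sum(choose(k, sizes))
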