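#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies the off-diagonal entries of the Brownian covariance by
#' `lam` in `[0, 1]`, leaving the diagonal intact. `lam = 1` is Brownian
#' evolution along the tree; `lam = 0` removes all phylogenetic covariance
#' (traits independent across tips).
#'
#' @param C Phylogenetic covariance matrix (see [bm_covariance()]).
#' @param lam Lambda in `[0, 1]`.
#' @return Transformed covariance matrix.
#' @export
lambda_transform <- function(C, lam) {
  if (!is.numeric(lam) || length(lam) != 1 || is.na(lam) || lam < 0 || lam > 1)
    stop("lambda must be a single value in [0, 1]")
  V <- C * lam
  diag(V) <- diag(C)
  V
}

#' Profile log-likelihood of a trait at a fixed lambda
#'
#' Maximum-likelihood profile: for a trait vector `x` on tips with
#' lambda-transformed covariance `V = C(lam)`, the root state and Brownian
#' rate have closed forms `mu_hat = (1' V^-1 x) / (1' V^-1 1)` and
#' `sigma2_hat = (x - mu_hat)' V^-1 (x - mu_hat) / n`, giving
#' `loglik = -n/2 log(2 pi sigma2_hat) - log|V|/2 - n/2`.
#'
#' Near-singular `V` (e.g. duplicated tips with zero-length terminal branches
#' at `lam = 1`) gets a ridge of `1e-10 * max(diag(C))` with a warning.
#'
#' @param x Named trait vector; names must match `rownames(C)`. `NA` entries
#'   are dropped.
#' @param C Phylogenetic covariance.
#' @param lam Lambda in `[0, 1]`.
#' @return List with `loglik`, `mu_hat`, `sigma2_hat`.
#' @export
profile_loglik <- function(x, C, lam) {
  if (!is.null(names(x))) {
    common <- intersect(names(x)[!is.na(x)], rownames(C))
    x <- x[common]
    C <- C[common, common, drop = FALSE]
  } else if (anyNA(x)) {
    keep <- !is.na(x)
    x <- x[keep]
    C <- C[keep, keep, drop = FALSE]
  }
  n <- length(x)
  if (n < 3) stop("need at least 3 non-missing trait values")
  V <- lambda_transform(C, lam)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    ridge <- 1e-10 * max(diag(C))
    warning("near-singular covariance at lambda = ", signif(lam, 4),
            "; adding ridge ", signif(ridge, 3))
    ch <- chol(V + diag(ridge, n))
  }
  .loglik_from_chol(x, ch, n)
}

.loglik_from_chol <- function(x, ch, n) {
  # two triangular solves give V^{-1/2}-whitened vectors
  z <- backsolve(ch, cbind(x, rep(1, n)), transpose = TRUE)
  zx <- z[, 1]; z1 <- z[, 2]
  mu <- sum(z1 * zx) / sum(z1 * z1)
  q <- sum((zx - mu * z1)^2)
  sigma2 <- q / n
  if (sigma2 <= 0 || !is.finite(sigma2)) stop("degenerate trait (zero variance)")
  logdet <- 2 * sum(log(diag(ch)))
  ll <- -n / 2 * log(2 * pi * sigma2) - logdet / 2 - n / 2
  list(loglik = ll, mu_hat = mu, sigma2_hat = sigma2)
}

# Precomputed spectral context for repeated lambda evaluations on one tree.
# For an ultrametric tree diag(C) = h for every tip, so
# C(lam) = U (lam * L + (1 - lam) * h) U' shares the eigenbasis U of C across
# all lambda; each profile evaluation is then O(n) after one O(n^2) projection
# of the trait vector. Non-ultrametric covariances fall back to per-lambda
# Cholesky factorisations.
.lambda_context <- function(C) {
  n <- nrow(C)
  h <- diag(C)
  ultra <- diff(range(h)) <= 1e-8 * max(h)
  if (ultra) {
    eg <- eigen(C, symmetric = TRUE)
    list(fast = TRUE, n = n, h = max(h), evals = pmax(eg$values, 0),
         U = eg$vectors, u1 = crossprod(eg$vectors, rep(1, n))[, 1], C = C)
  } else {
    list(fast = FALSE, n = n, C = C)
  }
}

.ctx_loglik <- function(ctx, xw, lam) {
  n <- ctx$n
  if (ctx$fast) {
    d <- lam * ctx$evals + (1 - lam) * ctx$h
    tiny <- d < 1e-10 * ctx$h
    if (any(tiny)) d[tiny] <- d[tiny] + 1e-10 * ctx$h
    iv <- 1 / d
    a11 <- sum(ctx$u1^2 * iv)
    a1x <- sum(ctx$u1 * xw * iv)
    mu <- a1x / a11
    q <- sum((xw - mu * ctx$u1)^2 * iv)
    sigma2 <- q / n
    if (sigma2 <= 0 || !is.finite(sigma2)) stop("degenerate trait (zero variance)")
    ll <- -n / 2 * log(2 * pi * sigma2) - sum(log(d)) / 2 - n / 2
    list(loglik = ll, mu_hat = mu, sigma2_hat = sigma2)
  } else {
    profile_loglik(xw, ctx$C, lam)
  }
}

.ctx_project <- function(ctx, x) if (ctx$fast) crossprod(ctx$U, x)[, 1] else x

.estimate_lambda_ctx <- function(ctx, x, grid_n = 21L) {
  xw <- .ctx_project(ctx, x)
  grid <- seq(0, 1, length.out = grid_n)
  ll <- vapply(grid, function(l) .ctx_loglik(ctx, xw, l)$loglik, numeric(1))
  k <- which.max(ll)
  lo <- grid[max(1, k - 1)]
  hi <- grid[min(grid_n, k + 1)]
  opt <- stats::optimize(function(l) .ctx_loglik(ctx, xw, l)$loglik,
                         lower = lo, upper = hi, maximum = TRUE, tol = 1e-8)
  if (opt$objective >= ll[k]) {
    lam <- opt$maximum
    best <- opt$objective
  } else {
    lam <- grid[k]
    best <- ll[k]
  }
  fit <- .ctx_loglik(ctx, xw, lam)
  list(lambda_hat = lam, loglik = best, mu_hat = fit$mu_hat,
       sigma2_hat = fit$sigma2_hat)
}

#' Maximum-likelihood estimate of Pagel's lambda for one trait
#'
#' Profiles the log-likelihood over lambda in `[0, 1]` with a 21-point grid
#' pre-scan followed by bounded scalar optimisation around the grid optimum
#' (the profile can be multimodal). ML, not REML.
#'
#' @param x Named trait vector (names = tip labels; `NA` allowed).
#' @param tree A `phylo` object.
#' @return List with `lambda_hat`, `loglik`, `mu_hat`, `sigma2_hat`, `n`.
#' @export
estimate_lambda <- function(x, tree) {
  C <- bm_covariance(tree)
  common <- intersect(names(x)[!is.na(x)], rownames(C))
  if (length(common) < 3) stop("need at least 3 non-missing trait values on tree tips")
  ctx <- .lambda_context(C[common, common])
  out <- .estimate_lambda_ctx(ctx, x[common])
  out$n <- length(common)
  out
}

#' Permutation significance test for Pagel's lambda
#'
#' Estimates lambda for the observed trait, then re-estimates it for
#' `n_perm` random permutations of the trait values across tips. The
#' permutation p-value uses the add-one correction
#' `p = (1 + #{lambda_perm >= lambda_hat}) / (1 + n_perm)` so p is never 0;
#' ties count against significance. The signal is called significant at
#' `p < 0.05` (i.e. the observed lambda exceeds the permuted one in more than
#' 95% of permutations).
#'
#' @param x Named trait vector.
#' @param tree A `phylo` object.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed for the permutation stream.
#' @return List with the [estimate_lambda()] fields plus `p_value`,
#'   `significant`, `n_perm`, `seed`.
#' @export
lambda_significance <- function(x, tree, n_perm = 1000L, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  C <- bm_covariance(tree)
  common <- intersect(names(x)[!is.na(x)], rownames(C))
  if (length(common) < 3) stop("need at least 3 non-missing trait values on tree tips")
  ctx <- .lambda_context(C[common, common])
  xx <- x[common]
  obs <- .estimate_lambda_ctx(ctx, xx)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    xp <- sample(unname(xx))
    lp <- .estimate_lambda_ctx(ctx, xp)$lambda_hat
    if (lp >= obs$lambda_hat) exceed <- exceed + 1L
  }
  p <- (1 + exceed) / (1 + n_perm)
  c(obs, list(n = length(common), p_value = p, significant = p < 0.05,
              n_perm = as.integer(n_perm), seed = as.integer(seed)))
}

#' Phylogenetic signal for every trait in a table
#'
#' Runs [lambda_significance()] per trait column. Traits with fewer than 3
#' non-missing values are skipped with a warning. Each trait gets its own
#' permutation stream derived from `seed` and its column index, so results do
#' not depend on trait order within the run.
#'
#' @param traits Strain-by-trait matrix (rownames = tip labels).
#' @param tree A `phylo` object.
#' @param n_perm Permutations per trait.
#' @param seed Root seed.
#' @return Data frame: trait, lambda, loglik, mu, sigma2, p_value, significant.
#' @export
signal_table <- function(traits, tree, n_perm = 1000L, seed = 1L) {
  traits <- as.matrix(traits)
  res <- lapply(seq_len(ncol(traits)), function(j) {
    x <- traits[, j]
    names(x) <- rownames(traits)
    if (sum(!is.na(x)) < 3) {
      warning("skipping trait with < 3 values: ", colnames(traits)[j])
      return(NULL)
    }
    s <- lambda_significance(x, tree, n_perm = n_perm,
                             seed = seed + 7919L * j)
    data.frame(trait = colnames(traits)[j], lambda = s$lambda_hat,
               loglik = s$loglik, mu = s$mu_hat, sigma2 = s$sigma2_hat,
               p_value = s$p_value, significant = s$significant)
  })
  do.call(rbind, res)
}
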