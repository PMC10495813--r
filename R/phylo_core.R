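#' Read a rooted phylogeny from a newick file
#'
#' Parses a newick tree, validates it (unique non-empty tip labels, branch
#' lengths present on every edge, non-negative lengths) and checks whether it
#' is ultrametric to within `tolerance * tree height`. Ultrametricity
#' violations are reported with a warning but the tree is returned as-is:
#' chronogram output commonly carries small rounding error and silently
#' "fixing" depths would change downstream covariances.
#'
#' @param path Path to a newick file. Branch lengths are mandatory.
#' @param tolerance Relative ultrametricity tolerance (default `1e-6`,
#'   interpreted as a fraction of tree height).
#' @return An object of class `phylo` (from \pkg{ape}) with two extra
#'   attributes: `ultrametric` (logical) and `depth_range` (max minus min
#'   root-to-tip depth).
#' @export
read_newick <- function(path, tolerance = 1e-6) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("malformed newick in ", path)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  validate_phylogeny(tree, tolerance = tolerance)
}

#' Validate a phylogeny object
#'
#' @param tree A `phylo` object.
#' @param tolerance Relative ultrametricity tolerance.
#' @return The tree, with `ultrametric` and `depth_range` attributes set.
#' @export
validate_phylogeny <- function(tree, tolerance = 1e-6) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (length(tree$edge.length) != nrow(tree$edge) || anyNA(tree$edge.length))
    stop("missing branch length on one or more edges")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  tips <- tree$tip.label
  if (any(!nzchar(tips))) stop("empty tip label")
  if (anyDuplicated(tips)) stop("duplicate tip labels: ",
                                paste(unique(tips[duplicated(tips)]), collapse = ", "))
  depths <- ape::node.depth.edgelength(tree)[seq_along(tips)]
  height <- max(depths)
  spread <- diff(range(depths))
  ultra <- height == 0 || spread <= tolerance * height
  if (!ultra)
    warning(sprintf("tree is not ultrametric: tip depth spread %.3g exceeds %.3g",
                    spread, tolerance * height))
  attr(tree, "ultrametric") <- ultra
  attr(tree, "depth_range") <- spread
  tree
}

#' Cophenetic (patristic) distance matrix
#'
#' Distance between two tips is the total branch length on the tip-to-tip
#' path.
#'
#' @param tree A `phylo` object.
#' @return Symmetric matrix with zero diagonal, tip labels as dimnames.
#' @export
cophenetic_matrix <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Brownian-motion phylogenetic covariance
#'
#' `C[i, j]` is the depth of the most recent common ancestor of tips i and j
#' (the shared root-to-tip path length), the trait covariance implied by
#' Brownian evolution with unit rate. Satisfies
#' `d[i, j] = C[i, i] + C[j, j] - 2 C[i, j]` with `d` the cophenetic matrix.
#'
#' @param tree A rooted `phylo` object.
#' @return Symmetric positive-semidefinite matrix with tip-label dimnames.
#' @export
bm_covariance <- function(tree) {
  # trees are interpreted as rooted at their root node; a basal polytomy
  # (e.g. a star tree) is a legitimate rooted shape here
  C <- ape::vcv.phylo(tree)
  C[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Phylogenetic nearest-neighbour distance (PNND)
#'
#' For each tip, the minimum cophenetic distance to any other tip. Tips in a
#' group with identical marker sequences (zero-length splits) have PNND 0.
#'
#' @param tree A `phylo` object with at least two tips.
#' @return Named numeric vector, one entry per tip.
#' @export
pnnd <- function(tree) {
  if (length(tree$tip.label) < 2) stop("PNND needs at least two tips")
  d <- cophenetic_matrix(tree)
  diag(d) <- Inf
  apply(d, 1, min)
}

#' Centre and scale trait columns
#'
#' Each trait column is centred to mean 0 and scaled to sample (n-1) standard
#' deviation 1 over its non-missing entries; missing entries stay missing.
#' Constant columns (sd 0, or fewer than 2 non-missing values) cannot be
#' scaled and are dropped with a warning naming them.
#'
#' @param table Numeric matrix or data frame, strains in rows (rownames set),
#'   traits in columns.
#' @return Scaled numeric matrix; dropped columns recorded in the
#'   `dropped_traits` attribute.
#' @export
scale_traits <- function(table) {
  x <- as.matrix(table)
  storage.mode(x) <- "double"
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  n_ok <- colSums(!is.na(x))
  bad <- is.na(sds) | sds == 0 | n_ok < 2
  if (any(bad)) {
    warning("dropping constant/degenerate trait columns: ",
            paste(colnames(x)[bad], collapse = ", "))
    x <- x[, !bad, drop = FALSE]
  }
  out <- scale(x, center = TRUE, scale = TRUE)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "dropped_traits") <- colnames(as.matrix(table))[bad]
  out
}

#' Pairwise Euclidean phenotypic distance with missing-data rescaling
#'
#' Euclidean distance over the traits non-missing in both rows, rescaled by
#' `sqrt(p_total / p_shared)` so that distances based on fewer shared traits
#' remain comparable in magnitude to complete pairs. Pairs sharing fewer than
#' two traits get `NA` with a warning.
#'
#' @param table Scaled trait matrix (see [scale_traits()]).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
trait_distance_matrix <- function(table) {
  x <- as.matrix(table)
  n <- nrow(x)
  p <- ncol(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  warned <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(x[i, ]) & !is.na(x[j, ])
      m <- sum(ok)
      if (m < 2) {
        d[i, j] <- d[j, i] <- NA_real_
        warned <- TRUE
      } else {
        d2 <- sum((x[i, ok] - x[j, ok])^2)
        d[i, j] <- d[j, i] <- sqrt(d2 * p / m)
      }
    }
  }
  if (warned) warning("some strain pairs share < 2 traits; distances set to NA")
  d
}

#' Correlation between two distance matrices
#'
#' Pearson correlation over upper-triangle pairs, with two significance
#' assessments: the naive correlation test (which treats pairs as
#' independent — they are not) and a Mantel permutation test that permutes
#' row/column labels of one matrix jointly.
#'
#' @param d_phylo,d_pheno Distance matrices with identical labels.
#' @param n_perm Number of Mantel permutations (0 skips the Mantel test).
#' @param seed Integer seed for the permutation test.
#' @return List with `r`, `p_naive`, `p_mantel` (NA when `n_perm == 0`) and
#'   `n_pairs`.
#' @export
distance_correlation <- function(d_phylo, d_pheno, n_perm = 999, seed = 1) {
  d_phylo <- as.matrix(d_phylo)
  d_pheno <- as.matrix(d_pheno)
  if (is.null(rownames(d_phylo)) || is.null(rownames(d_pheno)))
    stop("distance matrices must carry labels")
  common <- intersect(rownames(d_phylo), rownames(d_pheno))
  if (length(common) < 3) stop("fewer than 3 shared labels")
  d1 <- d_phylo[common, common]
  d2 <- d_pheno[common, common]
  ut <- upper.tri(d1)
  x <- d1[ut]
  y <- d2[ut]
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant distance vector; correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  p_mantel <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    mt <- vegan::mantel(stats::as.dist(d1), stats::as.dist(d2),
                        method = "pearson", permutations = n_perm)
    p_mantel <- mt$signif
  }
  list(r = unname(ct$estimate), p_naive = ct$p.value, p_mantel = p_mantel,
       n_pairs = length(x))
}

#' Read a strain-by-trait table from TSV
#'
#' Expects a header row, a `strain_id` column with row labels and numeric
#' trait columns; missing values written as `NA`.
#'
#' @param path TSV file path.
#' @return Numeric matrix with strain ids as rownames.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stop("trait table not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"strain_id" %in% names(df)) stop("trait table needs a 'strain_id' column")
  m <- as.matrix(df[, setdiff(names(df), "strain_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$strain_id
  m
}

#' Read strain metadata from TSV
#'
#' Columns: `strain_id`, `species`, `genus` and optionally `marker_group`
#' (strains sharing an identical marker sequence share a group). When
#' `marker_group` is absent it can be derived from the tree as connected
#' components of zero cophenetic distance via [derive_marker_groups()].
#'
#' @param path TSV file path.
#' @return Data frame.
#' @export
read_strain_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("strain_id", "species", "genus")
  if (!all(need %in% names(df)))
    stop("metadata needs columns: ", paste(need, collapse = ", "))
  df
}

#' Derive marker-identity groups from zero cophenetic distance
#'
#' Strains at cophenetic distance (numerically) zero carry identical marker
#' sequences and form one group.
#'
#' @param tree A `phylo` object.
#' @param tol Distances below `tol * tree height` count as zero.
#' @return Named character vector of group labels, one per tip.
#' @export
derive_marker_groups <- function(tree, tol = 1e-8) {
  d <- cophenetic_matrix(tree)
  h <- max(ape::node.depth.edgelength(tree))
  grp <- stats::cutree(stats::hclust(stats::as.dist(d), method = "single"),
                       h = tol * max(h, 1))
  stats::setNames(paste0("mg", grp), names(grp))
}
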