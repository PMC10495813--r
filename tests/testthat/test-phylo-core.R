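test_that("read_newick parses valid trees and reports ultrametricity", {
  f <- write_newick_tmp("(A:1,B:1):0;")
  tr <- read_newick(f)
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B"))
  expect_true(attr(tr, "ultrametric"))

  f3 <- write_newick_tmp("(A:1,(B:0.5,C:0.5):0.5):0;")
  tr3 <- read_newick(f3)
  expect_length(tr3$tip.label, 3)
  expect_true(attr(tr3, "ultrametric"))
  expect_equal(max(ape::node.depth.edgelength(tr3)), 1)

  # non-ultrametric trees are reported, not fixed
  fnu <- write_newick_tmp("(A:1,(B:0.2,C:0.5):0.5):0;")
  expect_warning(trnu <- read_newick(fnu), "not ultrametric")
  expect_false(attr(trnu, "ultrametric"))
})

test_that("read_newick rejects malformed input", {
  expect_error(read_newick(write_newick_tmp("(A:1,B);")), "branch length")
  expect_error(read_newick(write_newick_tmp("(A:1,A:1):0;")), "duplicate")
  expect_error(read_newick(tempfile()), "not found")
})

test_that("cophenetic distances are tip-to-tip path sums", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(cophenetic_matrix(tr)["A", "B"], 2)

  tr3 <- ape::read.tree(text = "(A:1,(B:0.5,C:0.5):0.5);")
  d <- cophenetic_matrix(tr3)
  expect_equal(d["B", "C"], 1)
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 2)
  expect_equal(diag(d), setNames(rep(0, 3), c("A", "B", "C")))
})

test_that("cophenetic matrix matches the path-walking oracle and is a tree metric", {
  for (k in 1:10) {
    tr <- simulate_yule_tree(10, seed = 400 + k)
    d <- cophenetic_matrix(tr)
    expect_lt(max(abs(d - oracle_cophenetic(tr))), 1e-12)
    expect_lt(max(abs(d - t(d))), 1e-12)
    # triangle inequality on all triples
    n <- nrow(d)
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (l in (j + 1):n) {
      expect_lte(d[i, j], d[i, l] + d[l, j] + 1e-12)
      expect_lte(d[i, l], d[i, j] + d[j, l] + 1e-12)
      expect_lte(d[j, l], d[j, i] + d[i, l] + 1e-12)
    }
  }
})

test_that("Brownian covariance is the shared-path matrix", {
  star <- ape::read.tree(text = "(A:2,B:2,C:2,D:2);")
  expect_equal(unname(bm_covariance(star)), 2 * diag(4))

  tr3 <- ape::read.tree(text = "(A:1,(B:0.5,C:0.5):0.5);")
  C <- bm_covariance(tr3)
  expect_equal(C["B", "C"], 0.5)
  expect_equal(C["A", "B"], 0)
  expect_equal(unname(diag(C)), rep(1, 3))
})

test_that("cophenetic/covariance identity d = Cii + Cjj - 2Cij holds on random trees", {
  for (k in 1:100) {
    tr <- simulate_yule_tree(sample(4:15, 1), seed = 1000 + k)
    d <- cophenetic_matrix(tr)
    C <- bm_covariance(tr)
    ident <- outer(diag(C), diag(C), "+") - 2 * C
    diag(ident) <- 0
    expect_lt(max(abs(d - ident)), 1e-12)
    expect_gt(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  }
})

test_that("PNND is the off-diagonal row minimum of the cophenetic matrix", {
  tr3 <- ape::read.tree(text = "(A:1,(B:0.5,C:0.5):0.5);")
  nn <- pnnd(tr3)
  expect_equal(nn[["A"]], 2)
  expect_equal(nn[["B"]], 1)
  expect_equal(nn[["C"]], 1)

  # identical-marker tips sit at zero distance
  dup <- ape::read.tree(text = "(A:1,(B:0,C:0):1);")
  expect_equal(pnnd(dup)[["B"]], 0)

  tr <- simulate_yule_tree(12, seed = 5)
  d <- cophenetic_matrix(tr)
  diag(d) <- Inf
  expect_equal(pnnd(tr), apply(d, 1, min))

  expect_error(pnnd(ape::read.tree(text = "(A:1);")), "two tips")
})

test_that("scale_traits centres and scales with sample sd, drops constants", {
  m <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  rownames(m) <- c("s1", "s2", "s3")
  expect_warning(sc <- scale_traits(m), "constant")
  expect_equal(colnames(sc), "a")
  expect_equal(unname(sc[, "a"]), c(-1, 0, 1))
  expect_equal(attr(sc, "dropped_traits"), "b")

  # missing entries: scaled by the non-missing mean/sd, stay missing
  m2 <- cbind(x = c(1, 2, 4, NA))
  sc2 <- scale_traits(m2)
  mu <- mean(c(1, 2, 4)); s <- sd(c(1, 2, 4))
  expect_equal(unname(sc2[1:3, "x"]), (c(1, 2, 4) - mu) / s)
  expect_true(is.na(sc2[4, "x"]))

  # idempotence
  m3 <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("t", 1:4)))
  once <- scale_traits(m3)
  twice <- scale_traits(once)
  expect_lt(max(abs(once - twice)), 1e-10)
  expect_lt(max(abs(colMeans(once))), 1e-10)
})

test_that("trait distances are missingness-rescaled Euclidean", {
  m <- rbind(s1 = c(0, 0), s2 = c(3, 4))
  d <- trait_distance_matrix(m)
  expect_equal(d["s1", "s2"], 5)
  expect_equal(trait_distance_matrix(rbind(a = 1:4, b = 1:4))["a", "b"], 0)

  # 8 traits, 4 shared: distance rescaled by sqrt(8/4)
  x <- c(1, 2, 3, 4, NA, NA, 7, 8)
  y <- c(2, 4, 3, 1, 5, 6, NA, NA)
  m2 <- rbind(s1 = x, s2 = y)
  shared <- sqrt(sum((x[1:4] - y[1:4])^2) * 8 / 4)
  expect_equal(trait_distance_matrix(m2)["s1", "s2"], shared)

  # pair sharing < 2 traits -> NA with a warning
  m3 <- rbind(s1 = c(1, NA, NA), s2 = c(NA, 1, 2), s3 = c(1, 1, 1))
  expect_warning(d3 <- trait_distance_matrix(m3), "share < 2")
  expect_true(is.na(d3["s1", "s2"]))
  expect_false(is.na(d3["s2", "s3"]))
})

test_that("distance correlation matches a brute-force upper-triangle loop", {
  tr <- simulate_yule_tree(15, seed = 77)
  d1 <- cophenetic_matrix(tr)
  x <- simulate_bm_traits(tr, 1, n_traits = 5, seed = 78)
  d2 <- trait_distance_matrix(scale_traits(x))
  res <- distance_correlation(d1, d2, n_perm = 0)

  v1 <- c(); v2 <- c()
  labs <- rownames(d1)
  for (i in seq_along(labs)[-length(labs)]) {
    for (j in (i + 1):length(labs)) {
      v1 <- c(v1, d1[labs[i], labs[j]])
      v2 <- c(v2, d2[labs[i], labs[j]])
    }
  }
  expect_equal(res$r, cor(v1, v2), tolerance = 1e-12)
  expect_equal(res$n_pairs, length(v1))
})

test_that("distance correlation is exact for linear relations and scale-invariant", {
  tr <- simulate_yule_tree(12, seed = 9)
  d1 <- cophenetic_matrix(tr)
  res <- distance_correlation(d1, 2 * d1, n_perm = 99, seed = 1)
  expect_equal(res$r, 1, tolerance = 1e-12)

  x <- simulate_bm_traits(tr, 0.6, n_traits = 4, seed = 10)
  d2 <- trait_distance_matrix(scale_traits(x))
  r1 <- distance_correlation(d1, d2, n_perm = 0)$r
  r2 <- distance_correlation(3.7 * d1, 0.2 * d2, n_perm = 0)$r
  expect_equal(r1, r2, tolerance = 1e-12)

  expect_error(distance_correlation(d1 * 0, d2, n_perm = 0), "constant")
})

test_that("Mantel test does not reject when one matrix's labels are shuffled", {
  tr <- simulate_yule_tree(100, seed = 321)
  d_phy <- cophenetic_matrix(tr)
  x <- simulate_bm_traits(tr, 0.9, n_traits = 10, seed = 322)
  d_phe <- trait_distance_matrix(scale_traits(x))
  keep_small_r <- 0; keep_ns <- 0
  for (k in 1:50) {
    set.seed(3000 + k)
    perm <- sample(rownames(d_phe))
    d_shuf <- d_phe
    dimnames(d_shuf) <- list(perm, perm)
    res <- distance_correlation(d_phy, d_shuf, n_perm = 99, seed = 4000 + k)
    if (abs(res$r) < 0.2) keep_small_r <- keep_small_r + 1
    if (res$p_mantel > 0.05) keep_ns <- keep_ns + 1
  }
  expect_gte(keep_ns, 45)       # >= 90% of runs non-significant
  expect_gte(keep_small_r, 45)  # r near 0
})

test_that("marker groups are connected components of zero cophenetic distance", {
  tr <- ape::read.tree(text = "((A:0,B:0):1,(C:0.6,D:0.6):0.4);")
  g <- derive_marker_groups(tr)
  expect_equal(g[["A"]], g[["B"]])
  expect_false(g[["C"]] == g[["D"]])
  expect_false(g[["A"]] == g[["C"]])
})
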