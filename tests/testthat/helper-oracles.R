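# Independent oracles used to cross-check the package's linear-algebra and
# lattice machinery. Deliberately written by different routes than the
# implementation (explicit path walking, generic dense MVN algebra, graph
# message passing, generic numerical optimisation).

# Cophenetic distance by explicit root-path traversal: the tip-to-tip path is
# the symmetric difference of the two root paths.
oracle_cophenetic <- function(tree) {
  n <- length(tree$tip.label)
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  path_edges <- function(tip) {
    out <- integer(0)
    v <- tip
    while (v != root) {
      out <- c(out, v)   # edge above v, indexed by child
      v <- parent[v]
    }
    out
  }
  paths <- lapply(seq_len(n), path_edges)
  d <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sym <- c(setdiff(paths[[i]], paths[[j]]), setdiff(paths[[j]], paths[[i]]))
      d[i, j] <- d[j, i] <- sum(elen[sym])
    }
  }
  d
}

# Generic multivariate-normal log-density via full matrix inversion.
oracle_mvn_loglik <- function(x, V, mu, sigma2) {
  n <- length(x)
  S <- sigma2 * V
  r <- x - mu
  -n / 2 * log(2 * pi) - 0.5 * determinant(S, logarithm = TRUE)$modulus -
    0.5 * drop(crossprod(r, solve(S, r)))
}

# Brownian tip prediction by rerooting at the missing tip's attachment node
# and running Felsenstein-pruning (message passing on the unrooted tree).
oracle_prune_predict <- function(tree, x, miss) {
  nt <- length(tree$tip.label)
  lab <- tree$tip.label
  edges <- rbind(cbind(tree$edge, tree$edge.length),
                 cbind(tree$edge[, 2:1], tree$edge.length))
  nbrs <- split(seq_len(nrow(edges)), edges[, 1])
  mtip <- match(miss, lab)
  v <- tree$edge[tree$edge[, 2] == mtip, 1]
  msg <- function(u, from) {
    if (u <= nt) {
      if (lab[u] == miss) return(NULL)
      return(c(x[lab[u]], 0))
    }
    ms <- list()
    for (ei in nbrs[[as.character(u)]]) {
      w <- edges[ei, 2]
      if (w == from) next
      m <- msg(w, u)
      if (is.null(m)) next
      ms[[length(ms) + 1]] <- c(m[1], m[2] + edges[ei, 3])
    }
    if (!length(ms)) return(NULL)
    zero <- vapply(ms, function(m) m[2] == 0, logical(1))
    if (any(zero)) return(c(ms[[which(zero)[1]]][1], 0))
    prec <- vapply(ms, function(m) 1 / m[2], numeric(1))
    c(sum(vapply(ms, function(m) m[1] / m[2], numeric(1))) / sum(prec),
      1 / sum(prec))
  }
  ms <- list()
  for (ei in nbrs[[as.character(v)]]) {
    w <- edges[ei, 2]
    if (w == mtip) next
    m <- msg(w, v)
    if (is.null(m)) next
    ms[[length(ms) + 1]] <- c(m[1], m[2] + edges[ei, 3])
  }
  zero <- vapply(ms, function(m) m[2] == 0, logical(1))
  if (any(zero)) return(ms[[which(zero)[1]]][1])
  prec <- vapply(ms, function(m) 1 / m[2], numeric(1))
  sum(vapply(ms, function(m) m[1] / m[2], numeric(1))) / sum(prec)
}

# Generic numerical minimiser of the lattice WLS objective, for comparison
# with the linear solve in predict_function.
oracle_lattice_optim <- function(target, dataset, fees) {
  target <- community_members(community_id(target))
  tid <- community_id(target)
  mn <- community_means(dataset)
  is_sub <- vapply(mn$community_id, function(id)
    all(community_members(id) %in% target), logical(1), USE.NAMES = FALSE)
  obs <- mn[is_sub, , drop = FALSE]
  ord <- order(-obs$richness, -obs$n_rep, obs$community_id)
  c0 <- community_members(obs$community_id[ord[1]])
  add <- setdiff(target, c0)
  subs <- list(character(0))
  for (s in add) subs <- c(subs, lapply(subs, function(z) c(z, s)))
  nodes <- vapply(subs, function(s) community_id(c(c0, s)), character(1))
  nodes <- sort(unique(c(nodes, obs$community_id)))
  observed_ids <- intersect(nodes, obs$community_id)
  latent_ids <- setdiff(nodes, observed_ids)
  fval <- function(id, th) {
    k <- match(id, latent_ids)
    if (!is.na(k)) th[k] else obs$F_mean[match(id, obs$community_id)]
  }
  objective <- function(th) {
    tot <- 0
    for (sid in nodes) {
      S <- community_members(sid)
      for (i in setdiff(target, S)) {
        if (!i %in% names(fees)) next
        sid2 <- community_id(c(S, i))
        if (!sid2 %in% nodes) next
        fee <- fees[[i]]
        r <- fval(sid2, th) - (1 + fee$b) * fval(sid, th) - fee$a
        tot <- tot + r^2 / fee$sigma2
      }
    }
    tot
  }
  th0 <- rep(0.5, length(latent_ids))
  opt <- stats::optim(th0, objective, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  opt$par[match(tid, latent_ids)]
}

# Tiny newick fixture writer.
write_newick_tmp <- function(text) {
  f <- tempfile(fileext = ".nwk")
  writeLines(text, f)
  f
}
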