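# small hand-built dataset used across several tests: backgrounds with
# spread-out function values plus a strain "P" that always drives
# consumption to exactly 1 (the perfect-consumer geometry, dF = 1 - F(B))
make_perfect_dataset <- function() {
  rows <- list()
  addm <- function(members, f) {
    id <- community_id(members)
    data.frame(community_id = id, members = id, replicate = 1:3, F = f)
  }
  rows[[1]] <- addm("x1", 0.2)
  rows[[2]] <- addm("x2", 0.5)
  rows[[3]] <- addm("x3", 0.8)
  rows[[4]] <- addm(c("x1", "x2"), 0.55)
  rows[[5]] <- addm(c("x1", "P"), 1)
  rows[[6]] <- addm(c("x2", "P"), 1)
  rows[[7]] <- addm(c("x3", "P"), 1)
  rows[[8]] <- addm("P", 1)
  rows[[9]] <- addm(c("x1", "x2", "P"), 1)
  do.call(rbind, rows)
}

test_that("community ids are canonical and reject duplicates", {
  expect_equal(community_id(c("b", "a")), community_id(c("a", "b")))
  expect_equal(community_id(character(0)), "")
  expect_equal(community_members(""), character(0))
  expect_equal(sort(community_members("b;a;c")), c("a", "b", "c"))
  expect_error(community_id(c("a", "a")), "duplicate")
})

test_that("fraction of sugars consumed is (initial - residual)/initial, clipped", {
  expect_equal(community_function(200, 10), 0.95)
  expect_equal(community_function(200, 200), 0)
  expect_warning(f <- community_function(200, 202), "clipping")
  expect_equal(f, 0)
  expect_error(community_function(200, 215), "inconsist")
})

test_that("functional effects are mean differences with propagated sd", {
  d <- rbind(
    data.frame(community_id = "a", members = "a", replicate = 1:3,
               F = c(0.1, 0.2, 0.3)),
    data.frame(community_id = "a;s", members = "a;s", replicate = 1:3,
               F = c(0.4, 0.5, 0.6)))
  fe <- functional_effect(d, "s", "a")
  expect_equal(fe$delta_F, 0.3)
  expect_equal(fe$sd, sqrt(sd(c(0.1, 0.2, 0.3))^2 + sd(c(0.4, 0.5, 0.6))^2))

  # empty background: F(empty) = 0, so dF equals the monoculture function
  d2 <- data.frame(community_id = "s", members = "s", replicate = 1, F = 0.95)
  expect_equal(functional_effect(d2, "s")$delta_F, 0.95)

  expect_error(functional_effect(d, "a", "a"), "already in background")
  expect_error(functional_effect(d, "s", "zz"), "not measured")
})

test_that("a perfect consumer fits a = 1, b = -1 with floored variance", {
  d <- make_perfect_dataset()
  fee <- fit_fee(d, "P")
  expect_equal(fee$a, 1, tolerance = 1e-12)
  expect_equal(fee$b, -1, tolerance = 1e-12)
  expect_equal(fee$sigma2, 1e-4)  # zero SSR hits the floor
  expect_gte(fee$n_points, 4)
})

test_that("FEE fitting errors on insufficient or degenerate designs", {
  d2 <- rbind(
    data.frame(community_id = "a", members = "a", replicate = 1, F = 0.2),
    data.frame(community_id = "a;s", members = "a;s", replicate = 1, F = 0.5),
    data.frame(community_id = "s", members = "s", replicate = 1, F = 0.4))
  # only pairs (empty -> s) and (a -> a;s): 2 pairs
  expect_error(fit_fee(d2, "s"), "fewer than 3")
  expect_warning(fees <- fit_all_fees(d2), "no FEE fitted")
  expect_length(fees, 0)
})

test_that("OLS recovers known FEE parameters from line-generated pairs", {
  # noiseless: exact recovery
  set.seed(101)
  fb <- runif(10, 0, 1)
  a0 <- 0.4; b0 <- -0.7
  rows <- lapply(seq_along(fb), function(k) {
    idB <- community_id(paste0("b", k))
    idBi <- community_id(c(paste0("b", k), "s"))
    rbind(data.frame(community_id = idB, members = idB, replicate = 1, F = fb[k]),
          data.frame(community_id = idBi, members = idBi, replicate = 1,
                     F = pmin(pmax(fb[k] + a0 + b0 * fb[k], 0), 1)))
  })
  d <- do.call(rbind, rows)
  fee <- fit_fee(d, "s")
  expect_equal(fee$a, a0, tolerance = 1e-10)
  expect_equal(fee$b, b0, tolerance = 1e-10)

  # noisy: estimates within 3 standard errors of truth in >= 95% of replicates
  hits <- 0
  n_rep <- 200
  for (r in 1:n_rep) {
    set.seed(5000 + r)
    fbr <- runif(20, 0.05, 0.95)
    df <- a0 + b0 * fbr + rnorm(20, 0, 0.05)
    fit <- lm(df ~ fbr)
    se <- sqrt(diag(vcov(fit)))
    ok <- abs(coef(fit)[1] - a0) <= 3 * se[1] && abs(coef(fit)[2] - b0) <= 3 * se[2]
    if (ok) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("FEE JSON round-trips", {
  d <- make_perfect_dataset()
  fees <- suppressWarnings(fit_all_fees(d))
  f <- tempfile(fileext = ".json")
  write_fees_json(fees, f)
  back <- read_fees_json(f)
  expect_equal(names(back), names(fees))
  expect_equal(back[["P"]]$a, fees[["P"]]$a)
  expect_equal(back[["P"]]$sigma2, fees[["P"]]$sigma2)
})

test_that("in-sample targets are returned at their observed means exactly", {
  d <- make_perfect_dataset()
  fees <- suppressWarnings(fit_all_fees(d))
  p <- predict_function(c("x1", "x2"), d, fees)
  expect_true(p$in_sample)
  expect_identical(p$F_pred, 0.55)
})

test_that("single missing species reduces to the closed-form concatenation", {
  # a single chain: the only observed subsets of the target are the empty
  # community and the background c0, and only the added strain carries an
  # FEE, so exactly one lattice edge reaches the target
  set.seed(112)
  fb <- seq(0.1, 0.9, length.out = 8)
  rows <- lapply(seq_along(fb), function(k) {
    idB <- community_id(paste0("q", k))
    idBi <- community_id(c(paste0("q", k), "s"))
    rbind(data.frame(community_id = idB, members = idB, replicate = 1, F = fb[k]),
          data.frame(community_id = idBi, members = idBi, replicate = 1,
                     F = pmin(fb[k] + 0.3 - 0.5 * fb[k] + rnorm(1, 0, 0.02), 1)))
  })
  d <- rbind(do.call(rbind, rows),
             data.frame(community_id = "q9", members = "q9", replicate = 1,
                        F = 0.42))
  fees <- suppressWarnings(fit_all_fees(d, strains = "s"))
  tid <- community_id(c("q9", "s"))
  p <- predict_function(tid, d, fees)
  s <- fees[["s"]]
  expect_equal(p$F_pred_raw, 0.42 + s$a + s$b * 0.42, tolerance = 1e-12)
  expect_equal(p$lattice_nodes - length(p$anchors), 1L)
})

test_that("lattice prediction is order-invariant and matches a numerical optimiser", {
  exp1 <- simulate_community_experiment(n_backgrounds = 40, n_base = 6,
                                        n_validation = 20, max_spread = 1,
                                        seed = 121)
  d <- exp1$dataset
  fees <- fit_all_fees(d)
  targets <- exp1$validation$community_id[1:6]
  for (tid in targets) {
    mem <- community_members(tid)
    p0 <- predict_function(mem, d, fees)
    # member-order invariance over random permutations of the member list
    for (k in 1:20) {
      set.seed(6000 + k)
      pk <- predict_function(sample(mem), d, fees)
      expect_lt(abs(pk$F_pred_raw - p0$F_pred_raw), 1e-9)
    }
    # row-order invariance of the training data
    set.seed(77)
    p_shuf <- predict_function(mem, d[sample(nrow(d)), ], fees)
    expect_lt(abs(p_shuf$F_pred_raw - p0$F_pred_raw), 1e-9)
    # generic optimiser agreement on small lattices
    n_latent <- p0$lattice_nodes - length(p0$anchors)
    if (n_latent >= 1 && n_latent <= 4) {
      orc <- oracle_lattice_optim(mem, d, fees)
      expect_equal(p0$F_pred_raw, orc, tolerance = 1e-6)
    }
  }
})

test_that("additive predictions follow the monoculture-plus-effects formula", {
  eff <- c(i = -0.1, j = -0.2)
  p <- additive_predict(c("i", "j"), 0.95, eff)
  expect_equal(p$F_pred, 0.65)
  expect_equal(additive_predict(character(0), 0.95, eff)$F_pred, 0.95)
  pc <- additive_predict(c("i", "j"), 0.1, c(i = -0.3, j = -0.4))
  expect_equal(pc$F_pred, 0)
  expect_equal(pc$F_pred_raw, -0.6)
  expect_true(pc$clipped)
  expect_error(additive_predict("z", 0.95, eff), "no pairwise effect")
})

test_that("evaluation metrics match hand-computed values", {
  pred <- data.frame(community_id = c("a", "b"), F_pred = c(0.8, 0.6))
  obs <- data.frame(community_id = c("a", "b"), F_obs = c(0.9, 0.4))
  ev <- evaluate_predictions(pred, obs)
  expect_equal(ev$overall$rmse, sqrt((0.01 + 0.04) / 2))
  expect_true(is.na(ev$overall$r))  # 2 points: correlation not reported

  ev1 <- evaluate_predictions(pred[1, ], obs)
  expect_true(is.na(ev1$overall$r))
  expect_equal(ev1$overall$rmse, 0.1)

  perf <- evaluate_predictions(
    data.frame(community_id = c("a", "b", "c;d"), F_pred = c(0.1, 0.5, 0.9)),
    data.frame(community_id = c("a", "b", "c;d"), F_obs = c(0.1, 0.5, 0.9)))
  expect_equal(perf$overall$rmse, 0)
  expect_equal(perf$overall$r, 1)
  expect_equal(perf$per_richness$richness, c(1, 2))
})
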