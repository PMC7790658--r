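test_that("collinearity pruning follows hand-computed UPGMA structure", {
  set.seed(81)
  n <- 60
  v1 <- runif(n)
  env <- data.frame(v1 = v1,
                    v2 = v1^2 + 0.001 * rnorm(n),  # near-monotone copy of v1
                    v3 = rnorm(n),
                    v4 = rnorm(n))
  pr <- collinearity_prune(env, variables = c("v1", "v2", "v3", "v4"))
  # hand UPGMA on 1 - |r_s|: v1-v2 merge first (~0), others stay apart
  expect_equal(pr$tree$merge[1, ], c(-1, -2))
  expect_equal(unname(pr$clusters[c("v1", "v2")]), c(1, 1))
  expect_length(unique(pr$clusters), 3)
  expect_true(sum(c("v1", "v2") %in% pr$retained) == 1)
  expect_true(all(c("v3", "v4") %in% pr$retained))

  # all pairwise |r_s| < 0.7: everything retained
  env_ind <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  pr2 <- collinearity_prune(env_ind, variables = c("a", "b", "c"))
  expect_setequal(pr2$retained, c("a", "b", "c"))

  # a duplicated variable keeps exactly one of the pair
  env_dup <- data.frame(a = v1, b = v1, c = rnorm(n))
  pr3 <- collinearity_prune(env_dup, variables = c("a", "b", "c"))
  expect_equal(sum(c("a", "b") %in% pr3$retained), 1)

  env_const <- data.frame(a = v1, b = rep(1, n))
  expect_error(collinearity_prune(env_const, variables = c("a", "b")),
               "constant")
})

test_that("logistic fitting matches a brute-force likelihood search", {
  x <- c(-2, -1, -0.5, 0.5, 1, 2, -1.5, 1.5)
  y <- c(0, 0, 1, 0, 1, 1, 0, 1)
  fit <- fit_logistic(matrix(x, ncol = 1), y)
  # iterated grid refinement over (b0, b1), independent of IRLS
  ll <- function(b0, b1) sum(dbinom(y, 1, plogis(b0 + b1 * x), log = TRUE))
  ctr <- c(0, 0); half <- c(8, 8)
  for (round in 1:12) {
    b0s <- seq(ctr[1] - half[1], ctr[1] + half[1], length.out = 21)
    b1s <- seq(ctr[2] - half[2], ctr[2] + half[2], length.out = 21)
    grid <- expand.grid(b0 = b0s, b1 = b1s)
    best <- grid[which.max(mapply(ll, grid$b0, grid$b1)), ]
    ctr <- c(best$b0, best$b1); half <- half / 5
  }
  expect_equal(unname(fit$coefficients), ctr, tolerance = 1e-6)

  # labels independent of a balanced predictor: coefficients near zero
  set.seed(82)
  xb <- rnorm(400)
  yb <- rep(c(0, 1), 200)
  fb <- fit_logistic(matrix(xb, ncol = 1), yb)
  expect_lt(abs(fb$coefficients[1]), 0.3)
  expect_lt(abs(fb$coefficients[2]), 0.3)

  # complete separation is an explicit error
  expect_error(fit_logistic(matrix(c(1, 2, 3, 10, 11, 12, 1.5, 11.5),
                                   ncol = 1),
                            c(0, 0, 0, 1, 1, 1, 0, 1)), "separation")
  expect_error(fit_logistic(matrix(1, 5, 1), rep(c(0, 1), c(2, 3))),
               "constant")
})

test_that("forward stepwise selects a planted signal and controls entry", {
  picked <- 0
  for (s in 1:40) {
    es <- sim_env_spec(n_localities = 500, nuisance = c(n1 = 0.2),
                       seed = 900 + s)
    env <- simulate_env_presence(es)
    m <- forward_stepwise_lr(env, c("n1", "bio17"))
    if (identical(m$variables, "bio17")) picked <- picked + 1
  }
  # the planted driver is always found; the noise candidate can slip in at
  # roughly the 5% entry rate, so exact selection runs near 95% of seeds
  expect_gte(picked / 40, 0.875)

  # a single all-noise candidate enters in about 5% of seeds
  set.seed(83)
  empty <- 0
  for (s in 1:100) {
    env0 <- data.frame(species = rep(c("M", "P"), 100), x = rnorm(200))
    m0 <- forward_stepwise_lr(env0, "x")
    if (length(m0$variables) == 0) empty <- empty + 1
  }
  expect_gt(empty / 100, 0.90)
  expect_lt(empty / 100, 0.995)
})

test_that("stepwise traces are consistent and an empty model is well-formed", {
  set.seed(84)
  env0 <- data.frame(species = rep(c("M", "P"), 50), x = rnorm(100))
  # force no entry by demanding an impossible criterion
  m <- forward_stepwise_lr(env0, "x", p_in = 1e-12)
  expect_length(m$variables, 0)
  expect_true(is.na(m$auc))

  es <- sim_env_spec(n_localities = 400, seed = 85)
  env <- simulate_env_presence(es)
  m2 <- forward_stepwise_lr(env, c("bio12", "bio01", "bio02", "bio17"))
  expect_true("bio17" %in% m2$variables)
  adds <- m2$trace[m2$trace$action == "add", ]
  expect_true(all(adds$p < 0.05))
  # likelihood-ratio statistics for nested models are non-negative by construction
  expect_true(all(m2$trace$p >= 0 & m2$trace$p <= 1))
})

test_that("AUC equals the concordant-pair count and is rank-invariant", {
  sc <- c(0.1, 0.4, 0.35, 0.8, 0.7, 0.2)
  lab <- c(0, 0, 0, 1, 1, 1)
  pairs <- expand.grid(i = which(lab == 1), j = which(lab == 0))
  oracle <- mean(ifelse(sc[pairs$i] > sc[pairs$j], 1,
                        ifelse(sc[pairs$i] == sc[pairs$j], 0.5, 0)))
  expect_equal(auc(sc, lab)$auc, oracle)
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(auc(rep(1, 6), lab)$auc, 0.5)
  expect_error(auc(1:3, c(1, 1, 1)), "both classes")
  # monotone transform of the scores leaves AUC unchanged
  set.seed(86)
  sc2 <- rnorm(100); lab2 <- rbinom(100, 1, plogis(sc2))
  expect_equal(auc(exp(sc2), lab2)$auc, auc(sc2, lab2)$auc)
  # independent cross-check against pROC on the same scores
  skip_if_not_installed("pROC")
  ro <- pROC::roc(lab2, sc2, quiet = TRUE, direction = "<")
  expect_equal(auc(sc2, lab2)$auc, as.numeric(pROC::auc(ro)), tolerance = 1e-12)
})

test_that("hindcast stacking thresholds, counts and propagates nodata", {
  es <- sim_env_spec(n_localities = 600, nuisance = c(), seed = 87)
  env <- simulate_env_presence(es)
  model <- forward_stepwise_lr(env, "bio17")
  r1 <- simulate_climate_raster(6, 6, value_range = c(0, 100), seed = 88)
  stack1 <- hindcast_stack(model, list(list(bio17 = r1)))
  expect_true(all(unclass(stack1$cumulative) %in% c(0, 1)))
  expect_equal(unclass(stack1$binary[[1]]),
               (unclass(stack1$probability[[1]]) > 0.5) * 1,
               ignore_attr = TRUE)

  stack3 <- hindcast_stack(model, list(list(bio17 = r1), list(bio17 = r1),
                                       list(bio17 = r1)))
  expect_true(all(unclass(stack3$cumulative) %in% c(0, 3)))

  r_na <- r1; r_na[2, 3] <- NA
  stack_na <- hindcast_stack(model, list(list(bio17 = r1),
                                         list(bio17 = r_na)))
  expect_true(is.na(unclass(stack_na$cumulative)[2, 3]))
  expect_true(is.na(unclass(stack_na$probability[[2]])[2, 3]))

  expect_error(hindcast_stack(model, list(list(bogus = r1))), "lacks")
  r_off <- raster_grid(unclass(r1)[1:5, ], 0, 0, 1)
  expect_error(hindcast_stack(model, list(list(bio17 = r1),
                                          list(bio17 = r_off))), "misaligned")
})
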