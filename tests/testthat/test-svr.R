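test_that("chain-level fold assignment is balanced, deterministic, and total", {
  ids <- sprintf("c%02d", 1:89)
  f <- chain_kfold_split(ids, k = 5, seed = 1)
  expect_setequal(f$chain, ids)
  expect_equal(sort(as.numeric(table(f$fold)), decreasing = TRUE),
               c(18, 18, 18, 18, 17))
  # determinism
  expect_identical(f, chain_kfold_split(ids, k = 5, seed = 1))
  expect_false(identical(f$fold, chain_kfold_split(ids, k = 5, seed = 2)$fold))
  # singleton folds
  f5 <- chain_kfold_split(letters[1:5], k = 5, seed = 3)
  expect_equal(sort(as.numeric(table(f5$fold))), rep(1, 5))
  expect_error(chain_kfold_split(letters[1:3], k = 5), "exceeds")
})

test_that("the SVR memorizes a noise-free affine map of the features", {
  set.seed(10)
  X <- matrix(stats::runif(500 * 12, -1, 1), nrow = 500)
  beta <- stats::rnorm(12)
  y <- as.numeric(X %*% beta) / 10 + 0.5
  m <- svr_train(X, y, svr_config(C = 10, gamma = 0.05, epsilon = 0.01, w = 1))
  p <- predict(m, X)
  expect_gt(pearson_r(p$asa_norm, y), 0.99)
})

test_that("degenerate and permuted training sets behave as contracts require", {
  set.seed(11)
  X <- matrix(stats::runif(60 * 8, -1, 1), nrow = 60)
  cfg <- svr_config(C = 1, gamma = 0.1, epsilon = 0.05, w = 1)

  # constant targets -> constant predictions within epsilon
  mc <- svr_train(X, rep(0.4, 60), cfg)
  expect_true(all(abs(predict(mc, X)$asa_norm - 0.4) <= cfg$epsilon + 1e-8))

  # row order does not matter
  y <- stats::runif(60)
  perm <- sample(60)
  m1 <- svr_train(X, y, cfg)
  m2 <- svr_train(X[perm, ], y[perm], cfg)
  Xnew <- matrix(stats::runif(20 * 8, -1, 1), nrow = 20)
  expect_equal(predict(m1, Xnew)$asa_norm, predict(m2, Xnew)$asa_norm,
               tolerance = 1e-9)

  expect_error(svr_train(X[1:5, ], y[1:5], cfg), "fewer than 10")
})

test_that("predictions are clipped to [0, 1.25] normalized and scaled to Angstrom^2", {
  set.seed(12)
  X <- matrix(stats::runif(40 * 4, -1, 1), nrow = 40)
  y <- stats::runif(40)
  m <- svr_train(X, y, svr_config(C = 1, gamma = 0.5, w = 0))
  p <- predict(m, X)
  expect_true(all(p$asa_norm >= 0 & p$asa_norm <= 1.25))
  expect_equal(p$asa_A2, p$asa_norm * 400)
  # the clip endpoints map to 0 and 500 Angstrom^2
  expect_equal(max(pmin(1.25, pmax(0, 1.5))) * 400, 500)
  expect_error(predict(m, X[, 1:3, drop = FALSE]), "dimension")
})

test_that("a persisted model reloads and re-predicts bit-identically", {
  set.seed(13)
  X <- matrix(stats::runif(50 * 8, -1, 1), nrow = 50)
  y <- stats::runif(50)
  m <- svr_train(X, y, svr_config(C = 2, gamma = 0.2, w = 1),
                 bounds = c(p_lo = 0, p_hi = 4), chains = c("a", "b"))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(predict(m, X), predict(m2, X))
  expect_equal(m2$bounds, c(p_lo = 0, p_hi = 4))
  expect_true(nzchar(m2$version))
})

test_that("cross-validation predicts every position exactly once without chain leakage", {
  set <- make_asa_regression_set(20, n_chains = 15, len_range = c(20, 30), h = 2)
  rf <- regression_features(set, w = 4)
  cv <- cross_validate(rf$features, rf$targets, rf$chain, k = 5, seed = 2,
                       cfg = svr_config(C = 4, w = 4))
  # partition: each row predicted exactly once
  expect_equal(sort(cv$predictions$row), seq_len(nrow(rf$features)))
  # leakage: each chain's predictions come only from its own fold's model
  fold_of <- cv$folds$fold[match(cv$predictions$chain, cv$folds$chain)]
  expect_equal(cv$predictions$fold, fold_of)
  for (f in 1:5) {
    test_chains <- cv$folds$chain[cv$folds$fold == f]
    train_chains <- cv$folds$chain[cv$folds$fold != f]
    expect_length(intersect(test_chains, train_chains), 0)
  }
  expect_equal(cv$r, pearson_oracle(cv$predictions$predicted,
                                    cv$predictions$actual))
})

test_that("grid search is exhaustive and prefers the generalizing gamma", {
  set <- make_asa_regression_set(21, n_chains = 15, len_range = c(20, 30), h = 2)
  rf <- regression_features(set, w = 4)

  # 1x1 grid returns that config
  g1 <- grid_search(rf$features, rf$targets, rf$chain, k = 5, seed = 2,
                    C_grid = 2, gamma_grid = 0.05)
  expect_equal(g1$best$C, 2)
  expect_equal(g1$best$gamma, 0.05)
  expect_equal(nrow(g1$table), 1)

  # an absurdly large gamma memorizes chains and fails held-out; the small
  # gamma must win, and the table covers the full grid
  g2 <- grid_search(rf$features, rf$targets, rf$chain, k = 5, seed = 2,
                    C_grid = 4, gamma_grid = c(0.05, 50))
  expect_equal(nrow(g2$table), 2)
  expect_equal(g2$best$gamma, 0.05)
  expect_gt(g2$table$r[g2$table$gamma == 0.05],
            g2$table$r[g2$table$gamma == 50])
})

test_that("held-out accuracy rises with window size until the planted span is covered", {
  set <- make_asa_regression_set(25, n_chains = 15, len_range = c(25, 35), h = 3)
  sweep <- window_sweep(set, w_grid = c(0, 4, 10), k = 5, seed = 6,
                        cfg = svr_config(C = 4))
  expect_equal(sweep$n_features, 4 * (2 * c(0, 4, 10) + 1))
  # rises sharply once the window covers the h = 3 dependency...
  expect_gt(sweep$r[sweep$w == 4], sweep$r[sweep$w == 0] + 0.2)
  # ...then plateaus or falls: tripling the window past the span buys nothing
  expect_lt(sweep$r[sweep$w == 10], sweep$r[sweep$w == 4] + 0.05)
})

test_that("tidy and glance summarise cross-validation results", {
  set <- make_asa_regression_set(22, n_chains = 10, len_range = c(15, 20), h = 1)
  rf <- regression_features(set, w = 2)
  cv <- cross_validate(rf$features, rf$targets, rf$chain, k = 5, seed = 4,
                       cfg = svr_config(C = 1, w = 2))
  td <- tidy(cv)
  expect_equal(nrow(td), 10)
  expect_named(td, c("chain", "fold", "n", "r"))
  gl <- glance(cv)
  expect_equal(gl$n_chains, 10)
  expect_equal(gl$n_positions, nrow(rf$features))
  expect_equal(gl$r, cv$r)
})
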