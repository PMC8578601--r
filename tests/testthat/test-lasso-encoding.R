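test_that("variance explained matches its defining formula", {
  y <- c(1, 2, 3, 4)
  expect_equal(variance_explained(y, y), 1)
  expect_equal(variance_explained(y, rep(mean(y), 4)), 0)
  expect_equal(variance_explained(y, c(1, 2, 3, 5)), 0.8)
  expect_error(variance_explained(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(variance_explained(1:3, 1:4), "length")
})

test_that("uninformative units are detected by matrix-scaled variance", {
  set.seed(8)
  # 7 healthy units, 3 engineered low-variance units (one exactly constant)
  healthy <- matrix(rnorm(200 * 7), 200, 7)
  quiet <- cbind(rep(2, 200), rnorm(200, sd = 1e-3), rnorm(200, sd = 5e-3))
  m <- response_matrix(cbind(healthy, quiet), kind = "model")
  cfg <- study_config()
  zu <- zero_uninformative(m, cfg)
  expect_equal(sum(!zu$informative), 3L)
  expect_true(all(zu$matrix$values[, 8:10] == 0))
  expect_true(all(zu$matrix$values[, 1:7] == m$values[, 1:7]))

  # a unit at scaled variance ~0.5 is retained
  m2 <- response_matrix(cbind(rnorm(100), rnorm(100, sd = sqrt(0.5))),
                        kind = "model")
  expect_true(all(zero_uninformative(m2, cfg)$informative))

  const_all <- response_matrix(matrix(1, 50, 3), kind = "model")
  expect_error(zero_uninformative(const_all, cfg), "no predictors")
})

test_that("sparse regression recovers planted supports", {
  set.seed(31)
  S <- 500
  X <- response_matrix(matrix(rnorm(S * 5), S, 5), kind = "model")
  cfg <- study_config()

  # exact copy of predictor 3
  fit <- fit_lasso(X$values[, 3], X, cfg, seed = 1)
  expect_setequal(names(which(fit$coefficients != 0)), "u3")
  expect_equal(unname(fit$coefficients["u3"]), 1, tolerance = 0.1)

  # independent response: the one-SE rule favours the null model
  fit0 <- fit_lasso(rnorm(S), X, cfg, seed = 2)
  expect_true(all(fit0$coefficients == 0))

  # planted two-coefficient signal at R^2 = 0.8; the one-SE refit is
  # penalized, so coefficients sit a shrinkage step (~lambda) below truth
  y <- 0.8 * X$values[, 1] + 0.6 * X$values[, 2] + rnorm(S, sd = 0.5)
  fit2 <- fit_lasso(y, X, cfg, seed = 3)
  expect_true(all(c("u1", "u2") %in% names(which(fit2$coefficients != 0))))
  expect_equal(unname(fit2$coefficients[c("u1", "u2")]), c(0.8, 0.6),
               tolerance = 0.25)
  # OLS oracle on the true support recovers the planted values; the lasso
  # estimate is uniformly below it by the penalty
  ols <- coef(lm(y ~ X$values[, 1] + X$values[, 2]))[-1]
  expect_equal(unname(ols), c(0.8, 0.6), tolerance = 0.1)
  expect_true(all(fit2$coefficients[c("u1", "u2")] < ols))
  expect_lt(max(abs(fit2$coefficients[c("u1", "u2")] - ols)), 0.2)

  expect_warning(fz <- fit_lasso(rep(1, S), X, cfg, seed = 1), "zero-variance")
  expect_true(all(fz$coefficients == 0))
  tiny <- response_matrix(matrix(rnorm(8 * 3), 8, 3), kind = "model")
  expect_error(fit_lasso(rnorm(8), tiny, cfg, seed = 1), "folds")
})

test_that("one-SE selection is sparser than the CV minimum and satisfies KKT", {
  set.seed(77)
  S <- 100
  X <- response_matrix(matrix(rnorm(S * 5), S, 5), kind = "model")
  y <- X$values %*% c(1, -0.5, 0, 0, 0.25) + rnorm(S, sd = 0.7)
  cfg <- study_config()
  fit <- fit_lasso(drop(y), X, cfg, seed = 4)
  expect_true(fit$chosen_lambda %in% fit$lambda_grid)
  i_min <- which.min(fit$cv_mse)
  i_sel <- which(fit$lambda_grid == fit$chosen_lambda)
  expect_gte(fit$chosen_lambda, fit$lambda_grid[i_min])
  expect_lte(fit$cv_mse[i_sel], min(fit$cv_mse) + fit$cv_se[i_min])

  # KKT subgradient conditions of the standardized problem at the chosen
  # lambda: |x_d' r / S| = lambda on the active set, <= lambda off it.
  mu <- colMeans(X$values)
  sd_n <- sqrt(colSums(sweep(X$values, 2, mu)^2) / S)
  Xs <- sweep(sweep(X$values, 2, mu), 2, sd_n, `/`)
  beta_s <- fit$coefficients * sd_n
  r <- drop(y) - mean(y) - drop(Xs %*% beta_s)
  g <- drop(crossprod(Xs, r)) / S
  lam <- fit$chosen_lambda
  active <- beta_s != 0
  expect_lt(max(abs(g[active] - lam * sign(beta_s[active])), 0), 1e-6)
  expect_lt(max(abs(g[!active])) - lam, 1e-6)
})

test_that("encoding and decoding populations behave at the two extremes", {
  w <- tiny_world(S = 200, K = 4, J = 10, noise_sd = 0.3, seed = 19)
  neu <- realize_neural(w)
  cfg <- tiny_config(cv_folds = 5L)

  # model = exact copy of the neural matrix
  copy <- response_matrix(neu$values, kind = "model")
  enc <- encode_population(neu, copy, cfg, seed = 1)
  expect_gte(median(enc$ve, na.rm = TRUE), 0.99)
  expect_true(all(enc$weights >= 0))

  # model independent of the neurons
  noise <- response_matrix(matrix(rnorm(200 * 6), 200, 6), kind = "model")
  enc0 <- encode_population(neu, noise, cfg, seed = 2)
  expect_lte(median(enc0$ve, na.rm = TRUE), 0.05)

  # decoding mirror: units copied from neurons give VE ~ 1
  dec <- decode_population(copy, neu, cfg, seed = 3)
  expect_true(all(dec$ve > 0.95))

  # training-set VE of the refit model never falls below the mean predictor
  split <- enc$split
  tr <- intersect(neu$stimulus_ids, split$train)
  for (j in seq_len(3)) {
    fit <- fit_lasso(neu$values[match(tr, neu$stimulus_ids), j],
                     select_stimuli(copy, tr), cfg, seed = j)
    pred <- drop(select_stimuli(copy, tr)$values %*% fit$coefficients) +
      fit$intercept
    expect_gte(variance_explained(neu$values[match(tr, neu$stimulus_ids), j],
                                  pred), 0)
  }
})

test_that("weight matrices are invariant to predictor sign flips", {
  w <- tiny_world(S = 200, K = 4, J = 6, seed = 23)
  neu <- realize_neural(w)
  model <- realize_model(w, model_recipe("disentangled", n_units = 4,
                                         noise_sd = 0.1, seed = 2))
  cfg <- tiny_config(cv_folds = 5L)
  enc1 <- encode_population(neu, model, cfg, seed = 5)
  flipped <- response_matrix(model$values %*% diag(c(-1, 1, -1, 1)),
                             kind = "model", unit_ids = model$unit_ids,
                             stimulus_ids = model$stimulus_ids)
  enc2 <- encode_population(neu, flipped, cfg, seed = 5)
  expect_equal(enc1$weights, enc2$weights, tolerance = 1e-6)
})

test_that("model filtering applies the mean-minus-SD rule", {
  f <- filter_models(c(a = 0.5, b = 0.45, c = 0.1))
  expect_equal(f$threshold, mean(c(0.5, 0.45, 0.1)) - sd(c(0.5, 0.45, 0.1)))
  expect_identical(f$excluded, "c")

  expect_identical(filter_models(c(a = 0.3, b = 0.3, c = 0.3))$excluded,
                   character(0))

  # arithmetic oracle: 0.29 sits just below mean - SD of {0.3, 0.3, 0.29}
  ve <- c(m1 = 0.3, m2 = 0.3, m3 = 0.29)
  expect_lt(ve[["m3"]], mean(ve) - sd(ve))
  expect_identical(filter_models(ve)$excluded, "m3")

  expect_warning(single <- filter_models(c(only = 0.4)), "single")
  expect_identical(single$kept, "only")
})
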