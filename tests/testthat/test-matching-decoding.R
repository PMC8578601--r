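test_that("the assignment solver is exact against exhaustive enumeration", {
  set.seed(55)
  for (i in 1:200) {
    n <- sample(1:6, 1)
    m <- sample(n:7, 1)
    cost <- matrix(runif(n * m, -1, 2), n, m)
    sol <- neuralign:::lap_solve(cost)
    expect_equal(sol$cost, oracle_assignment_cost(cost), tolerance = 1e-10)
    expect_false(anyDuplicated(sol$assignment) > 0)
    expect_equal(sol$cost, sum(cost[cbind(seq_len(n), sol$assignment)]))
  }
  expect_error(neuralign:::lap_solve(matrix(1, 3, 2)), "nrow")
})

test_that("matching follows the published correlation-cost example", {
  D <- matrix(c(0.9, 0.2, 0.1, 0.8, 0.85, 0.3), 2, 3, byrow = TRUE)
  sol <- neuralign:::lap_solve(1 - D)
  expect_equal(sol$assignment, c(1L, 2L))
})

test_that("match_units pairs copies with their sources", {
  w <- tiny_world(S = 200, K = 4, J = 10, seed = 61)
  neu <- realize_neural(w)
  src <- c(2, 5, 9)
  model <- response_matrix(neu$values[, src], kind = "model")
  asg <- match_units(model, neu)
  expect_identical(asg$pairs$neuron, neu$unit_ids[src])
  expect_lt(asg$total_cost, 1e-9)

  # a single unit is matched to its maximum-correlation neuron
  one <- select_units(model, 1)
  asg1 <- match_units(one, neu)
  cors <- cor(one$values, neu$values)
  expect_identical(asg1$pairs$neuron, neu$unit_ids[which.max(cors)])

  big <- response_matrix(matrix(rnorm(200 * 12), 200, 12), kind = "model")
  expect_error(match_units(big, neu), "one-to-one matching impossible")
})

test_that("matched decoding reproduces noiseless latents on held-out data", {
  w <- generate_world(S = 150, K = 4, J = 4, redundancy = 1, noise_sd = 0,
                      seed = 71)
  neu <- realize_neural(w)
  # pure one-to-one ground truth: units are permuted copies of the neurons
  model <- response_matrix(neu$values[, c(3, 1, 4, 2)], kind = "model",
                           unit_ids = paste0("z", 1:4))
  sp <- split_heldout(neu, 30, seed = 1)
  ids <- list(train = sp$train$stimulus_ids, heldout = sp$heldout$stimulus_ids)
  asg <- match_units(select_stimuli(model, ids$train),
                     select_stimuli(neu, ids$train))
  fit <- decode_from_matched(asg,
                             select_stimuli(neu, ids$train),
                             select_stimuli(model, ids$train),
                             select_stimuli(neu, ids$heldout),
                             select_stimuli(model, ids$heldout))
  expect_lt(max(abs(fit$predicted - fit$truth)), 1e-9)
  expect_equal(cosine_distance_score(fit$truth, fit$predicted), 0,
               tolerance = 1e-12, ignore_attr = TRUE)
  # raw-scale predictions reproduce the latents themselves
  true_raw <- select_stimuli(model, ids$heldout)$values[, asg$pairs$unit]
  expect_lt(max(abs(fit$predicted_raw - true_raw)), 1e-9)
})

test_that("regression slopes track training correlation under noise", {
  set.seed(81)
  S <- 2000
  unit <- rnorm(S)
  sigma <- 0.75
  neuron <- unit + rnorm(S, sd = sigma)
  model <- response_matrix(cbind(z1 = unit), kind = "model")
  neural <- response_matrix(cbind(n1 = neuron), kind = "neural")
  sp_ids <- list(train = paste0("s", 1:1600), heldout = paste0("s", 1601:2000))
  asg <- match_units(select_stimuli(model, sp_ids$train),
                     select_stimuli(neural, sp_ids$train))
  fit <- decode_from_matched(asg,
                             select_stimuli(neural, sp_ids$train),
                             select_stimuli(model, sp_ids$train),
                             select_stimuli(neural, sp_ids$heldout),
                             select_stimuli(model, sp_ids$heldout))
  r <- cor(neuron[1:1600], unit[1:1600])
  # standardized univariate regression: slope ~ r, residual variance ~ 1 - r^2
  resid <- fit$truth - fit$predicted
  expect_equal(var(drop(resid)), 1 - r^2, tolerance = 0.1)
})

test_that("shuffled pairings decode worse than matched ones", {
  worse <- 0L
  for (seed in 1:5) {
    w <- tiny_world(S = 250, K = 4, J = 12, seed = seed)
    neu <- realize_neural(w)
    model <- realize_model(w, model_recipe("disentangled", n_units = 4,
                                           noise_sd = 0.1, seed = seed))
    sp <- split_heldout(neu, 50, seed = seed)
    ids <- list(train = sp$train$stimulus_ids,
                heldout = sp$heldout$stimulus_ids)
    asg <- match_units(select_stimuli(model, ids$train),
                       select_stimuli(neu, ids$train))
    shuffled <- asg
    set.seed(seed + 500)
    shuffled$pairs$neuron <- sample(shuffled$pairs$neuron)
    args <- list(select_stimuli(neu, ids$train),
                 select_stimuli(model, ids$train),
                 select_stimuli(neu, ids$heldout),
                 select_stimuli(model, ids$heldout))
    fit_m <- do.call(decode_from_matched, c(list(asg), args))
    fit_s <- do.call(decode_from_matched, c(list(shuffled), args))
    d_m <- cosine_distance_score(fit_m$truth, fit_m$predicted)
    d_s <- cosine_distance_score(fit_s$truth, fit_s$predicted)
    worse <- worse + (d_s > d_m)
  }
  expect_gte(worse, 4L)
})

test_that("cosine distances obey their geometry", {
  U <- rbind(c(1, 0), c(0, 2))
  expect_equal(cosine_distance_score(U, U), 0, ignore_attr = TRUE)
  V <- rbind(c(0, 1), c(3, 0)) # orthogonal on every stimulus
  expect_equal(cosine_distance_score(U, V), 1, ignore_attr = TRUE)
  expect_equal(cosine_distance_score(rbind(c(1, 0)), rbind(c(1, 1))),
               1 - 1 / sqrt(2), tolerance = 1e-12, ignore_attr = TRUE)
  # invariance to positive rescaling of either argument
  set.seed(3)
  A <- matrix(rnorm(20), 5, 4)
  B <- matrix(rnorm(20), 5, 4)
  expect_equal(as.numeric(cosine_distance_score(A, B)),
               as.numeric(cosine_distance_score(3.7 * A, 0.2 * B)),
               tolerance = 1e-12)
  d <- cosine_distance_score(A, B)
  expect_true(d >= 0 && d <= 2)
  # zero-norm stimuli are excluded with a warning
  A0 <- A
  A0[2, ] <- 0
  expect_warning(d0 <- cosine_distance_score(A0, B), "zero-norm")
  expect_equal(attr(d0, "n_excluded"), 1L)
  expect_error(cosine_distance_score(A, B[, 1:2]), "shape")
})

test_that("reconstruction error propagates factor noise through the decoder", {
  w <- tiny_world(S = 400, K = 4, J = 8, noise_sd = 0, seed = 91)
  model <- realize_model(w, model_recipe("disentangled", n_units = 4,
                                         noise_sd = 0, seed = 7))
  held <- w$factors$stimulus_ids[1:100]
  truth <- model$values[1:100, , drop = FALSE]
  # perfect predictions reconstruct perfectly
  expect_equal(reconstruction_error(w, truth, model, held), 0,
               tolerance = 1e-18)
  # additive N(0, sigma^2) latent noise -> error ~ sigma^2 tr(DD')/P
  sigma <- 0.3
  set.seed(13)
  noisy <- truth + matrix(rnorm(length(truth), sd = sigma), nrow(truth))
  expected <- sigma^2 * sum(w$decoder^2) / ncol(w$decoder)
  expect_equal(reconstruction_error(w, noisy, model, held), expected,
               tolerance = 0.25 * expected)
  # recipes without a ground-truth factor map are refused
  pca <- realize_model(w, model_recipe("pca_like", n_units = 4, seed = 1))
  expect_error(reconstruction_error(w, truth, pca, held), "factor map")
})
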