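# The heteroscedastic log posterior, MAP training and MC-dropout.

test_that("log posterior reduces to the mean-squared loss at constant noise", {
  # linear model with unit noise and flat prior: lp = -0.5 * RSS
  set.seed(1)
  X <- matrix(rnorm(40), 20, 2)
  y <- rnorm(20)
  model <- linear_model(2, noise_var = 1)
  theta <- rnorm(2)
  rss <- sum((y - X %*% theta)^2)
  expect_equal(log_posterior(model, theta, list(X = X, y = y), flat_prior()),
               -rss / 2, tolerance = 1e-12)

  # graph network with the aleatoric head disabled at sigma^2 = 1
  cfg <- tiny_config()
  model2 <- mpnn_model(cfg, fixed_var = 1)
  data <- fixture_data()
  th <- model2$init(2)
  mu <- model2$predict(th, data)[, "mean"]
  expect_equal(log_posterior(model2, th, data, flat_prior()),
               -sum((data$y - mu)^2) / 2, tolerance = 1e-10)

  # perfect predictions give a zero data term
  expect_equal(log_posterior(model, as.numeric(solve(crossprod(X),
                                                     crossprod(X, y))),
                             list(X = X, y = X %*% solve(crossprod(X),
                                                         crossprod(X, y))),
               flat_prior()), 0, tolerance = 1e-12)
})

test_that("heteroscedastic two-point toy case matches the hand-computed sum", {
  # two residuals r = (0.5, -1), variances (0.25, 4):
  #   lp = -(0.25/0.5) - 0.5*log(0.25) - (1/8) - 0.5*log(4)
  hl <- molbayes:::.hetero_ll(y = c(1.5, 1), mu = c(1, 2),
                              log_var = log(c(0.25, 4)))
  expect_equal(hl$ll,
               -0.5^2 / (2 * 0.25) - 0.5 * log(0.25) -
                 1 / (2 * 4) - 0.5 * log(4), tolerance = 1e-12)
  # gradient entries: d/dmu = r/s2, d/dlogvar = r^2/(2 s2) - 1/2
  expect_equal(hl$d_mu, c(0.5 / 0.25, -1 / 4), tolerance = 1e-12)
  expect_equal(hl$d_lv, c(0.5^2 / 0.5 - 0.5, 1 / 8 - 0.5), tolerance = 1e-12)
})

test_that("MAP training recovers the ridge closed form and is reproducible", {
  task <- make_conjugate_task(dim = 3, n = 40, prior_scale = 1,
                              noise_scale = 0.5, seed = 3)
  model <- linear_model(3, noise_var = task$noise_scale^2)
  data <- list(X = task$X, y = task$y)
  fit <- train_map(model, data, gaussian_prior(1), steps = 1500, lr = 0.05)
  ridge <- as.numeric(solve(crossprod(task$X) / 0.25 + diag(3),
                            crossprod(task$X, task$y) / 0.25))
  expect_equal(fit$theta, ridge, tolerance = 1e-8)

  fit2 <- train_map(model, data, gaussian_prior(1), steps = 1500, lr = 0.05)
  expect_identical(fit$theta, fit2$theta)

  # single data point, ample steps: residual driven near zero
  m1 <- linear_model(1, noise_var = 1)
  f1 <- train_map(m1, list(X = matrix(1), y = 2), flat_prior(),
                  steps = 3000, lr = 0.1)
  expect_lt(abs(2 - f1$theta), 1e-4)
})

test_that("divergence raises an error naming the iteration", {
  m1 <- linear_model(1, noise_var = 1e-8)
  expect_error(
    train_map(m1, list(X = matrix(1e4), y = 1), flat_prior(),
              steps = 50, lr = 1e6, optimizer = "sgd"),
    "step")
})

test_that("dropout with p = 0 reproduces the MAP trajectory", {
  cfg <- tiny_config()
  model <- mpnn_model(cfg)
  data <- fixture_data()
  f_map <- train_map(model, data, gaussian_prior(1), steps = 30, lr = 0.01,
                     seed = 4)
  f_d0 <- train_dropout(model, data, gaussian_prior(1),
                        dropout = dropout_config(p = 0), steps = 30,
                        lr = 0.01, seed = 4)
  expect_identical(f_map$theta, f_d0$theta)

  f_d <- train_dropout(model, data, gaussian_prior(1),
                       dropout = dropout_config(p = 0.2), steps = 30,
                       lr = 0.01, seed = 4)
  f_d2 <- train_dropout(model, data, gaussian_prior(1),
                        dropout = dropout_config(p = 0.2), steps = 30,
                        lr = 0.01, seed = 4)
  expect_identical(f_d$theta, f_d2$theta)
  expect_false(identical(f_map$theta, f_d$theta))
})

test_that("sampled masks are i.i.d. Bernoulli(1 - p) per unit", {
  cfg <- tiny_config()
  p <- 0.2
  set.seed(8)
  draws <- replicate(2000, {
    m <- sample_dropout_masks(cfg, p, scope = "all")
    c(unlist(m$h), m$fp, m$head1, m$head2)
  })
  keep_rate <- mean(draws)
  n <- length(draws)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(keep_rate - (1 - p)), 3 * se)
})

test_that("the variance decomposition is exact and recomputable from samples", {
  cfg <- tiny_config()
  model <- mpnn_model(cfg)
  data <- fixture_data()
  fit <- train_dropout(model, data, gaussian_prior(1),
                       dropout = dropout_config(p = 0.2, n_samples = 25),
                       steps = 40, lr = 0.01, seed = 5)
  pr <- predict_dropout(fit, data, seed = 6)
  expect_uncertain_prediction(pr, length(data$y))

  # brute-force recomputation from the stored raw samples
  s <- attr(pr, "samples")
  N <- nrow(s$means)
  for (j in seq_len(ncol(s$means))) {
    # same documented estimator, recomputed element by element
    mu <- s$means[1, j] + sum(s$means[, j] - s$means[1, j]) / N
    epi <- sum((s$means[, j] - mu)^2) / N
    ale <- sum(s$vars[, j]) / N
    expect_identical(pr$mean[j], mu)
    expect_identical(pr$var_epistemic[j], epi)
    expect_identical(pr$var_aleatoric[j], ale)
    expect_identical(pr$var_total[j], epi + ale)
  }

  # p = 0: all passes identical, epistemic exactly zero
  fit0 <- train_dropout(model, data, gaussian_prior(1),
                        dropout = dropout_config(p = 0), steps = 20,
                        lr = 0.01, seed = 5)
  pr0 <- predict_dropout(fit0, data, n_samples = 10, seed = 6)
  expect_identical(pr0$var_epistemic, rep(0, length(data$y)))

  # N = 1: total equals aleatoric, with a warning when p > 0
  expect_warning(pr1 <- predict_dropout(fit, data, n_samples = 1, seed = 7),
                 "epistemic")
  expect_identical(pr1$var_total, pr1$var_aleatoric)
})

test_that("prediction-time dropout is reproducible under a seed", {
  cfg <- tiny_config()
  model <- mpnn_model(cfg)
  data <- fixture_data()
  fit <- train_dropout(model, data, gaussian_prior(1),
                       dropout = dropout_config(p = 0.3, n_samples = 15),
                       steps = 15, lr = 0.01, seed = 1)
  a <- predict_dropout(fit, data, seed = 42)
  b <- predict_dropout(fit, data, seed = 42)
  expect_identical(a$mean, b$mean)
  expect_identical(a$var_total, b$var_total)
})
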