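# Bayesian regression engine.
#
# The generative model is y_i = F(x_i, theta) + eps_i with input-dependent
# Gaussian noise eps_i ~ N(0, sigma(x_i)^2). The log posterior, up to an
# additive constant, is
#   sum_i [ -(y_i - F(x_i,theta))^2 / (2 sigma_i^2) - 1/2 log sigma_i^2 ]
#     + log P(theta),
# which reduces to the (scaled) mean-squared loss plus the regulariser
# log P(theta) when sigma_i is constant. Inference engines (MAP, MC-dropout,
# SVGD) operate on a generic `uq_model` interface so the same machinery
# runs over the graph network and over plain linear-Gaussian regression
# (whose exact posterior is analytic and serves as an oracle).

#' Isotropic Gaussian prior over all weights
#' @param scale prior standard deviation (> 0).
#' @export
gaussian_prior <- function(scale = 1) {
  stopifnot(scale > 0)
  structure(list(kind = "gaussian", scale = scale,
                 log_density = function(theta) -sum(theta^2) / (2 * scale^2),
                 grad = function(theta) -theta / scale^2),
            class = "uq_prior")
}

#' Flat (improper, constant) prior
#' @export
flat_prior <- function() {
  structure(list(kind = "flat",
                 log_density = function(theta) 0,
                 grad = function(theta) numeric(length(theta))),
            class = "uq_prior")
}

#' Evaluate the heteroscedastic log posterior
#'
#' @param model a `uq_model` (see [mpnn_model()], [linear_model()]).
#' @param theta flat parameter vector.
#' @param data a data object understood by the model.
#' @param prior a `uq_prior`.
#' @return scalar log posterior (up to the discarded normalizing constant).
#' @export
log_posterior <- function(model, theta, data, prior = gaussian_prior(1)) {
  model$objective(theta, data, prior)
}

# shared likelihood-and-gradient core given network outputs
.hetero_ll <- function(y, mu, log_var, fixed_var = NULL) {
  if (!is.null(fixed_var)) {
    s2 <- fixed_var
    if (!is.finite(s2) || s2 <= 0) stop("non-finite or non-positive variance")
    ll <- -sum((y - mu)^2) / (2 * s2) - length(y) * 0.5 * log(s2)
    list(ll = ll, d_mu = (y - mu) / s2, d_lv = numeric(length(y)))
  } else {
    # clamp the log-variance to keep exp() finite; the gradient vanishes
    # in the saturated zone so training can pull back from it
    lv <- pmin(pmax(log_var, -20), 20)
    s2 <- exp(lv)
    if (any(!is.finite(s2))) stop("non-finite aleatoric variance")
    r <- y - mu
    live <- (log_var > -20) & (log_var < 20)
    ll <- sum(-r^2 / (2 * s2) - 0.5 * lv)
    list(ll = ll, d_mu = r / s2, d_lv = (r^2 / (2 * s2) - 0.5) * live)
  }
}

#' Graph-network regression model
#'
#' Wraps the message-passing network as a `uq_model`. `trainable` selects
#' which parameter groups the flat vector theta covers; frozen groups are
#' taken from `template` (used by the semi-supervised pipeline, where the
#' message-passing weights are learned without labels and then frozen).
#'
#' @param config an [mpnn_config()].
#' @param template optional `mpnn_params` supplying frozen groups.
#' @param trainable subset of c("H","W","head").
#' @param dropout_scope "all" or "head" (see [sample_dropout_masks()]).
#' @param fixed_var if non-NULL, the aleatoric head is ignored and the
#'   noise variance is held at this constant (homoscedastic regression).
#' @return a `uq_model`.
#' @export
mpnn_model <- function(config, template = NULL,
                       trainable = c("H", "W", "head"),
                       dropout_scope = c("all", "head"),
                       fixed_var = NULL) {
  dropout_scope <- match.arg(dropout_scope)
  if (is.null(template)) template <- init_mpnn_params(config, seed = 0L)
  force(trainable); force(fixed_var)

  as_params <- function(theta) unflatten_params(theta, template, trainable)

  grad_fn <- function(theta, data, prior, masks = NULL, idx = NULL,
                      weight = 1) {
    params <- as_params(theta)
    batch <- data$batch; y <- data$y
    if (!is.null(idx)) {
      batch <- subset_batch(batch, idx)
      y <- y[idx]
      weight <- weight * length(data$y) / length(idx)
    }
    fw <- mpnn_forward(params, batch, masks, keep_cache = TRUE)
    hl <- .hetero_ll(y, fw$mean, fw$log_var, fixed_var)
    d_out <- weight * cbind(hl$d_mu, hl$d_lv)
    g <- mpnn_backward(params, batch, fw$cache, d_out)
    list(lp = weight * hl$ll + prior$log_density(theta),
         grad = flatten_params(g, trainable) + prior$grad(theta))
  }

  structure(list(
    kind = "mpnn",
    config = config,
    template = template,
    trainable = trainable,
    dropout_scope = dropout_scope,
    n_par = n_params(template, trainable),
    init = function(seed) flatten_params(init_mpnn_params(config, seed),
                                         trainable),
    sample_masks = function(p) sample_dropout_masks(config, p, dropout_scope),
    objective = function(theta, data, prior) {
      params <- as_params(theta)
      fw <- mpnn_forward(params, data$batch)
      .hetero_ll(data$y, fw$mean, fw$log_var, fixed_var)$ll +
        prior$log_density(theta)
    },
    grad = grad_fn,
    predict = function(theta, newdata, masks = NULL) {
      batch <- if (inherits(newdata, "graph_batch")) newdata else newdata$batch
      fw <- mpnn_forward(as_params(theta), batch, masks)
      if (!is.null(fixed_var))
        fw$log_var <- rep(log(fixed_var), length(fw$mean))
      cbind(mean = fw$mean, log_var = fw$log_var)
    },
    as_params = as_params
  ), class = "uq_model")
}

#' Assemble training data for an mpnn `uq_model`
#' @param graphs list of `mol_graph` (or a `mol_dataset`).
#' @param y numeric labels (taken from the dataset when omitted).
#' @export
mpnn_data <- function(graphs, y = NULL) {
  if (inherits(graphs, "mol_dataset")) {
    if (is.null(y)) y <- graphs$y
    graphs <- graphs$graphs
  }
  keep <- !is.na(y)
  list(batch = graph_batch(graphs[keep]), y = y[keep])
}

#' Linear-Gaussian regression model with known noise
#'
#' F(x, theta) = X theta with fixed noise variance; with a Gaussian prior
#' its posterior is analytic, making it the oracle for SVGD and MAP tests.
#'
#' @param d number of coefficients.
#' @param noise_var fixed observation noise variance.
#' @return a `uq_model` whose data objects are `list(X, y)`.
#' @export
linear_model <- function(d, noise_var = 1) {
  stopifnot(d >= 1, noise_var > 0)
  structure(list(
    kind = "linear",
    n_par = as.integer(d),
    dropout_scope = "head",
    init = function(seed) { set.seed(seed); stats::rnorm(d) },
    sample_masks = function(p) NULL,
    objective = function(theta, data, prior) {
      r <- data$y - as.numeric(data$X %*% theta)
      -sum(r^2) / (2 * noise_var) + prior$log_density(theta)
    },
    grad = function(theta, data, prior, masks = NULL, idx = NULL,
                    weight = 1) {
      X <- data$X; y <- data$y
      if (!is.null(idx)) {
        X <- X[idx, , drop = FALSE]; y <- y[idx]
        weight <- weight * length(data$y) / length(idx)
      }
      r <- y - as.numeric(X %*% theta)
      list(lp = weight * (-sum(r^2) / (2 * noise_var)) +
             prior$log_density(theta),
           grad = weight * as.numeric(crossprod(X, r)) / noise_var +
             prior$grad(theta))
    },
    predict = function(theta, newdata, masks = NULL) {
      X <- if (is.list(newdata) && !is.null(newdata$X)) newdata$X else newdata
      cbind(mean = as.numeric(X %*% theta),
            log_var = rep(log(noise_var), nrow(X)))
    }
  ), class = "uq_model")
}
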