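# Optimizers and the MAP / MC-dropout training loops.

# Adam, the decayed-accumulator AdaGrad variant used by the original SVGD
# reference implementation, and plain constant-step gradient ascent. All
# are closures returning an ascent step (gradients here are gradients of
# the log posterior, which is maximized).
make_optimizer <- function(kind = c("adam", "adagrad", "sgd"), lr = 1e-3) {
  kind <- match.arg(kind)
  if (kind == "sgd") {
    return(list(init = function(n) list(),
                step = function(g, s) list(delta = lr * g, state = s)))
  }
  if (kind == "adam") {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    list(
      init = function(n) list(m = numeric(n), v = numeric(n), t = 0L),
      step = function(g, s) {
        s$t <- s$t + 1L
        s$m <- b1 * s$m + (1 - b1) * g
        s$v <- b2 * s$v + (1 - b2) * g^2
        mh <- s$m / (1 - b1^s$t)
        vh <- s$v / (1 - b2^s$t)
        list(delta = lr * mh / (sqrt(vh) + eps), state = s)
      }
    )
  } else {
    alpha <- 0.9; eps <- 1e-6
    list(
      init = function(n) list(hist = numeric(n), t = 0L),
      step = function(g, s) {
        s$t <- s$t + 1L
        s$hist <- if (s$t == 1L) g^2 else alpha * s$hist + (1 - alpha) * g^2
        list(delta = lr * g / (eps + sqrt(s$hist)), state = s)
      }
    )
  }
}

#' Dropout configuration
#' @param p per-unit drop probability in [0, 1).
#' @param n_samples number of stochastic forward passes at prediction time.
#' @param seed seed for prediction-time mask sampling.
#' @export
dropout_config <- function(p = 0.2, n_samples = 50L, seed = 1L) {
  stopifnot(p >= 0, p < 1, n_samples >= 1)
  structure(list(p = p, n_samples = as.integer(n_samples),
                 seed = as.integer(seed)), class = "dropout_config")
}

# shared gradient-ascent loop; mask_fn() is called once per step
.train_loop <- function(model, data, prior, steps, lr, optimizer, seed,
                        init, batch_size, mask_fn) {
  set.seed(seed)
  theta <- if (is.null(init)) model$init(seed) else init
  set.seed(seed + 1L)  # decouple the loop RNG stream from initialization
  opt <- make_optimizer(optimizer, lr)
  st <- opt$init(length(theta))
  trace <- numeric(steps)
  n_obs <- if (!is.null(data$y)) length(data$y) else NULL
  for (i in seq_len(steps)) {
    idx <- NULL
    if (!is.null(batch_size) && !is.null(n_obs) && batch_size < n_obs)
      idx <- sample.int(n_obs, batch_size)
    g <- model$grad(theta, data, prior, masks = mask_fn(), idx = idx)
    if (!is.finite(g$lp) || any(!is.finite(g$grad)))
      stop(sprintf("training diverged (non-finite objective) at step %d", i))
    sp <- opt$step(g$grad, st)
    st <- sp$state
    theta <- theta + sp$delta
    trace[i] <- g$lp
  }
  list(theta = theta, trace = trace)
}

#' Maximum-a-posteriori (frequentist) training
#'
#' Gradient ascent on the log posterior without dropout: the N = 1 /
#' maximum-likelihood special case of the Bayesian machinery.
#'
#' @param model a `uq_model`.
#' @param data model data object.
#' @param prior a `uq_prior`.
#' @param steps,lr,optimizer optimization budget, step size and update rule
#'   ("adam" default; "adagrad" matches the SVGD update for trajectory
#'   comparisons).
#' @param seed RNG seed (initialization and mini-batch draws).
#' @param init optional initial flat parameter vector.
#' @param batch_size optional mini-batch size; mini-batch gradients are
#'   rescaled to full-dataset scale so the target distribution is the full
#'   posterior.
#' @return a `map_fit` with `theta` and the log-posterior `trace`.
#' @export
train_map <- function(model, data, prior = gaussian_prior(1), steps = 200L,
                      lr = 1e-3, optimizer = "adam", seed = 1L, init = NULL,
                      batch_size = NULL) {
  out <- .train_loop(model, data, prior, steps, lr, optimizer, seed, init,
                     batch_size, function() NULL)
  structure(list(model = model, theta = out$theta, trace = out$trace,
                 inference = "map"), class = c("map_fit", "uq_fit"))
}

#' Training with Monte-Carlo dropout
#'
#' As [train_map()], but an independent Bernoulli per-unit mask is sampled
#' at every step (approximately fitting the Bernoulli-mask variational
#' family to the posterior). With `p = 0` the trajectory is identical to
#' [train_map()] under the same seed.
#'
#' @inheritParams train_map
#' @param dropout a [dropout_config()].
#' @return a `dropout_fit` carrying the dropout configuration for
#'   prediction-time mask sampling.
#' @export
train_dropout <- function(model, data, prior = gaussian_prior(1),
                          dropout = dropout_config(), steps = 200L,
                          lr = 1e-3, optimizer = "adam", seed = 1L,
                          init = NULL, batch_size = NULL) {
  mask_fn <- if (dropout$p > 0) function() model$sample_masks(dropout$p)
             else function() NULL
  out <- .train_loop(model, data, prior, steps, lr, optimizer, seed, init,
                     batch_size, mask_fn)
  structure(list(model = model, theta = out$theta, trace = out$trace,
                 dropout = dropout, inference = "dropout"),
            class = c("dropout_fit", "uq_fit"))
}

# -- uncertainty decomposition ----------------------------------------------

#' Decompose stochastic predictions into epistemic and aleatoric variance
#'
#' Given N predictive samples per input (rows of `means`: one stochastic
#' pass or particle; matching per-pass aleatoric variances in `vars`),
#' returns the predictive mean, the variance of the N means (epistemic),
#' the mean of the N variances (aleatoric), and their sum (total). The
#' additivity `var_total = var_epistemic + var_aleatoric` holds exactly by
#' construction.
#'
#' @param means `N x n` matrix of per-pass predictive means.
#' @param vars `N x n` matrix of per-pass aleatoric variances.
#' @return an `uncertain_prediction` data frame with attribute `"samples"`
#'   holding the raw inputs.
#' @export
decompose_samples <- function(means, vars) {
  means <- rbind(means); vars <- rbind(vars)
  stopifnot(all(dim(means) == dim(vars)))
  N <- nrow(means)
  dimnames(means) <- dimnames(vars) <- NULL
  # centered estimator: anchoring on the first sample keeps the variance
  # exactly zero when all passes coincide (p = 0 or identical particles)
  m1 <- means[1, ]
  dev1 <- means - rep(m1, each = N)
  mu <- m1 + colSums(dev1) / N
  var_epi <- colSums((means - rep(mu, each = N))^2) / N
  var_ale <- colSums(vars) / N
  out <- data.frame(mean = mu, var_epistemic = var_epi,
                    var_aleatoric = var_ale,
                    var_total = var_epi + var_ale)
  attr(out, "samples") <- list(means = means, vars = vars)
  class(out) <- c("uncertain_prediction", "data.frame")
  out
}

#' Predict with Monte-Carlo dropout
#'
#' Runs `n_samples` stochastic forward passes, each with a fresh per-unit
#' Bernoulli mask, and decomposes the predictive variance into epistemic
#' (spread of the pass means) and aleatoric (mean predicted noise
#' variance) parts.
#'
#' @param fit a `dropout_fit` (or `map_fit`, giving p = 0: purely
#'   aleatoric uncertainty).
#' @param newdata data object or `graph_batch` for the fit's model.
#' @param n_samples,seed override the fit's dropout configuration.
#' @return an `uncertain_prediction`.
#' @export
predict_dropout <- function(fit, newdata, n_samples = NULL, seed = NULL) {
  dcfg <- fit$dropout
  if (is.null(dcfg)) dcfg <- dropout_config(p = 0)
  if (is.null(n_samples)) n_samples <- dcfg$n_samples
  if (is.null(seed)) seed <- dcfg$seed
  if (n_samples < 2 && dcfg$p > 0)
    warning("n_samples < 2: epistemic variance is 0 by construction")
  set.seed(seed)
  means <- NULL; vars <- NULL
  for (s in seq_len(n_samples)) {
    masks <- if (dcfg$p > 0) fit$model$sample_masks(dcfg$p) else NULL
    out <- fit$model$predict(fit$theta, newdata, masks)
    means <- rbind(means, out[, "mean"])
    vars <- rbind(vars, exp(out[, "log_var"]))
  }
  decompose_samples(means, vars)
}

#' @export
print.uq_fit <- function(x, ...) {
  cat(sprintf("%s fit of a %s model: %d parameters, %d steps, final log posterior %.4g\n",
              x$inference, x$model$kind, length(x$theta),
              length(x$trace), x$trace[length(x$trace)]))
  invisible(x)
}
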