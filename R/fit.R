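# High-level fitting surface: choose a model family (fully supervised
# graph network, or semi-supervised embedding + supervised head) and an
# inference engine (MAP, MC-dropout, SVGD), get back one object that
# predicts with decomposed uncertainty.

#' Fit a Bayesian molecular property model
#'
#' @param dataset a labelled `mol_dataset` (rows with NA targets are used
#'   as unlabelled structures by the semi-supervised stage and ignored by
#'   supervised training).
#' @param config an [mpnn_config()].
#' @param model_kind "supervised" (all weights learned from labels) or
#'   "semisupervised" (message-passing weights learned from structures
#'   alone, then frozen; only readout and head see labels).
#' @param inference "map", "dropout" or "svgd".
#' @param prior a `uq_prior`.
#' @param steps,lr supervised training budget and step size.
#' @param var_warmup fraction of `steps` spent fitting the predictive mean
#'   with the noise variance held at 1 before the heteroscedastic head is
#'   unlocked (map/dropout inference). Stabilizes the variance head: while
#'   the mean model is still poor, its residuals would otherwise swamp the
#'   noise signal. Set 0 to disable.
#' @param dropout a [dropout_config()] (dropout inference).
#' @param svgd an [svgd_config()] (SVGD inference); `n_particles` sets the
#'   ensemble size.
#' @param semisup_epochs,semisup_lr embedding stage budget
#'   (semisupervised only).
#' @param unlabelled optional extra structures (list of `mol_graph` or
#'   `mol_dataset`) for the embedding stage.
#' @param semisup_model optionally reuse an existing trained
#'   [train_semisupervised()] model.
#' @param seed master RNG seed.
#' @return a `molbayes_fit`; use [predict.molbayes_fit()] for uncertainty-
#'   decomposed predictions.
#' @export
molbayes_fit <- function(dataset, config = mpnn_config(),
                         model_kind = c("supervised", "semisupervised"),
                         inference = c("dropout", "map", "svgd"),
                         prior = gaussian_prior(1),
                         steps = 300L, lr = 0.02, var_warmup = 0.5,
                         dropout = dropout_config(),
                         svgd = svgd_config(), n_particles = 50L,
                         semisup_epochs = 30L, semisup_lr = 1e-2,
                         unlabelled = NULL, semisup_model = NULL,
                         seed = 1L) {
  model_kind <- match.arg(model_kind)
  inference <- match.arg(inference)
  stopifnot(inherits(dataset, "mol_dataset"))
  labelled <- !is.na(dataset$y)
  if (!any(labelled)) stop("no labelled molecules to train on")

  ss <- semisup_model
  if (model_kind == "semisupervised") {
    if (is.null(ss)) {
      extra <- if (is.null(unlabelled)) list()
               else if (inherits(unlabelled, "mol_dataset"))
                 unlabelled$graphs else unlabelled
      ss <- train_semisupervised(c(dataset$graphs, extra), config,
                                 epochs = semisup_epochs, lr = semisup_lr,
                                 seed = seed)
    }
    model <- semisup_head_model(ss)
    model_fix <- semisup_head_model(ss, fixed_var = 1)
    data <- semisup_data(ss, dataset$graphs[labelled],
                         dataset$y[labelled])
  } else {
    model <- mpnn_model(config)
    model_fix <- mpnn_model(config, fixed_var = 1)
    data <- mpnn_data(dataset$graphs[labelled], dataset$y[labelled])
  }

  n_warm <- if (inference == "svgd") 0L
            else as.integer(round(var_warmup * steps))
  init <- NULL
  if (n_warm > 0) {
    warm <- if (inference == "dropout")
      train_dropout(model_fix, data, prior, dropout = dropout,
                    steps = n_warm, lr = lr, seed = seed)
    else
      train_map(model_fix, data, prior, steps = n_warm, lr = lr,
                seed = seed)
    init <- warm$theta
  }
  n_main <- max(1L, steps - n_warm)

  fit <- switch(inference,
    map = train_map(model, data, prior, steps = n_main, lr = lr,
                    seed = seed, init = init),
    dropout = train_dropout(model, data, prior, dropout = dropout,
                            steps = n_main, lr = lr, seed = seed,
                            init = init),
    svgd = {
      cfg <- svgd
      cfg$steps <- as.integer(steps)
      cfg$seed <- as.integer(seed)
      train_svgd(model, data, prior, n_particles = n_particles,
                 config = cfg)
    })

  structure(list(model_kind = model_kind, inference = inference,
                 fit = fit, model = model, semisup = ss, config = config,
                 dropout = dropout, seed = seed),
            class = "molbayes_fit")
}

# normalize molecules into the prediction data object the inner model expects
.predict_data <- function(object, newdata) {
  graphs <- if (inherits(newdata, "mol_dataset")) newdata$graphs
            else if (inherits(newdata, "mol_graph")) list(newdata)
            else newdata
  if (object$model_kind == "semisupervised")
    semisup_data(object$semisup, graphs, y = NULL)
  else list(batch = graph_batch(graphs))
}

#' Predict molecular properties with decomposed uncertainty
#'
#' @param object a `molbayes_fit`.
#' @param newdata molecules: `mol_dataset`, list of `mol_graph`, or a
#'   single graph.
#' @param n_samples stochastic passes (dropout inference only).
#' @param seed seed for prediction-time dropout masks.
#' @param ... unused.
#' @return an `uncertain_prediction` with columns `mean`,
#'   `var_epistemic`, `var_aleatoric`, `var_total`.
#' @export
predict.molbayes_fit <- function(object, newdata, n_samples = NULL,
                                 seed = NULL, ...) {
  pd <- .predict_data(object, newdata)
  if (object$inference == "svgd")
    predict_ensemble(object$fit, pd)
  else if (object$inference == "dropout")
    predict_dropout(object$fit, pd, n_samples = n_samples, seed = seed)
  else
    predict_dropout(object$fit, pd, n_samples = 1L, seed = 1L)
}

#' @rdname bias_probe
#' @details For a fitted model the call is
#'   `bias_probe(fit, in_domain_molecules, out_domain_molecules)`.
#' @export
bias_probe.molbayes_fit <- function(x, out, ...) {
  out_domain <- ..1
  bias_probe(predict(x, out), predict(x, out_domain))
}

#' @export
print.molbayes_fit <- function(x, ...) {
  cat(sprintf("molbayes_fit: %s model, %s inference\n",
              x$model_kind, x$inference))
  print(x$fit)
  invisible(x)
}

#' Read a model/inference configuration file
#'
#' Reads a YAML or JSON file describing a fitting configuration and
#' returns the corresponding argument list for [molbayes_fit()].
#' Recognized fields: `model.kind` ("supervised" | "semisupervised"),
#' `inference.kind` ("map" | "dropout" | "svgd"), `network`
#' (`n_steps`, `n_hidden`, `fp_length`, `head_units`), `training`
#' (`steps`, `lr`, `seed`, `var_warmup`), `prior` (`scale`), `dropout`
#' (`p`, `n_samples`), `svgd` (`eta`, `n_particles`, `bandwidth_rule`),
#' `semisup` (`epochs`, `lr`).
#'
#' @param path file ending in .yaml/.yml or .json.
#' @return named list of [molbayes_fit()] arguments.
#' @export
read_model_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  net <- cfg$network
  args <- list(
    config = mpnn_config(
      n_steps = net$n_steps %||% 3L,
      n_hidden = net$n_hidden %||% 128L,
      fp_length = net$fp_length %||% 2L * (net$n_hidden %||% 128L),
      head_units = net$head_units %||% 128L),
    model_kind = cfg$model$kind %||% "supervised",
    inference = cfg$inference$kind %||% "dropout")
  tr <- cfg$training
  if (!is.null(tr$steps)) args$steps <- as.integer(tr$steps)
  if (!is.null(tr$lr)) args$lr <- tr$lr
  if (!is.null(tr$seed)) args$seed <- as.integer(tr$seed)
  if (!is.null(tr$var_warmup)) args$var_warmup <- tr$var_warmup
  if (!is.null(cfg$prior$scale)) args$prior <- gaussian_prior(cfg$prior$scale)
  if (!is.null(cfg$dropout))
    args$dropout <- dropout_config(p = cfg$dropout$p %||% 0.2,
                                   n_samples = cfg$dropout$n_samples %||% 50L)
  if (!is.null(cfg$svgd)) {
    args$svgd <- svgd_config(
      eta = cfg$svgd$eta %||% 1e-2,
      bandwidth_rule = cfg$svgd$bandwidth_rule %||% "median")
    if (!is.null(cfg$svgd$n_particles))
      args$n_particles <- as.integer(cfg$svgd$n_particles)
  }
  if (!is.null(cfg$semisup)) {
    if (!is.null(cfg$semisup$epochs))
      args$semisup_epochs <- as.integer(cfg$semisup$epochs)
    if (!is.null(cfg$semisup$lr)) args$semisup_lr <- cfg$semisup$lr
  }
  args
}

`%||%` <- function(a, b) if (is.null(a)) b else a
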