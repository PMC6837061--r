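# Text (JSON) checkpoints for parameters, ensembles and semi-supervised
# models. Shape metadata is stored alongside the values and verified on
# load, so restoring into a mismatched architecture fails loudly. Numeric
# payloads are serialized as %.17g strings: enough digits to round-trip
# IEEE doubles exactly, so a reloaded model predicts bit-identically.

.num_out <- function(x) sprintf("%.17g", as.numeric(x))
.num_in <- function(x) as.numeric(x)

.cfg_to_list <- function(config)
  list(n_steps = config$n_steps, n_hidden = config$n_hidden,
       fp_length = config$fp_length, head_units = config$head_units,
       elements = config$spec$elements)

.cfg_from_list <- function(l)
  mpnn_config(l$n_steps, l$n_hidden, l$fp_length, l$head_units,
              spec = atom_feature_spec(unlist(l$elements)))

#' Save a model object to a JSON checkpoint
#'
#' Supports `mpnn_params`, `semisup_model` and `particle_ensemble`
#' objects; the model kind, the architecture and (for ensembles) the seed
#' are stored so loading restores bit-identical predictions.
#'
#' @param object the object to save; `path` output file.
#' @export
save_checkpoint <- function(object, path) {
  obj <- if (inherits(object, "mpnn_params")) {
    list(kind = "mpnn_params", config = .cfg_to_list(object$config),
         theta = .num_out(flatten_params(object)))
  } else if (inherits(object, "semisup_model")) {
    list(kind = "semisup_model", config = .cfg_to_list(object$config),
         embed = .num_out(flatten_params(object$embed_params)),
         u = .num_out(object$u), n_mols = nrow(object$u),
         C = .num_out(object$C), P = .num_out(object$P),
         n_negative = object$n_negative, seed = object$seed)
  } else if (inherits(object, "particle_ensemble")) {
    if (!object$model$kind %in% c("mpnn", "semisup_head"))
      stop("only graph-network ensembles can be checkpointed")
    list(kind = "particle_ensemble", model_kind = object$model$kind,
         config = .cfg_to_list(object$model$config),
         n_particles = object$n_particles,
         particles = .num_out(object$particles),
         seed = object$config$seed)
  } else stop("unsupported object for checkpointing")
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a JSON checkpoint
#'
#' @param path checkpoint file.
#' @return the restored object; `mpnn_params` checkpoints come back as
#'   parameter objects, `semisup_model` as models, `particle_ensemble` as
#'   a list with the particle matrix and architecture (re-attach a model
#'   with [mpnn_model()] / [semisup_head_model()] to predict).
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  config <- .cfg_from_list(obj$config)
  if (obj$kind == "mpnn_params") {
    template <- init_mpnn_params(config, seed = 0L)
    theta <- .num_in(obj$theta)
    if (length(theta) != n_params(template))
      stop("checkpoint parameter count does not match its architecture")
    unflatten_params(theta, template)
  } else if (obj$kind == "semisup_model") {
    template <- init_mpnn_params(config, seed = 0L)
    nh <- config$n_hidden
    structure(list(
      embed_params = unflatten_params(.num_in(obj$embed), template),
      u = matrix(.num_in(obj$u), obj$n_mols, nh),
      C = matrix(.num_in(obj$C), nh, nh),
      P = matrix(.num_in(obj$P), nh, nh),
      config = config, n_negative = obj$n_negative,
      trace = numeric(0), seed = obj$seed), class = "semisup_model")
  } else if (obj$kind == "particle_ensemble") {
    list(kind = "particle_ensemble", model_kind = obj$model_kind,
         config = config,
         particles = matrix(.num_in(obj$particles),
                            nrow = obj$n_particles),
         seed = obj$seed)
  } else stop("unknown checkpoint kind: ", obj$kind)
}
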