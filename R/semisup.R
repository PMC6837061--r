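# Semi-supervised atom-environment embedding.
#
# The message-passing weights are learned from unlabelled structures alone
# by making each atom's final hidden state predictable from its context: a
# per-molecule identifier vector u_n plus a projection of the mean of its
# neighbours' hidden states. Following the paragraph-vector construction,
# the objective is a negative-sampling log likelihood:
#   for atom v of molecule n, with target code z_v = P h_v^T and context
#   c_v = u_n + C mean_{w in N(v)} h_w^T,
#   l(v) = log s(c_v . z_v) + sum_{k=1}^{K} log s(-c_v . z_{g_k}),
# where s is the logistic function and the g_k are atoms drawn uniformly
# from the batch. Maximizing sum_v l(v) pulls hidden states of recurring
# atomic environments together, so similar molecules get similar
# descriptors without any property labels. The identifiers u_n are
# training-only nuisance parameters; embedding an unseen molecule needs no
# identifier. After this stage the message-passing weights are frozen and
# only the readout matrices W_t and the output head are trained on labels.

#' Train the semi-supervised molecular embedding
#'
#' Stochastic gradient ascent (Adam) on the negative-sampling objective.
#' One step per epoch processes the full structure set with freshly drawn
#' negatives. Deterministic under `seed`.
#'
#' @param molecules a `mol_dataset` or list of `mol_graph` (labels, if any,
#'   are ignored: this stage is unsupervised).
#' @param config an [mpnn_config()].
#' @param epochs number of gradient steps.
#' @param lr Adam step size.
#' @param n_negative negative samples per atom.
#' @param seed RNG seed.
#' @return a `semisup_model` with fields `embed_params` (the learned
#'   message-passing weights), `u` (per-molecule identifiers), `C`, `P`
#'   (context/target projections) and the objective `trace`.
#' @export
train_semisupervised <- function(molecules, config = mpnn_config(),
                                 epochs = 50L, lr = 1e-2, n_negative = 5L,
                                 seed = 1L) {
  graphs <- if (inherits(molecules, "mol_dataset")) molecules$graphs
            else molecules
  stopifnot(length(graphs) >= 2)
  batch <- graph_batch(graphs)
  nh <- config$n_hidden
  n_mols <- batch$n_mols

  set.seed(seed)
  params <- init_mpnn_params(config, seed)
  u <- matrix(stats::rnorm(n_mols * nh, sd = 0.1), n_mols, nh)
  C <- matrix(stats::rnorm(nh * nh, sd = 1 / sqrt(nh)), nh, nh)
  P <- matrix(stats::rnorm(nh * nh, sd = 1 / sqrt(nh)), nh, nh)

  pack <- function(params, u, C, P)
    c(flatten_params(params, "H"), as.numeric(u), as.numeric(C),
      as.numeric(P))
  n_embed <- n_params(params, "H")

  set.seed(seed + 1L)
  opt <- make_optimizer("adam", lr)
  theta <- pack(params, u, C, P)
  st <- opt$init(length(theta))
  trace <- numeric(epochs)

  for (e in seq_len(epochs)) {
    og <- .semisup_obj_grad(params, u, C, P, batch, n_negative)
    if (!is.finite(og$obj)) stop("semi-supervised objective diverged")
    g <- c(flatten_params(og$gH_shape, "H"), as.numeric(og$gu),
           as.numeric(og$gC), as.numeric(og$gP))
    sp <- opt$step(g, st)
    st <- sp$state
    theta <- theta + sp$delta
    params <- unflatten_params(theta[seq_len(n_embed)], params, "H")
    pos <- n_embed
    u <- matrix(theta[pos + seq_len(n_mols * nh)], n_mols, nh)
    pos <- pos + n_mols * nh
    C <- matrix(theta[pos + seq_len(nh * nh)], nh, nh)
    pos <- pos + nh * nh
    P <- matrix(theta[pos + seq_len(nh * nh)], nh, nh)
    trace[e] <- og$obj
  }

  structure(list(embed_params = params, u = u, C = C, P = P,
                 config = config, n_negative = as.integer(n_negative),
                 trace = trace, seed = seed),
            class = "semisup_model")
}

# Objective and gradients for one pass; negatives are drawn from the
# current RNG stream as matrix(sample(n_atoms, n_atoms*K, replace = TRUE),
# n_atoms, K) -- this draw order is part of the contract so the objective
# can be reproduced externally.
.semisup_obj_grad <- function(params, u, C, P, batch, n_negative,
                              grad = TRUE) {
  T <- params$config$n_steps
  n <- batch$n_atoms
  nh <- params$config$n_hidden
  mi <- batch$mol_index
  K <- n_negative

  mp <- .message_pass(params, batch, keep_cache = grad)
  HT <- mp$h[[T + 1]]

  deg <- pmax(batch$degree, 1)
  Q <- as.matrix(batch$A %*% HT) / deg       # mean of neighbour states
  Ctx <- u[mi, , drop = FALSE] + Q %*% t(C)
  Zt <- HT %*% t(P)

  neg <- matrix(sample.int(n, n * K, replace = TRUE), n, K)

  s_pos <- rowSums(Ctx * Zt)
  obj <- sum(stats::plogis(s_pos, log.p = TRUE))
  sig_neg <- matrix(0, n, K)
  for (k in seq_len(K)) {
    s_k <- rowSums(Ctx * Zt[neg[, k], , drop = FALSE])
    obj <- obj + sum(stats::plogis(-s_k, log.p = TRUE))
    sig_neg[, k] <- .sigmoid(s_k)
  }
  if (!grad) return(list(obj = obj, neg = neg))

  w_pos <- 1 - .sigmoid(s_pos)
  dCtx <- w_pos * Zt
  dZt <- w_pos * Ctx
  for (k in seq_len(K)) {
    dCtx <- dCtx - sig_neg[, k] * Zt[neg[, k], , drop = FALSE]
    contrib <- rowsum(-sig_neg[, k] * Ctx, neg[, k])
    rows <- as.integer(rownames(contrib))
    dZt[rows, ] <- dZt[rows, , drop = FALSE] + contrib
  }

  gu <- rowsum(dCtx, mi)
  gC <- t(dCtx) %*% Q
  gP <- t(dZt) %*% HT
  dQ <- dCtx %*% C
  dHT <- dZt %*% P + as.matrix(batch$A %*% (dQ / deg))

  d_h <- vector("list", T + 1)
  d_h[[T + 1]] <- dHT
  gH <- .message_backward(params, batch, mp, d_h)
  gH_shape <- params
  gH_shape$H <- gH

  list(obj = obj, gu = gu, gC = gC, gP = gP, gH_shape = gH_shape,
       neg = neg)
}

#' Evaluate the semi-supervised objective
#'
#' Computes the negative-sampling log likelihood of a set of molecules
#' under a trained (or freshly initialized) model, drawing `n_negative`
#' negatives per atom from the RNG stream after `set.seed(seed)` in the
#' documented order (a single `sample.int(n_atoms, n_atoms * K,
#' replace = TRUE)` call filled column-wise).
#'
#' @param molecules `mol_dataset` or list of `mol_graph`.
#' @param model a `semisup_model`; molecules must be among those the model
#'   was trained on (their identifiers are looked up by position via
#'   `mol_ids`).
#' @param mol_ids identifier row for each molecule (default: positions
#'   1..n, matching training order).
#' @param seed seed for the negative draws.
#' @return scalar log likelihood (finite for all inputs).
#' @export
semisup_objective <- function(molecules, model,
                              mol_ids = NULL, seed = 1L) {
  graphs <- if (inherits(molecules, "mol_dataset")) molecules$graphs
            else molecules
  stopifnot(length(graphs) >= 1)
  if (is.null(mol_ids)) mol_ids <- seq_along(graphs)
  if (any(mol_ids > nrow(model$u)))
    stop("molecule not registered in the semi-supervised model")
  batch <- graph_batch(graphs)
  u_local <- model$u[mol_ids, , drop = FALSE]
  set.seed(seed)
  og <- .semisup_obj_grad(model$embed_params, u_local, model$C, model$P,
                          batch, model$n_negative, grad = FALSE)
  og$obj
}

#' Embed molecules with frozen semi-supervised weights
#'
#' Computes hidden states for (possibly unseen) molecules with the frozen
#' message-passing weights; no molecule identifier is needed at inference.
#'
#' @param graphs a `mol_graph`, list of them, or `mol_dataset`.
#' @param model a `semisup_model`.
#' @return list with the packed `batch` and `h`, the per-step hidden
#'   states (`h[[t+1]]` is step t; step 0 is the raw atom features).
#' @export
embed_molecule <- function(graphs, model) {
  if (inherits(graphs, "mol_graph")) graphs <- list(graphs)
  if (inherits(graphs, "mol_dataset")) graphs <- graphs$graphs
  batch <- graph_batch(graphs)
  if (ncol(batch$X) != model$config$fa)
    stop("atom feature scheme does not match the embedding model")
  mp <- .message_pass(model$embed_params, batch)
  list(batch = batch, h = mp$h)
}

#' Supervised head over frozen semi-supervised embeddings
#'
#' Returns a `uq_model` whose trainable parameters are only the readout
#' matrices W_t and the output head; hidden states come from the frozen
#' embedding and are precomputed once per dataset by [semisup_data()].
#' Dropout applies only to the layers on top of the hidden states.
#'
#' @param ss_model a `semisup_model`.
#' @param fixed_var optional constant noise variance (see [mpnn_model()]).
#' @export
semisup_head_model <- function(ss_model, fixed_var = NULL) {
  config <- ss_model$config
  template <- ss_model$embed_params
  trainable <- c("W", "head")
  force(fixed_var)
  as_params <- function(theta) unflatten_params(theta, template, trainable)

  structure(list(
    kind = "semisup_head",
    config = config,
    template = template,
    trainable = trainable,
    dropout_scope = "head",
    n_par = n_params(template, trainable),
    init = function(seed) flatten_params(init_mpnn_params(config, seed),
                                         trainable),
    sample_masks = function(p) sample_dropout_masks(config, p, "head"),
    objective = function(theta, data, prior) {
      params <- as_params(theta)
      ro <- .readout_forward(params, data$h, data$batch$mol_index,
                             data$batch$n_mols, hb = data$hb)
      .hetero_ll(data$y, ro$mean, ro$log_var, fixed_var)$ll +
        prior$log_density(theta)
    },
    grad = function(theta, data, prior, masks = NULL, idx = NULL,
                    weight = 1) {
      h <- data$h; hb <- data$hb; y <- data$y
      mol_index <- data$batch$mol_index
      n_mols <- data$batch$n_mols
      if (!is.null(idx)) {
        rows <- which(mol_index %in% idx)
        h <- lapply(h, function(m) m[rows, , drop = FALSE])
        hb <- if (!is.null(hb))
          lapply(hb, function(m) m[rows, , drop = FALSE])
        mol_index <- match(mol_index[rows], idx)
        y <- y[idx]
        n_mols <- length(idx)
        weight <- weight * length(data$y) / length(idx)
      }
      params <- as_params(theta)
      ro <- .readout_forward(params, h, mol_index, n_mols, masks,
                             keep_cache = TRUE, hb = hb)
      hl <- .hetero_ll(y, ro$mean, ro$log_var, fixed_var)
      d_out <- weight * cbind(hl$d_mu, hl$d_lv)
      rb <- .readout_backward(params, h, ro$cache, d_out, mol_index)
      g <- list(W = rb$W, head = rb$head)
      list(lp = weight * hl$ll + prior$log_density(theta),
           grad = flatten_params(g, trainable) + prior$grad(theta))
    },
    predict = function(theta, newdata, masks = NULL) {
      params <- as_params(theta)
      ro <- .readout_forward(params, newdata$h, newdata$batch$mol_index,
                             newdata$batch$n_mols, masks, hb = newdata$hb)
      lv <- if (!is.null(fixed_var)) rep(log(fixed_var), length(ro$mean))
            else ro$log_var
      cbind(mean = ro$mean, log_var = lv)
    },
    as_params = as_params
  ), class = "uq_model")
}

#' Precompute embedding data for the supervised head
#' @param ss_model a `semisup_model`.
#' @param graphs molecules (list or `mol_dataset`).
#' @param y labels (default: taken from the dataset; NA rows dropped).
#' @export
semisup_data <- function(ss_model, graphs, y = NULL) {
  if (inherits(graphs, "mol_dataset")) {
    if (is.null(y)) y <- graphs$y
    graphs <- graphs$graphs
  }
  if (!is.null(y)) {
    keep <- !is.na(y)
    graphs <- graphs[keep]; y <- y[keep]
  }
  emb <- embed_molecule(graphs, ss_model)
  list(batch = emb$batch, h = emb$h,
       hb = lapply(emb$h, function(m) cbind(m, 1)), y = y)
}

#' @export
print.semisup_model <- function(x, ...) {
  cat(sprintf(
    "semisup_model: %d molecules embedded, n_h = %d, final objective %.4g\n",
    nrow(x$u), x$config$n_hidden, x$trace[length(x$trace)]))
  invisible(x)
}
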