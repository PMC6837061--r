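# Graph-convolutional fingerprint network.
#
# Message passing (steps t = 1..T):
#   m_v^t = sum_{w in N(v)} [ h_w^{t-1} ; e_vw ]
#   h_v^t = sigmoid( H_{deg(v)}^t  [ h_v^{t-1} ; m_v^t ; 1 ] )
# with a learned matrix H_N^t per step and per vertex degree N (0..5).
# Readout sums a per-step softmax over atoms into a fingerprint
#   f = sum_t sum_v softmax( W_t [ h_v^t ; 1 ] )
# and a two-hidden-layer relu head maps f to (predicted mean,
# log aleatoric variance). Each softmax summand is a probability vector,
# so the fingerprint is invariant to atom relabelling.

#' Network configuration
#'
#' Defaults follow the reference architecture: `T = 3` message-passing
#' steps, `n_h = 128` hidden units per step, fingerprint length
#' `L = 2 * n_h`, and a head with two hidden layers of 128 rectified-linear
#' units ending in two outputs (predictive mean and log aleatoric
#' variance). The bundled synthetic studies use much smaller widths; every
#' dimension is overridable.
#'
#' @param n_steps number of message-passing steps T.
#' @param n_hidden hidden-state width n_h.
#' @param fp_length fingerprint length L (default `2 * n_hidden`).
#' @param head_units width of the two head hidden layers.
#' @param spec an [atom_feature_spec()].
#' @export
mpnn_config <- function(n_steps = 3L, n_hidden = 128L,
                        fp_length = 2L * n_hidden, head_units = 128L,
                        spec = atom_feature_spec()) {
  stopifnot(n_steps >= 1, n_hidden >= 1, fp_length >= 1, head_units >= 1)
  structure(list(
    n_steps = as.integer(n_steps), n_hidden = as.integer(n_hidden),
    fp_length = as.integer(fp_length), head_units = as.integer(head_units),
    fa = spec$n_atom_features, fb = spec$n_bond_features,
    max_degree = 5L, spec = spec
  ), class = "mpnn_config")
}

# hidden-state width at step t (t = 0 is the raw atom features)
.h_width <- function(config, t) if (t == 0) config$fa else config$n_hidden

# input width of H matrices at step t: self-state + message (neighbor state
# + bond features) + bias
.z_width <- function(config, t) {
  w <- .h_width(config, t - 1)
  w + w + config$fb + 1L
}

.rnorm_mat <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nc)), nr, nc)
}

#' Initialize network parameters
#'
#' Centered Gaussian entries with scale 1/sqrt(fan-in), deterministic under
#' `seed`.
#'
#' @param config an [mpnn_config()].
#' @param seed integer seed.
#' @return an `mpnn_params` object.
#' @export
init_mpnn_params <- function(config, seed = 1L) {
  set.seed(seed)
  T <- config$n_steps; nh <- config$n_hidden; L <- config$fp_length
  u <- config$head_units
  H <- lapply(seq_len(T), function(t) {
    zw <- .z_width(config, t)
    lapply(0:config$max_degree, function(d) .rnorm_mat(nh, zw))
  })
  W <- lapply(0:T, function(t) .rnorm_mat(L, .h_width(config, t) + 1L))
  head <- list(W1 = .rnorm_mat(u, L + 1L),
               W2 = .rnorm_mat(u, u + 1L),
               W3 = .rnorm_mat(2L, u + 1L))
  structure(list(H = H, W = W, head = head, config = config),
            class = "mpnn_params")
}

.sigmoid <- function(x) 1 / (1 + exp(pmin(pmax(-x, -40), 40)))

.softmax_rows <- function(S) {
  mx <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - mx)
  E / rowSums(E)
}

.mask_cols <- function(M, mask) {
  if (is.null(mask)) return(M)
  z <- which(mask == 0)
  if (length(z)) M[, z] <- 0
  M
}

# -- dropout masks -----------------------------------------------------------
# A mask is one Bernoulli(1-p) 0/1 value per *unit* (hidden channel), shared
# across atoms/molecules within one pass, realizing one sample of the
# Bernoulli-mask variational family. scope "all" masks message-passing
# hidden units, the fingerprint and the head; scope "head" masks only the
# layers on top of the (frozen) hidden states: fingerprint + head.

#' Sample a per-unit dropout mask set
#' @param config an [mpnn_config()].
#' @param p drop probability in [0, 1).
#' @param scope "all" (every supervised-trained unit) or "head" (only the
#'   layers above the hidden states, for the semi-supervised model).
#' @return list of 0/1 vectors, or `NULL` when `p == 0`.
#' @export
sample_dropout_masks <- function(config, p, scope = c("all", "head")) {
  scope <- match.arg(scope)
  stopifnot(p >= 0, p < 1)
  if (p <= 0) return(NULL)
  draw <- function(n) stats::rbinom(n, 1L, 1 - p)
  list(
    h = if (scope == "all")
      lapply(seq_len(config$n_steps), function(t) draw(config$n_hidden))
    else NULL,
    fp = draw(config$fp_length),
    head1 = draw(config$head_units),
    head2 = draw(config$head_units)
  )
}

# -- message passing ---------------------------------------------------------

# Run the message-passing recursion over a packed batch.
# Returns post-mask states h (list over t = 0..T), pre-mask states h_pre,
# and (if keep_cache) the per-step H-matrix inputs Z.
.message_pass <- function(params, batch, masks = NULL, keep_cache = FALSE) {
  config <- params$config
  T <- config$n_steps; nh <- config$n_hidden
  n <- batch$n_atoms
  if (ncol(batch$X) != config$fa)
    stop("atom feature width does not match the network configuration")
  h <- vector("list", T + 1)
  h_pre <- vector("list", T + 1)
  Z <- if (keep_cache) vector("list", T) else NULL
  h[[1]] <- h_pre[[1]] <- batch$X
  for (t in seq_len(T)) {
    hp <- h[[t]]
    Mh <- as.matrix(batch$A %*% hp)
    Zt <- cbind(hp, Mh, batch$Esum, 1)
    ht <- matrix(0, n, nh)
    for (d in 0:config$max_degree) {
      rows <- batch$deg_groups[[d + 1]]
      if (!length(rows)) next
      ht[rows, ] <- .sigmoid(tcrossprod(Zt[rows, , drop = FALSE],
                                        params$H[[t]][[d + 1]]))
    }
    h_pre[[t + 1]] <- ht
    if (!is.null(masks) && !is.null(masks$h))
      ht <- .mask_cols(ht, masks$h[[t]])
    h[[t + 1]] <- ht
    if (keep_cache) Z[[t]] <- Zt
  }
  list(h = h, h_pre = h_pre, Z = Z)
}

# Backpropagate d_h (list of gradients wrt post-mask h^t, t = 0..T; entries
# may be NULL) through the message-passing recursion.
.message_backward <- function(params, batch, mp, d_h) {
  config <- params$config
  T <- config$n_steps; nh <- config$n_hidden
  n <- batch$n_atoms
  gH <- lapply(seq_len(T), function(t)
    lapply(0:config$max_degree, function(d)
      matrix(0, nh, .z_width(config, t))))
  for (t in T:1) {
    dht <- d_h[[t + 1]]
    if (is.null(dht)) next
    if (!is.null(mp$masks) && !is.null(mp$masks$h))
      dht <- .mask_cols(dht, mp$masks$h[[t]])
    hp <- mp$h_pre[[t + 1]]
    dpre <- dht * hp * (1 - hp)
    zw <- .z_width(config, t)
    wprev <- .h_width(config, t - 1)
    dZ <- matrix(0, n, zw)
    for (d in 0:config$max_degree) {
      rows <- batch$deg_groups[[d + 1]]
      if (!length(rows)) next
      dp <- dpre[rows, , drop = FALSE]
      gH[[t]][[d + 1]] <- gH[[t]][[d + 1]] +
        crossprod(dp, mp$Z[[t]][rows, , drop = FALSE])
      dZ[rows, ] <- dp %*% params$H[[t]][[d + 1]]
    }
    d_prev <- dZ[, seq_len(wprev), drop = FALSE] +
      as.matrix(batch$A %*% dZ[, wprev + seq_len(wprev), drop = FALSE])
    d_h[[t]] <- if (is.null(d_h[[t]])) d_prev else d_h[[t]] + d_prev
  }
  gH
}

# -- readout + head ----------------------------------------------------------

.readout_forward <- function(params, h, mol_index, n_mols, masks = NULL,
                             keep_cache = FALSE, hb = NULL) {
  config <- params$config
  T <- config$n_steps; L <- config$fp_length
  fp <- matrix(0, n_mols, L)
  P <- if (keep_cache) vector("list", T + 1) else NULL
  if (is.null(hb)) hb <- lapply(0:T, function(t) cbind(h[[t + 1]], 1))
  for (t in 0:T) {
    St <- tcrossprod(hb[[t + 1]], params$W[[t + 1]])
    Pt <- .softmax_rows(St)
    if (keep_cache) P[[t + 1]] <- Pt
    fp <- fp + rowsum(Pt, mol_index)
  }
  dimnames(fp) <- NULL
  fp_pre <- fp
  if (!is.null(masks)) fp <- .mask_cols(fp, masks$fp)
  hd <- params$head
  a1_pre <- tcrossprod(cbind(fp, 1), hd$W1)
  a1 <- a1_pre * (a1_pre > 0)
  if (!is.null(masks)) a1 <- .mask_cols(a1, masks$head1)
  a2_pre <- tcrossprod(cbind(a1, 1), hd$W2)
  a2 <- a2_pre * (a2_pre > 0)
  if (!is.null(masks)) a2 <- .mask_cols(a2, masks$head2)
  out <- tcrossprod(cbind(a2, 1), hd$W3)
  res <- list(mean = out[, 1], log_var = out[, 2], fingerprint = fp_pre)
  if (keep_cache)
    res$cache <- list(P = P, hb = hb, fp = fp, a1 = a1, a2 = a2,
                      a1_pre = a1_pre, a2_pre = a2_pre, masks = masks)
  res
}

# Returns gradients for W and head plus the gradient flowing into each
# post-mask hidden-state matrix (list over t = 0..T).
.readout_backward <- function(params, h, cache, d_out, mol_index) {
  config <- params$config
  T <- config$n_steps
  n_mols <- nrow(d_out)
  masks <- cache$masks
  hd <- params$head
  d_a2 <- d_out %*% hd$W3[, seq_len(config$head_units), drop = FALSE]
  gW3 <- crossprod(d_out, cbind(cache$a2, 1))
  if (!is.null(masks)) d_a2 <- .mask_cols(d_a2, masks$head2)
  d_a2 <- d_a2 * (cache$a2_pre > 0)
  gW2 <- crossprod(d_a2, cbind(cache$a1, 1))
  d_a1 <- d_a2 %*% hd$W2[, seq_len(config$head_units), drop = FALSE]
  if (!is.null(masks)) d_a1 <- .mask_cols(d_a1, masks$head1)
  d_a1 <- d_a1 * (cache$a1_pre > 0)
  gW1 <- crossprod(d_a1, cbind(cache$fp, 1))
  d_fp <- d_a1 %*% hd$W1[, seq_len(config$fp_length), drop = FALSE]
  if (!is.null(masks)) d_fp <- .mask_cols(d_fp, masks$fp)

  gW <- vector("list", T + 1)
  d_h <- vector("list", T + 1)
  G <- d_fp[mol_index, , drop = FALSE]
  for (t in 0:T) {
    Pt <- cache$P[[t + 1]]
    dS <- Pt * (G - rowSums(Pt * G))
    gW[[t + 1]] <- crossprod(dS, cache$hb[[t + 1]])
    wt <- .h_width(config, t)
    d_h[[t + 1]] <- dS %*% params$W[[t + 1]][, seq_len(wt), drop = FALSE]
  }
  list(W = gW, head = list(W1 = gW1, W2 = gW2, W3 = gW3), d_h = d_h)
}

# -- full network ------------------------------------------------------------

#' Forward pass over a packed batch
#'
#' @param params `mpnn_params`.
#' @param batch a [graph_batch()].
#' @param masks optional dropout mask set from [sample_dropout_masks()].
#' @param keep_cache retain intermediates for [mpnn_backward()].
#' @return list with `mean`, `log_var` (length `n_mols`), `fingerprint`,
#'   and `cache` when requested. The aleatoric variance is
#'   `exp(log_var) > 0` by construction.
#' @export
mpnn_forward <- function(params, batch, masks = NULL, keep_cache = FALSE) {
  mp <- .message_pass(params, batch, masks, keep_cache = keep_cache)
  ro <- .readout_forward(params, mp$h, batch$mol_index, batch$n_mols,
                         masks, keep_cache = keep_cache)
  res <- list(mean = ro$mean, log_var = ro$log_var,
              fingerprint = ro$fingerprint)
  if (keep_cache) {
    mp$masks <- masks
    res$cache <- list(mp = mp, ro = ro$cache)
  }
  res
}

#' Backpropagate output gradients through the network
#'
#' Given `d_out`, an `n_mols x 2` matrix of gradients of a scalar objective
#' with respect to the network outputs (column 1: predicted mean, column 2:
#' log aleatoric variance), returns gradients in the same nested shape as
#' the parameters. An optional `d_hidden` adds gradient flowing directly
#' into the final-step hidden states (used by the semi-supervised
#' objective).
#'
#' @param params `mpnn_params`.
#' @param batch the batch used in the forward pass.
#' @param cache from `mpnn_forward(..., keep_cache = TRUE)`.
#' @param d_out `n_mols x 2` gradient matrix.
#' @param d_hidden optional `n_atoms x n_h` matrix.
#' @return list `H`, `W`, `head` of gradient matrices.
#' @export
mpnn_backward <- function(params, batch, cache, d_out, d_hidden = NULL) {
  rb <- .readout_backward(params, cache$mp$h, cache$ro, d_out,
                          batch$mol_index)
  d_h <- rb$d_h
  if (!is.null(d_hidden)) {
    T <- params$config$n_steps
    d_h[[T + 1]] <- d_h[[T + 1]] + d_hidden
  }
  gH <- .message_backward(params, batch, cache$mp, d_h)
  list(H = gH, W = rb$W, head = rb$head)
}

# -- parameter vector utilities ---------------------------------------------

#' Flatten parameters (or a gradient of the same shape) to a vector
#' @param params nested `mpnn_params`-shaped list.
#' @param groups subset of c("H","W","head") to include.
#' @export
flatten_params <- function(params, groups = c("H", "W", "head")) {
  out <- list()
  if ("H" %in% groups)
    out <- c(out, lapply(unlist(params$H, recursive = FALSE), as.numeric))
  if ("W" %in% groups) out <- c(out, lapply(params$W, as.numeric))
  if ("head" %in% groups) out <- c(out, lapply(params$head, as.numeric))
  unlist(out, use.names = FALSE)
}

#' Write a flat vector back into a parameter template
#' @param vec numeric vector from [flatten_params()].
#' @param template an `mpnn_params`.
#' @param groups the same subset used to flatten.
#' @export
unflatten_params <- function(vec, template, groups = c("H", "W", "head")) {
  pos <- 0L
  take <- function(m) {
    k <- length(m)
    v <- vec[(pos + 1L):(pos + k)]
    pos <<- pos + k
    matrix(v, nrow(m), ncol(m))
  }
  p <- template
  if ("H" %in% groups)
    p$H <- lapply(template$H, function(ht) lapply(ht, take))
  if ("W" %in% groups) p$W <- lapply(template$W, take)
  if ("head" %in% groups) p$head <- lapply(template$head, take)
  if (pos != length(vec)) stop("parameter vector length mismatch")
  p
}

#' Number of parameters in the selected groups
#' @inheritParams flatten_params
#' @export
n_params <- function(params, groups = c("H", "W", "head")) {
  length(flatten_params(params, groups))
}
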