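# Synthetic benchmark generators with known ground truth: template-based
# molecule libraries (chemically valid by construction), a documented
# closed-form structure->property map with input-dependent Gaussian noise,
# and linear-Gaussian regression tasks whose exact posterior is analytic
# (the oracle for posterior-sampling inference).

# Substituent sets enumerable into each core template. Heteroatom-bearing
# substituents spread the heteroatom count, which drives the
# heteroscedastic noise model.
.substituents <- c("", "C", "CC", "CCC", "O", "N", "CO", "CN", "CCO",
                   "OC", "NC", "Cl", "CCN")

.family_templates <- list(
  benzene    = function(s1, s2) sprintf("%sc1ccc(%s)cc1", s1, s2),
  pyridine   = function(s1, s2) sprintf("%sc1ccc(%s)nc1", s1, s2),
  pyrimidine = function(s1, s2) sprintf("%sc1ncc(%s)cn1", s1, s2),
  cyclohexane = function(s1, s2) sprintf("%sC1CCC(%s)CC1", s1, s2),
  chain      = function(s1, s2) sprintf("CC(%s)CC%s", s1, s2)
)

#' Built-in scaffold family names
#' @export
scaffold_families <- function() names(.family_templates)

#' Generate a synthetic molecule library
#'
#' Draws `n` molecules by decorating hard-coded core templates (benzene,
#' pyridine, pyrimidine, cyclohexane cores and an acyclic branched chain)
#' with enumerable substituents, guaranteeing chemical validity without a
#' generative model. Deterministic under `seed`; every emitted SMILES
#' parses.
#'
#' @param n number of molecules.
#' @param families subset of [scaffold_families()].
#' @param seed RNG seed.
#' @return data frame with columns `smiles` and `family`.
#' @export
generate_molecule_library <- function(n, families = c("benzene", "chain"),
                                      seed = 1L) {
  stopifnot(n >= 1, length(families) >= 1,
            all(families %in% names(.family_templates)))
  set.seed(seed)
  fam <- families[1 + (seq_len(n) - 1) %% length(families)]
  subs <- .substituents
  s1 <- sample(subs, n, replace = TRUE)
  s2 <- sample(subs, n, replace = TRUE)
  smiles <- vapply(seq_len(n),
                   function(k) .family_templates[[fam[k]]](s1[k], s2[k]),
                   character(1))
  smiles <- gsub("()", "", smiles, fixed = TRUE)  # empty substituent slot
  data.frame(smiles = smiles, family = fam, stringsAsFactors = FALSE)
}

#' Default synthetic structure->property map
#'
#' A linear combination of interpretable graph statistics:
#' `0.25 * heavy-atom count + 1.0 * aromatic-ring count +
#'  0.75 * heteroatom count`.
#' Learnable by a small message-passing network, yet the exact noiseless
#' value is known for every molecule.
#'
#' @param graph a `mol_graph`.
#' @return scalar noiseless property value.
#' @export
default_truth_fn <- function(graph) {
  s <- graph_stats(graph)
  unname(0.25 * s["heavy"] + 1.0 * s["aromatic_rings"] + 0.75 * s["hetero"])
}

#' Default aleatoric noise map
#'
#' Input-dependent measurement noise `sigma(graph) = 0.2 + 0.2 *
#' heteroatom count`: regions of chemical space rich in heteroatoms are
#' intrinsically more variable, giving the aleatoric head a recoverable
#' signal.
#'
#' @param graph a `mol_graph`.
#' @return scalar noise standard deviation (> 0).
#' @export
default_noise_fn <- function(graph) {
  unname(0.2 + 0.2 * graph_stats(graph)["hetero"])
}

#' Label a molecule library with noisy synthetic measurements
#'
#' y = truth_fn(graph) + eps, eps ~ N(0, noise_fn(graph)^2). The returned
#' ground-truth table stores the noiseless values and true noise levels
#' for recovery tests.
#'
#' @param smiles character vector (or the data frame from
#'   [generate_molecule_library()], whose `family` tags are carried
#'   through).
#' @param truth_fn,noise_fn pure functions of a `mol_graph`.
#' @param seed RNG seed for the noise draws.
#' @param spec an [atom_feature_spec()].
#' @return list with `dataset` (a labelled `mol_dataset`) and `truth`
#'   (data frame: `smiles`, `family`, `y_true`, `sigma_true`, `y`).
#' @export
label_library <- function(smiles, truth_fn = default_truth_fn,
                          noise_fn = default_noise_fn, seed = 1L,
                          spec = atom_feature_spec()) {
  family <- NULL
  if (is.data.frame(smiles)) {
    family <- smiles$family
    smiles <- smiles$smiles
  }
  graphs <- parse_smiles_batch(smiles, spec)
  ok <- !vapply(graphs, is.null, logical(1))
  if (!all(ok)) stop("synthetic library contains unparseable SMILES")
  y_true <- vapply(graphs, truth_fn, numeric(1))
  sigma <- vapply(graphs, noise_fn, numeric(1))
  stopifnot(all(sigma >= 0))
  set.seed(seed)
  y <- y_true + stats::rnorm(length(y_true), sd = sigma)
  ds <- structure(list(graphs = graphs, smiles = smiles, y = y,
                       n_dropped = 0L, spec = spec),
                  class = "mol_dataset")
  truth <- data.frame(smiles = smiles,
                      family = if (is.null(family)) NA_character_ else family,
                      y_true = y_true, sigma_true = sigma, y = y,
                      stringsAsFactors = FALSE)
  list(dataset = ds, truth = truth)
}

#' Write a labelled synthetic task to CSV
#' @param task result of [label_library()].
#' @param path data CSV path; a `<path>_truth.csv` sidecar stores the
#'   ground-truth table.
#' @export
write_synthetic_csv <- function(task, path) {
  utils::write.csv(data.frame(smiles = task$truth$smiles,
                              y = task$truth$y),
                   path, row.names = FALSE)
  utils::write.csv(task$truth, sub("\\.csv$", "_truth.csv", path),
                   row.names = FALSE)
  invisible(path)
}

#' Conjugate linear-Gaussian regression task
#'
#' Random Gaussian design, targets from a drawn true weight vector with
#' homoscedastic noise, and the exact posterior under an isotropic
#' Gaussian prior computed in closed form:
#' `Sigma = (X'X / s^2 + I / t^2)^-1`, `mu = Sigma X'y / s^2`.
#'
#' @param dim number of coefficients (<= 10).
#' @param n number of observations.
#' @param prior_scale prior standard deviation t.
#' @param noise_scale observation noise standard deviation s.
#' @param seed RNG seed.
#' @return a `conjugate_task` with the data, the generating weights and
#'   the analytic posterior mean/covariance.
#' @export
make_conjugate_task <- function(dim = 3L, n = 50L, prior_scale = 1,
                                noise_scale = 0.5, seed = 1L) {
  stopifnot(dim >= 1, dim <= 10, n >= 1)
  set.seed(seed)
  X <- matrix(stats::rnorm(n * dim), n, dim)
  w <- stats::rnorm(dim, sd = prior_scale)
  y <- as.numeric(X %*% w) + stats::rnorm(n, sd = noise_scale)
  post <- conjugate_posterior(X, y, prior_scale, noise_scale)
  structure(list(X = X, y = y, w_true = w, prior_scale = prior_scale,
                 noise_scale = noise_scale,
                 post_mean = post$mean, post_cov = post$cov),
            class = "conjugate_task")
}

#' Closed-form posterior of linear-Gaussian regression
#' @param X design matrix; `y` targets.
#' @param prior_scale,noise_scale prior / noise standard deviations.
#' @return list with `mean` and `cov`.
#' @export
conjugate_posterior <- function(X, y, prior_scale, noise_scale) {
  d <- ncol(X)
  prec <- crossprod(X) / noise_scale^2 + diag(d) / prior_scale^2
  cov <- solve(prec)
  list(mean = as.numeric(cov %*% crossprod(X, y)) / noise_scale^2,
       cov = cov)
}
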