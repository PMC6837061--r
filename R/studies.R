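# Packaged validation studies on the synthetic benchmark. Each function
# runs one protocol end to end (generate -> label -> train -> evaluate)
# at a documented problem size and returns the summary statistics the
# protocol is judged on. The same functions back the test suite, the
# acceptance script and the vignette examples.

# default architecture for the synthetic studies: small enough to train
# in seconds on one CPU, large enough to learn the closed-form property
.study_config <- function(n_hidden = 12L)
  mpnn_config(n_steps = 2L, n_hidden = n_hidden,
              fp_length = 2L * n_hidden, head_units = 16L)

#' Aleatoric-recovery study
#'
#' Trains the semi-supervised heteroscedastic model on the default
#' synthetic task and measures, per seed, the Spearman correlation
#' between the predicted aleatoric variance on held-out molecules and the
#' generator's true noise variance. The embedding is trained once on the
#' training structures (it never sees labels); each seed then redraws the
#' measurement noise and retrains the supervised head with the two-phase
#' variance warm-up.
#'
#' @param n_train,n_test problem size (training/test molecules).
#' @param seeds seed vector; one supervised run per seed.
#' @param steps supervised budget per phase (mean warm-up and full
#'   heteroscedastic loss get `steps` each).
#' @param config network architecture.
#' @param seed_library seed for the molecule library and embedding.
#' @return list with `spearman` (per seed), `median_spearman`, `rmse`
#'   (per seed) and the fitted sizes.
#' @export
study_aleatoric_recovery <- function(n_train = 2000L, n_test = 500L,
                                     seeds = 1:5, steps = 400L,
                                     config = .study_config(),
                                     seed_library = 11L) {
  lib <- generate_molecule_library(n_train + n_test,
                                   c("benzene", "pyridine", "pyrimidine",
                                     "chain"), seed = seed_library)
  graphs <- parse_smiles_batch(lib$smiles)
  tr <- seq_len(n_train)
  te <- n_train + seq_len(n_test)
  ss <- train_semisupervised(graphs[tr], config, epochs = 25L, lr = 0.01,
                             seed = seed_library)
  m_fix <- semisup_head_model(ss, fixed_var = 1)
  m_het <- semisup_head_model(ss)
  dtr0 <- semisup_data(ss, graphs[tr], y = NULL)
  dte <- semisup_data(ss, graphs[te], y = NULL)

  sp <- rmse <- numeric(length(seeds))
  for (k in seq_along(seeds)) {
    s <- seeds[k]
    task <- label_library(lib, seed = 1000L + s)
    dtr <- dtr0
    dtr$y <- task$truth$y[tr]
    f1 <- train_dropout(m_fix, dtr, gaussian_prior(2),
                        dropout = dropout_config(p = 0.1, n_samples = 50L),
                        steps = steps, lr = 0.02, seed = s)
    f2 <- train_dropout(m_het, dtr, gaussian_prior(2),
                        dropout = dropout_config(p = 0.1, n_samples = 50L),
                        steps = steps, lr = 0.01, seed = s,
                        init = f1$theta)
    pr <- predict_dropout(f2, dte, seed = s + 500L)
    sp[k] <- stats::cor(pr$var_aleatoric, task$truth$sigma_true[te]^2,
                        method = "spearman")
    rmse[k] <- sqrt(mean((pr$mean - task$truth$y[te])^2))
  }
  list(spearman = sp, median_spearman = stats::median(sp), rmse = rmse,
       n_train = n_train, n_test = n_test)
}

#' Scaffold-bias (out-of-domain uncertainty) study
#'
#' Trains on two scaffold families (benzene-cored aromatics and acyclic
#' chains) and probes a held-out third family (pyrimidines) against fresh
#' held-out molecules of the training families. Counts, across seeds, how
#' often the median predicted total variance is higher out of domain.
#'
#' @param seeds seed vector (one full experiment each).
#' @param n_train,n_probe training-set size and per-group probe size.
#' @param steps supervised budget per phase.
#' @param config network architecture.
#' @return list with per-seed in/out medians, rank-sum p-values and
#'   `wins` (number of seeds with the expected inflation).
#' @export
study_bias_probe <- function(seeds = 1:10, n_train = 300L, n_probe = 80L,
                             steps = 200L,
                             config = mpnn_config(n_steps = 2L,
                                                  n_hidden = 10L,
                                                  fp_length = 20L,
                                                  head_units = 12L)) {
  med_in <- med_out <- pval <- numeric(length(seeds))
  for (k in seq_along(seeds)) {
    s <- seeds[k]
    lib_in <- generate_molecule_library(n_train, c("benzene", "chain"),
                                        seed = 200L + s)
    lib_it <- generate_molecule_library(n_probe, c("benzene", "chain"),
                                        seed = 500L + s)
    lib_out <- generate_molecule_library(n_probe, "pyrimidine",
                                         seed = 300L + s)
    task <- label_library(lib_in, seed = 400L + s)
    g_in <- task$dataset$graphs
    g_it <- parse_smiles_batch(lib_it$smiles)
    g_out <- parse_smiles_batch(lib_out$smiles)
    ss <- train_semisupervised(g_in, config, epochs = 20L, lr = 0.01,
                               seed = s)
    m_fix <- semisup_head_model(ss, fixed_var = 1)
    m_het <- semisup_head_model(ss)
    dtr <- semisup_data(ss, g_in, task$dataset$y)
    f1 <- train_dropout(m_fix, dtr, gaussian_prior(2),
                        dropout = dropout_config(p = 0.1, n_samples = 40L),
                        steps = steps, lr = 0.02, seed = s)
    f2 <- train_dropout(m_het, dtr, gaussian_prior(2),
                        dropout = dropout_config(p = 0.1, n_samples = 40L),
                        steps = steps, lr = 0.01, seed = s,
                        init = f1$theta)
    pin <- predict_dropout(f2, semisup_data(ss, g_it, y = NULL),
                           seed = s + 900L)
    pout <- predict_dropout(f2, semisup_data(ss, g_out, y = NULL),
                            seed = s + 950L)
    bp <- bias_probe(pin, pout)
    med_in[k] <- bp$median_in
    med_out[k] <- bp$median_out
    pval[k] <- bp$p_value
  }
  list(median_in = med_in, median_out = med_out, p_value = pval,
       wins = sum(med_out > med_in), n_seeds = length(seeds))
}

#' Active-learning direction study
#'
#' The uncertainty-sampling protocol on the default synthetic task:
#' paired active (largest epistemic variance) versus random acquisition
#' runs sharing seeds, splits and the label-free embedding, with dropout
#' variational inference inside the loop. Returns mean final-iteration
#' test RMSE and mean learning-curve AUC per strategy.
#'
#' @param n_runs number of paired runs (seeds `seed_base + 1:n_runs`).
#' @param n_molecules dataset size per run.
#' @param n_iterations acquisition cycles per run.
#' @param steps supervised budget per retraining.
#' @param config network architecture.
#' @param seed_base offset added to every per-run seed.
#' @return list with the per-run final RMSEs and AUCs for both arms and
#'   their means.
#' @export
study_active_learning <- function(n_runs = 20L, n_molecules = 400L,
                                  n_iterations = 4L, steps = 350L,
                                  config = .study_config(),
                                  seed_base = 0L) {
  res <- matrix(0, n_runs, 4,
                dimnames = list(NULL, c("final_active", "final_random",
                                        "auc_active", "auc_random")))
  for (run in seq_len(n_runs)) {
    s <- seed_base + run
    lib <- generate_molecule_library(n_molecules,
                                     c("benzene", "pyridine", "pyrimidine",
                                       "chain"), seed = 600L + s)
    task <- label_library(lib, seed = 700L + s)
    ds <- task$dataset
    # the embedding sees structures only; the paired arms share it
    set.seed(s)
    n <- length(ds$graphs)
    test_idx <- sort(sample.int(n, round(0.2 * n)))
    tr_idx <- setdiff(seq_len(n), test_idx)
    ss <- train_semisupervised(ds$graphs[tr_idx], config, epochs = 12L,
                               seed = s)
    loop <- al_config(n_iterations = n_iterations,
                      model_kind = "semisupervised", steps = steps,
                      lr = 0.02,
                      dropout = dropout_config(p = 0.2, n_samples = 30L))
    loop$strategy <- "active"
    ta <- run_active_learning(ds, config, loop, seed = s,
                              semisup_model = ss)
    loop$strategy <- "random"
    tr <- run_active_learning(ds, config, loop, seed = s,
                              semisup_model = ss)
    res[run, ] <- c(utils::tail(ta$iterations$test_rmse, 1),
                  utils::tail(tr$iterations$test_rmse, 1),
                  mean(ta$iterations$test_rmse),
                  mean(tr$iterations$test_rmse))
  }
  list(per_run = as.data.frame(res),
       mean_final_active = mean(res[, 1]),
       mean_final_random = mean(res[, 2]),
       mean_auc_active = mean(res[, 3]),
       mean_auc_random = mean(res[, 4]))
}
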