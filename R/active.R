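# Scaffold-aware splitting and the uncertainty-driven active-learning
# loop: train on a small labelled pool, acquire the unlabelled molecules
# with the largest predicted epistemic uncertainty, retrain, repeat.

#' Bemis-Murcko scaffold identifier
#'
#' The molecular framework is obtained by iteratively pruning terminal
#' (degree-1) atoms until only ring systems and their linkers remain. The
#' framework graph, with atoms labelled by element and aromaticity and
#' bonds by order, is reduced to a canonical string via a canonical graph
#' labelling, so two molecules share an identifier iff their frameworks
#' are isomorphic. Acyclic molecules have an empty framework and return
#' `""` (each such molecule forms its own singleton group in
#' [scaffold_split()]).
#'
#' @param graph a `mol_graph`.
#' @return character scaffold key ("" for ring-free molecules).
#' @export
murcko_scaffold <- function(graph) {
  stopifnot(inherits(graph, "mol_graph"))
  keep <- rep(TRUE, graph$n_atoms)
  bonds <- graph$bonds
  repeat {
    deg <- integer(graph$n_atoms)
    act <- which(keep)
    if (nrow(bonds) > 0) {
      live <- keep[bonds$i] & keep[bonds$j]
      tab <- table(c(bonds$i[live], bonds$j[live]))
      deg[as.integer(names(tab))] <- as.integer(tab)
    }
    leaves <- act[deg[act] <= 1]
    if (length(leaves) == 0 || length(leaves) == length(act)) {
      if (length(leaves) == length(act)) keep[] <- FALSE  # acyclic
      break
    }
    keep[leaves] <- FALSE
  }
  verts <- which(keep)
  if (length(verts) == 0) return("")
  live <- bonds$i %in% verts & bonds$j %in% verts
  bi <- match(bonds$i[live], verts)
  bj <- match(bonds$j[live], verts)
  btype <- apply(graph$bond_features[live, 1:4, drop = FALSE], 1, which.max)

  # canonical labelling with bond vertices carrying the bond order as color
  n_v <- length(verts); n_b <- length(bi)
  elem_code <- match(graph$elements[verts],
                     c(graph$spec$elements, ".other"))
  elem_code[is.na(elem_code)] <- length(graph$spec$elements) + 1L
  colors <- c(elem_code * 2L + as.integer(graph$aromatic[verts]),
              100L + btype)
  edges <- rbind(cbind(bi, n_v + seq_len(n_b)),
                 cbind(bj, n_v + seq_len(n_b)))
  ig <- igraph::graph_from_edgelist(edges, directed = FALSE)
  perm <- igraph::canonical_permutation(ig, colors = colors)$labeling
  cg <- igraph::permute(ig, perm)
  el <- igraph::as_edgelist(cg)
  el <- el[order(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])), ,
           drop = FALSE]
  paste(c(colors[order(perm)], t(el)), collapse = ",")
}

#' Scaffold split
#'
#' Groups molecules by Bemis-Murcko scaffold and assigns whole groups,
#' largest first, to partitions until the requested fractions are met
#' (molecules sharing a framework never straddle a partition boundary).
#' Ring-free molecules form singleton groups. Deterministic given `seed`
#' (the seed shuffles the order of equal-sized groups).
#'
#' @param graphs list of `mol_graph`.
#' @param fractions numeric partition fractions summing to 1.
#' @param seed RNG seed for tie shuffling.
#' @return list of integer index vectors, one per fraction.
#' @export
scaffold_split <- function(graphs, fractions = c(0.8, 0.2), seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, all(fractions >= 0))
  keys <- vapply(graphs, murcko_scaffold, character(1))
  keys[keys == ""] <- paste0(".acyclic", seq_along(keys)[keys == ""])
  groups <- split(seq_along(graphs), keys)
  set.seed(seed)
  groups <- groups[sample.int(length(groups))]        # random tie order
  groups <- groups[order(-lengths(groups))]           # stable: largest first
  targets <- fractions * length(graphs)
  parts <- rep(list(integer(0)), length(fractions))
  for (g in groups) {
    open <- which(lengths(parts) < targets)
    dest <- if (length(open)) open[1] else which.min(lengths(parts) / targets)
    parts[[dest]] <- c(parts[[dest]], g)
  }
  if (any(lengths(parts) == 0 & fractions > 0))
    warning("scaffold split left a requested partition empty ",
            "(too few distinct scaffolds)")
  parts
}

#' Select the highest-epistemic-uncertainty batch
#'
#' @param preds `uncertain_prediction` over the unlabelled pool.
#' @param batch_size number of molecules to acquire.
#' @param kind variance used for ranking ("epistemic" per the acquisition
#'   rule; "total" available as an extension).
#' @return integer indices of the `batch_size` most uncertain pool
#'   entries, ties broken by stable input order.
#' @export
acquire <- function(preds, batch_size, kind = c("epistemic", "total")) {
  kind <- match.arg(kind)
  n <- nrow(preds)
  if (is.null(n) || n == 0) stop("empty unlabelled pool")
  stopifnot(batch_size >= 1, batch_size <= n)
  v <- .pick_variance(preds, kind)
  order(-v)[seq_len(batch_size)]
}

#' Active-learning loop configuration
#'
#' Defaults follow the reference protocol: hold out 20% of the data as a
#' fixed test set, seed the labelled pool with 25% of the training set,
#' and acquire 2.5% of the training set per iteration, either at random or
#' by largest predicted epistemic uncertainty; the model is retrained from
#' scratch each iteration with dropout variational inference.
#'
#' @param init_frac initial labelled fraction of the training pool.
#' @param batch_frac acquisition batch size as a fraction of the training
#'   pool (constant batch: always relative to the full training set).
#' @param test_frac held-out test fraction of the full dataset.
#' @param n_iterations number of acquire-retrain cycles.
#' @param strategy "active" (epistemic-uncertainty acquisition) or
#'   "random".
#' @param init_split "random" or "scaffold" (scaffold-biased initial pool).
#' @param model_kind "supervised" or "semisupervised".
#' @param steps,lr supervised training budget per iteration.
#' @param dropout a [dropout_config()].
#' @param semisup_epochs embedding budget (semisupervised only; the
#'   embedding is trained once on all training-pool structures, without
#'   labels, and frozen across iterations).
#' @param warm_start reuse the previous iteration's weights instead of
#'   re-initializing (off by default: from-scratch retraining keeps
#'   acquisition quality separate from optimization path effects).
#' @export
al_config <- function(init_frac = 0.25, batch_frac = 0.025,
                      test_frac = 0.20, n_iterations = 10L,
                      strategy = c("active", "random"),
                      init_split = c("random", "scaffold"),
                      model_kind = c("supervised", "semisupervised"),
                      steps = 150L, lr = 0.02,
                      dropout = dropout_config(p = 0.1, n_samples = 30L),
                      semisup_epochs = 20L, warm_start = FALSE) {
  structure(list(init_frac = init_frac, batch_frac = batch_frac,
                 test_frac = test_frac,
                 n_iterations = as.integer(n_iterations),
                 strategy = match.arg(strategy),
                 init_split = match.arg(init_split),
                 model_kind = match.arg(model_kind),
                 steps = as.integer(steps), lr = lr, dropout = dropout,
                 semisup_epochs = as.integer(semisup_epochs),
                 warm_start = warm_start),
            class = "al_config")
}

#' Run one active-learning experiment
#'
#' @param dataset a labelled `mol_dataset`.
#' @param config an [mpnn_config()] for the property model.
#' @param loop an [al_config()].
#' @param seed seed controlling the test split, pool initialization,
#'   training and prediction randomness.
#' @param semisup_model optional pretrained [train_semisupervised()] model
#'   reused across paired runs (the embedding stage sees structures only,
#'   never labels, so sharing it between strategy arms of one seed is
#'   leakage-free).
#' @return an `al_trace`: per-iteration data frame (`iteration`,
#'   `labelled_frac`, `n_labelled`, `test_rmse`), the acquisition history
#'   and the index bookkeeping.
#' @export
run_active_learning <- function(dataset, config = mpnn_config(),
                                loop = al_config(), seed = 1L,
                                semisup_model = NULL) {
  stopifnot(inherits(dataset, "mol_dataset"), all(!is.na(dataset$y)))
  n <- length(dataset$graphs)
  set.seed(seed)
  test_idx <- sort(sample.int(n, round(loop$test_frac * n)))
  train_idx <- setdiff(seq_len(n), test_idx)
  n_train <- length(train_idx)
  n_init <- max(2L, round(loop$init_frac * n_train))
  batch_size <- max(1L, round(loop$batch_frac * n_train))

  if (loop$init_split == "scaffold") {
    parts <- scaffold_split(dataset$graphs[train_idx],
                            c(loop$init_frac, 1 - loop$init_frac),
                            seed = seed)
    labelled <- train_idx[parts[[1]]]
  } else {
    labelled <- sort(sample(train_idx, n_init))
  }
  pool <- setdiff(train_idx, labelled)

  full_batch <- graph_batch(dataset$graphs)
  test_y <- dataset$y[test_idx]

  ss_model <- semisup_model
  if (loop$model_kind == "semisupervised") {
    if (is.null(ss_model))
      ss_model <- train_semisupervised(dataset$graphs[train_idx], config,
                                       epochs = loop$semisup_epochs,
                                       seed = seed)
    states_all <- semisup_data(ss_model, dataset$graphs, y = NULL)
  }

  sub_data <- function(idx) {
    if (loop$model_kind == "semisupervised") {
      rows <- which(states_all$batch$mol_index %in% idx)
      list(batch = list(mol_index = match(states_all$batch$mol_index[rows],
                                          idx),
                        n_mols = length(idx)),
           h = lapply(states_all$h, function(m) m[rows, , drop = FALSE]),
           hb = lapply(states_all$hb, function(m) m[rows, , drop = FALSE]),
           y = dataset$y[idx])
    } else {
      list(batch = subset_batch(full_batch, idx), y = dataset$y[idx])
    }
  }
  model <- if (loop$model_kind == "semisupervised")
    semisup_head_model(ss_model) else mpnn_model(config)

  theta0 <- NULL
  fit_and_eval <- function(labelled, iter) {
    fit <- train_dropout(model, sub_data(labelled),
                         prior = gaussian_prior(1),
                         dropout = loop$dropout, steps = loop$steps,
                         lr = loop$lr, seed = seed + 1000L * iter,
                         init = if (loop$warm_start) theta0 else NULL)
    if (loop$warm_start) theta0 <<- fit$theta
    preds_test <- predict_dropout(fit, sub_data(test_idx),
                                  seed = seed + 1000L * iter + 1L)
    list(fit = fit, rmse = sqrt(mean((preds_test$mean - test_y)^2)))
  }

  rows <- list(); acquired <- list()
  fe <- fit_and_eval(labelled, 0L)
  rows[[1]] <- data.frame(iteration = 0L,
                          labelled_frac = length(labelled) / n_train,
                          n_labelled = length(labelled),
                          test_rmse = fe$rmse)
  it <- 0L
  while (it < loop$n_iterations && length(pool) > 0) {
    it <- it + 1L
    take <- min(batch_size, length(pool))
    if (loop$strategy == "active") {
      preds_pool <- predict_dropout(fe$fit, sub_data(pool),
                                    seed = seed + 1000L * it + 2L)
      sel <- pool[acquire(preds_pool, take)]
    } else {
      set.seed(seed + 1000L * it + 3L)
      sel <- sample(pool, take)
    }
    acquired[[it]] <- sel
    labelled <- sort(c(labelled, sel))
    pool <- setdiff(pool, sel)
    fe <- fit_and_eval(labelled, it)
    rows[[it + 1L]] <- data.frame(iteration = it,
                                  labelled_frac = length(labelled) / n_train,
                                  n_labelled = length(labelled),
                                  test_rmse = fe$rmse)
  }
  structure(list(iterations = do.call(rbind, rows), acquired = acquired,
                 strategy = loop$strategy, init = loop$init_split,
                 model_kind = loop$model_kind, seed = seed,
                 test_idx = test_idx, final_labelled = labelled,
                 pool = pool, n_train = n_train),
            class = "al_trace")
}

#' Summarize active-learning traces
#'
#' Per-iteration mean test error and standard error of the mean per
#' strategy, plus the area under each trace's learning curve (mean error
#' across iterations).
#'
#' @param traces list of `al_trace` objects on a common iteration grid.
#' @return list with `summary` (strategy x iteration means and SEMs) and
#'   `auc` (one row per trace).
#' @export
compare_strategies <- function(traces) {
  stopifnot(length(traces) >= 1)
  grids <- lapply(traces, function(tr) tr$iterations$labelled_frac)
  if (length(unique(vapply(grids, paste, character(1), collapse = ","))) > 1)
    stop("traces have mismatched iteration grids")
  long <- do.call(rbind, lapply(seq_along(traces), function(k) {
    df <- traces[[k]]$iterations
    df$strategy <- traces[[k]]$strategy
    df$run <- k
    df
  }))
  agg <- do.call(rbind, lapply(split(long, list(long$strategy,
                                                long$iteration),
                                     drop = TRUE), function(d)
    data.frame(strategy = d$strategy[1], iteration = d$iteration[1],
               labelled_frac = d$labelled_frac[1],
               mean_rmse = mean(d$test_rmse),
               sem_rmse = if (nrow(d) > 1)
                 stats::sd(d$test_rmse) / sqrt(nrow(d)) else 0)))
  agg <- agg[order(agg$strategy, agg$iteration), ]
  rownames(agg) <- NULL
  auc <- do.call(rbind, lapply(split(long, long$run), function(d)
    data.frame(run = d$run[1], strategy = d$strategy[1],
               auc = mean(d$test_rmse))))
  rownames(auc) <- NULL
  list(summary = agg, auc = auc)
}

#' @export
print.al_trace <- function(x, ...) {
  cat(sprintf("al_trace (%s, %s init, %s model): %d iterations\n",
              x$strategy, x$init, x$model_kind,
              nrow(x$iterations) - 1L))
  print(x$iterations)
  invisible(x)
}
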