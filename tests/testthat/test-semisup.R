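# Semi-supervised embedding: the negative-sampling objective, training,
# and the frozen-core contract of the supervised head stage.

test_that("objective is finite and matches a brute-force re-enumeration", {
  cfg <- tiny_config()
  g <- fixture_graphs()[1:3]
  ss <- train_semisupervised(g, cfg, epochs = 3, seed = 1, n_negative = 2)

  obj <- semisup_objective(g, ss, seed = 21)
  expect_true(is.finite(obj))

  # independent oracle: loop over atoms with the documented negative-draw
  # order (one sample.int call after set.seed, filled column-wise)
  batch <- graph_batch(g)
  mp <- molbayes:::.message_pass(ss$embed_params, batch)
  HT <- mp$h[[cfg$n_steps + 1]]
  n <- batch$n_atoms
  set.seed(21)
  neg <- matrix(sample.int(n, n * 2, replace = TRUE), n, 2)
  obj_ref <- 0
  for (v in seq_len(n)) {
    nbrs <- which(batch$A[v, ] != 0)
    q <- if (length(nbrs)) colMeans(HT[nbrs, , drop = FALSE]) else rep(0, 4)
    ctx <- ss$u[batch$mol_index[v], ] + as.numeric(ss$C %*% q)
    zv <- as.numeric(ss$P %*% HT[v, ])
    obj_ref <- obj_ref + plogis(sum(ctx * zv), log.p = TRUE)
    for (k in 1:2) {
      zneg <- as.numeric(ss$P %*% HT[neg[v, k], ])
      obj_ref <- obj_ref + plogis(-sum(ctx * zneg), log.p = TRUE)
    }
  }
  expect_equal(obj, obj_ref, tolerance = 1e-10)
})

test_that("training is seeded-deterministic and improves the objective", {
  cfg <- tiny_config()
  g <- fixture_graphs()
  ss1 <- train_semisupervised(g, cfg, epochs = 15, seed = 7)
  ss2 <- train_semisupervised(g, cfg, epochs = 15, seed = 7)
  expect_identical(flatten_params(ss1$embed_params, "H"),
                   flatten_params(ss2$embed_params, "H"))
  expect_identical(ss1$u, ss2$u)

  # optimization sanity: late objective above early objective
  expect_gt(mean(tail(ss1$trace, 3)), mean(head(ss1$trace, 3)))

  # a duplicated molecule with tied identifier contributes identically
  gd <- list(g[[1]], g[[1]])
  ssd <- train_semisupervised(gd, cfg, epochs = 2, seed = 1)
  emb <- embed_molecule(gd, ssd)
  n1 <- g[[1]]$n_atoms
  expect_identical(emb$h[[cfg$n_steps + 1]][seq_len(n1), ],
                   emb$h[[cfg$n_steps + 1]][n1 + seq_len(n1), ])
})

test_that("unregistered molecules are rejected by the objective", {
  cfg <- tiny_config()
  g <- fixture_graphs()[1:2]
  ss <- train_semisupervised(g, cfg, epochs = 2, seed = 1)
  expect_error(semisup_objective(fixture_graphs()[1:3], ss), "registered")
})

test_that("embedding is frozen, inductive and schema-checked", {
  cfg <- tiny_config()
  g <- fixture_graphs()
  ss <- train_semisupervised(g[1:4], cfg, epochs = 5, seed = 3)

  e1 <- embed_molecule(g[[1]], ss)
  e2 <- embed_molecule(g[[1]], ss)
  expect_identical(e1$h, e2$h)

  # unseen molecule embeds without error (no identifier needed)
  expect_silent(embed_molecule(parse_smiles("CCCCCCO"), ss))
  # isolated atom goes through the degree-0 path
  expect_silent(embed_molecule(parse_smiles("C"), ss))

  # mismatched feature schema is rejected
  alt <- atom_feature_spec(elements = c("C", "O"))
  galt <- parse_smiles("CCO", spec = alt)
  expect_error(embed_molecule(galt, ss), "scheme")
})

test_that("supervised head training never touches the embedding weights", {
  cfg <- tiny_config()
  g <- fixture_graphs()
  ss <- train_semisupervised(g, cfg, epochs = 5, seed = 2)
  before <- flatten_params(ss$embed_params, "H")

  model <- semisup_head_model(ss)
  data <- semisup_data(ss, g, y = c(1, 2, 3, 4, 5, 6))
  fit <- train_dropout(model, data, gaussian_prior(1),
                       dropout = dropout_config(p = 0.1), steps = 40,
                       lr = 0.02, seed = 1)
  after <- flatten_params(ss$embed_params, "H")
  expect_identical(before, after)
  # the trainable vector covers only readout + head
  expect_equal(length(fit$theta),
               n_params(ss$embed_params, c("W", "head")))

  pr <- predict_dropout(fit, data, seed = 2)
  expect_uncertain_prediction(pr, 6)
})

test_that("repeated-scaffold molecules embed closer than dissimilar ones", {
  cfg <- tiny_config(n_hidden = 6L)
  # fixture of repeated scaffolds: several benzene-core and chain molecules
  smiles <- c("Cc1ccccc1", "CCc1ccccc1", "Oc1ccccc1", "c1ccccc1",
              "CCCC", "CCCCC", "CCCCO", "CCCN")
  g <- parse_smiles_batch(smiles)
  ss <- train_semisupervised(g, cfg, epochs = 60, lr = 0.02, seed = 5)
  emb <- embed_molecule(g, ss)
  HT <- emb$h[[cfg$n_steps + 1]]
  mi <- emb$batch$mol_index
  mean_state <- t(sapply(1:8, function(k) colMeans(HT[mi == k, , drop = FALSE])))
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  sim_like <- cosine(mean_state[1, ], mean_state[2, ])    # two toluene-like
  sim_unlike <- cosine(mean_state[1, ], mean_state[5, ])  # aromatic vs chain
  expect_gt(sim_like, sim_unlike)
})

test_that("semisup checkpoints restore embeddings exactly", {
  cfg <- tiny_config()
  g <- fixture_graphs()[1:3]
  ss <- train_semisupervised(g, cfg, epochs = 3, seed = 4)
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  save_checkpoint(ss, f)
  ss2 <- load_checkpoint(f)
  expect_equal(embed_molecule(g[[2]], ss)$h,
               embed_molecule(g[[2]], ss2)$h, tolerance = 1e-12)
})
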