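# Scaffold splitting, acquisition and the active-learning loop mechanics.

test_that("murcko scaffolds identify frameworks and ring-free molecules", {
  # same benzene framework under different substituents
  s1 <- murcko_scaffold(parse_smiles("Cc1ccccc1"))
  s2 <- murcko_scaffold(parse_smiles("CCOc1ccccc1"))
  s3 <- murcko_scaffold(parse_smiles("c1ccccc1"))
  expect_identical(s1, s2)
  expect_identical(s1, s3)
  # pyridine differs from benzene
  expect_false(identical(s1, murcko_scaffold(parse_smiles("c1ccncc1"))))
  # acyclic molecules have no framework
  expect_identical(murcko_scaffold(parse_smiles("CCCCO")), "")
  # two-ring framework retains the linker
  biphenyl <- murcko_scaffold(parse_smiles("c1ccc(-c2ccccc2)cc1"))
  expect_identical(biphenyl,
                   murcko_scaffold(parse_smiles("Cc1ccc(-c2ccccc2)cc1C")))
})

test_that("scaffold split keeps groups whole and follows greedy assignment", {
  # two scaffold families, 50/50 request: partitions are scaffold-pure
  lib <- generate_molecule_library(20, c("benzene", "pyridine"), seed = 2)
  g <- parse_smiles_batch(lib$smiles)
  parts <- scaffold_split(g, c(0.5, 0.5), seed = 1)
  fam_of <- function(idx) unique(lib$family[idx])
  expect_length(fam_of(parts[[1]]), 1)
  expect_length(fam_of(parts[[2]]), 1)
  expect_setequal(unlist(parts), seq_along(g))

  # all molecules share one scaffold: everything in the first partition
  lib1 <- generate_molecule_library(8, "benzene", seed = 3)
  g1 <- parse_smiles_batch(lib1$smiles)
  expect_warning(p1 <- scaffold_split(g1, c(0.6, 0.4), seed = 1), "empty")
  expect_length(p1[[1]], 8)
  expect_length(p1[[2]], 0)

  # hand-executed greedy run: group sizes 6,5,4,3,2,1 into 70/30 of 21.
  # largest-first fill: 6,5,4 -> part1 (15 >= 14.7), then 3,2,1 -> part2.
  sizes <- c(6, 5, 4, 3, 2, 1)
  smiles <- unlist(lapply(seq_along(sizes), function(k) {
    core <- c("c1ccccc1", "c1ccncc1", "c1cnccn1", "C1CCCCC1",
              "C1CCCC1", "C1CCCCCC1")[k]
    subs <- c("C", "CC", "CCC", "O", "N", "CCO")
    vapply(seq_len(sizes[k]), function(i) paste0(subs[i], core),
           character(1))
  }))
  gg <- parse_smiles_batch(smiles)
  pp <- scaffold_split(gg, c(0.7, 0.3), seed = 5)
  expect_equal(sort(lengths(pp)), c(6, 15))
  key <- vapply(gg, murcko_scaffold, character(1))
  for (part in pp) {
    # no scaffold straddles the boundary
    expect_length(intersect(key[part], key[setdiff(seq_along(gg), part)]), 0)
  }
  # determinism
  expect_identical(pp, scaffold_split(gg, c(0.7, 0.3), seed = 5))
})

test_that("acquisition selects the largest epistemic variances, stably", {
  pr <- data.frame(mean = rep(0, 7),
                   var_epistemic = c(3, 1, 4, 1, 5, 9, 2),
                   var_aleatoric = rep(0, 7))
  pr$var_total <- pr$var_epistemic
  class(pr) <- c("uncertain_prediction", "data.frame")
  expect_equal(acquire(pr, 3), c(6, 5, 3))      # hand-sorted top 3
  expect_equal(sort(acquire(pr, 7)), 1:7)       # batch = pool returns all

  # one inflated item is picked first
  pr$var_epistemic[4] <- 100; pr$var_total <- pr$var_epistemic
  expect_equal(acquire(pr, 1), 4)

  # ties broken by stable input order
  pr$var_epistemic <- rep(1, 7); pr$var_total <- pr$var_epistemic
  expect_equal(acquire(pr, 3), 1:3)

  expect_error(acquire(pr[0, ], 1), "empty")
})

test_that("the loop keeps pool bookkeeping consistent and reproducible", {
  lib <- generate_molecule_library(60, c("benzene", "chain"), seed = 4)
  task <- label_library(lib, seed = 5)
  cfg <- tiny_config()
  loop <- al_config(n_iterations = 2, strategy = "random", steps = 15,
                    lr = 0.02, dropout = dropout_config(p = 0.1,
                                                        n_samples = 5))
  tr1 <- run_active_learning(task$dataset, cfg, loop, seed = 3)
  tr2 <- run_active_learning(task$dataset, cfg, loop, seed = 3)
  expect_identical(tr1$iterations, tr2$iterations)
  expect_identical(tr1$acquired, tr2$acquired)

  n <- length(task$dataset$graphs)
  # labelled, pool and test partition the dataset at the end
  expect_setequal(c(tr1$final_labelled, tr1$pool, tr1$test_idx), seq_len(n))
  expect_length(intersect(tr1$final_labelled, tr1$test_idx), 0)
  # no test index was ever acquired; acquired sets disjoint across iters
  acq <- unlist(tr1$acquired)
  expect_length(intersect(acq, tr1$test_idx), 0)
  expect_false(any(duplicated(acq)))
  # labelled fraction strictly increasing
  expect_true(all(diff(tr1$iterations$labelled_frac) > 0))

  # active strategy bookkeeping too
  loop$strategy <- "active"
  tra <- run_active_learning(task$dataset, cfg, loop, seed = 3)
  expect_length(intersect(unlist(tra$acquired), tra$test_idx), 0)

  # zero iterations: only the initial evaluation
  loop0 <- al_config(n_iterations = 0, strategy = "random", steps = 10,
                     dropout = dropout_config(p = 0.1, n_samples = 4))
  tr0 <- run_active_learning(task$dataset, cfg, loop0, seed = 1)
  expect_equal(nrow(tr0$iterations), 1L)
})

test_that("an oversized final batch shrinks and the loop stops", {
  lib <- generate_molecule_library(30, "benzene", seed = 6)
  task <- label_library(lib, seed = 7)
  cfg <- tiny_config()
  # init 60%, batches of 20% of train: pool exhausts mid-run
  loop <- al_config(init_frac = 0.6, batch_frac = 0.2, test_frac = 0.2,
                    n_iterations = 5, strategy = "random", steps = 8,
                    dropout = dropout_config(p = 0.1, n_samples = 3))
  tr <- run_active_learning(task$dataset, cfg, loop, seed = 2)
  expect_lte(nrow(tr$iterations), 4)
  expect_length(tr$pool, 0)
})

test_that("scaffold-biased initialization yields a scaffold-pure seed pool", {
  lib <- generate_molecule_library(60, c("benzene", "pyridine",
                                         "pyrimidine", "cyclohexane"),
                                   seed = 8)
  task <- label_library(lib, seed = 9)
  cfg <- tiny_config()
  loop <- al_config(n_iterations = 1, strategy = "random",
                    init_split = "scaffold", steps = 8,
                    dropout = dropout_config(p = 0.1, n_samples = 3))
  tr <- run_active_learning(task$dataset, cfg, loop, seed = 4)
  init_pool <- setdiff(tr$final_labelled, unlist(tr$acquired))
  init_fams <- unique(lib$family[init_pool])
  expect_lt(length(init_fams), length(unique(lib$family)))
})

test_that("strategy comparison aggregates means, SEMs and AUC correctly", {
  mk <- function(rmse, strategy) {
    structure(list(iterations = data.frame(
      iteration = seq_along(rmse) - 1L,
      labelled_frac = seq(0.25, by = 0.025, length.out = length(rmse)),
      n_labelled = seq_along(rmse), test_rmse = rmse),
      strategy = strategy), class = "al_trace")
  }
  t1 <- mk(c(2, 1.5, 1.0), "active")
  t2 <- mk(c(2.2, 1.7, 1.4), "active")
  t3 <- mk(c(2.1, 1.9, 1.6), "random")
  cs <- compare_strategies(list(t1, t2, t3))
  a0 <- cs$summary[cs$summary$strategy == "active" &
                     cs$summary$iteration == 0, ]
  expect_equal(a0$mean_rmse, mean(c(2, 2.2)))
  expect_equal(a0$sem_rmse, sd(c(2, 2.2)) / sqrt(2))
  expect_equal(cs$auc$auc[cs$auc$run == 1], mean(c(2, 1.5, 1.0)))
  # single-strategy input: summary only, no error
  expect_silent(compare_strategies(list(t3)))
  # identical traces: zero SEM
  cz <- compare_strategies(list(t1, t1))
  expect_true(all(cz$summary$sem_rmse == 0))
  # mismatched grids rejected
  t4 <- mk(c(2, 1), "random")
  expect_error(compare_strategies(list(t1, t4)), "grid")
})
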