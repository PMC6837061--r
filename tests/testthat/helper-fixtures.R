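# Shared tiny fixtures: a small network configuration and a handful of
# parsed molecules, reused across test files to keep parsing overhead low.

tiny_config <- function(n_steps = 2L, n_hidden = 4L)
  mpnn_config(n_steps = n_steps, n_hidden = n_hidden,
              fp_length = 6L, head_units = 5L)

fixture_smiles <- c("CCO", "c1ccccc1", "CC(=O)O", "c1ccncc1", "CCCC",
                    "Oc1ccccc1")

fixture_graphs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- parse_smiles_batch(fixture_smiles)
    cache
  }
})

# A tiny labelled regression fixture on those molecules
fixture_data <- function(config = tiny_config()) {
  g <- fixture_graphs()
  y <- c(1.0, 2.5, 1.8, 2.2, 0.7, 3.0)
  mpnn_data(g, y)
}

expect_uncertain_prediction <- function(pr, n) {
  expect_s3_class(pr, "uncertain_prediction")
  expect_equal(nrow(pr), n)
  expect_true(all(pr$var_epistemic >= 0))
  expect_true(all(pr$var_aleatoric >= 0))
  expect_identical(pr$var_total, pr$var_epistemic + pr$var_aleatoric)
}
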