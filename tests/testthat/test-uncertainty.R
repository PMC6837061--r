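# Confidence-error curves, variance-error rank correlation and the
# out-of-domain probe.

fake_preds <- function(means, epi, ale) {
  out <- data.frame(mean = means, var_epistemic = epi, var_aleatoric = ale,
                    var_total = epi + ale)
  class(out) <- c("uncertain_prediction", "data.frame")
  out
}

test_that("curve endpoint equals the full test RMSE and hand values match", {
  # 5 hand-written (variance, error) pairs; truths at 0, means = error
  errs <- c(0.1, 0.2, 0.4, 1.0, 2.0)
  vars <- c(1, 2, 3, 4, 5)          # variance already sorted with error
  pr <- fake_preds(errs, vars, 0 * vars)
  truths <- rep(0, 5)
  cur <- confidence_error_curve(pr, truths, kind = "epistemic",
                                grid = c(20, 40, 60, 80, 100))
  hand <- c(sqrt(mean(errs[1]^2)), sqrt(mean(errs[1:2]^2)),
            sqrt(mean(errs[1:3]^2)), sqrt(mean(errs[1:4]^2)),
            sqrt(mean(errs^2)))
  expect_equal(cur$error, hand, tolerance = 1e-12)
  expect_identical(cur$error[5], sqrt(mean(errs^2)))

  # mae variant
  cm <- confidence_error_curve(pr, truths, kind = "epistemic",
                               grid = c(40, 100), metric = "mae")
  expect_equal(cm$error, c(mean(errs[1:2]), mean(errs)), tolerance = 1e-12)
})

test_that("constant variance gives a flat curve; informative variance a rising one", {
  set.seed(3)
  errs <- rnorm(40)
  pr <- fake_preds(errs, rep(1, 40), rep(0.5, 40))
  truths <- rep(0, 40)
  cur <- confidence_error_curve(pr, truths, grid = seq(10, 100, 10))
  # ties broken by stable input order: prefix RMSEs of the input order
  hand <- vapply(seq(10, 100, 10), function(q)
    sqrt(mean(errs[seq_len(ceiling(q / 100 * 40))]^2)), numeric(1))
  expect_equal(cur$error, hand, tolerance = 1e-12)

  # variance perfectly aligned with |error|: curve is non-decreasing
  pr2 <- fake_preds(errs, abs(errs), 0 * errs)
  cur2 <- confidence_error_curve(pr2, truths, grid = seq(5, 100, 5))
  expect_true(all(diff(cur2$error) >= -1e-12))
})

test_that("spearman correlation hits its bounds and handles ties", {
  e <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  pr_up <- fake_preds(e, e * 2, 0 * e)
  pr_dn <- fake_preds(e, rev(e * 2), 0 * e)
  truths <- rep(0, 6)
  expect_equal(variance_error_spearman(pr_up, truths, "epistemic"), 1)
  expect_equal(variance_error_spearman(pr_dn, truths, "epistemic"), -1)

  # 6-point set with one tie, hand-ranked:
  v <- c(1, 2, 2, 3, 4, 5)
  pr_t <- fake_preds(e, v, 0 * v)
  hand <- cor(rank(v), rank(e))
  expect_equal(variance_error_spearman(pr_t, truths, "epistemic"), hand,
               tolerance = 1e-12)

  # negating the ranking negates the correlation
  expect_equal(variance_error_spearman(fake_preds(e, -v, 0 * v), truths,
                                       "epistemic"),
               -hand, tolerance = 1e-12)

  # constant ranks: flagged missing value
  expect_warning(
    out <- variance_error_spearman(fake_preds(e, rep(1, 6), rep(0, 6)),
                                   truths, "epistemic"),
    "undefined")
  expect_true(is.na(out))
  expect_error(variance_error_spearman(pr_up, truths[1:2], "epistemic"),
               "at least 3")
})

test_that("source ablation collapses correctly in degenerate cases", {
  set.seed(4)
  errs <- rnorm(20)
  truths <- rep(0, 20)

  # no epistemic variance: total and aleatoric curves identical
  ale <- runif(20)
  pr <- fake_preds(errs, rep(0, 20), ale)
  cur <- ablate_uncertainty_sources(pr, truths, grid = seq(10, 100, 10))
  tot <- cur[cur$variance_kind == "total", "error"]
  expect_equal(tot, cur[cur$variance_kind == "aleatoric", "error"],
               tolerance = 1e-12)

  # no aleatoric variance: total and epistemic curves identical
  pr2 <- fake_preds(errs, ale, rep(0, 20))
  cur2 <- ablate_uncertainty_sources(pr2, truths, grid = seq(10, 100, 10))
  expect_equal(cur2[cur2$variance_kind == "total", "error"],
               cur2[cur2$variance_kind == "epistemic", "error"],
               tolerance = 1e-12)
})

test_that("bias probe summarizes group shift with hand-checked medians", {
  pin <- fake_preds(rep(0, 5), c(1, 2, 3, 4, 5), rep(0, 5))
  pout <- fake_preds(rep(0, 4), c(10, 20, 30, 40), rep(0, 4))
  bp <- bias_probe(pin, pout)
  expect_equal(bp$median_in, 3)
  expect_equal(bp$median_out, 25)
  expect_equal(bp$shift, 22)
  expect_lt(bp$p_value, 0.05)
  expect_error(bias_probe(pin, fake_preds(numeric(0), numeric(0),
                                          numeric(0))),
               "empty")
})

test_that("identical groups show no spurious shift", {
  set.seed(9)
  v <- runif(50)
  pin <- fake_preds(rep(0, 50), v, rep(0, 50))
  bp <- bias_probe(pin, pin)
  expect_equal(bp$shift, 0)
  expect_gt(bp$p_value, 0.9)
})

test_that("curves export to tidy CSV", {
  pr <- fake_preds(1:5, 5:1, rep(0, 5))
  cur <- confidence_error_curve(pr, rep(0, 5), grid = c(50, 100))
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_curve_csv(cur, f)
  back <- read.csv(f)
  expect_equal(back$percentile, c(50, 100))
  expect_named(back, c("percentile", "error", "variance_kind", "metric"))
})
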