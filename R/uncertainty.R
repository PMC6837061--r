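# Uncertainty diagnostics: confidence-error curves, variance-error rank
# correlation, epistemic/aleatoric ablations and the out-of-domain
# (dataset-bias) probe.

.pick_variance <- function(preds, kind = c("total", "epistemic",
                                           "aleatoric")) {
  kind <- match.arg(kind)
  switch(kind,
         total = preds$var_total,
         epistemic = preds$var_epistemic,
         aleatoric = preds$var_aleatoric)
}

#' Confidence-error curve
#'
#' Ranks test predictions by predicted variance (confidence is the inverse
#' of uncertainty) and reports, for each confidence percentile q, the
#' error over the top-q% most confident predictions. Ties in the variance
#' ranking are broken by stable input order. The value at q = 100 is the
#' full test-set error.
#'
#' @param preds an `uncertain_prediction`.
#' @param truths numeric observed values, aligned with `preds`.
#' @param kind which variance ranks the predictions: "total", "epistemic"
#'   or "aleatoric".
#' @param grid confidence percentiles in (0, 100].
#' @param metric "rmse" (default) or "mae".
#' @return a `confidence_error_curve` data frame with columns
#'   `percentile`, `error`, `variance_kind`, `metric`.
#' @export
confidence_error_curve <- function(preds, truths,
                                   kind = c("total", "epistemic",
                                            "aleatoric"),
                                   grid = seq(5, 100, by = 5),
                                   metric = c("rmse", "mae")) {
  kind <- match.arg(kind); metric <- match.arg(metric)
  n <- nrow(preds)
  if (is.null(n) || n == 0 || length(truths) != n)
    stop("preds and truths must be non-empty and aligned")
  if (any(grid <= 0 | grid > 100)) stop("grid percentiles must lie in (0, 100]")
  v <- .pick_variance(preds, kind)
  ord <- order(v)                      # stable: ties keep input order
  err <- (preds$mean - truths)[ord]
  agg <- if (metric == "rmse") function(e) sqrt(mean(e^2))
         else function(e) mean(abs(e))
  out <- data.frame(
    percentile = grid,
    error = vapply(grid, function(q) agg(err[seq_len(ceiling(q / 100 * n))]),
                   numeric(1)),
    variance_kind = kind,
    metric = metric
  )
  class(out) <- c("confidence_error_curve", "data.frame")
  out
}

#' Spearman correlation between predicted variance and model error
#'
#' Rank correlation (average ranks for ties) between the chosen predicted
#' variance and the absolute prediction error on test points; the summary
#' statistic used to compare inference methods.
#'
#' @inheritParams confidence_error_curve
#' @return correlation in [-1, 1]; `NA` (with a warning) when either
#'   ranking is constant.
#' @export
variance_error_spearman <- function(preds, truths,
                                    kind = c("total", "epistemic",
                                             "aleatoric")) {
  kind <- match.arg(kind)
  n <- nrow(preds)
  if (is.null(n) || n < 3 || length(truths) != n)
    stop("need at least 3 aligned (prediction, truth) pairs")
  v <- .pick_variance(preds, kind)
  e <- abs(preds$mean - truths)
  if (stats::sd(rank(v)) == 0 || stats::sd(rank(e)) == 0) {
    warning("constant ranks: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(v, e, method = "spearman")
}

#' Confidence-error curves for each uncertainty source
#'
#' The ablation asks whether epistemic or aleatoric uncertainty alone
#' suffices to rank predictions: returns the curve for total, epistemic
#' and aleatoric ranking on one test set.
#'
#' @inheritParams confidence_error_curve
#' @return stacked `confidence_error_curve` rows for the three kinds.
#' @export
ablate_uncertainty_sources <- function(preds, truths,
                                       grid = seq(5, 100, by = 5),
                                       metric = "rmse") {
  out <- do.call(rbind, lapply(c("total", "epistemic", "aleatoric"),
                               function(k)
                                 confidence_error_curve(preds, truths, k,
                                                        grid, metric)))
  class(out) <- c("confidence_error_curve", "data.frame")
  out
}

#' Out-of-domain uncertainty probe
#'
#' Compares predicted total variance between an in-domain group (data like
#' the training set) and an out-of-domain group (e.g. an unseen scaffold
#' family). A model with honest epistemic uncertainty should inflate its
#' predicted variance out of domain; the claim probed is the direction of
#' the shift, tested with a two-sided rank-sum test (a single planned
#' comparison, no multiplicity correction).
#'
#' @param x either an `uncertain_prediction` for the in-domain group (with
#'   `out` the out-of-domain predictions) or a fitted `molbayes_fit` (with
#'   `out` and `out2` the in-/out-of-domain molecules to predict on).
#' @param out,... see `x`.
#' @return list with per-group medians, the median shift, the rank-sum
#'   p-value and the two total-variance vectors.
#' @export
bias_probe <- function(x, out, ...) UseMethod("bias_probe")

#' @rdname bias_probe
#' @export
bias_probe.uncertain_prediction <- function(x, out, ...) {
  vi <- x$var_total; vo <- out$var_total
  if (length(vi) == 0 || length(vo) == 0) stop("empty prediction group")
  wt <- suppressWarnings(stats::wilcox.test(vo, vi))
  list(median_in = stats::median(vi),
       median_out = stats::median(vo),
       shift = stats::median(vo) - stats::median(vi),
       p_value = wt$p.value,
       var_in = vi, var_out = vo)
}

#' Write curves to tidy CSV
#' @param curve a `confidence_error_curve`; `path` output file.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
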