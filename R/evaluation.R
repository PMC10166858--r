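#' Match predicted to ground-truth change-points and compute the MAE
#'
#' Pairs every ground-truth change-point with its nearest predicted one
#' (ties broken towards the earlier predicted index; predicted points may be
#' reused) and returns the mean absolute index distance over ground-truth
#' points. When nothing was predicted the maximal penalty `mae = n` is
#' returned with a warning. False positives are not penalized here -- they
#' enter through the prediction ratio in [prediction_loss_mae()].
#'
#' @param pred Integer vector of predicted change-points (may be empty).
#' @param gt Integer vector of ground-truth change-points (non-empty).
#' @param n Series length in time steps.
#' @return List with `pairs` (tibble: gt, pred, error) and `mae`.
#' @export
match_and_mae <- function(pred, gt, n) {
  gt <- validate_changepoints(gt, n)
  if (length(gt) == 0) abort("ground truth must contain at least one change-point")
  pred <- sort(as.integer(pred))
  if (length(pred) == 0) {
    warn("no predicted change-points; assigning the maximal penalty mae = n")
    return(list(
      pairs = tibble(gt = gt, pred = NA_integer_, error = as.numeric(n)),
      mae = as.numeric(n)
    ))
  }
  matched <- vapply(gt, function(g) {
    d <- abs(pred - g)
    pred[which.min(d)]   # first minimum = earlier predicted index on ties
  }, integer(1))
  err <- abs(matched - gt)
  list(pairs = tibble(gt = gt, pred = matched, error = as.numeric(err)),
       mae = mean(err))
}

#' ScoreRegimes: normalized change-point error
#'
#' Sum of matched absolute errors divided by the number of ground-truth
#' change-points times the series length -- equivalently the matched MAE
#' divided by `n`. 0 is a perfect segmentation; values are comparable across
#' recordings of different lengths and change-point counts.
#'
#' @inheritParams match_and_mae
#' @return Single non-negative number.
#' @export
#' @examples
#' score_regimes(pred = c(110), gt = c(100), n = 1000) # 0.01
score_regimes <- function(pred, gt, n) {
  if (n <= 0) abort("n must be positive")
  match_and_mae(pred, gt, n)$mae / n
}

#' Prediction Loss MAE: count-aware error for online extraction
#'
#' Online extractors do not know the true number of change-points, so the
#' matched MAE alone can reward over-prediction (a dense spray of predicted
#' points puts something near every true change-point). This metric weights
#' the MAE by the deviation of the prediction ratio `N_pred / N_GT` from 1.
#' Two interpretations of the combination are provided:
#'
#' * `"inflation_default"` (default): `(1 + |1 - N_pred/N_GT|) * mae`, so a
#'   correct count gives exactly the MAE and count errors inflate it;
#' * `"as_printed_abs"`: `|1 - N_pred/N_GT| * mae`, the combination as
#'   printed in the source description -- note it collapses to 0 whenever
#'   the count is correct, regardless of the MAE.
#'
#' Results should always be labeled with the interpretation used.
#'
#' @inheritParams match_and_mae
#' @param interpretation `"inflation_default"` or `"as_printed_abs"`.
#' @return Single non-negative number.
#' @export
prediction_loss_mae <- function(pred, gt, n,
                                interpretation = c("inflation_default",
                                                   "as_printed_abs")) {
  interpretation <- match.arg(interpretation)
  gt <- validate_changepoints(gt, n)
  if (length(gt) == 0) abort("ground truth must contain at least one change-point")
  mm <- match_and_mae(pred, gt, n)
  dev <- abs(1 - length(pred) / length(gt))
  switch(interpretation,
    inflation_default = (1 + dev) * mm$mae,
    as_printed_abs = dev * mm$mae
  )
}

#' Score one segmentation
#'
#' All segmentation metrics for one recording, as a one-row tibble.
#'
#' @inheritParams prediction_loss_mae
#' @return Tibble with columns `n_pred`, `n_gt`, `prediction_ratio`, `mae`,
#'   `score_regimes`, `prediction_loss_mae`, `n`, `interpretation`.
#' @export
score_segmentation <- function(pred, gt, n,
                               interpretation = c("inflation_default",
                                                  "as_printed_abs")) {
  interpretation <- match.arg(interpretation)
  mm <- match_and_mae(pred, gt, n)
  tibble(
    n_pred = length(pred),
    n_gt = length(gt),
    prediction_ratio = length(pred) / length(gt),
    mae = mm$mae,
    score_regimes = mm$mae / n,
    prediction_loss_mae = prediction_loss_mae(pred, gt, n, interpretation),
    n = as.integer(n),
    interpretation = interpretation
  )
}

#' Score a collection of recordings
#'
#' Per-recording scores plus their unweighted means, the form in which
#' segmentation algorithms are compared across a dataset of recordings.
#'
#' @param results List of lists, each with elements `pred`, `gt`, `n` (and
#'   optionally `id`).
#' @inheritParams prediction_loss_mae
#' @return List with `per_recording` (tibble, one row each) and `summary`
#'   (one-row tibble of means).
#' @export
score_dataset <- function(results,
                          interpretation = c("inflation_default",
                                             "as_printed_abs")) {
  interpretation <- match.arg(interpretation)
  if (length(results) < 1) abort("need at least one recording")
  rows <- purrr::imap(results, function(res, idx) {
    dplyr::mutate(
      score_segmentation(res$pred, res$gt, res$n, interpretation),
      id = res$id %||% as.character(idx), .before = 1
    )
  })
  per <- dplyr::bind_rows(rows)
  summary <- dplyr::summarise(
    per,
    mean_score_regimes = mean(.data$score_regimes),
    mean_mae = mean(.data$mae),
    mean_prediction_ratio = mean(.data$prediction_ratio),
    mean_prediction_loss_mae = mean(.data$prediction_loss_mae),
    n_recordings = dplyr::n()
  )
  list(per_recording = per, summary = summary)
}
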