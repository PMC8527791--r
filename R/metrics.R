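r_squared <- function(y, yhat) {
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  1 - ss_res / ss_tot
}

#' Evaluation metrics for one trait
#'
#' The three metrics reported per trait over a test partition:
#' \itemize{
#'   \item `r2` — coefficient of determination
#'     \eqn{1 - \sum(y-\hat y)^2 / \sum(y-\bar y)^2}; may be negative when a
#'     model underperforms the mean predictor.
#'   \item `abs_bias_pct` — absolute relative bias,
#'     \eqn{|100 (\overline{\hat y} - \bar y) / \bar y|}.
#'   \item `rep` — relative error of prediction,
#'     \eqn{100 \cdot RMSE / |\bar y|}, the RMSE as a percentage of the
#'     observed mean.
#' }
#'
#' @param y Observed trait values (at least 2, non-constant).
#' @param yhat Predicted values, same length.
#' @return Named numeric vector `c(r2, abs_bias_pct, rep)`.
#' @export
#' @examples
#' compute_metrics(c(1, 2, 3), c(1, 2, 3))  # 1, 0, 0
compute_metrics <- function(y, yhat) {
  if (length(y) != length(yhat)) stop_validation("y and yhat differ in length")
  if (length(y) < 2L) stop_validation("need at least 2 pairs")
  if (stats::var(y) == 0) stop_validation("y has zero variance: R-squared undefined")
  if (mean(y) == 0) stop_validation("mean(y) is zero: percentage metrics undefined")
  rmse <- sqrt(mean((y - yhat)^2))
  c(r2 = r_squared(y, yhat),
    abs_bias_pct = abs(100 * (mean(yhat) - mean(y)) / mean(y)),
    rep = 100 * rmse / abs(mean(y)))
}

#' Per-trait test metrics for a fitted model
#'
#' Predicts the requested partition and computes [compute_metrics()] per
#' trait over the observed (masked-in) pairs, plus the across-trait mean.
#'
#' @param model A fitted model (anything with a `predict` method returning an
#'   observations-by-traits matrix).
#' @param data A [split_dataset()].
#' @param partition Partition to evaluate (default `"test"`).
#' @param traits Traits to report; defaults to the intersection of the
#'   model's and the data's traits.
#' @return Data frame with columns `trait`, `n`, `r2`, `abs_bias_pct`, `rep`;
#'   the final row `mean` averages the metric columns.
#' @export
evaluate_model <- function(model, data,
                           partition = c("test", "validation", "train"),
                           traits = NULL) {
  partition <- match.arg(partition)
  part <- split_part(data, partition)
  pred <- stats::predict(model, part$x)
  if (is.null(traits)) traits <- intersect(colnames(pred), colnames(part$y))
  rows <- lapply(traits, function(trait) {
    m <- part$mask[, trait]
    data.frame(trait = trait, n = sum(m),
               t(compute_metrics(part$y[m, trait], pred[m, trait])))
  })
  out <- do.call(rbind, rows)
  rbind(out, data.frame(trait = "mean", n = NA_integer_,
                        r2 = mean(out$r2), abs_bias_pct = mean(out$abs_bias_pct),
                        rep = mean(out$rep)))
}

#' Average metric reports over runs
#'
#' Reported results are conventionally the mean of several runs with
#' different random seeds; this averages the numeric columns of
#' [evaluate_model()] outputs row-wise.
#'
#' @param reports List of data frames with identical `trait` columns.
#' @return A single averaged data frame with a `seeds` attribute when the
#'   inputs carry one.
#' @export
aggregate_reports <- function(reports) {
  stopifnot(length(reports) >= 1L)
  out <- reports[[1L]]
  for (col in c("r2", "abs_bias_pct", "rep"))
    out[[col]] <- rowMeans(vapply(reports, `[[`, numeric(nrow(out)), col))
  out
}
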