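#' Mean relative error (percent)
#'
#' `MRE = 100/N * sum_i |y_i - yhat_i| / |y_i|`. The square root of the
#' squared ratio in the defining formula is algebraically the absolute
#' value, which is what is computed. Truth values with magnitude below
#' `eps` are rejected (the surrogate guarantees strictly positive TAWSS).
#'
#' @param y per-point ground truth.
#' @param yhat per-point prediction, same length.
#' @param eps guard on the denominators, Pa.
#' @return MRE in percent (scalar).
#' @examples
#' mre(c(10, 10), c(11, 9))  # 10
#' @export
mre <- function(y, yhat, eps = 1e-12) {
  if (length(y) != length(yhat)) {
    stop("y and yhat differ in length", call. = FALSE)
  }
  bad <- which(abs(y) <= eps)
  if (length(bad)) {
    stop("near-zero truth values at indices: ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  mean(abs(y - yhat) / abs(y)) * 100
}

#' Normalized absolute mean error (percent)
#'
#' `NAME = 100/N * sum_i |y_i - yhat_i| / (max{y} - min{y})`, where the
#' normalizing range is the dataset-global TAWSS range taken over every
#' point of every generated model (not the per-model range).
#'
#' @param y,yhat per-point truth / prediction.
#' @param global_max,global_min dataset-global TAWSS extremes, Pa.
#' @return NAME in percent (scalar).
#' @examples
#' name_metric(c(0, 10), c(1, 9), 10, 0)  # 10
#' @export
name_metric <- function(y, yhat, global_max, global_min) {
  if (length(y) != length(yhat)) {
    stop("y and yhat differ in length", call. = FALSE)
  }
  if (!(global_max > global_min)) {
    stop("global_max must exceed global_min", call. = FALSE)
  }
  mean(abs(y - yhat)) / (global_max - global_min) * 100
}

#' Per-model error report
#'
#' Computes MRE and NAME per model plus their mean and standard deviation
#' across models (the across-model convention used for headline figures).
#'
#' @param truth named list of truth vectors (or `tawss_field`s).
#' @param pred named list of prediction vectors aligned to `truth`.
#' @param global_max,global_min dataset-global TAWSS extremes.
#' @return Object of class `tawss_metrics`: `per_model` data.frame
#'   (`model_id`, `mre`, `name`, `n_points`) and `summary` (mean/sd rows).
#' @export
metric_report <- function(truth, pred, global_max, global_min) {
  ids <- names(truth)
  stopifnot(!is.null(ids), setequal(ids, names(pred)))
  val <- function(x) if (inherits(x, "tawss_field")) x$values else as.numeric(x)
  per <- do.call(rbind, lapply(ids, function(id) {
    y <- val(truth[[id]]); yh <- val(pred[[id]])
    data.frame(model_id = id,
               mre = mre(y, yh),
               name = name_metric(y, yh, global_max, global_min),
               n_points = length(y), stringsAsFactors = FALSE)
  }))
  summ <- data.frame(metric = c("mre", "name"),
                     mean = c(mean(per$mre), mean(per$name)),
                     sd = c(stats::sd(per$mre), stats::sd(per$name)))
  structure(list(per_model = per, summary = summ,
                 global_max = global_max, global_min = global_min),
            class = "tawss_metrics")
}

#' @export
print.tawss_metrics <- function(x, ...) {
  s <- x$summary
  cat(sprintf("TAWSS errors over %d models:\n", nrow(x$per_model)))
  cat(sprintf("  MRE  = %.2f +/- %.2f %%\n", s$mean[1], s$sd[1]))
  cat(sprintf("  NAME = %.2f +/- %.2f %%\n", s$mean[2], s$sd[2]))
  invisible(x)
}

#' Serialize a metric report
#'
#' Writes the per-model table as CSV and the full report (per-model rows,
#' summary, normalization constants) as JSON.
#'
#' @param report a `tawss_metrics`.
#' @param csv,json output paths (either may be `NULL` to skip).
#' @return `report`, invisibly.
#' @export
write_metrics <- function(report, csv = NULL, json = NULL) {
  if (!is.null(csv)) utils::write.csv(report$per_model, csv, row.names = FALSE)
  if (!is.null(json)) {
    jsonlite::write_json(unclass(report), json, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  }
  invisible(report)
}
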