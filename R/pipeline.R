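#' tawssnet: point-cloud deep-learning surrogates for coronary TAWSS
#'
#' End-to-end pipeline: parametric idealized LM/LAD/LCx bifurcation
#' geometries sampled as structured surface point clouds, a pulsatile
#' Carreau-Yasuda wall-shear surrogate labelling each cloud with
#' time-averaged wall shear stress, PCA canonical point ordering, a compact
#' convolutional U-Net regressing per-point TAWSS from coordinates, and the
#' MRE/NAME error metrics.
#'
#' @useDynLib tawssnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @keywords internal
"_PACKAGE"

#' Run the full surrogate experiment in one call
#'
#' Samples morphologies, builds the split manifest batch-wise, generates
#' the labeled dataset, fits the U-Net, and evaluates on the held-out test
#' split. Problem sizes are arguments so the same driver serves both quick
#' smoke runs and full experiments.
#'
#' @param n_models total models to generate.
#' @param split_batch,test_per_batch,val_frac split-manifest parameters
#'   (test ids drawn per consecutive batch; validation fraction of the
#'   remainder).
#' @param grid_rows,grid_cols structured grid per model.
#' @param config a [unet_config()] (its grid must match).
#' @param ordering point ordering method.
#' @param seed master seed (drives morphology sampling, splits and network
#'   initialization).
#' @param out_dir optional run directory; when given, the dataset
#'   (`manifest.json`, `models/*.ply`) and a metric report
#'   (`reports/test_metrics.{csv,json}`) are written there.
#' @param ranges a [morph_ranges()].
#' @param geometry_cfg,surrogate_cfg geometry and surrogate configuration.
#' @param overwrite passed to [write_dataset()].
#' @param verbose print progress.
#' @return List with `model` (`tawss_unet`), `metrics` (`tawss_metrics`),
#'   `data` (`tawss_dataset`) and `manifest`.
#' @export
run_tawss_pipeline <- function(n_models = 300L, split_batch = 50L,
                               test_per_batch = 10L, val_frac = 0.10,
                               grid_rows = 32L, grid_cols = 32L,
                               config = NULL, ordering = "pca", seed = 0L,
                               out_dir = NULL, ranges = morph_ranges(),
                               geometry_cfg = geometry_config(),
                               surrogate_cfg = surrogate_config(),
                               overwrite = FALSE, verbose = FALSE) {
  if (is.null(config)) {
    config <- unet_config(grid_rows = grid_rows, grid_cols = grid_cols,
                          seed = seed)
  }
  morph <- sample_morphologies(ranges, n = n_models, seed = seed)
  manifest <- make_splits(morph$model_id, batch_size = split_batch,
                          test_per_batch = test_per_batch,
                          val_frac = val_frac, seed = seed)
  data <- generate_tawss_data(morph, manifest, grid_rows = grid_rows,
                              grid_cols = grid_cols,
                              geometry_cfg = geometry_cfg,
                              surrogate_cfg = surrogate_cfg,
                              progress = verbose)
  manifest <- data$manifest
  model <- tawss_unet(data, config = config, ordering = ordering,
                      verbose = verbose)
  metrics <- if (length(manifest$test_ids)) {
    evaluate_tawss(model, data, split = "test")
  } else NULL
  if (!is.null(out_dir)) {
    write_dataset(data, out_dir, overwrite = overwrite)
    dir.create(file.path(out_dir, "reports"), showWarnings = FALSE)
    if (!is.null(metrics)) {
      write_metrics(metrics,
                    csv = file.path(out_dir, "reports", "test_metrics.csv"),
                    json = file.path(out_dir, "reports", "test_metrics.json"))
    }
  }
  list(model = model, metrics = metrics, data = data, manifest = manifest)
}

#' Ordering ablation: PCA versus axis orderings
#'
#' Trains one U-Net per ordering method on the same dataset, manifest,
#' seeds and budgets, and reports test-split MRE and NAME (mean and sd over
#' test models) per arm.
#'
#' @param data a labeled `tawss_dataset` with a split manifest.
#' @param config a [unet_config()] shared by all arms.
#' @param orderings character vector of arms.
#' @param verbose print per-arm progress.
#' @return Object of class `ordering_ablation`: data.frame with one row per
#'   ordering and columns `ordering`, `mre_mean`, `mre_sd`, `name_mean`,
#'   `name_sd`, plus a `models` attribute holding the fitted arms.
#' @export
ablate_ordering <- function(data, config = NULL,
                            orderings = c("x", "y", "z", "pca"),
                            verbose = FALSE) {
  if (is.null(config)) {
    config <- unet_config(grid_rows = data$grid_rows,
                          grid_cols = data$grid_cols)
  }
  models <- list()
  rows <- lapply(orderings, function(o) {
    if (verbose) cat("ordering:", o, "\n")
    m <- tawss_unet(data, config = config, ordering = o, verbose = FALSE)
    models[[o]] <<- m
    rep <- evaluate_tawss(m, data, split = "test")
    s <- rep$summary
    data.frame(ordering = o,
               mre_mean = s$mean[1], mre_sd = s$sd[1],
               name_mean = s$mean[2], name_sd = s$sd[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "models") <- models
  class(out) <- c("ordering_ablation", "data.frame")
  out
}

#' @export
print.ordering_ablation <- function(x, ...) {
  cat("Ordering ablation (test split):\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-4s  MRE %6.2f +/- %5.2f %%   NAME %5.2f +/- %4.2f %%\n",
                x$ordering[i], x$mre_mean[i], x$mre_sd[i], x$name_mean[i],
                x$name_sd[i]))
  }
  invisible(x)
}
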