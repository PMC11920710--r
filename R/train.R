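# Training front-end: assembles ordered/normalized tensors from a labeled
# dataset, runs Adam with the staircase learning-rate schedule, early-stops
# on validation NAME, and exposes the usual modelling-object methods.

prep_model_matrix <- function(cloud, field, method, input_scale, t_min,
                              t_max) {
  # coordinates stay in the shared canonical frame (bifurcation origin at 0)
  # and are only rescaled: the common origin anchors the junction for the net
  o <- order_cloud(cloud$coords, method)
  X <- cloud$coords[o$permutation, , drop = FALSE] / input_scale
  tgt <- if (is.null(field)) NULL else {
    matrix((field$values[o$permutation] - t_min) / (t_max - t_min), ncol = 1L)
  }
  list(X = X, target = tgt, ordering = o)
}

dataset_input_scale <- function(clouds) {
  mean(vapply(clouds, function(cl) sqrt(mean(cl$coords^2)), numeric(1)))
}

#' Fit the point-cloud U-Net TAWSS regressor
#'
#' The one-call model fit: canonically orders every cloud (PCA by default),
#' rescales the canonical-frame coordinates by a dataset-global factor,
#' min-max-normalizes the TAWSS targets by the dataset-global range from
#' the manifest, and trains the U-Net of [unet_config()] with Adam under
#' the staircase learning-rate schedule, tracking validation NAME per epoch
#' and restoring the best-validation weights.
#'
#' @param data a `tawss_dataset` from [generate_tawss_data()].
#' @param config a [unet_config()]; its grid must match the dataset.
#' @param ordering point ordering: `"pca"`, `"x"`, `"y"` or `"z"`.
#' @param manifest a `split_manifest`; defaults to the one on `data`.
#' @param verbose print one line per epoch.
#' @return Object of class `tawss_unet` (trained), with `history` (one row
#'   per epoch: `epoch`, `lr`, `train_mse`, `val_name`), `norm`
#'   (normalization constants), `parameter_count` and the validation
#'   residuals of the best epoch.
#' @seealso [predict.tawss_unet()], [evaluate_tawss()], [ablate_ordering()]
#' @export
tawss_unet <- function(data, config = unet_config(), ordering = "pca",
                       manifest = data$manifest, verbose = FALSE) {
  model <- build_unet(config)
  train_unet(model, data, manifest = manifest, ordering = ordering,
             verbose = verbose)
}

#' Train (or continue training) a built U-Net on a labeled dataset
#'
#' @param model an (untrained) model from [build_unet()].
#' @inheritParams tawss_unet
#' @param epochs,batch_size optional overrides of the model config.
#' @return The trained `tawss_unet`.
#' @export
train_unet <- function(model, data, manifest = data$manifest,
                       ordering = "pca", epochs = NULL, batch_size = NULL,
                       verbose = FALSE) {
  cfg <- model$config
  if (!is.null(epochs)) cfg$epochs <- as.integer(epochs)
  if (!is.null(batch_size)) cfg$batch_size <- as.integer(batch_size)
  npts <- data$grid_rows * data$grid_cols
  if (npts != cfg$points || data$grid_rows != cfg$grid_rows) {
    stop("dataset grid ", data$grid_rows, " x ", data$grid_cols,
         " does not match the model config", call. = FALSE)
  }
  if (is.null(manifest)) {
    manifest <- make_splits(names(data$clouds),
                            batch_size = length(data$clouds),
                            test_per_batch = 0L, val_frac = 0, seed = 0L)
  }
  t_min <- data$tawss_global_min %||% manifest$tawss_global_min
  t_max <- data$tawss_global_max %||% manifest$tawss_global_max
  if (!is.finite(t_min) || !is.finite(t_max) || t_max <= t_min) {
    stop("manifest lacks valid dataset-global TAWSS extremes", call. = FALSE)
  }
  ordering <- match.arg(tolower(ordering), c("pca", "x", "y", "z"))
  train_ids <- intersect(manifest$train_ids, names(data$clouds))
  val_ids <- intersect(manifest$val_ids, names(data$clouds))
  if (length(train_ids) == 0L) stop("no training models in manifest", call. = FALSE)

  input_scale <- dataset_input_scale(data$clouds[train_ids])
  prep <- function(id) {
    prep_model_matrix(data$clouds[[id]], data$fields[[id]], ordering,
                      input_scale, t_min, t_max)
  }
  tr <- lapply(train_ids, prep); names(tr) <- train_ids
  va <- lapply(val_ids, prep); names(va) <- val_ids

  n_tr <- length(tr)
  bsz <- min(cfg$batch_size, n_tr)
  range_t <- t_max - t_min
  const_name <- NA_real_
  if (length(va)) {
    ybar <- mean(unlist(lapply(tr, function(m) m$target)))
    const_name <- mean(vapply(va, function(m) {
      mean(abs(m$target - ybar)) * 100
    }, numeric(1)))
  }

  history <- vector("list", cfg$epochs)
  best <- list(val = Inf, params = model$params, bn = model$bn_state,
               epoch = 0L, residuals = NULL)
  opt <- adam_init(model$params)
  step <- 0L
  with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      perm <- sample(n_tr)
      ep_loss <- 0; n_batch <- 0L
      for (start in seq(1L, n_tr, by = bsz)) {
        ids <- perm[start:min(start + bsz - 1L, n_tr)]
        B <- length(ids)
        X <- do.call(rbind, lapply(tr[ids], `[[`, "X"))
        tg <- do.call(rbind, lapply(tr[ids], `[[`, "target"))
        fw <- unet_forward(model, X, B, training = TRUE, keep = TRUE)
        model$bn_state <- fw$bn_state
        err <- fw$y - tg
        loss <- mean(err^2)
        lr <- staircase_lr(cfg$lr0, cfg$decay_rate, cfg$decay_every, step)
        if (!is.finite(loss)) {
          stop("NaN/Inf training loss at epoch ", ep, ", batch ",
               n_batch + 1L, ", lr ", signif(lr, 4), call. = FALSE)
        }
        gr <- unet_backward(model, fw$cache, 2 * err / length(err))
        up <- adam_step(model$params, gr, opt, lr)
        model$params <- up$params; opt <- up$state
        step <- step + 1L
        ep_loss <- ep_loss + loss; n_batch <- n_batch + 1L
      }
      val_name <- NA_real_
      if (length(va)) {
        res <- lapply(va, function(m) {
          yh <- unet_forward(model, m$X, 1L, training = FALSE)$y
          drop(yh - m$target)
        })
        val_name <- mean(vapply(res, function(r) mean(abs(r)) * 100,
                                numeric(1)))
        if (val_name < best$val) {
          best <- list(val = val_name, params = model$params,
                       bn = model$bn_state, epoch = ep,
                       residuals = lapply(res, function(r) r * range_t))
        }
      }
      history[[ep]] <- data.frame(
        epoch = ep, lr = staircase_lr(cfg$lr0, cfg$decay_rate,
                                      cfg$decay_every, step),
        train_mse = ep_loss / n_batch, val_name = val_name)
      if (verbose) {
        cat(sprintf("epoch %3d  mse %.3e  val NAME %s\n", ep,
                    ep_loss / n_batch,
                    if (is.na(val_name)) "-" else sprintf("%.3f%%", val_name)))
      }
      if (length(va) && is.finite(cfg$patience) &&
          ep - best$epoch >= cfg$patience) break
    }
  })
  if (length(va)) {
    model$params <- best$params
    model$bn_state <- best$bn
  }
  model$trained <- TRUE
  model$config <- cfg
  model$history <- do.call(rbind, history[!vapply(history, is.null,
                                                  logical(1))])
  model$norm <- list(input_scale = input_scale, tawss_min = t_min,
                     tawss_max = t_max)
  model$ordering_method <- ordering
  model$val_residuals <- best$residuals
  model$best_val_name <- if (length(va)) best$val else NA_real_
  model$const_baseline_val_name <- const_name
  model$manifest <- manifest
  model
}

#' Predict per-point TAWSS for new clouds
#'
#' Orders the cloud with the ordering the model was trained with, runs the
#' forward pass in inference mode, de-normalizes, and returns the values in
#' the original point order of the cloud.
#'
#' @param object a trained `tawss_unet`.
#' @param newdata a `surface_cloud`, a list of them, or a `tawss_dataset`.
#' @param ... unused.
#' @return A `tawss_field` (or named list of them).
#' @export
predict.tawss_unet <- function(object, newdata, ...) {
  if (!object$trained) stop("model is not trained", call. = FALSE)
  if (inherits(newdata, "tawss_dataset")) newdata <- newdata$clouds
  single <- inherits(newdata, "surface_cloud")
  clouds <- if (single) list(newdata) else newdata
  cfg <- object$config
  nm <- object$norm
  out <- lapply(clouds, function(cl) {
    if (nrow(cl$coords) != cfg$points) {
      stop("cloud has ", nrow(cl$coords), " points; model expects ",
           cfg$points, call. = FALSE)
    }
    m <- prep_model_matrix(cl, NULL, object$ordering_method, nm$input_scale,
                           nm$tawss_min, nm$tawss_max)
    yh <- drop(unet_forward(object, m$X, 1L, training = FALSE)$y)
    vals <- numeric(cfg$points)
    vals[m$ordering$permutation] <- yh * (nm$tawss_max - nm$tawss_min) +
      nm$tawss_min
    structure(list(values = vals, model_id = cl$model_id),
              class = "tawss_field")
  })
  if (single) out[[1]] else out
}

#' Evaluate a trained model on a dataset split
#'
#' @param object a trained `tawss_unet`.
#' @param data a `tawss_dataset` holding the clouds and true fields.
#' @param split `"test"`, `"val"` or `"train"` (ids from the manifest used
#'   at fit time unless `manifest` is given).
#' @param manifest optional `split_manifest` override.
#' @return A `tawss_metrics` report (per-model MRE/NAME + mean/sd).
#' @export
evaluate_tawss <- function(object, data, split = c("test", "val", "train"),
                           manifest = NULL) {
  split <- match.arg(split)
  man <- manifest %||% object$manifest
  ids <- intersect(man[[paste0(split, "_ids")]], names(data$clouds))
  if (!length(ids)) stop("no '", split, "' models found in the dataset",
                         call. = FALSE)
  t_min <- object$norm$tawss_min; t_max <- object$norm$tawss_max
  d_min <- data$tawss_global_min; d_max <- data$tawss_global_max
  if (is.finite(d_min) &&
      (abs(d_min - t_min) > 1e-9 * max(1, abs(t_min)) ||
       abs(d_max - t_max) > 1e-9 * max(1, abs(t_max)))) {
    stop("normalization constants of model and dataset disagree (",
         signif(t_min, 6), "/", signif(t_max, 6), " vs ",
         signif(d_min, 6), "/", signif(d_max, 6), ")", call. = FALSE)
  }
  preds <- predict(object, data$clouds[ids])
  metric_report(data$fields[ids], preds, global_max = t_max,
                global_min = t_min)
}

#' @export
print.tawss_unet <- function(x, ...) {
  cfg <- x$config
  cat("Point-cloud U-Net TAWSS regressor\n")
  cat(sprintf("  grid %d x %d (%d points), width %d, %d levels, %s\n",
              cfg$grid_rows, cfg$grid_cols, cfg$points, cfg$width,
              cfg$levels,
              if (cfg$skip_connections) "skip connections" else "no skips"))
  cat(sprintf("  parameters: %d\n", x$parameter_count))
  if (x$trained) {
    cat(sprintf("  trained %d epochs (ordering: %s)", nrow(x$history),
                x$ordering_method))
    if (is.finite(x$best_val_name)) {
      cat(sprintf(", best val NAME %.2f%%", x$best_val_name))
    }
    cat("\n")
  } else cat("  untrained\n")
  invisible(x)
}

#' @export
summary.tawss_unet <- function(object, ...) {
  cfg <- object$config
  sizes <- cfg$grid_rows / 2^(0:cfg$levels)
  structure(list(model = object,
                 encoder_sizes = sizes,
                 config = cfg),
            class = "summary.tawss_unet")
}

#' @export
print.summary.tawss_unet <- function(x, ...) {
  print(x$model)
  cat("  encoder spatial sizes:", paste(x$encoder_sizes, collapse = " -> "),
      "\n")
  cat(sprintf("  lr schedule: %.4g x %.2f^(step/%d)\n", x$config$lr0,
              x$config$decay_rate, x$config$decay_every))
  if (!is.null(x$model$history)) {
    h <- x$model$history
    cat(sprintf("  final train MSE %.3e; baseline (constant-mean) val NAME %s\n",
                h$train_mse[nrow(h)],
                if (is.finite(x$model$const_baseline_val_name))
                  sprintf("%.2f%%", x$model$const_baseline_val_name)
                else "-"))
  }
  invisible(x)
}

#' @export
coef.tawss_unet <- function(object, ...) object$params

#' @export
residuals.tawss_unet <- function(object, newdata = NULL, data = NULL, ...) {
  if (is.null(newdata)) {
    if (is.null(object$val_residuals)) {
      stop("no stored validation residuals; supply newdata and data",
           call. = FALSE)
    }
    return(object$val_residuals)
  }
  stopifnot(inherits(newdata, "tawss_dataset"))
  preds <- predict(object, newdata$clouds)
  Map(function(f, p) f$values - p$values, newdata$fields[names(preds)], preds)
}

#' @export
plot.tawss_unet <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop("model has no training history", call. = FALSE)
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$train_mse, type = "l", log = "y",
                 xlab = "epoch", ylab = "train MSE (normalized)",
                 main = "training loss", ...)
  if (any(is.finite(h$val_name))) {
    graphics::plot(h$epoch, h$val_name, type = "l", xlab = "epoch",
                   ylab = "validation NAME (%)", main = "validation error",
                   ...)
  }
  invisible(x)
}
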