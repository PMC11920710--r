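#' Morphological parameter ranges for an idealized left-coronary bifurcation
#'
#' The bifurcation is described by five parameters: the diameters of the left
#' main (LM), left circumflex (LCx) and left anterior descending (LAD)
#' arteries, the LM--LAD bend angle `gamma` (180 degrees = straight
#' continuation) and the LAD--LCx opening angle `alpha`. Defaults are the
#' literature ranges for healthy adult left-coronary anatomy used to build
#' the training population.
#'
#' @param d_lm,d_lcx,d_lad length-2 numeric, min/max diameter in mm.
#' @param gamma length-2 numeric, min/max LM--LAD angle in degrees.
#' @param alpha length-2 numeric, min/max LAD--LCx angle in degrees.
#' @return An object of class `morph_ranges`.
#' @examples
#' r <- morph_ranges()
#' r$d_lm
#' @export
morph_ranges <- function(d_lm = c(2.18, 4.18),
                         d_lcx = c(1.5, 3.5),
                         d_lad = c(1.5, 3.5),
                         gamma = c(112.75, 172.75),
                         alpha = c(15, 130)) {
  r <- list(d_lm = as.numeric(d_lm), d_lcx = as.numeric(d_lcx),
            d_lad = as.numeric(d_lad), gamma = as.numeric(gamma),
            alpha = as.numeric(alpha))
  for (nm in names(r)) {
    v <- r[[nm]]
    if (length(v) != 2L || anyNA(v)) {
      stop("range '", nm, "' must be two finite numbers", call. = FALSE)
    }
    if (v[1] > v[2]) {
      stop("invalid range for '", nm, "': min ", v[1], " > max ", v[2],
           call. = FALSE)
    }
  }
  if (any(c(r$d_lm, r$d_lcx, r$d_lad) <= 0)) {
    stop("diameter ranges must be positive", call. = FALSE)
  }
  if (any(c(r$gamma, r$alpha) <= 0) || any(c(r$gamma, r$alpha) >= 180)) {
    stop("angle ranges must lie in (0, 180) degrees", call. = FALSE)
  }
  structure(r, class = "morph_ranges")
}

assert_strict_ranges <- function(ranges) {
  for (nm in names(unclass(ranges))) {
    v <- ranges[[nm]]
    if (v[1] >= v[2]) {
      stop("degenerate range for '", nm, "': min ", v[1], " >= max ", v[2],
           call. = FALSE)
    }
  }
  invisible(ranges)
}

#' Sample a population of bifurcation morphologies
#'
#' Draws `n` parameter vectors from `ranges`, either by seeded independent
#' uniform sampling per parameter (default) or by a Latin hypercube. Output
#' is reproducible: identical `(ranges, n, seed, method)` give identical
#' draws.
#'
#' @param ranges a [morph_ranges()] object.
#' @param n number of models to draw.
#' @param seed integer RNG seed.
#' @param method `"uniform"` for independent uniforms, `"lhs"` for a random
#'   Latin hypercube (via the \pkg{lhs} package).
#' @return A data.frame with columns `model_id`, `d_lm`, `d_lcx`, `d_lad`,
#'   `gamma`, `alpha`; one row per model.
#' @examples
#' m <- sample_morphologies(morph_ranges(), n = 5, seed = 1)
#' range(m$alpha)
#' @export
sample_morphologies <- function(ranges = morph_ranges(), n, seed = 0L,
                                method = c("uniform", "lhs")) {
  method <- match.arg(method)
  stopifnot(inherits(ranges, "morph_ranges"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer", call. = FALSE)
  nms <- c("d_lm", "d_lcx", "d_lad", "gamma", "alpha")
  degenerate <- vapply(nms, function(f) ranges[[f]][1] == ranges[[f]][2],
                       logical(1))
  u <- with_seed(seed, {
    if (method == "uniform") {
      matrix(stats::runif(n * 5L), nrow = n, ncol = 5L)
    } else {
      lhs::randomLHS(n, 5L)
    }
  })
  out <- data.frame(model_id = sprintf("m%04d", seq_len(n) - 1L),
                    stringsAsFactors = FALSE)
  for (k in seq_along(nms)) {
    v <- ranges[[nms[k]]]
    out[[nms[k]]] <- if (degenerate[k]) rep(v[1], n) else v[1] + u[, k] * (v[2] - v[1])
  }
  out
}

# save/restore the global RNG state so sampling helpers are seeded but do not
# perturb the caller's stream
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

with_seed <- function(seed, expr) {
  old <- .Random.seed_exists()
  on.exit(restore_seed(old))
  set.seed(as.integer(seed))
  expr
}

#' Build a reproducible train/validation/test split manifest
#'
#' Test models are drawn batch-wise: the ordered id list is cut into
#' consecutive batches of `batch_size` and `test_per_batch` ids are selected
#' uniformly at random (seeded) from each batch. From the remaining pool a
#' fraction `val_frac` (rounded half to even) is drawn for validation; the
#' rest is the training set. With the dataset-scale defaults (1800 ids,
#' batches of 300, 60 per batch, 10 percent validation) this yields 360 test,
#' 144 validation and 1296 training models.
#'
#' @param model_ids character vector of model identifiers, in generation order.
#' @param batch_size ids per consecutive batch; must divide `length(model_ids)`.
#' @param test_per_batch test ids drawn per batch; `< batch_size`.
#' @param val_frac fraction of the post-test pool used for validation, in `[0, 1)`.
#' @param seed integer RNG seed.
#' @return An object of class `split_manifest`: list with `test_ids`,
#'   `val_ids`, `train_ids`, `seed`, and (until a dataset is labeled)
#'   `tawss_global_max = NA`, `tawss_global_min = NA`.
#' @examples
#' sm <- make_splits(sprintf("m%04d", 0:599), batch_size = 300,
#'                   test_per_batch = 60, val_frac = 0.1, seed = 0)
#' lengths(sm[c("test_ids", "val_ids", "train_ids")])
#' @export
make_splits <- function(model_ids, batch_size = 300L, test_per_batch = 60L,
                        val_frac = 0.10, seed = 0L) {
  n <- length(model_ids)
  batch_size <- as.integer(batch_size)
  test_per_batch <- as.integer(test_per_batch)
  if (anyDuplicated(model_ids)) stop("model_ids must be unique", call. = FALSE)
  if (n %% batch_size != 0L) {
    stop("number of ids (", n, ") is not divisible by batch_size (",
         batch_size, ")", call. = FALSE)
  }
  if (test_per_batch >= batch_size || test_per_batch < 0L) {
    stop("test_per_batch must lie in [0, batch_size)", call. = FALSE)
  }
  if (val_frac < 0 || val_frac >= 1) stop("val_frac must lie in [0, 1)", call. = FALSE)

  n_batches <- n %/% batch_size
  test_ids <- with_seed(seed, {
    unlist(lapply(seq_len(n_batches), function(b) {
      ids <- model_ids[((b - 1L) * batch_size + 1L):(b * batch_size)]
      if (test_per_batch == 0L) character(0) else sample(ids, test_per_batch)
    }))
  })
  pool <- setdiff(model_ids, test_ids)
  n_val <- round(val_frac * length(pool))  # round-half-to-even
  val_ids <- with_seed(seed + 1L, {
    if (n_val == 0L) character(0) else sample(pool, n_val)
  })
  train_ids <- setdiff(pool, val_ids)
  structure(list(test_ids = sort(test_ids), val_ids = sort(val_ids),
                 train_ids = sort(train_ids), seed = as.integer(seed),
                 batch_size = batch_size, test_per_batch = test_per_batch,
                 val_frac = val_frac,
                 tawss_global_max = NA_real_, tawss_global_min = NA_real_),
            class = "split_manifest")
}

#' @export
print.split_manifest <- function(x, ...) {
  cat("Split manifest (seed ", x$seed, "): ",
      length(x$train_ids), " train / ", length(x$val_ids), " val / ",
      length(x$test_ids), " test\n", sep = "")
  if (is.finite(x$tawss_global_max)) {
    cat("TAWSS global range: [", format(x$tawss_global_min, digits = 4), ", ",
        format(x$tawss_global_max, digits = 4), "] Pa\n", sep = "")
  }
  invisible(x)
}

#' Write / read a split manifest (with morphology table) as JSON
#'
#' @param manifest a `split_manifest`.
#' @param morph optional morphology data.frame (one row per id) stored
#'   alongside the splits.
#' @param path file path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest` the
#'   manifest (with `$morphologies` if stored).
#' @export
write_manifest <- function(manifest, path, morph = NULL) {
  obj <- unclass(manifest)
  if (!is.null(morph)) obj$morphologies <- morph
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  morph <- obj$morphologies
  obj$morphologies <- NULL
  man <- structure(obj, class = "split_manifest")
  for (f in c("test_ids", "val_ids", "train_ids")) {
    man[[f]] <- as.character(man[[f]] %||% character(0))
  }
  man$morphologies <- morph
  man
}

`%||%` <- function(a, b) if (is.null(a)) b else a
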