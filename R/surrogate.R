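#' Configuration of the synthetic wall-shear surrogate
#'
#' The surrogate labels a surface point cloud with a pulsatile,
#' morphology-dependent wall shear stress field standing in for a transient
#' CFD solve. The base stress at each instant is the Poiseuille wall shear
#' of the owning vessel evaluated with Carreau-Yasuda viscosity, blended
#' continuously across the junction, and multiplied by smooth spatial
#' modulators: an amplification centered at the flow-divider apex, a
#' reduction on the lateral (outer) junction wall, and a circumferential
#' front/back asymmetry.
#'
#' `front_back_ratio` is the target ratio of front-half to back-half mean
#' stress over a pure-tube segment; the cosine amplitude that realizes it
#' exactly is `A_c = (r - 1)/(r + 1) * pi/2` (the half-circle mean of
#' `|cos|` is `2/pi`).
#'
#' @param apex_gain amplitude of the apex amplification (`A_a`).
#' @param apex_sigma_factor Gaussian width of the apex bump, x `d_lm`.
#' @param lateral_drop amplitude of the lateral-wall reduction (`A_l`).
#' @param lateral_sigma_factor Gaussian width of the lateral dip, x `d_lm`.
#' @param front_back_ratio target front/back half-mean stress ratio.
#' @param alpha_apex_gain optional linear gain of the apex amplitude with the
#'   LAD-LCx opening angle (0 disables; `A_a` is scaled by
#'   `1 + alpha_apex_gain * (alpha - 15)/115`).
#' @param stress_blend_k_factor softness of the cross-junction stress blend,
#'   x `d_lm`.
#' @param modulators logical; `FALSE` leaves the pure blended Poiseuille
#'   stress (used by calibration checks).
#' @param v_mean cycle-mean inlet velocity, mm/s.
#' @param n_time number of time samples over one cycle (endpoints included).
#' @return List of class `surrogate_config`.
#' @export
surrogate_config <- function(apex_gain = 1.0, apex_sigma_factor = 0.5,
                             lateral_drop = 0.4, lateral_sigma_factor = 1.0,
                             front_back_ratio = 1.25, alpha_apex_gain = 0,
                             stress_blend_k_factor = 1.0,
                             modulators = TRUE, v_mean = 600, n_time = 65L) {
  stopifnot(front_back_ratio >= 1, n_time >= 16L)
  structure(list(apex_gain = apex_gain, apex_sigma_factor = apex_sigma_factor,
                 lateral_drop = lateral_drop,
                 lateral_sigma_factor = lateral_sigma_factor,
                 front_back_ratio = front_back_ratio,
                 alpha_apex_gain = alpha_apex_gain,
                 stress_blend_k_factor = stress_blend_k_factor,
                 modulators = modulators, v_mean = v_mean,
                 n_time = as.integer(n_time)),
            class = "surrogate_config")
}

circ_asym_amplitude <- function(ratio) (ratio - 1) / (ratio + 1) * pi / 2

#' Instantaneous wall shear stress series for a labeled cloud
#'
#' For vessel `v` with diameter `D_v` and flow `Q_v(t)`, the wall shear rate
#' is the Poiseuille expression `gdot = 32 Q_v(t) / (pi D_v^3)` and the base
#' stress `tau_v(t) = mu(gdot) * gdot` with Carreau-Yasuda viscosity. Each
#' point mixes the three vessel stresses with smooth softmin weights in the
#' tube distance fields (continuous across the junction) and applies the
#' spatial modulators of [surrogate_config()].
#'
#' @param cloud a `surface_cloud`.
#' @param flow a [flow_state()]; defaults to one built from the cloud params.
#' @param vp a [viscosity_params()].
#' @param cfg a [surrogate_config()].
#' @param t_grid strictly increasing time samples spanning exactly one
#'   period, >= 16 intervals.
#' @return N x length(t_grid) matrix of wall shear stress (Pa), with
#'   attributes `t_grid` and `model_id`.
#' @export
wall_shear_series <- function(cloud, flow = NULL, vp = viscosity_params(),
                              cfg = surrogate_config(), t_grid = NULL) {
  p <- cloud$params
  if (is.null(flow)) flow <- flow_state(p, v_mean = cfg$v_mean)
  if (is.null(t_grid)) {
    t_grid <- seq(0, flow$period, length.out = cfg$n_time)
  }
  if (length(t_grid) < 16L || any(diff(t_grid) <= 0)) {
    stop("t_grid must be strictly increasing with >= 16 samples",
         call. = FALSE)
  }
  if (abs((t_grid[length(t_grid)] - t_grid[1]) - flow$period) >
      1e-9 * flow$period) {
    stop("t_grid must span exactly one period", call. = FALSE)
  }
  d <- c(LM = p$d_lm, LAD = p$d_lad, LCX = p$d_lcx)
  if (any(d <= 0)) stop("zero or negative vessel diameter", call. = FALSE)
  frac <- c(LM = 1, flow$q_fractions)

  w_t <- flow$waveform(t_grid)
  # per-vessel stress time series: 3 x nt
  tau_v <- t(vapply(names(d), function(v) {
    q <- flow$q_mean_lm * frac[[v]] * w_t
    gdot <- 32 * q / (pi * d[[v]]^3)
    carreau_yasuda(gdot, vp) * gdot
  }, numeric(length(t_grid))))

  # softmin blend weights over the tube fields f_v = dist_v - r_v
  ks <- cfg$stress_blend_k_factor * p$d_lm
  f <- sweep(cloud$vessel_dist, 2, d[colnames(cloud$vessel_dist)] / 2)
  fmin <- do.call(pmin, lapply(seq_len(ncol(f)), function(j) f[, j]))
  wgt <- exp(-(f - fmin) / ks)
  wgt <- wgt / rowSums(wgt)
  wss <- wgt %*% tau_v[colnames(cloud$vessel_dist), , drop = FALSE]

  if (isTRUE(cfg$modulators)) {
    d_apex <- sqrt(rowSums(sweep(cloud$coords, 2, cloud$apex)^2))
    d_lat <- sqrt(rowSums(sweep(cloud$coords, 2, cloud$lateral)^2))
    sig_a <- cfg$apex_sigma_factor * p$d_lm
    sig_l <- cfg$lateral_sigma_factor * p$d_lm
    a_a <- cfg$apex_gain
    if (cfg$alpha_apex_gain != 0) {
      a_a <- a_a * (1 + cfg$alpha_apex_gain * (p$alpha - 15) / 115)
    }
    a_c <- circ_asym_amplitude(cfg$front_back_ratio)
    mod <- (1 + a_a * exp(-d_apex^2 / (2 * sig_a^2))) *
      (1 - cfg$lateral_drop * exp(-d_lat^2 / (2 * sig_l^2))) *
      (1 + a_c * cos(cloud$circ_angle))
    wss <- wss * mod
  }
  attr(wss, "t_grid") <- t_grid
  attr(wss, "model_id") <- cloud$model_id
  wss
}

#' Time-averaged wall shear stress
#'
#' Trapezoidal time average of `|WSS(t)|` over one cardiac cycle:
#' `TAWSS = (1/T) * integral_0^T |WSS(t)| dt`.
#'
#' @param wss_series N x nt matrix (e.g. from [wall_shear_series()]).
#' @param t_grid time samples; defaults to the matrix attribute.
#' @return Object of class `tawss_field`: list with `values` (N positives,
#'   Pa) and `model_id`.
#' @export
tawss <- function(wss_series, t_grid = attr(wss_series, "t_grid")) {
  wss_series <- as.matrix(wss_series)
  nt <- ncol(wss_series)
  if (is.null(t_grid) || length(t_grid) != nt || nt < 2L) {
    stop("need a time grid with at least 2 samples", call. = FALSE)
  }
  if (any(diff(t_grid) <= 0)) stop("t_grid must be strictly increasing", call. = FALSE)
  aw <- abs(wss_series)
  dt <- diff(t_grid)
  vals <- drop((aw[, -nt, drop = FALSE] + aw[, -1L, drop = FALSE]) %*% dt) / 2 /
    (t_grid[nt] - t_grid[1])
  structure(list(values = vals,
                 model_id = attr(wss_series, "model_id") %||% NA_character_),
            class = "tawss_field")
}

#' Label one cloud with surrogate TAWSS
#'
#' @param cloud a `surface_cloud`.
#' @inheritParams wall_shear_series
#' @return A `tawss_field` aligned to `cloud`.
#' @export
label_cloud <- function(cloud, vp = viscosity_params(),
                        cfg = surrogate_config()) {
  tawss(wall_shear_series(cloud, vp = vp, cfg = cfg))
}

#' Generate a labeled in-memory dataset
#'
#' Builds one surface cloud per morphology row, labels it with surrogate
#' TAWSS, and records the dataset-global TAWSS extremes on the manifest
#' (the convention used by the NAME metric: the range is taken over every
#' point of every generated model).
#'
#' @param morph morphology data.frame from [sample_morphologies()].
#' @param manifest optional `split_manifest` over `morph$model_id`; updated
#'   with the global extremes.
#' @param grid_rows,grid_cols structured grid size per model.
#' @param geometry_cfg a [geometry_config()].
#' @param surrogate_cfg a [surrogate_config()].
#' @param vp a [viscosity_params()].
#' @param frame optional rigid frame `list(R, t)` posing every model (the
#'   canonical construction frame is used when `NULL`).
#' @param progress print a dot every 25 models.
#' @return Object of class `tawss_dataset`: `clouds` (named list),
#'   `fields` (named list of `tawss_field`), `morph`, `manifest`.
#' @export
generate_tawss_data <- function(morph, manifest = NULL, grid_rows = 64L,
                                grid_cols = 64L,
                                geometry_cfg = geometry_config(),
                                surrogate_cfg = surrogate_config(),
                                vp = viscosity_params(), frame = NULL,
                                progress = FALSE) {
  ids <- morph$model_id
  clouds <- vector("list", length(ids)); names(clouds) <- ids
  fields <- vector("list", length(ids)); names(fields) <- ids
  for (i in seq_along(ids)) {
    p <- as.list(morph[i, , drop = FALSE])
    cl <- bifurcation_cloud(p, grid_rows, grid_cols, geometry_cfg,
                            frame = frame)
    clouds[[i]] <- cl
    fields[[i]] <- label_cloud(cl, vp = vp, cfg = surrogate_cfg)
    if (progress && i %% 25L == 0L) cat(".")
  }
  if (progress) cat("\n")
  rng <- range(unlist(lapply(fields, `[[`, "values")))
  if (!is.null(manifest)) {
    manifest$tawss_global_min <- rng[1]
    manifest$tawss_global_max <- rng[2]
  }
  structure(list(clouds = clouds, fields = fields, morph = morph,
                 manifest = manifest,
                 tawss_global_min = rng[1], tawss_global_max = rng[2],
                 grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols)),
            class = "tawss_dataset")
}

#' @export
print.tawss_dataset <- function(x, ...) {
  cat("TAWSS dataset:", length(x$clouds), "models of",
      x$grid_rows * x$grid_cols, "points\n")
  cat("  global TAWSS range: [", format(x$tawss_global_min, digits = 4), ", ",
      format(x$tawss_global_max, digits = 4), "] Pa\n", sep = "")
  invisible(x)
}

#' Write a labeled dataset to disk
#'
#' Layout: `out_dir/manifest.json` plus one PLY (or CSV) file per model
#' under `out_dir/models/`. Refuses to touch an existing non-empty
#' directory unless `overwrite = TRUE`. Output is byte-deterministic for a
#' fixed dataset.
#'
#' @param data a `tawss_dataset`.
#' @param out_dir destination directory.
#' @param format `"ply"` (binary little-endian) or `"csv"`.
#' @param overwrite replace an existing run directory.
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(data, out_dir, format = c("ply", "csv"),
                          overwrite = FALSE) {
  format <- match.arg(format)
  if (dir.exists(out_dir) && length(dir(out_dir, all.files = FALSE)) > 0L) {
    if (!overwrite) {
      stop("output directory '", out_dir,
           "' already exists; use overwrite = TRUE", call. = FALSE)
    }
    unlink(out_dir, recursive = TRUE)
  }
  dir.create(file.path(out_dir, "models"), recursive = TRUE,
             showWarnings = FALSE)
  for (id in names(data$clouds)) {
    path <- file.path(out_dir, "models",
                      paste0(id, if (format == "ply") ".ply" else ".csv"))
    if (format == "ply") {
      write_ply(data$clouds[[id]], path, tawss = data$fields[[id]]$values)
    } else {
      write_cloud_csv(data$clouds[[id]], path,
                      tawss = data$fields[[id]]$values)
    }
  }
  man <- data$manifest
  if (is.null(man)) {
    man <- structure(list(test_ids = character(0), val_ids = character(0),
                          train_ids = data$morph$model_id, seed = NA_integer_,
                          tawss_global_max = data$tawss_global_max,
                          tawss_global_min = data$tawss_global_min),
                     class = "split_manifest")
  }
  write_manifest(man, file.path(out_dir, "manifest.json"), morph = data$morph)
  invisible(out_dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir run directory containing `manifest.json` and `models/`.
#' @return A `tawss_dataset` (clouds carry coordinates and labels read back
#'   from disk; derived junction metadata is not reloaded).
#' @export
read_dataset <- function(dir) {
  man <- read_manifest(file.path(dir, "manifest.json"))
  morph <- as.data.frame(man$morphologies)
  man$morphologies <- NULL
  files <- list.files(file.path(dir, "models"), full.names = TRUE)
  ids <- sub("\\.(ply|csv)$", "", basename(files))
  clouds <- list(); fields <- list()
  for (i in seq_along(files)) {
    obj <- if (grepl("\\.ply$", files[i])) read_ply(files[i]) else
      read_cloud_csv(files[i])
    obj$cloud$model_id <- ids[i]
    obj$cloud$params <- as.list(morph[morph$model_id == ids[i], , drop = FALSE])
    clouds[[ids[i]]] <- obj$cloud
    fields[[ids[i]]] <- structure(list(values = obj$tawss, model_id = ids[i]),
                                  class = "tawss_field")
  }
  structure(list(clouds = clouds, fields = fields, morph = morph,
                 manifest = man,
                 tawss_global_min = man$tawss_global_min,
                 tawss_global_max = man$tawss_global_max,
                 grid_rows = clouds[[1]]$grid_rows,
                 grid_cols = clouds[[1]]$grid_cols),
            class = "tawss_dataset")
}
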