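#' U-Net configuration
#'
#' Architecture and training hyperparameters of the point-cloud U-Net.
#' The default reproduces the compact TAWSS regressor: a two-layer shared
#' per-point stem lifting xyz coordinates to `width` channels, a reshape of
#' the ordered points onto a `grid_rows x grid_cols` grid, an encoder of
#' `levels` max-pooling stages with `convs_per_level` 3x3 convolutions each,
#' `bottleneck_convs` convolutions at the coarsest resolution, a decoder of
#' 2x2 stride-2 transposed convolutions with skip concatenations, and a
#' final 1x1 linear head (no normalization) back to one value per point.
#' Batch normalization sits after every convolution and before its ReLU.
#' Training uses Adam on the mean squared error of min-max-normalized
#' TAWSS, with a staircase-exponential learning rate (`lr0` decayed by
#' `decay_rate` every `decay_every` optimizer steps) and early stopping on
#' validation NAME.
#'
#' @param grid_rows,grid_cols grid shape; `grid_rows * grid_cols` points per
#'   model (default 64 x 64 = 4096).
#' @param in_channels input channels per point (3 coordinates).
#' @param width channel width of every convolution.
#' @param levels number of pooling steps; the grid must divide by
#'   `2^levels`.
#' @param convs_per_level convolutions per encoder/decoder stage.
#' @param bottleneck_convs convolutions at the coarsest resolution.
#' @param skip_connections concatenate encoder features onto the decoder.
#' @param batch_norm use batch normalization (pre-activation).
#' @param lr0 initial learning rate.
#' @param decay_every optimizer steps between learning-rate decays.
#' @param decay_rate multiplicative decay factor.
#' @param batch_size models per optimizer step.
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience on validation NAME (epochs);
#'   `Inf` disables early stopping.
#' @param bn_momentum running-statistics momentum of batch normalization.
#' @param seed RNG seed for initialization and batch shuffling.
#' @return Object of class `unet_config`.
#' @export
unet_config <- function(grid_rows = 64L, grid_cols = 64L, in_channels = 3L,
                        width = 8L, levels = 4L, convs_per_level = 2L,
                        bottleneck_convs = 4L, skip_connections = TRUE,
                        batch_norm = TRUE, lr0 = 1e-3, decay_every = 2000L,
                        decay_rate = 0.9, batch_size = 16L, epochs = 200L,
                        patience = 20L, bn_momentum = 0.9, seed = 0L) {
  cfg <- list(grid_rows = as.integer(grid_rows),
              grid_cols = as.integer(grid_cols),
              in_channels = as.integer(in_channels),
              width = as.integer(width), levels = as.integer(levels),
              convs_per_level = as.integer(convs_per_level),
              bottleneck_convs = as.integer(bottleneck_convs),
              skip_connections = isTRUE(skip_connections),
              batch_norm = isTRUE(batch_norm),
              lr0 = lr0, decay_every = as.integer(decay_every),
              decay_rate = decay_rate, batch_size = as.integer(batch_size),
              epochs = as.integer(epochs), patience = patience,
              bn_momentum = bn_momentum, seed = as.integer(seed))
  cfg$points <- cfg$grid_rows * cfg$grid_cols
  if (cfg$levels < 1L) stop("levels must be >= 1", call. = FALSE)
  if (cfg$grid_rows %% 2L^cfg$levels != 0L ||
      cfg$grid_cols %% 2L^cfg$levels != 0L) {
    stop("grid ", cfg$grid_rows, " x ", cfg$grid_cols,
         " is not divisible by 2^levels = ", 2L^cfg$levels, call. = FALSE)
  }
  structure(cfg, class = "unet_config")
}

unet_unit_names <- function(cfg) {
  w <- cfg$width
  units <- list(stem1 = c(cfg$in_channels, w), stem2 = c(w, w))
  for (l in 0:cfg$levels) {
    for (cc in seq_len(cfg$convs_per_level)) {
      units[[paste0("enc", l, "_", cc)]] <- c(w, w)
    }
  }
  for (cc in seq_len(cfg$bottleneck_convs)) {
    units[[paste0("bot", cc)]] <- c(w, w)
  }
  for (l in (cfg$levels - 1L):0L) {
    units[[paste0("up", l)]] <- c(w, w)
    for (cc in seq_len(cfg$convs_per_level)) {
      cin <- if (cc == 1L && cfg$skip_connections) 2L * w else w
      units[[paste0("dec", l, "_", cc)]] <- c(cin, w)
    }
  }
  units$head <- c(w, 1L)
  units
}

unit_kind <- function(u) {
  if (u %in% c("stem1", "stem2", "head")) "linear"
  else if (grepl("^up", u)) "tconv"
  else "conv"
}

#' Build an untrained point-cloud U-Net
#'
#' Initializes all weights (He-normal, seeded) and the batch-normalization
#' running statistics, and records the total trainable parameter count.
#'
#' @param cfg a [unet_config()].
#' @return Object of class `tawss_unet` with `trained = FALSE`.
#' @examples
#' m <- build_unet(unet_config(grid_rows = 16, grid_cols = 16, levels = 2))
#' m$parameter_count
#' @export
build_unet <- function(cfg = unet_config()) {
  stopifnot(inherits(cfg, "unet_config"))
  units <- unet_unit_names(cfg)
  params <- list(); bn_state <- list()
  with_seed(cfg$seed, {
    for (u in names(units)) {
      io <- units[[u]]
      kind <- unit_kind(u)
      fan_in <- switch(kind, linear = io[1], conv = 9L * io[1],
                       tconv = io[1])
      sd <- sqrt(2 / fan_in)
      unit <- switch(kind,
        linear = list(W = matrix(stats::rnorm(io[1] * io[2], sd = sd),
                                 io[1], io[2]),
                      b = numeric(io[2])),
        conv = list(W = matrix(stats::rnorm(9L * io[1] * io[2], sd = sd),
                               9L * io[1], io[2]),
                    b = numeric(io[2])),
        tconv = list(W = array(stats::rnorm(io[1] * io[2] * 4L, sd = sd),
                               c(io[1], io[2], 4L)),
                     b = numeric(io[2])))
      if (cfg$batch_norm && u != "head") {
        unit$gamma <- rep(1, io[2]); unit$beta <- numeric(io[2])
        bn_state[[u]] <- list(mean = numeric(io[2]), var = rep(1, io[2]))
      }
      params[[u]] <- unit
    }
  })
  structure(list(config = cfg, params = params, bn_state = bn_state,
                 parameter_count = params_count(params),
                 trained = FALSE, history = NULL, norm = NULL,
                 ordering_method = NA_character_),
            class = "tawss_unet")
}

# forward pass on X: (B * points) x in_channels, pixel rows row-major per
# sample. Returns y, updated bn running state and (optionally) caches.
unet_forward <- function(model, X, B, training = FALSE, keep = FALSE) {
  cfg <- model$config
  pr <- model$params
  bnst <- model$bn_state
  cc <- if (keep) new.env(parent = emptyenv()) else NULL
  cpl <- cfg$convs_per_level

  block_post <- function(u, y, extra) {
    pu <- pr[[u]]
    bnc <- NULL
    if (cfg$batch_norm) {
      r <- nn_bn_fwd(y, pu$gamma, pu$beta, bnst[[u]], training,
                     cfg$bn_momentum)
      bnst[[u]] <<- r$state
      y <- r$y
      bnc <- list(xhat = r$xhat, inv = r$inv)
    }
    rl <- nn_relu_fwd(y)
    if (keep) assign(u, c(extra, list(bn = bnc, mask = rl$mask)), cc)
    rl$y
  }
  lin_block <- function(u, X) {
    block_post(u, nn_linear_fwd(X, pr[[u]]$W, pr[[u]]$b), list(X = X))
  }
  conv_block <- function(u, X, B, H, W) {
    cv <- nn_conv_fwd(X, pr[[u]]$W, pr[[u]]$b, B, H, W)
    block_post(u, cv$y, list(P = cv$P, B = B, H = H, W = W, C_in = ncol(X)))
  }

  h <- lin_block("stem1", X)
  h <- lin_block("stem2", h)
  H <- cfg$grid_rows; W <- cfg$grid_cols
  skips <- list()
  for (ci in seq_len(cpl)) h <- conv_block(paste0("enc0_", ci), h, B, H, W)
  skips[["0"]] <- h
  for (l in seq_len(cfg$levels)) {
    pl <- nn_pool_fwd(h, B, H, W)
    if (keep) assign(paste0("pool", l), pl, cc)
    h <- pl$y; H <- H %/% 2L; W <- W %/% 2L
    for (ci in seq_len(cpl)) {
      h <- conv_block(paste0("enc", l, "_", ci), h, B, H, W)
    }
    if (l < cfg$levels) skips[[as.character(l)]] <- h
  }
  for (ci in seq_len(cfg$bottleneck_convs)) {
    h <- conv_block(paste0("bot", ci), h, B, H, W)
  }
  for (l in (cfg$levels - 1L):0L) {
    u <- paste0("up", l)
    tc <- nn_tconv_fwd(h, pr[[u]]$W, pr[[u]]$b, B, H, W)
    h <- block_post(u, tc$y, list(X = h, idx = tc$idx))
    H <- 2L * H; W <- 2L * W
    if (cfg$skip_connections) h <- cbind(h, skips[[as.character(l)]])
    for (ci in seq_len(cpl)) {
      h <- conv_block(paste0("dec", l, "_", ci), h, B, H, W)
    }
  }
  if (keep) assign("head", list(X = h), cc)
  y <- nn_linear_fwd(h, pr$head$W, pr$head$b)
  list(y = y, bn_state = bnst, cache = cc,
       bottleneck_size = c(cfg$grid_rows %/% 2L^cfg$levels,
                           cfg$grid_cols %/% 2L^cfg$levels))
}

# backward pass; cc is the cache environment from unet_forward(keep = TRUE)
unet_backward <- function(model, cc, dY) {
  cfg <- model$config
  pr <- model$params
  cpl <- cfg$convs_per_level
  w <- cfg$width
  gr <- list()

  post_bwd <- function(u, d) {
    cache <- get(u, cc)
    d <- nn_relu_bwd(cache$mask, d)
    if (cfg$batch_norm) {
      bb <- nn_bn_bwd(cache$bn, pr[[u]]$gamma, d)
      gr[[u]]$gamma <<- bb$dgamma; gr[[u]]$beta <<- bb$dbeta
      d <- bb$dX
    }
    list(cache = cache, d = d)
  }
  conv_bwd <- function(u, d) {
    gr[[u]] <<- list()
    r <- post_bwd(u, d)
    cb <- nn_conv_bwd(r$cache$P, pr[[u]]$W, r$d, r$cache$B, r$cache$H,
                      r$cache$W, r$cache$C_in)
    gr[[u]]$W <<- cb$dW; gr[[u]]$b <<- cb$db
    cb$dX
  }
  lin_bwd <- function(u, d) {
    gr[[u]] <<- list()
    r <- post_bwd(u, d)
    lb <- nn_linear_bwd(r$cache$X, pr[[u]]$W, r$d)
    gr[[u]]$W <<- lb$dW; gr[[u]]$b <<- lb$db
    lb$dX
  }

  hc <- get("head", cc)
  lb <- nn_linear_bwd(hc$X, pr$head$W, dY)
  gr$head <- list(W = lb$dW, b = lb$db)
  d <- lb$dX

  skip_grads <- list()
  for (l in 0:(cfg$levels - 1L)) {
    for (ci in rev(seq_len(cpl))) d <- conv_bwd(paste0("dec", l, "_", ci), d)
    if (cfg$skip_connections) {
      skip_grads[[as.character(l)]] <- d[, (w + 1L):(2L * w), drop = FALSE]
      d <- d[, seq_len(w), drop = FALSE]
    } else {
      skip_grads[[as.character(l)]] <- NULL
    }
    u <- paste0("up", l)
    gr[[u]] <- list()
    r <- post_bwd(u, d)
    tb <- nn_tconv_bwd(r$cache$X, pr[[u]]$W, r$cache$idx, r$d)
    gr[[u]]$W <- tb$dW; gr[[u]]$b <- tb$db
    d <- tb$dX
  }
  for (ci in rev(seq_len(cfg$bottleneck_convs))) {
    d <- conv_bwd(paste0("bot", ci), d)
  }
  for (l in cfg$levels:1L) {
    if (l < cfg$levels && cfg$skip_connections) {
      d <- d + skip_grads[[as.character(l)]]
    }
    for (ci in rev(seq_len(cpl))) d <- conv_bwd(paste0("enc", l, "_", ci), d)
    d <- nn_pool_bwd(get(paste0("pool", l), cc), d)
  }
  if (cfg$skip_connections) d <- d + skip_grads[["0"]]
  for (ci in rev(seq_len(cpl))) d <- conv_bwd(paste0("enc0_", ci), d)
  d <- lin_bwd("stem2", d)
  d <- lin_bwd("stem1", d)
  gr
}
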