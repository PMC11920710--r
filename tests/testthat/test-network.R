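test_that("config validation enforces grid divisibility", {
  expect_error(unet_config(grid_rows = 48, grid_cols = 48, levels = 5),
               "divisible")
  expect_s3_class(unet_config(grid_rows = 16, grid_cols = 16, levels = 2),
                  "unet_config")
})

test_that("the forward pass honors the shape contract across configs", {
  cases <- list(c(16, 2), c(32, 3), c(32, 4))
  for (cs in cases) {
    g <- cs[1]; lv <- cs[2]
    cfg <- unet_config(grid_rows = g, grid_cols = g, levels = lv, seed = 1)
    m <- build_unet(cfg)
    B <- 2L
    X <- matrix(rnorm(B * g * g * 3), B * g * g, 3)
    fw <- tawssnet:::unet_forward(m, X, B)
    expect_equal(dim(fw$y), c(B * g * g, 1L))
    expect_equal(fw$bottleneck_size, c(g / 2^lv, g / 2^lv))
  }
})

test_that("encoder halves the grid at each of the four default levels", {
  s <- summary(build_unet(unet_config()))
  expect_equal(s$encoder_sizes, c(64, 32, 16, 8, 4))
})

test_that("dropping skip connections removes decoder input channels", {
  with_sk <- build_unet(unet_config(grid_rows = 16, grid_cols = 16,
                                    levels = 2))
  no_sk <- build_unet(unet_config(grid_rows = 16, grid_cols = 16,
                                  levels = 2, skip_connections = FALSE))
  expect_lt(no_sk$parameter_count, with_sk$parameter_count)
  # the parameter count matches an explicit accounting of the layer stack
  count <- tawssnet:::params_count(with_sk$params)
  expect_equal(with_sk$parameter_count, count)
})

test_that("the staircase learning-rate schedule matches its closed form", {
  lr <- tawssnet:::staircase_lr
  expect_equal(lr(1e-3, 0.9, 2000, 0), 1e-3)
  expect_equal(lr(1e-3, 0.9, 2000, 1999), 1e-3)
  expect_equal(lr(1e-3, 0.9, 2000, 2000), 1e-3 * 0.9)
  expect_equal(lr(1e-3, 0.9, 2000, 4000), 1e-3 * 0.81)
})

test_that("backpropagation matches finite differences", {
  # biases/offsets randomized so no preactivation sits exactly on the ReLU
  # kink, where two-sided differences measure half-subgradients
  set.seed(12)
  cfg <- unet_config(grid_rows = 8, grid_cols = 8, levels = 2, width = 3,
                     bottleneck_convs = 2, batch_norm = FALSE, seed = 7)
  m <- build_unet(cfg)
  for (u in names(m$params)) {
    m$params[[u]]$b <- rnorm(length(m$params[[u]]$b), sd = 0.3)
  }
  B <- 2L
  X <- matrix(rnorm(B * 64 * 3), B * 64, 3)
  tg <- matrix(rnorm(B * 64), ncol = 1)
  lossfn <- function(mm) {
    mean((tawssnet:::unet_forward(mm, X, B, training = TRUE)$y - tg)^2)
  }
  fw <- tawssnet:::unet_forward(m, X, B, training = TRUE, keep = TRUE)
  gr <- tawssnet:::unet_backward(m, fw$cache, 2 * (fw$y - tg) / length(tg))
  worst <- 0
  for (u in names(m$params)) {
    for (p in names(m$params[[u]])) {
      a <- m$params[[u]][[p]]
      for (i in sample(length(a), min(3, length(a)))) {
        m2 <- m; m2$params[[u]][[p]][i] <- a[i] + 1e-6
        m3 <- m; m3$params[[u]][[p]][i] <- a[i] - 1e-6
        fd <- (lossfn(m2) - lossfn(m3)) / 2e-6
        an <- gr[[u]][[p]][i]
        worst <- max(worst, abs(fd - an) / max(1e-7, abs(fd) + abs(an)))
      }
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("training is seed-deterministic and reduces the loss", {
  data <- tiny_dataset(n = 4, rows = 16, seed = 2)
  cfg <- unet_config(grid_rows = 16, grid_cols = 16, levels = 2, epochs = 40,
                     batch_size = 4, patience = Inf, seed = 3)
  m1 <- tawss_unet(data, config = cfg)
  m2 <- tawss_unet(data, config = cfg)
  expect_identical(m1$history$train_mse, m2$history$train_mse)
  expect_lt(tail(m1$history$train_mse, 1), 0.5 * m1$history$train_mse[1])
  cfg2 <- unet_config(grid_rows = 16, grid_cols = 16, levels = 2,
                      epochs = 40, batch_size = 4, patience = Inf, seed = 4)
  m3 <- tawss_unet(data, config = cfg2)
  expect_false(identical(m1$history$train_mse, m3$history$train_mse))
})

test_that("prediction undoes the ordering and checks point counts", {
  data <- tiny_dataset(n = 4, rows = 16, seed = 2)
  cfg <- unet_config(grid_rows = 16, grid_cols = 16, levels = 2, epochs = 10,
                     batch_size = 4, patience = Inf, seed = 3)
  m <- tawss_unet(data, config = cfg)
  cl <- data$clouds[[1]]
  p1 <- predict(m, cl)
  expect_length(p1$values, 256)
  set.seed(31)
  perm <- sample(256)
  p2 <- predict(m, permute_cloud(cl, perm))
  expect_equal(p2$values, p1$values[perm], tolerance = 1e-10)
  bad <- small_cloud(8, 8)
  expect_error(predict(m, bad), "expects")
})

test_that("mismatched normalization constants are a hard error", {
  data <- tiny_dataset(n = 4, rows = 16, seed = 2)
  man <- make_splits(names(data$clouds), batch_size = 4, test_per_batch = 1,
                     val_frac = 0.3, seed = 1)
  man$tawss_global_min <- data$tawss_global_min
  man$tawss_global_max <- data$tawss_global_max
  cfg <- unet_config(grid_rows = 16, grid_cols = 16, levels = 2, epochs = 5,
                     batch_size = 2, patience = Inf, seed = 0)
  m <- tawss_unet(data, config = cfg, manifest = man)
  other <- data
  other$tawss_global_max <- data$tawss_global_max * 2
  expect_error(evaluate_tawss(m, other, split = "test"), "disagree")
})

test_that("the model object exposes the standard methods", {
  data <- tiny_dataset(n = 4, rows = 16, seed = 2)
  man <- make_splits(names(data$clouds), batch_size = 4, test_per_batch = 1,
                     val_frac = 0.5, seed = 1)
  man$tawss_global_min <- data$tawss_global_min
  man$tawss_global_max <- data$tawss_global_max
  cfg <- unet_config(grid_rows = 16, grid_cols = 16, levels = 2, epochs = 6,
                     batch_size = 2, patience = Inf, seed = 0)
  m <- tawss_unet(data, config = cfg, manifest = man)
  expect_output(print(m), "U-Net")
  expect_output(print(summary(m)), "encoder spatial sizes")
  expect_type(coef(m), "list")
  expect_true("head" %in% names(coef(m)))
  r <- residuals(m)
  expect_length(r, length(man$val_ids))
  rn <- residuals(m, newdata = data)
  expect_length(rn[[1]], 256)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(m))
})
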