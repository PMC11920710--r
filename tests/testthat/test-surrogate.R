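test_that("Carreau-Yasuda viscosity matches its closed-form limits", {
  vp <- viscosity_params()
  expect_identical(carreau_yasuda(0, vp), 0.056)
  expect_equal(carreau_yasuda(1e6, vp), 0.0035, tolerance = 1e-3)
  # independently computed reference value at 1 1/s
  expect_equal(carreau_yasuda(1, vp), 0.028741299997361254, tolerance = 1e-12)
  expect_error(carreau_yasuda(-1, vp), "nonnegative")
})

test_that("viscosity is bounded and monotone decreasing in shear rate", {
  vp <- viscosity_params()
  g <- 10^seq(-3, 6, length.out = 200)
  mu <- carreau_yasuda(g, vp)
  expect_true(all(mu <= vp$mu_0 & mu >= vp$mu_inf))
  expect_true(all(diff(mu) < 0))
})

test_that("Murray flow split follows the cube law and normalizes", {
  expect_equal(murray_flow_split(2, 2), c(LAD = 0.5, LCX = 0.5))
  expect_equal(murray_flow_split(2, 1), c(LAD = 8 / 9, LCX = 1 / 9))
  set.seed(1)
  for (i in 1:10) {
    s <- murray_flow_split(runif(1, 0.5, 5), runif(1, 0.5, 5))
    expect_equal(unname(sum(s)), 1, tolerance = 1e-12)
  }
  expect_error(murray_flow_split(0, 1), "positive")
})

test_that("the inlet waveform has unit cycle mean and conserves flow", {
  w <- flow_waveform()
  T <- attr(w, "period")
  t <- seq(0, T, length.out = 4001)
  m <- sum((w(t[-1]) + w(t[-length(t)])) / 2 * diff(t)) / T
  expect_equal(m, 1, tolerance = 1e-6)
  expect_true(all(w(t) >= 0))
  fs <- flow_state(demo_params())
  expect_equal(unname(sum(fs$q_fractions)), 1, tolerance = 1e-12)
  # Q_LAD(t) + Q_LCX(t) = Q_LM(t) at every instant
  q <- fs$q_mean_lm * w(t)
  expect_equal(q * fs$q_fractions[["LAD"]] + q * fs$q_fractions[["LCX"]], q,
               tolerance = 1e-12)
})

test_that("steady flow with modulators off reduces to Poiseuille stress", {
  p <- demo_params()
  cfg_geo <- geometry_config(arc_radius = Inf)
  cl <- bifurcation_cloud(p, 16, 16, cfg_geo)
  # a truly constant waveform isolates the Poiseuille base stress
  const_wave <- function(t) rep(1, length(t))
  attr(const_wave, "period") <- 0.8
  fs <- flow_state(p, v_mean = 400, waveform = const_wave)
  scfg <- surrogate_config(modulators = FALSE, stress_blend_k_factor = 0.05)
  wss <- wall_shear_series(cl, flow = fs, cfg = scfg)
  # LAD tip station: centre of the last LAD row (far from the junction)
  i <- which(cl$station_index == (4 + 6 - 1))[1]
  q_lad <- fs$q_mean_lm * fs$q_fractions[["LAD"]]
  gd <- 32 * q_lad / (pi * p$d_lad^3)
  tau_hand <- carreau_yasuda(gd) * gd
  expect_equal(unname(wss[i, 1]), tau_hand, tolerance = 1e-6)
  # constant WSS integrates to itself
  f <- tawss(wss)
  expect_equal(unname(f$values[i]), tau_hand, tolerance = 1e-6)
})

test_that("wall shear rate scales with the inverse diameter cube", {
  # Newtonian viscosity, fixed flow, modulators off: halving every diameter
  # multiplies the stress by exactly 8
  vp_newt <- viscosity_params(mu_inf = 0.0035, mu_0 = 0.0035)
  const_wave <- function(t) rep(1, length(t))
  attr(const_wave, "period") <- 0.8
  p1 <- demo_params()
  p2 <- within(as.list(p1), {d_lm <- d_lm / 2; d_lad <- d_lad / 2
                             d_lcx <- d_lcx / 2})
  fs <- flow_state(p1, v_mean = 400, waveform = const_wave)
  scfg <- surrogate_config(modulators = FALSE, stress_blend_k_factor = 0.05)
  cl1 <- bifurcation_cloud(p1, 16, 16)
  cl2 <- bifurcation_cloud(p2, 16, 16)
  w1 <- wall_shear_series(cl1, flow = fs, vp = vp_newt, cfg = scfg)
  w2 <- wall_shear_series(cl2, flow = fs, vp = vp_newt, cfg = scfg)
  i <- which(cl1$station_index == 0)[1]  # LM inlet
  expect_equal(unname(w2[i, 1] / w1[i, 1]), 8, tolerance = 1e-9)
})

test_that("with Newtonian viscosity and modulators off TAWSS is linear in flow", {
  vp_newt <- viscosity_params(mu_inf = 0.0035, mu_0 = 0.0035)
  p <- demo_params()
  cl <- small_cloud(16, 16)
  scfg <- surrogate_config(modulators = FALSE)
  wss <- wall_shear_series(cl, vp = vp_newt, cfg = scfg)
  f <- tawss(wss)
  const_wave <- function(t) rep(1, length(t))
  attr(const_wave, "period") <- 0.8
  fs_mean <- flow_state(p, v_mean = scfg$v_mean, waveform = const_wave)
  f_mean <- tawss(wall_shear_series(cl, flow = fs_mean, vp = vp_newt,
                                    cfg = scfg))
  # time average commutes with a stress linear in Q (waveform mean is 1, up
  # to its analytic normalization)
  expect_equal(f$values, f_mean$values, tolerance = 1e-6)
})

test_that("front/back circumferential asymmetry hits the configured ratio", {
  cl <- small_cloud(32, 32)
  f <- label_cloud(cl)
  # pure-tube LM segment: first four stations
  seg <- cl$station_index <= 3
  front <- seg & cos(cl$circ_angle) > 1e-9
  back <- seg & cos(cl$circ_angle) < -1e-9
  ratio <- mean(f$values[front]) / mean(f$values[back])
  expect_equal(ratio, 1.25, tolerance = 0.02 / 1.25)
})

test_that("TAWSS quadrature is exact for constant and linear series", {
  t <- seq(0, 0.8, length.out = 33)
  const <- matrix(3.5, 2, length(t))
  f <- tawss(const, t)
  expect_equal(f$values, c(3.5, 3.5))
  lin <- matrix(2 * t / 0.8, 1, length(t), byrow = TRUE)
  expect_equal(tawss(lin, t)$values, 1, tolerance = 1e-9)
  expect_error(tawss(matrix(1, 2, 1), 0.1), "at least 2")
})

test_that("coarse-grid TAWSS agrees with a fine quadrature oracle", {
  set.seed(7)
  T <- 0.8
  t64 <- seq(0, T, length.out = 65)
  t1024 <- seq(0, T, length.out = 1025)
  for (i in 1:5) {
    a <- runif(3, 0.5, 2); ph <- runif(3, 0, 2 * pi)
    series <- function(t) {
      2 + a[1] * sin(2 * pi * t / T + ph[1]) +
        a[2] * sin(4 * pi * t / T + ph[2]) +
        a[3] * sin(6 * pi * t / T + ph[3])
    }
    v64 <- tawss(matrix(series(t64), 1), t64)$values
    v1024 <- tawss(matrix(series(t1024), 1), t1024)$values
    expect_equal(v64, v1024, tolerance = 1e-3)
  }
})

test_that("generated datasets record global extremes and plausible scales", {
  morph <- sample_morphologies(n = 100, seed = 4)
  man <- make_splits(morph$model_id, batch_size = 50, test_per_batch = 10,
                     val_frac = 0.1, seed = 4)
  data <- generate_tawss_data(morph, man, grid_rows = 32, grid_cols = 32)
  pooled <- unlist(lapply(data$fields, `[[`, "values"))
  expect_true(all(pooled > 0))
  expect_equal(data$manifest$tawss_global_max, max(pooled))
  expect_equal(data$manifest$tawss_global_min, min(pooled))
  q <- stats::quantile(pooled, c(0.05, 0.95))
  expect_gte(q[[1]], 2)
  expect_lte(q[[2]], 20)
})

test_that("datasets round-trip through disk and refuse accidental overwrite", {
  data <- tiny_dataset(n = 3, rows = 8, seed = 6)
  dir <- withr::local_tempdir()
  out <- file.path(dir, "run")
  write_dataset(data, out)
  expect_error(write_dataset(data, out), "overwrite")
  back <- read_dataset(out)
  id <- names(data$clouds)[2]
  expect_equal(back$clouds[[id]]$coords, unname(data$clouds[[id]]$coords),
               ignore_attr = TRUE)
  expect_equal(back$fields[[id]]$values, unname(data$fields[[id]]$values),
               tolerance = 1e-12)
  # byte-identical regeneration
  out2 <- file.path(dir, "run2")
  write_dataset(data, out2)
  f1 <- file.path(out, "models", paste0(id, ".ply"))
  f2 <- file.path(out2, "models", paste0(id, ".ply"))
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("degenerate surrogate inputs raise domain errors", {
  cl <- small_cloud(16, 16)
  expect_error(wall_shear_series(cl, t_grid = seq(0, 0.8, length.out = 5)),
               ">= 16")
  bad <- cl; bad$params$d_lad <- 0
  expect_error(wall_shear_series(bad), "diameter|positive")
})
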