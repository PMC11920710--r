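tangent_angle_deg <- function(u, v) {
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

test_that("built centerlines reproduce the bifurcation angles", {
  set.seed(11)
  r <- morph_ranges()
  for (i in 1:25) {
    p <- list(d_lm = runif(1, 2.18, 4.18), d_lcx = runif(1, 1.5, 3.5),
              d_lad = runif(1, 1.5, 3.5), gamma = runif(1, 112.75, 172.75),
              alpha = runif(1, 15, 130))
    cls <- build_centerlines(p)
    # gamma: angle between the upstream LM direction (-t_LM) and LAD tangent
    g <- tangent_angle_deg(-cls$LM$t0, cls$LAD$t0)
    a <- tangent_angle_deg(cls$LAD$t0, cls$LCX$t0)
    expect_equal(g, p$gamma, tolerance = 1e-6 / p$gamma)
    expect_equal(a, p$alpha, tolerance = 1e-6 / p$alpha)
  }
  # printed-range endpoints
  p <- demo_params(); p$gamma <- 172.75
  cls <- build_centerlines(p)
  expect_equal(tangent_angle_deg(-cls$LM$t0, cls$LAD$t0), 172.75,
               tolerance = 1e-8)
  p$alpha <- 15
  cls <- build_centerlines(p)
  expect_equal(tangent_angle_deg(cls$LAD$t0, cls$LCX$t0), 15,
               tolerance = 1e-7)
})

test_that("infinite arc radius gives straight daughters", {
  cfg <- geometry_config(arc_radius = Inf)
  cls <- build_centerlines(demo_params(), cfg)
  for (v in c("LAD", "LCX")) {
    tans <- cls[[v]]$tangents
    expect_lt(max(abs(sweep(tans, 2, tans[1, ]))), 1e-12)
  }
})

test_that("folded-back daughter configurations are rejected", {
  p <- demo_params()
  # within the printed parameter ranges the guard can never fire (the LCx
  # stays >55 degrees away from the upstream axis), so exercise it with a
  # deliberately nonsensical opening angle
  p$gamma <- 112.75; p$alpha <- 220
  expect_error(build_centerlines(p), "folds back")
})

test_that("the structured grid has the configured point budget", {
  cl <- small_cloud(16, 16)
  expect_equal(nrow(cl$coords), 256)
  expect_true(all(is.finite(cl$coords)))
  expect_equal(length(unique(cl$station_index)), 16)
  expect_equal(sum(cl$station_index == 0), 16)
})

test_that("stations away from the junction are exact vessel circles", {
  cl <- small_cloud(16, 16)
  # inlet-most LM station
  i <- which(cl$station_index == 0)
  ctr <- colMeans(cl$coords[i, ])
  radii <- sqrt(rowSums(sweep(cl$coords[i, ], 2, ctr)^2))
  expect_equal(2 * radii, rep(demo_params()$d_lm, length(i)),
               tolerance = 1e-7)
  expect_lt(max(abs(2 * radii - demo_params()$d_lm)), 1e-6)
})

test_that("least-squares circle fits recover the vessel diameters", {
  p <- demo_params()
  cl <- bifurcation_cloud(p, 32, 32)
  diam <- c(LM = p$d_lm, LAD = p$d_lad, LCX = p$d_lcx)
  # last station of each daughter and first of LM are farthest from junction
  check_station <- function(st, d_true) {
    i <- which(cl$station_index == st)
    pts <- cl$coords[i, ]
    ctr <- colMeans(pts)
    r <- mean(sqrt(rowSums(sweep(pts, 2, ctr)^2)))
    expect_equal(2 * r, unname(d_true), tolerance = 1e-3)
  }
  check_station(0, diam["LM"])           # LM inlet
  check_station(8 + 12 - 1, diam["LAD"]) # LAD tip
  check_station(31, diam["LCX"])         # LCx tip
})

test_that("every emitted point lies on the blended implicit surface", {
  cl <- small_cloud(16, 16)
  p <- demo_params()
  cfg <- geometry_config()
  cls <- build_centerlines(p, cfg)
  k <- cfg$blend_k_factor * p$d_lm
  resid <- tawssnet:::blend_implicit(cls, cl$coords, k)
  expect_lt(max(abs(resid)), 1e-6)
})

test_that("construction is equivariant under rigid motions", {
  p <- demo_params()
  th <- 0.7; ax <- c(1, 2, 3) / sqrt(14)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  tr <- c(5, -3, 2)
  frame <- tawssnet:::make_frame(R, tr)
  base <- bifurcation_cloud(p, 12, 12)
  moved <- bifurcation_cloud(p, 12, 12, frame = frame)
  expected <- t(R %*% t(base$coords)) + rep(tr, each = nrow(base$coords))
  expect_lt(max(abs(moved$coords - expected)), 1e-9)
})

test_that("junction points are labeled and all labels are meaningful", {
  cl <- small_cloud(16, 16)
  expect_setequal(unique(cl$vessel_label),
                  c("LM", "LAD", "LCX", "JUNCTION"))
  # junction points cluster near the origin (bifurcation point)
  d0 <- sqrt(rowSums(cl$coords^2))
  expect_lt(max(d0[cl$vessel_label == "JUNCTION"]),
            min(max(d0), 6 * demo_params()$d_lm))
})
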