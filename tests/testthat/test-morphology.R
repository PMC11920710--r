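test_that("parameter ranges validate their invariants", {
  expect_s3_class(morph_ranges(), "morph_ranges")
  expect_error(morph_ranges(d_lm = c(4, 2)), "min 4 > max 2")
  expect_error(morph_ranges(d_lm = c(-1, 2)), "positive")
  expect_error(morph_ranges(gamma = c(90, 181)), "\\(0, 180\\)")
})

test_that("morphology sampling covers the ranges and is seed-deterministic", {
  r <- morph_ranges()
  m <- sample_morphologies(r, n = 200, seed = 0)
  expect_equal(nrow(m), 200)
  expect_true(all(m$d_lm >= r$d_lm[1] & m$d_lm <= r$d_lm[2]))
  expect_true(all(m$d_lcx >= 1.5 & m$d_lcx <= 3.5))
  expect_true(all(m$d_lad >= 1.5 & m$d_lad <= 3.5))
  expect_true(all(m$gamma >= 112.75 & m$gamma <= 172.75))
  expect_true(all(m$alpha >= 15 & m$alpha <= 130))
  expect_false(anyDuplicated(m$model_id) > 0)

  m2 <- sample_morphologies(r, n = 200, seed = 0)
  expect_identical(m, m2)
  m3 <- sample_morphologies(r, n = 200, seed = 1)
  expect_false(identical(m$d_lm, m3$d_lm))

  lhs1 <- sample_morphologies(r, n = 50, seed = 3, method = "lhs")
  lhs2 <- sample_morphologies(r, n = 50, seed = 3, method = "lhs")
  expect_identical(lhs1, lhs2)
  expect_true(all(lhs1$alpha >= 15 & lhs1$alpha <= 130))
})

test_that("degenerate ranges return the single corner vector", {
  r <- morph_ranges(d_lm = c(3, 3), d_lcx = c(2, 2), d_lad = c(2, 2),
                    gamma = c(150, 150), alpha = c(60, 60))
  m <- sample_morphologies(r, n = 1, seed = 9)
  expect_equal(unlist(m[1, -1]), c(d_lm = 3, d_lcx = 2, d_lad = 2,
                                   gamma = 150, alpha = 60))
})

test_that("batch-wise split manifest reproduces the dataset-scale counts", {
  ids <- sprintf("m%04d", 0:1799)
  sm <- make_splits(ids, batch_size = 300, test_per_batch = 60,
                    val_frac = 0.10, seed = 0)
  expect_length(sm$test_ids, 360)
  expect_length(sm$val_ids, 144)
  expect_length(sm$train_ids, 1296)
  # each consecutive batch contributes exactly its quota
  batch_of <- (match(sm$test_ids, ids) - 1L) %/% 300L
  expect_equal(as.vector(table(batch_of)), rep(60L, 6L))
})

test_that("splits partition the ids for randomized configurations", {
  set.seed(42)
  for (i in 1:8) {
    nb <- sample(2:6, 1)
    bs <- sample(c(10L, 20L, 50L), 1)
    tpb <- sample.int(bs - 1L, 1)
    vf <- stats::runif(1, 0, 0.4)
    ids <- sprintf("id%03d", seq_len(nb * bs))
    sm <- make_splits(ids, batch_size = bs, test_per_batch = tpb,
                      val_frac = vf, seed = i)
    expect_length(sm$test_ids, nb * tpb)
    expect_length(intersect(sm$test_ids, sm$val_ids), 0)
    expect_length(intersect(sm$test_ids, sm$train_ids), 0)
    expect_length(intersect(sm$val_ids, sm$train_ids), 0)
    expect_setequal(c(sm$test_ids, sm$val_ids, sm$train_ids), ids)
    expect_length(sm$val_ids, round(vf * (nb * bs - nb * tpb)))
  }
})

test_that("split manifests are seed-deterministic and seed-sensitive", {
  ids <- sprintf("m%03d", 1:300)
  a <- make_splits(ids, 100, 20, 0.1, seed = 5)
  b <- make_splits(ids, 100, 20, 0.1, seed = 5)
  expect_identical(a, b)
  diffs <- vapply(1:5, function(s) {
    !setequal(make_splits(ids, 100, 20, 0.1, seed = s)$test_ids,
              make_splits(ids, 100, 20, 0.1, seed = s + 100)$test_ids)
  }, logical(1))
  expect_true(any(diffs))
})

test_that("empty splits and invalid configurations are handled", {
  ids <- sprintf("m%02d", 1:20)
  sm <- make_splits(ids, batch_size = 10, test_per_batch = 0, val_frac = 0,
                    seed = 0)
  expect_length(sm$train_ids, 20)
  expect_length(sm$test_ids, 0)
  expect_error(make_splits(ids, batch_size = 7, test_per_batch = 2,
                           val_frac = 0.1, seed = 0), "20.*7|7.*20")
  expect_error(make_splits(ids, batch_size = 10, test_per_batch = 10,
                           val_frac = 0.1, seed = 0), "test_per_batch")
})

test_that("manifest JSON round-trips with morphologies", {
  morph <- sample_morphologies(n = 12, seed = 2)
  sm <- make_splits(morph$model_id, batch_size = 6, test_per_batch = 2,
                    val_frac = 0.2, seed = 3)
  sm$tawss_global_min <- 1.5
  sm$tawss_global_max <- 12.25
  path <- withr::local_tempfile(fileext = ".json")
  write_manifest(sm, path, morph = morph)
  back <- read_manifest(path)
  expect_identical(back$test_ids, sm$test_ids)
  expect_identical(back$val_ids, sm$val_ids)
  expect_identical(back$train_ids, sm$train_ids)
  expect_equal(back$tawss_global_max, 12.25)
  expect_equal(as.data.frame(back$morphologies)$d_lm, morph$d_lm)
})
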