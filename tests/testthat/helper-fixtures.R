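# Shared fixtures: a mid-range morphology, small clouds, and a helper that
# permutes a cloud's points consistently across all per-point fields.

demo_params <- function(model_id = "demo") {
  list(d_lm = 3.18, d_lcx = 2.3, d_lad = 2.7, gamma = 150, alpha = 70,
       model_id = model_id)
}

small_cloud <- local({
  cache <- new.env(parent = emptyenv())
  function(rows = 16L, cols = 16L) {
    key <- paste0(rows, "x", cols)
    if (is.null(cache[[key]])) {
      cache[[key]] <- bifurcation_cloud(demo_params(), rows, cols)
    }
    cache[[key]]
  }
})

permute_cloud <- function(cloud, perm) {
  cloud$coords <- cloud$coords[perm, , drop = FALSE]
  cloud$vessel_label <- cloud$vessel_label[perm]
  cloud$station_index <- cloud$station_index[perm]
  cloud$circ_angle <- cloud$circ_angle[perm]
  cloud$station_vessel <- cloud$station_vessel[perm]
  cloud$vessel_dist <- cloud$vessel_dist[perm, , drop = FALSE]
  cloud
}

# tiny labeled dataset with an all-train manifest, reused across tests
tiny_dataset <- local({
  cache <- new.env(parent = emptyenv())
  function(n = 5L, rows = 16L, seed = 1L) {
    key <- paste(n, rows, seed, sep = "_")
    if (is.null(cache[[key]])) {
      morph <- sample_morphologies(n = n, seed = seed)
      man <- make_splits(morph$model_id, batch_size = n, test_per_batch = 0L,
                         val_frac = 0, seed = 0L)
      data <- generate_tawss_data(morph, man, grid_rows = rows,
                                  grid_cols = rows)
      cache[[key]] <- data
    }
    cache[[key]]
  }
})
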