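# Shared fixtures: geometric masks, random instance maps, and memoised tiny
# models so repeated tests do not rebuild networks.

disk_mask <- function(H, W, cy, cx, r) {
  Y <- matrix(seq_len(H), H, W)
  X <- matrix(seq_len(W), H, W, byrow = TRUE)
  (Y - cy)^2 + (X - cx)^2 <= r^2
}

rect_mask <- function(H, W, r1, r2, c1, c2) {
  m <- matrix(FALSE, H, W)
  m[r1:r2, c1:c2] <- TRUE
  m
}

# Random instance map with up to max_obj rectangular/disk objects that may
# overlap; used to exercise the AJI implementations.
random_instance_map <- function(H = 32, W = 32, max_obj = 5) {
  n <- sample.int(max_obj + 1, 1) - 1L   # 0..max_obj
  objs <- list()
  for (k in seq_len(n)) {
    if (runif(1) < 0.5) {
      r1 <- sample.int(H - 4, 1); c1 <- sample.int(W - 4, 1)
      m <- rect_mask(H, W, r1, min(H, r1 + sample.int(8, 1)),
                     c1, min(W, c1 + sample.int(8, 1)))
    } else {
      m <- disk_mask(H, W, runif(1, 4, H - 4), runif(1, 4, W - 4),
                     runif(1, 2, 5))
    }
    if (any(m)) objs[[length(objs) + 1L]] <- list(label_id = length(objs) + 1L,
                                                  mask = m)
  }
  instance_map(objs, shape = c(H, W))
}

tiny_model_cache <- new.env(parent = emptyenv())

tiny_sunets <- function(in_channels = 3L, seed = 7L) {
  key <- paste0("m", in_channels, "_", seed)
  if (is.null(tiny_model_cache[[key]]))
    tiny_model_cache[[key]] <- build_sunets(in_channels, base_width = 8L,
                                            depth = 3L, agm_width = 8L,
                                            seed = seed)
  tiny_model_cache[[key]]
}

micro_sunets <- function(in_channels = 3L, seed = 5L) {
  key <- paste0("u", in_channels, "_", seed)
  if (is.null(tiny_model_cache[[key]]))
    tiny_model_cache[[key]] <- build_sunets(in_channels, base_width = 4L,
                                            depth = 2L, agm_width = 4L,
                                            seed = seed)
  tiny_model_cache[[key]]
}

small_trainset <- function(n, seed = 11L, canvas = 32L,
                           overlap_fraction = 0.5) {
  spec <- scene_spec(canvas = c(canvas, canvas), n_nuclei = 3L,
                     radius_range = c(3, 6),
                     overlap_fraction = overlap_fraction, seed = seed)
  seeds <- sunseg:::derive_seeds(seed, n)
  lapply(seeds, function(s) { sp <- spec; sp$seed <- s; generate_sample(sp) })
}
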