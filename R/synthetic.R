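#' Specification of a synthetic overlapping-nuclei scene
#'
#' Defines the study conditions of the generator: canvas size, nucleus count
#' and size range, the target fraction of nuclei placed to overlap an
#' existing neighbour, stain-like colors, and additive noise. Defaults mimic
#' hematoxylin-and-eosin appearance: purple nuclei on a pink background.
#'
#' @param canvas Integer `(H, W)` canvas in pixels.
#' @param n_nuclei Number of nuclei to place.
#' @param radius_range `(min, max)` of ellipse semi-axes in pixels.
#' @param overlap_fraction Target fraction of nuclei (after the first)
#'   placed within one diameter of an existing nucleus to force overlap,
#'   in `[0, 1]`.
#' @param nucleus_color,background_color Mean RGB triples in `[0, 255]`.
#' @param noise_sd Additive Gaussian noise standard deviation (intensity
#'   units on the 0--255 scale).
#' @param color_jitter Per-nucleus RGB jitter standard deviation.
#' @param seed RNG seed; fixed seed gives bit-identical samples.
#' @param max_tries Placement retries per nucleus before giving up.
#' @return List of class `scene_spec`.
#' @export
scene_spec <- function(canvas = c(64L, 64L), n_nuclei = 5L,
                       radius_range = c(4, 9), overlap_fraction = 0.5,
                       nucleus_color = c(90, 60, 150),
                       background_color = c(230, 200, 215),
                       noise_sd = 8, color_jitter = 12, seed = 1L,
                       max_tries = 100L) {
  stopifnot(overlap_fraction >= 0, overlap_fraction <= 1,
            radius_range[1] > 0, radius_range[1] <= radius_range[2],
            all(nucleus_color >= 0), all(nucleus_color <= 255),
            all(background_color >= 0), all(background_color <= 255))
  if (any(canvas < 2 * radius_range[2] + 2))
    stop_sunseg("canvas too small for the maximum nucleus radius",
                "sunseg_size_error")
  structure(list(canvas = as.integer(canvas), n_nuclei = as.integer(n_nuclei),
                 radius_range = radius_range,
                 overlap_fraction = overlap_fraction,
                 nucleus_color = nucleus_color,
                 background_color = background_color,
                 noise_sd = noise_sd, color_jitter = color_jitter,
                 seed = as.integer(seed), max_tries = as.integer(max_tries)),
            class = "scene_spec")
}

ellipse_mask <- function(H, W, cy, cx, a, b, theta) {
  Y <- matrix(seq_len(H), H, W) - cy
  X <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  u <- X * cos(theta) + Y * sin(theta)
  v <- -X * sin(theta) + Y * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Generate one synthetic sample with full ground truth
#'
#' Places rotated filled ellipses on the canvas. With probability
#' `overlap_fraction` a nucleus is centred within one diameter of a
#' previously placed nucleus (and is required to actually intersect it);
#' otherwise placement keeps clear of existing nuclei. Rendering is
#' multiplicative stain attenuation -- each covering nucleus darkens the
#' pixel towards its jittered color -- so doubly covered (overlap) pixels
#' are darker than singly covered ones, as chromatin-dense overlaps are in
#' real stained tissue. Gaussian noise is added and intensities are rounded
#' and clipped to `[0, 255]`.
#'
#' @param spec A [scene_spec].
#' @return List of class `synthetic_sample` with elements `image`
#'   ([rgb_patch]), `instances` ([instance_map]), `semantic_mask` and
#'   `overlap_mask` (logical matrices).
#' @export
generate_sample <- function(spec) {
  set.seed(spec$seed)
  H <- spec$canvas[1]; W <- spec$canvas[2]
  rmax <- spec$radius_range[2]
  lo <- rmax + 1; hiH <- H - rmax; hiW <- W - rmax
  centers <- matrix(0, 0, 2)
  majors <- numeric(0)
  masks <- list()
  for (k in seq_len(spec$n_nuclei)) {
    a <- runif(1, spec$radius_range[1], spec$radius_range[2])
    b <- runif(1, spec$radius_range[1], a)
    theta <- runif(1, 0, pi)
    want_overlap <- k > 1 && runif(1) < spec$overlap_fraction
    placed <- FALSE
    for (try in seq_len(spec$max_tries)) {
      if (want_overlap) {
        # partial overlap: centres at 0.5-0.95 of the summed semi-majors
        # (within one diameter), so both nuclei stay distinguishable --
        # near-concentric placements would not be annotated as two nuclei
        j <- sample.int(nrow(centers), 1)
        d <- runif(1, 0.5, 0.95) * (majors[j] + a)
        ang <- runif(1, 0, 2 * pi)
        cy <- min(max(centers[j, 1] + d * sin(ang), lo), hiH)
        cx <- min(max(centers[j, 2] + d * cos(ang), lo), hiW)
      } else {
        cy <- runif(1, lo, hiH)
        cx <- runif(1, lo, hiW)
      }
      m <- ellipse_mask(H, W, cy, cx, a, b, theta)
      if (!any(m)) next
      hits <- length(masks) > 0 &&
        any(vapply(masks, function(mm) any(mm & m), logical(1)))
      ok <- if (want_overlap) hits else !hits
      if (ok) {
        centers <- rbind(centers, c(cy, cx))
        majors <- c(majors, a)
        masks[[length(masks) + 1L]] <- m
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop_sunseg(sprintf(
        "could not place nucleus %d after %d tries (achieved %d of %d)",
        k, spec$max_tries, length(masks), spec$n_nuclei),
        "sunseg_generation_error")
  }
  cover <- matrix(0L, H, W)
  logimg <- array(0, c(H, W, 3))
  for (ch in 1:3) logimg[, , ch] <- log(max(spec$background_color[ch], 1))
  for (m in masks) {
    cover <- cover + m
    col <- pmin(pmax(spec$nucleus_color + rnorm(3, sd = spec$color_jitter),
                     15), 240)
    for (ch in 1:3) {
      att <- log(col[ch] / max(spec$background_color[ch], 1))
      logimg[, , ch] <- logimg[, , ch] + att * m
    }
  }
  img <- exp(logimg)
  if (spec$noise_sd > 0)
    img <- img + array(rnorm(H * W * 3, sd = spec$noise_sd), c(H, W, 3))
  img <- pmin(pmax(round(img), 0), 255)
  objs <- lapply(seq_along(masks), function(i)
    list(label_id = i, mask = masks[[i]]))
  structure(list(
    image = rgb_patch(img),
    instances = instance_map(objs, shape = c(H, W)),
    semantic_mask = cover > 0L,
    overlap_mask = cover >= 2L), class = "synthetic_sample")
}

derive_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate a synthetic dataset on disk
#'
#' Writes, per sample, the image (PNG), the instance masks (lossless RLE
#' CSV), and the semantic and overlap masks (PNG), plus a `manifest.csv`.
#' Per-sample seeds are derived deterministically from the master seed, so
#' a rerun with the same seed reproduces identical file bytes.
#'
#' @param spec A [scene_spec]; its `seed` is the master seed.
#' @param n_images Number of samples.
#' @param out_dir Output directory (created if missing).
#' @return The manifest as a data frame (invisibly written to
#'   `manifest.csv`): columns `sample_id`, the four file paths, `n_nuclei`,
#'   `n_overlap_pixels`.
#' @export
generate_dataset <- function(spec, n_images, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0)
    stop_sunseg(paste0("output directory not writable: ", out_dir),
                "sunseg_io_error")
  seeds <- derive_seeds(spec$seed, n_images)
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    s <- spec; s$seed <- seeds[i]
    smp <- generate_sample(s)
    id <- sprintf("sample_%04d", i)
    paths <- c(image = file.path(out_dir, paste0(id, "_image.png")),
               instances = file.path(out_dir, paste0(id, "_instances.csv")),
               semantic = file.path(out_dir, paste0(id, "_semantic.png")),
               overlap = file.path(out_dir, paste0(id, "_overlap.png")))
    write_image(smp$image, paths["image"])
    write_instances_rle(smp$instances, paths["instances"])
    write_mask(smp$semantic_mask, paths["semantic"])
    write_mask(smp$overlap_mask, paths["overlap"])
    rows[[i]] <- data.frame(
      sample_id = id, image = paths[["image"]],
      instances = paths[["instances"]], semantic = paths[["semantic"]],
      overlap = paths[["overlap"]], n_nuclei = n_objects(smp$instances),
      n_overlap_pixels = sum(smp$overlap_mask))
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Load a dataset manifest into memory
#'
#' Reads the files referenced by a `manifest.csv` produced by
#' [generate_dataset()] back into a list of samples.
#'
#' @param manifest Data frame or path to `manifest.csv`.
#' @return List of samples, each with `image`, `instances`,
#'   `semantic_mask`, `overlap_mask`.
#' @export
load_dataset <- function(manifest) {
  if (is.character(manifest)) manifest <- read.csv(manifest)
  if (!nrow(manifest)) stop_sunseg("empty dataset manifest", "sunseg_data_error")
  lapply(seq_len(nrow(manifest)), function(i) list(
    image = read_image(manifest$image[i]),
    instances = read_instances_rle(manifest$instances[i]),
    semantic_mask = read_mask(manifest$semantic[i]),
    overlap_mask = read_mask(manifest$overlap[i])))
}
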