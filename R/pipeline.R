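# End-to-end orchestration: tile -> stage-1 stacked U-Net -> stitch ->
# threshold -> watershed -> stage-2 stacked U-Net on the 4-channel input ->
# overlap components -> merge.

#' Run the full two-stage pipeline on one image
#'
#' @param image [rgb_patch] (any size at least `patch_size`).
#' @param stage1 Trained 3-channel `sunets` model.
#' @param stage2 Trained 4-channel `sunets` model, or `NULL` to stop after
#'   stage one (watershed instances only).
#' @param patch_size,stride Tiling parameters; patches at the borders are
#'   shifted inward and overlaps averaged when stitching.
#' @param threshold Probability cut for both stages.
#' @param min_overlap Merge threshold in pixels, see [merge_overlaps()].
#' @param ... Watershed parameters passed to [watershed_instances()].
#' @return List with `instances` (final [instance_map]), `instances_stage1`,
#'   `semantic_prob`, `semantic_mask`, `overlap_prob`, `overlap_mask`,
#'   `components`.
#' @export
predict_image <- function(image, stage1, stage2 = NULL, patch_size = 64L,
                          stride = patch_size, threshold = 0.5,
                          min_overlap = 10L, ...) {
  px <- if (inherits(image, "rgb_patch")) image$pixels else as_hwc(image)
  shape <- dim(px)[1:2]
  tiles <- tile_patches(image, patch_size, stride)
  pieces <- lapply(tiles, function(tl)
    list(map = sunets_forward(stage1, tl), origin = tl$origin))
  prob1 <- stitch_patches(pieces, shape)
  mask1 <- binarize(prob1, threshold)
  inst1 <- watershed_instances(mask1, ...)
  if (is.null(stage2))
    return(list(instances = inst1, instances_stage1 = inst1,
                semantic_prob = prob1, semantic_mask = mask1,
                overlap_prob = NULL, overlap_mask = NULL, components = NULL))
  x2 <- make_stage2_input(px, mask1)
  tiles2 <- tile_patches(x2, patch_size, stride)
  pieces2 <- lapply(tiles2, function(tl)
    list(map = sunets_forward(stage2, tl$pixels), origin = tl$origin))
  prob2 <- stitch_patches(pieces2, shape)
  mask2 <- binarize(prob2, threshold)
  comps <- extract_overlap_components(mask2)
  inst <- merge_overlaps(inst1, comps, min_overlap = min_overlap)
  list(instances = inst, instances_stage1 = inst1, semantic_prob = prob1,
       semantic_mask = mask1, overlap_prob = prob2, overlap_mask = mask2,
       components = comps)
}

#' Batch prediction over image files
#'
#' Runs [predict_image()] on every file and writes, per image, the final
#' instances (16-bit label TIFF rendering plus lossless RLE CSV), the
#' semantic mask and, when stage two is given, the overlap mask, along with
#' a manifest and a JSON run log recording the configuration.
#'
#' @param paths Character vector of image files (PNG/TIFF).
#' @param stage1,stage2 Trained models (`stage2` may be `NULL`).
#' @param out_dir Output directory.
#' @param ... Passed to [predict_image()].
#' @return Manifest data frame. Unreadable images are skipped with a
#'   warning; an error is raised if every image fails.
#' @export
predict_files <- function(paths, stage1, stage2 = NULL, out_dir, ...) {
  if (!length(paths)) stop_sunseg("no input images", "sunseg_data_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (p in paths) {
    img <- tryCatch(read_image(p), error = function(e) {
      warning(sprintf("skipping unreadable image %s: %s", p,
                      conditionMessage(e)))
      NULL
    })
    if (is.null(img)) next
    res <- predict_image(img, stage1, stage2, ...)
    id <- tools::file_path_sans_ext(basename(p))
    lab_path <- file.path(out_dir, paste0(id, "_instances.tif"))
    rle_path <- file.path(out_dir, paste0(id, "_instances.csv"))
    sem_path <- file.path(out_dir, paste0(id, "_semantic.png"))
    write_label_map(flatten_instances(res$instances), lab_path)
    write_instances_rle(res$instances, rle_path)
    write_mask(res$semantic_mask, sem_path)
    ovl_path <- NA_character_
    if (!is.null(res$overlap_mask)) {
      ovl_path <- file.path(out_dir, paste0(id, "_overlap.png"))
      write_mask(res$overlap_mask, ovl_path)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      image = p, instances = rle_path, label_map = lab_path,
      semantic = sem_path, overlap = ovl_path,
      n_instances = n_objects(res$instances))
  }
  if (!length(rows))
    stop_sunseg("all input images failed to load", "sunseg_data_error")
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "predictions.csv"),
            row.names = FALSE)
  manifest
}

#' Recall of ground-truth overlap pixels
#'
#' Predicted overlap pixels are those covered by at least two final
#' instance masks; after stage one alone the watershed instances are
#' disjoint, so this recall is zero whenever ground truth contains overlap
#' -- the quantity stage two exists to improve.
#'
#' @param gt_overlap Logical ground-truth overlap mask.
#' @param pred_instances Final [instance_map].
#' @return `list(tp, positives)` pixel counts.
#' @export
overlap_recall_counts <- function(gt_overlap, pred_instances) {
  pred_ovl <- coverage_from_instances(pred_instances) >= 2L
  list(tp = sum(gt_overlap & pred_ovl), positives = sum(gt_overlap))
}

#' Scaled-down end-to-end demonstration
#'
#' Generates a synthetic train/test split of overlapping-nuclei images,
#' trains tiny stage-one and stage-two stacked U-Nets from scratch on one
#' CPU, predicts on the held-out images, and evaluates: overall AJI and F1,
#' AJI of the overlap regions (ground-truth overlap components vs predicted
#' ones), and pooled overlap-pixel recall with stage two enabled vs stage
#' one alone. All randomness derives from `seed`.
#'
#' @param seed Master seed.
#' @param out_dir If non-`NULL`, the report (JSON), per-image scores (CSV)
#'   and trained models (RDS) are written there.
#' @param n_train,n_test Number of training / held-out images.
#' @param epochs Epochs for stage one.
#' @param epochs_stage2 Epochs for stage two.
#' @param overlap_fraction Generator overlap fraction.
#' @param base_width,depth,agm_width,patch_size Tiny network profile.
#' @param lr,batch_size Optimizer settings for the tiny profile.
#' @param lr_stage2 Stage-two learning rate; larger than `lr` because the
#'   focal modulation `(1 - p_t)^gamma` scales early-training gradients
#'   down by roughly an order of magnitude.
#' @param focal_alpha Foreground weight of the stage-two focal loss; the
#'   demo weights the rare overlap class at 0.75 (roughly the complement
#'   of its prior) so the detector is calibrated around the 0.5 cut.
#' @param n_nuclei,radius_range,noise_sd Scene settings per [scene_spec()].
#' @param verbose Log progress to stderr.
#' @return Report list; see Details in the package vignette.
#' @export
run_demo <- function(seed = 1L, out_dir = NULL, n_train = 200L, n_test = 25L,
                     epochs = 2L, overlap_fraction = 0.5, base_width = 8L,
                     depth = 3L, agm_width = 8L, patch_size = 64L, lr = 0.05,
                     batch_size = 4L, focal_alpha = 0.75, lr_stage2 = 0.4,
                     epochs_stage2 = 3L, n_nuclei = 5L,
                     radius_range = c(4, 9), noise_sd = 8, verbose = TRUE) {
  t0 <- Sys.time()
  spec <- scene_spec(canvas = c(patch_size, patch_size), n_nuclei = n_nuclei,
                     radius_range = radius_range,
                     overlap_fraction = overlap_fraction,
                     noise_sd = noise_sd, seed = seed)
  seeds <- derive_seeds(seed, n_train + n_test + 3L)
  gen <- function(s) { sp <- spec; sp$seed <- s; generate_sample(sp) }
  train_set <- lapply(seeds[seq_len(n_train)], gen)
  test_set <- lapply(seeds[n_train + seq_len(n_test)], gen)
  if (verbose) message(sprintf("[demo] generated %d train / %d test images",
                               n_train, n_test))
  stage1 <- build_sunets(3L, base_width, depth, agm_width,
                         seed = seeds[n_train + n_test + 1L])
  cfg1 <- train_config(lr = lr, batch_size = batch_size, epochs = epochs,
                       loss = "cross_entropy",
                       seed = seeds[n_train + n_test + 2L], verbose = verbose)
  tr1 <- train_stage(stage1, train_set, "semantic", cfg1)
  stage1 <- tr1$model
  stage2 <- build_sunets(4L, base_width, depth, agm_width,
                         seed = seeds[n_train + n_test + 3L])
  cfg2 <- train_config(lr = lr_stage2, batch_size = batch_size,
                       epochs = epochs_stage2, loss = "focal",
                       focal_alpha = focal_alpha,
                       seed = seeds[n_train + n_test + 2L], verbose = verbose)
  tr2 <- train_stage(stage2, train_set, "overlap", cfg2)
  stage2 <- tr2$model
  if (verbose) message("[demo] training done, predicting held-out images")
  pairs <- list()
  ovl_rows <- list()
  tp2 <- pos2 <- tp1 <- pos1 <- 0
  for (i in seq_along(test_set)) {
    smp <- test_set[[i]]
    res <- predict_image(smp$image, stage1, stage2, patch_size = patch_size)
    pairs[[i]] <- list(gt = smp$instances, pred = res$instances)
    rc2 <- overlap_recall_counts(smp$overlap_mask, res$instances)
    rc1 <- overlap_recall_counts(smp$overlap_mask, res$instances_stage1)
    tp2 <- tp2 + rc2$tp; pos2 <- pos2 + rc2$positives
    tp1 <- tp1 + rc1$tp; pos1 <- pos1 + rc1$positives
    gt_comps <- extract_overlap_components(smp$overlap_mask)
    gt_ovl_map <- instance_map(lapply(gt_comps, function(cm)
      list(label_id = cm$component_id, mask = cm$mask)),
      shape = dim(smp$overlap_mask))
    pred_ovl <- coverage_from_instances(res$instances) >= 2L
    pred_comps <- extract_overlap_components(pred_ovl)
    pred_ovl_map <- instance_map(lapply(pred_comps, function(cm)
      list(label_id = cm$component_id, mask = cm$mask)),
      shape = dim(pred_ovl))
    ovl_rows[[i]] <- aji(gt_ovl_map, pred_ovl_map)
  }
  ev <- evaluate_set(pairs)
  report <- list(
    seed = seed,
    n_train = n_train, n_test = n_test, epochs = epochs,
    epochs_stage2 = epochs_stage2,
    overall_aji = ev$overall$aji,
    overall_f1 = ev$overall$f1,
    overall_precision = ev$overall$precision,
    overall_recall = ev$overall$recall,
    overlap_region_aji = mean(unlist(ovl_rows)),
    overlap_recall_stage2 = if (pos2 > 0) tp2 / pos2 else 1,
    overlap_recall_stage1 = if (pos1 > 0) tp1 / pos1 else 1,
    loss_history_stage1 = tr1$history,
    loss_history_stage2 = tr2$history,
    runtime_sec = as.numeric(Sys.time() - t0, units = "secs"),
    per_image = ev$per_image)
  if (verbose)
    message(sprintf(
      "[demo] AJI %.4f  F1 %.4f  overlap-AJI %.4f  ovl-recall s2 %.4f vs s1 %.4f (%.0f s)",
      report$overall_aji, report$overall_f1, report$overlap_region_aji,
      report$overlap_recall_stage2, report$overlap_recall_stage1,
      report$runtime_sec))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report[setdiff(names(report), "per_image")],
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    write.csv(report$per_image, file.path(out_dir, "per_image.csv"),
              row.names = FALSE)
    saveRDS(stage1, file.path(out_dir, "stage1.rds"))
    saveRDS(stage2, file.path(out_dir, "stage2.rds"))
  }
  report
}

#' Evaluate prediction files against ground truth files
#'
#' Matches `*_instances.csv` RLE files in the two directories by sample
#' name and computes per-image and overall scores.
#'
#' @param gt_dir,pred_dir Directories holding RLE instance CSVs.
#' @param out_csv Optional path for the per-image + overall score table.
#' @return `list(per_image, overall)` as in [evaluate_set()].
#' @export
evaluate_dirs <- function(gt_dir, pred_dir, out_csv = NULL) {
  gts <- sort(list.files(gt_dir, pattern = "_instances\\.csv$",
                         full.names = TRUE))
  if (!length(gts)) stop_sunseg("no ground truth files", "sunseg_data_error")
  pairs <- list()
  for (g in gts) {
    p <- file.path(pred_dir, basename(g))
    if (!file.exists(p))
      stop_sunseg(paste0("missing prediction for ", basename(g)),
                  "sunseg_data_error")
    pairs[[length(pairs) + 1L]] <- list(gt = read_instances_rle(g),
                                        pred = read_instances_rle(p))
  }
  ev <- evaluate_set(pairs)
  if (!is.null(out_csv)) {
    d <- ev$per_image
    d$image <- basename(gts)
    d <- rbind(d, data.frame(image = "overall", aji = ev$overall$aji,
                             precision = ev$overall$precision,
                             recall = ev$overall$recall, f1 = ev$overall$f1,
                             TP = ev$overall$confusion$TP,
                             FP = ev$overall$confusion$FP,
                             FN = ev$overall$confusion$FN,
                             TN = ev$overall$confusion$TN))
    write.csv(d, out_csv, row.names = FALSE)
  }
  ev
}
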