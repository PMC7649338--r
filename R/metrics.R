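# Object-level (Aggregated Jaccard Index) and pixel-level
# (precision/recall/F1) segmentation metrics.

jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Segmentation score container
#' @param aji Aggregated Jaccard Index (or `NA`).
#' @param precision,recall,f1 Pixel-level ratios.
#' @param confusion List with `TP`, `FP`, `FN`, `TN` pixel counts.
#' @return List of class `seg_scores`.
#' @export
seg_scores <- function(aji = NA_real_, precision = NA_real_,
                       recall = NA_real_, f1 = NA_real_, confusion = NULL) {
  structure(list(aji = aji, precision = precision, recall = recall,
                 f1 = f1, confusion = confusion), class = "seg_scores")
}

#' @export
print.seg_scores <- function(x, ...) {
  cat(sprintf("<seg_scores AJI %.4f  precision %.4f  recall %.4f  F1 %.4f>\n",
              x$aji, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Aggregated Jaccard Index
#'
#' For each ground-truth object the predicted object with maximum Jaccard
#' index is selected (ties broken by lowest predicted label id; no
#' intersecting prediction means an empty match contributing the GT area to
#' the union sum). AJI is the summed best-match intersections divided by
#' the summed best-match unions plus the areas of unmatched predictions.
#' Objects are compared mask-wise, so overlapping per-object masks are
#' handled exactly.
#'
#' @param gt,pred [instance_map] objects of the same shape.
#' @param variant How unmatched predictions are defined: `"printed"`
#'   penalizes predictions with no intersection with any GT object (the
#'   definition as printed in the source formulation); `"used_flag"`
#'   additionally penalizes predictions that intersect GT but are never
#'   selected as a best match (the original AJI reference behaviour).
#' @return AJI in `[0, 1]`. Empty vs empty is 1 by convention; one side
#'   empty is 0.
#' @export
aji <- function(gt, pred, variant = c("printed", "used_flag")) {
  variant <- match.arg(variant)
  if (!identical(gt$shape, pred$shape))
    stop_sunseg("instance map shapes differ", "sunseg_shape_error")
  K <- n_objects(gt); L <- n_objects(pred)
  if (K == 0 && L == 0) return(1)
  if (K == 0 || L == 0) return(0)
  pm <- vapply(pred$objects, function(o) as.vector(o$mask),
               logical(prod(pred$shape)))
  num <- 0; den <- 0
  used <- logical(L)
  touched <- logical(L)
  for (i in seq_len(K)) {
    gv <- as.vector(gt$objects[[i]]$mask)
    inter <- colSums(pm & gv)
    touched <- touched | inter > 0
    ga <- sum(gv)
    if (all(inter == 0)) {
      den <- den + ga
      next
    }
    uni <- ga + colSums(pm) - inter
    J <- inter / uni
    j <- which.max(J)  # first maximum = lowest label id (objects id-sorted)
    num <- num + inter[j]
    den <- den + uni[j]
    used[j] <- TRUE
  }
  unmatched <- if (variant == "printed") !touched else !used
  den <- den + sum(vapply(pred$objects[unmatched], function(o) sum(o$mask),
                          numeric(1)))
  num / den
}

#' Brute-force AJI oracle
#'
#' Recomputes the AJI contract by direct enumeration over pixel index sets
#' (`which`/`intersect`/`union`), independent of the vectorised
#' implementation in [aji()]. Intended for testing on small maps.
#'
#' @inheritParams aji
#' @return AJI in `[0, 1]`.
#' @export
aji_bruteforce <- function(gt, pred, variant = c("printed", "used_flag")) {
  variant <- match.arg(variant)
  if (!identical(gt$shape, pred$shape))
    stop_sunseg("instance map shapes differ", "sunseg_shape_error")
  if (n_objects(gt) > 8 || n_objects(pred) > 8)
    stop_sunseg("brute-force oracle limited to 8 objects per map",
                "sunseg_size_error")
  K <- n_objects(gt); L <- n_objects(pred)
  if (K == 0 && L == 0) return(1)
  if (K == 0 || L == 0) return(0)
  gsets <- lapply(gt$objects, function(o) which(o$mask))
  psets <- lapply(pred$objects, function(o) which(o$mask))
  num <- 0; den <- 0
  used <- rep(FALSE, L); touched <- rep(FALSE, L)
  for (i in seq_len(K)) {
    best_j <- 0; best_J <- -1
    for (j in seq_len(L)) {
      inter <- length(intersect(gsets[[i]], psets[[j]]))
      if (inter > 0) touched[j] <- TRUE
      J <- inter / length(union(gsets[[i]], psets[[j]]))
      if (J > best_J) { best_J <- J; best_j <- j }
    }
    if (best_J > 0) {
      num <- num + length(intersect(gsets[[i]], psets[[best_j]]))
      den <- den + length(union(gsets[[i]], psets[[best_j]]))
      used[best_j] <- TRUE
    } else {
      den <- den + length(gsets[[i]])
    }
  }
  unmatched <- if (variant == "printed") !touched else !used
  for (j in which(unmatched)) den <- den + length(psets[[j]])
  num / den
}

#' Pixel-level precision, recall and F1
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F1 = 2TP/(2TP+FN+FP)`. If both masks are empty all three are 1 by
#' convention; if exactly one is empty they are 0.
#'
#' @param gt_mask,pred_mask Binary masks of the same shape.
#' @return A [seg_scores] with the pixel fields and confusion counts set.
#' @export
pixel_scores <- function(gt_mask, pred_mask) {
  if (!identical(dim(gt_mask), dim(pred_mask)))
    stop_sunseg("mask shapes differ", "sunseg_shape_error")
  g <- gt_mask > 0; p <- pred_mask > 0
  TP <- sum(g & p); FP <- sum(!g & p); FN <- sum(g & !p); TN <- sum(!g & !p)
  if (TP + FP + FN == 0) {
    pr <- rc <- f1 <- 1
  } else {
    pr <- if (TP + FP > 0) TP / (TP + FP) else 0
    rc <- if (TP + FN > 0) TP / (TP + FN) else 0
    f1 <- 2 * TP / (2 * TP + FN + FP)
  }
  seg_scores(precision = pr, recall = rc, f1 = f1,
             confusion = list(TP = TP, FP = FP, FN = FN, TN = TN))
}

#' Evaluate a set of ground-truth/prediction pairs
#'
#' Computes per-image AJI (object-level) and precision/recall/F1 on the
#' semantic union masks (pixel-level), reports their unweighted means over
#' images, and sums the confusion counts.
#'
#' @param pairs Nonempty list of `list(gt, pred)` [instance_map] pairs.
#' @param variant Passed to [aji()].
#' @return `list(per_image = data.frame, overall = seg_scores)`.
#' @export
evaluate_set <- function(pairs, variant = "printed") {
  if (!length(pairs)) stop_sunseg("empty evaluation set", "sunseg_data_error")
  rows <- lapply(seq_along(pairs), function(i) {
    gt <- pairs[[i]]$gt; pred <- pairs[[i]]$pred
    a <- aji(gt, pred, variant = variant)
    ps <- pixel_scores(semantic_from_instances(gt),
                       semantic_from_instances(pred))
    data.frame(image = i, aji = a, precision = ps$precision,
               recall = ps$recall, f1 = ps$f1,
               TP = ps$confusion$TP, FP = ps$confusion$FP,
               FN = ps$confusion$FN, TN = ps$confusion$TN)
  })
  d <- do.call(rbind, rows)
  overall <- seg_scores(aji = mean(d$aji), precision = mean(d$precision),
                        recall = mean(d$recall), f1 = mean(d$f1),
                        confusion = list(TP = sum(d$TP), FP = sum(d$FP),
                                         FN = sum(d$FN), TN = sum(d$TN)))
  list(per_image = d, overall = overall)
}
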