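box_smooth <- function(m, passes = 2L) {
  x <- array(m, c(dim(m), 1L))
  for (i in seq_len(passes))
    x <- cpp_conv2d_fwd(x, matrix(1 / 9, 1, 9), 0, 3L)
  x[, , 1]
}

#' Marker-based watershed instance extraction
#'
#' Splits a binary nucleus mask into instances via the distance-transform
#' recipe: the Euclidean distance transform (EDT) of the mask is computed,
#' nucleus-core markers are extracted from it, and a priority flood grows
#' the markers outward in order of decreasing distance, restricted to the
#' mask. Objects smaller than `min_size` pixels are removed. The resulting
#' instances partition the (size-filtered) foreground; no pixels are
#' shared at this stage.
#'
#' Two marker extraction methods are available:
#' \describe{
#'   \item{`"peaks"` (default)}{Connected plateaus of local maxima of the
#'     lightly smoothed EDT within a `(2*peak_footprint+1)` square
#'     neighbourhood, keeping peaks of smoothed distance at least
#'     `min_peak`. Robust when touching nuclei differ in size, since each
#'     nucleus core is a regional maximum regardless of its neighbour's.}
#'   \item{`"ratio"`}{Connected components of pixels whose EDT is at least
#'     `marker_ratio` times the maximum EDT of their mask component. Two
#'     touching convex objects separate when the EDT at their waist is
#'     below that fraction of the core EDT (0.7 splits moderately
#'     overlapping equal disks, whose waist/core ratio is around 0.6), but
#'     a small nucleus attached to a much larger one is missed.}
#' }
#'
#' @param mask Logical or 0/1 matrix.
#' @param min_size Minimum object area in pixels.
#' @param marker_method `"peaks"` or `"ratio"`.
#' @param peak_footprint Half-width of the local-maximum neighbourhood in
#'   pixels; should be below the minimum distance between the centres of
#'   nuclei that must be separated.
#' @param min_peak Minimum smoothed EDT of a marker, suppressing 1-pixel
#'   boundary noise peaks.
#' @param marker_ratio Core threshold for the `"ratio"` method.
#' @return An [instance_map] with disjoint masks, labels 1..n.
#' @export
watershed_instances <- function(mask, min_size = 20L,
                                marker_method = c("peaks", "ratio"),
                                peak_footprint = 2L, min_peak = 1,
                                marker_ratio = 0.7) {
  marker_method <- match.arg(marker_method)
  mask <- mask > 0
  H <- nrow(mask); W <- ncol(mask)
  if (!any(mask)) return(instance_map(list(), shape = c(H, W)))
  mi <- matrix(as.integer(mask), H)
  dist <- EBImage::distmap(mi, metric = "euclidean")
  if (marker_method == "peaks") {
    ds <- box_smooth(dist, passes = 1L)
    mx <- cpp_maxfilter(ds, as.integer(peak_footprint))
    marker_mask <- mask & ds >= mx & ds >= min_peak
  } else {
    comp <- cpp_label8(mi)
    cmax <- tapply(dist[mask], comp[mask], max)
    thr <- matrix(0, H, W)
    thr[mask] <- cmax[as.character(comp[mask])]
    marker_mask <- mask & dist >= marker_ratio * thr
  }
  markers <- cpp_label8(matrix(as.integer(marker_mask), H))
  lab <- cpp_marker_watershed(dist, markers, mi)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_size)
  lab[!(lab %in% keep)] <- 0L
  if (!any(lab > 0)) return(instance_map(list(), shape = c(H, W)))
  lab <- matrix(match(lab, sort(unique(lab[lab > 0])), nomatch = 0L), H)
  instances_from_labels(lab)
}

#' Assemble the 4-channel stage-two input
#'
#' Concatenates the RGB patch with the stage-one binary mask scaled to
#' \{0, 255\} as the fourth channel.
#'
#' @param patch [rgb_patch] or `H x W x 3` array on the 0--255 scale.
#' @param stage1_mask Logical or 0/1 matrix of the same spatial shape.
#' @return `H x W x 4` array.
#' @export
make_stage2_input <- function(patch, stage1_mask) {
  px <- if (inherits(patch, "rgb_patch")) patch$pixels else as_hwc(patch)
  if (!identical(dim(px)[1:2], dim(stage1_mask)[1:2]))
    stop_sunseg("patch and mask shapes differ", "sunseg_shape_error")
  array(c(px, (stage1_mask > 0) * 255), c(dim(px)[1:2], 4L))
}

#' Extract 8-connected components of the overlap mask
#'
#' @param overlap_mask Logical or 0/1 matrix (stage-two output).
#' @return List of class `overlap_components`; each element is
#'   `list(component_id, mask)`, components pairwise disjoint and nonempty.
#' @export
extract_overlap_components <- function(overlap_mask) {
  m <- overlap_mask > 0
  lab <- cpp_label8(matrix(as.integer(m), nrow(m)))
  ids <- seq_len(max(lab))
  comps <- lapply(ids, function(id)
    list(component_id = id, mask = lab == id))
  structure(comps, shape = dim(m), class = "overlap_components")
}

#' Merge overlap components into the instance segmentation
#'
#' For each overlap component, every instance sharing at least
#' `min_overlap` pixels with it absorbs the whole component into its mask.
#' A component intersecting several instances is added to each of them, so
#' the final per-object masks may overlap -- this is how shared nuclei
#' pixels are represented. Components matching no instance are discarded;
#' no pixel is ever removed from an instance.
#'
#' @param instances An [instance_map] (stage-one watershed result).
#' @param overlaps An `overlap_components` object.
#' @param min_overlap Minimum shared pixel count (default 10).
#' @return Updated [instance_map].
#' @export
merge_overlaps <- function(instances, overlaps, min_overlap = 10L) {
  stopifnot(min_overlap >= 1)
  if (length(overlaps) &&
      !identical(as.integer(attr(overlaps, "shape")), instances$shape))
    stop_sunseg("instance map and overlap mask shapes differ",
                "sunseg_shape_error")
  objs <- instances$objects
  for (comp in overlaps) {
    for (i in seq_along(objs)) {
      if (sum(comp$mask & objs[[i]]$mask) >= min_overlap)
        objs[[i]]$mask <- objs[[i]]$mask | comp$mask
    }
  }
  instance_map(objs, shape = instances$shape)
}
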