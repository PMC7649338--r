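#' Instance label map with overlap support
#'
#' Stores one binary mask per object so a pixel may belong to several
#' objects (overlapping nuclei). The flattened integer rendering assigns
#' each shared pixel to the lowest label id; that is a rendering convention
#' only and loses overlap information.
#'
#' @param objects List of `list(label_id, mask)`; `label_id` positive
#'   integer, `mask` logical `H x W` matrix with at least one `TRUE` pixel.
#' @param shape Integer `(H, W)`; inferred from the first mask if omitted.
#' @return Object of class `instance_map`.
#' @export
instance_map <- function(objects = list(), shape = NULL) {
  if (is.null(shape)) {
    if (!length(objects))
      stop_sunseg("shape is required for an empty instance map",
                  "sunseg_size_error")
    shape <- dim(objects[[1]]$mask)
  }
  ids <- vapply(objects, function(o) as.integer(o$label_id), integer(1))
  if (anyDuplicated(ids))
    stop_sunseg("label ids must be unique", "sunseg_format_error")
  for (o in objects) {
    if (!identical(dim(o$mask), as.integer(shape)))
      stop_sunseg("object mask shape mismatch", "sunseg_shape_error")
    if (!any(o$mask))
      stop_sunseg("object masks must be nonempty", "sunseg_format_error")
  }
  objects <- objects[order(ids)]
  structure(list(shape = as.integer(shape), objects = objects),
            class = "instance_map")
}

#' @export
print.instance_map <- function(x, ...) {
  cat(sprintf("<instance_map %d x %d, %d objects>\n",
              x$shape[1], x$shape[2], length(x$objects)))
  invisible(x)
}

#' Number of objects in an instance map
#' @param x An [instance_map].
#' @return Integer count.
#' @export
n_objects <- function(x) length(x$objects)

#' Build an instance map from a flat integer label matrix
#'
#' @param labels Integer matrix; 0 = background, `k > 0` = object `k`.
#' @return [instance_map] with one (disjoint) mask per positive label.
#' @export
instances_from_labels <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  objs <- lapply(ids, function(id)
    list(label_id = as.integer(id), mask = labels == id))
  instance_map(objs, shape = dim(labels))
}

#' Flatten an instance map to an integer label matrix
#'
#' Shared (overlapping) pixels are assigned to the lowest label id.
#'
#' @param x An [instance_map].
#' @return Integer matrix, 0 = background.
#' @export
flatten_instances <- function(x) {
  out <- matrix(0L, x$shape[1], x$shape[2])
  for (o in rev(x$objects))  # objects sorted by id; lowest painted last
    out[o$mask] <- o$label_id
  out
}

#' Union (semantic) mask of an instance map
#' @param x An [instance_map].
#' @return Logical `H x W` matrix.
#' @export
semantic_from_instances <- function(x) {
  out <- matrix(FALSE, x$shape[1], x$shape[2])
  for (o in x$objects) out <- out | o$mask
  out
}

#' Pixel coverage count of an instance map
#' @param x An [instance_map].
#' @return Integer matrix counting, per pixel, how many object masks cover it.
#' @export
coverage_from_instances <- function(x) {
  out <- matrix(0L, x$shape[1], x$shape[2])
  for (o in x$objects) out <- out + o$mask
  out
}
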