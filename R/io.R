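read_raster <- function(path) {
  if (!file.exists(path))
    stop_sunseg(paste0("cannot read image file: ", path), "sunseg_format_error")
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch({
    if (ext == "png") png::readPNG(path)
    else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
    else stop("unsupported extension")
  }, error = function(e)
    stop_sunseg(paste0("cannot decode image file: ", path),
                "sunseg_format_error"))
  arr
}

#' Read an image file as an RGB patch
#'
#' Reads a PNG or TIFF with 1, 3, or 4 channels. Grayscale is replicated to
#' three channels; an alpha channel is dropped. Intensities are returned on
#' the 0--255 scale; the origin is `(0, 0)`.
#'
#' @param path Path to a PNG or TIFF file.
#' @return An [rgb_patch].
#' @export
read_image <- function(path) {
  arr <- read_raster(path)
  if (is.matrix(arr)) arr <- array(rep(arr, 3), c(dim(arr), 3L))
  nc <- dim(arr)[3]
  if (nc == 1L) arr <- array(rep(arr[, , 1], 3), c(dim(arr)[1:2], 3L))
  else if (nc == 2L) arr <- array(rep(arr[, , 1], 3), c(dim(arr)[1:2], 3L))
  else if (nc == 4L) arr <- arr[, , 1:3, drop = FALSE]
  else if (nc != 3L)
    stop_sunseg(paste0("unsupported channel count in: ", path),
                "sunseg_format_error")
  rgb_patch(round(arr * 255))
}

#' Write an RGB patch to a PNG file
#' @param patch [rgb_patch] or `H x W x 3` array on the 0--255 scale.
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(patch, path) {
  px <- if (inherits(patch, "rgb_patch")) patch$pixels else as_hwc(patch)
  png::writePNG(px / 255, path)
  invisible(path)
}

#' Write a binary mask as an 8-bit PNG (0 = background, 255 = foreground)
#' @param mask Logical or 0/1 matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask > 0), nrow(mask)), path)
  invisible(path)
}

#' Read a binary mask written by [write_mask()]
#' @param path PNG/TIFF path.
#' @return Logical matrix.
#' @export
read_mask <- function(path) {
  arr <- read_raster(path)
  if (!is.matrix(arr)) arr <- arr[, , 1]
  arr > 0.5
}

#' Write a flat integer label map as a 16-bit single-channel TIFF
#' @param labels Integer matrix, 0 = background; values must be < 65536.
#' @param path Output path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_label_map <- function(labels, path) {
  stopifnot(max(labels) < 65536)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a 16-bit label map written by [write_label_map()]
#' @param path TIFF path.
#' @return Integer matrix.
#' @export
read_label_map <- function(path) {
  arr <- read_raster(path)
  if (!is.matrix(arr)) arr <- arr[, , 1]
  matrix(as.integer(round(arr * 65535)), nrow(arr))
}

#' Write an instance map losslessly as run-length-encoded CSV
#'
#' One row per run of foreground pixels per object, in column-major order,
#' so overlapping per-object masks survive the round trip (unlike the
#' flattened label rendering).
#'
#' @param x An [instance_map].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_instances_rle <- function(x, path) {
  rows <- list(data.frame(h = x$shape[1], w = x$shape[2], label_id = 0L,
                          start = 0L, length = 0L))
  for (o in x$objects) {
    r <- rle(as.vector(o$mask))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (any(keep))
      rows[[length(rows) + 1L]] <- data.frame(
        h = x$shape[1], w = x$shape[2], label_id = o$label_id,
        start = starts[keep], length = r$lengths[keep])
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read an instance map written by [write_instances_rle()]
#' @param path CSV path.
#' @return An [instance_map].
#' @export
read_instances_rle <- function(path) {
  d <- read.csv(path)
  shape <- c(d$h[1], d$w[1])
  d <- d[d$label_id > 0, , drop = FALSE]
  objs <- lapply(split(d, d$label_id), function(g) {
    m <- matrix(FALSE, shape[1], shape[2])
    for (i in seq_len(nrow(g)))
      m[g$start[i] + seq_len(g$length[i]) - 1L] <- TRUE
    list(label_id = g$label_id[1], mask = m)
  })
  instance_map(unname(objs), shape = shape)
}
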