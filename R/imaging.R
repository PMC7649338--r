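#' Construct an RGB patch
#'
#' An `rgb_patch` wraps an `H x W x 3` array of 8-bit intensities together
#' with the 0-based `(row, col)` offset of the patch within its source image.
#'
#' @param pixels Numeric `H x W x 3` array with values in `[0, 255]`.
#' @param origin Integer vector of length 2, 0-based `(row, col)` offset.
#' @return An object of class `rgb_patch`: a list with elements `pixels`
#'   and `origin`.
#' @export
rgb_patch <- function(pixels, origin = c(0L, 0L)) {
  pixels <- as_hwc(pixels)
  stopifnot(length(dim(pixels)) == 3L)
  if (any(dim(pixels)[1:2] < 1L))
    stop_sunseg("patch must have positive height and width", "sunseg_size_error")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop_sunseg("pixel intensities must lie in [0, 255]", "sunseg_format_error")
  structure(list(pixels = pixels, origin = as.integer(origin)),
            class = "rgb_patch")
}

#' @export
print.rgb_patch <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_patch %d x %d x %d, origin (%d, %d)>\n",
              d[1], d[2], d[3], x$origin[1], x$origin[2]))
  invisible(x)
}

#' Split an image into fixed-size patches
#'
#' Tiles the image with the given stride. Patches at the right/bottom border
#' are shifted inward so that every patch is exactly `patch_size` pixels and
#' no padding is introduced; together the patches cover every pixel.
#'
#' @param image An [rgb_patch] (or bare `H x W x C` array).
#' @param patch_size Patch side length in pixels.
#' @param stride Step between patch origins; defaults to `patch_size`
#'   (disjoint tiling).
#' @return List of [rgb_patch] objects with recorded origins.
#' @export
tile_patches <- function(image, patch_size, stride = patch_size) {
  px <- if (inherits(image, "rgb_patch")) image$pixels else as_hwc(image)
  H <- dim(px)[1]; W <- dim(px)[2]
  stopifnot(patch_size >= 1, stride >= 1, stride <= patch_size)
  if (H < patch_size || W < patch_size)
    stop_sunseg(sprintf("image %d x %d smaller than patch size %d",
                        H, W, patch_size), "sunseg_size_error")
  starts <- function(n) {
    s <- seq(0L, n - patch_size, by = stride)
    if (s[length(s)] != n - patch_size) s <- c(s, n - patch_size)
    s
  }
  out <- list()
  for (r in starts(H))
    for (cc in starts(W))
      out[[length(out) + 1L]] <- rgb_patch(
        px[r + seq_len(patch_size), cc + seq_len(patch_size), , drop = FALSE],
        origin = c(r, cc))
  out
}

#' Stitch per-patch probability maps back into a full-size map
#'
#' Pieces are placed at their origins; pixels covered by several pieces are
#' averaged. Every output pixel must be covered by at least one piece.
#'
#' @param pieces List of `list(map = H_p x W_p matrix, origin = c(row, col))`.
#' @param out_shape Integer `(H, W)` of the output.
#' @return `H x W` numeric matrix.
#' @export
stitch_patches <- function(pieces, out_shape) {
  H <- out_shape[1]; W <- out_shape[2]
  acc <- matrix(0, H, W); cnt <- matrix(0, H, W)
  for (p in pieces) {
    m <- p$map
    if (is.null(m)) m <- p$pixels[, , 1]
    r <- p$origin[1]; cc <- p$origin[2]
    hp <- nrow(m); wp <- ncol(m)
    if (r < 0 || cc < 0 || r + hp > H || cc + wp > W)
      stop_sunseg("piece extends past the output border", "sunseg_coverage_error")
    ri <- r + seq_len(hp); ci <- cc + seq_len(wp)
    acc[ri, ci] <- acc[ri, ci] + m
    cnt[ri, ci] <- cnt[ri, ci] + 1
  }
  if (any(cnt == 0))
    stop_sunseg("output pixels not covered by any piece", "sunseg_coverage_error")
  acc / cnt
}

#' Pyramid scale factors
#'
#' The four fixed rescaling factors applied to every input patch before the
#' four parallel backbone nets.
#' @return Numeric vector `c(1.25, 1.0, 0.75, 0.5)`.
#' @export
pyramid_factors <- function() c(1.25, 1.0, 0.75, 0.5)

is_binary_channel <- function(v) all(v %in% c(0, 1)) || all(v %in% c(0, 255))

#' Build the four-level scale pyramid of a patch
#'
#' Rescales a square patch to the four fixed factors (1.25, 1.0, 0.75, 0.5 of
#' the base size, rounded). Continuous channels are resampled bilinearly;
#' channels whose values are all in \{0, 1\} or \{0, 255\} (e.g. the stage-two
#' binary mask channel) are resampled by nearest neighbour so they stay
#' binary.
#'
#' @param patch [rgb_patch] or `H x W x C` array (C = 3 or 4), square.
#' @return List of class `scale_pyramid`; each level is
#'   `list(factor, pixels)`.
#' @export
build_pyramid <- function(patch) {
  px <- if (inherits(patch, "rgb_patch")) patch$pixels else as_hwc(patch)
  H <- dim(px)[1]; W <- dim(px)[2]; C <- dim(px)[3]
  stopifnot(H == W)
  binary <- vapply(seq_len(C), function(c) is_binary_channel(px[, , c]),
                   logical(1))
  levels <- lapply(pyramid_factors(), function(f) {
    s <- as.integer(round(H * f))
    out <- array(0, c(s, s, C))
    if (any(!binary))
      out[, , !binary] <- cpp_resize_bilinear(px[, , !binary, drop = FALSE], s, s)
    if (any(binary))
      out[, , binary] <- cpp_resize_nearest(px[, , binary, drop = FALSE], s, s)
    list(factor = f, pixels = out)
  })
  structure(levels, class = "scale_pyramid")
}
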