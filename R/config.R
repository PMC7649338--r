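#' Default pipeline configuration
#'
#' Nested configuration covering all modules. The `"paper"` profile uses
#' the full-scale settings (384-pixel patches, VGG16-width depth-4
#' backbones, learning rate 1e-4, momentum 0.9, batch size 4, 20 epochs);
#' the `"tiny"` profile is the CPU-trainable variant used by the demo
#' (64-pixel patches, base width 8, depth 3, larger learning rate, 2
#' epochs).
#'
#' @param profile `"paper"` or `"tiny"`.
#' @return Nested configuration list.
#' @export
default_config <- function(profile = c("paper", "tiny")) {
  profile <- match.arg(profile)
  cfg <- list(
    profile = profile,
    imaging = list(patch_size = 384L, stride = 384L,
                   pyramid_factors = pyramid_factors()),
    network = list(base_width = 64L, depth = 4L, agm_width = 16L),
    training = list(lr = 1e-4, momentum = 0.9, batch_size = 4L,
                    epochs = 20L, stage1_loss = "cross_entropy",
                    stage2_loss = "focal", focal_gamma = 2,
                    focal_alpha = 0.25,
                    augment = c("rot90s", "vflip", "hflip")),
    postprocess = list(threshold = 0.5, min_size = 20L,
                       marker_method = "peaks", peak_footprint = 2L,
                       min_peak = 1, marker_ratio = 0.7,
                       min_overlap = 10L),
    metrics = list(aji_variant = "printed"),
    seed = 1L)
  if (profile == "tiny") {
    cfg$imaging$patch_size <- 64L
    cfg$imaging$stride <- 64L
    cfg$network <- list(base_width = 8L, depth = 3L, agm_width = 8L)
    cfg$training$lr <- 0.05
    cfg$training$epochs <- 2L
    cfg$postprocess$min_size <- 20L
  }
  cfg
}

#' Write a configuration to a YAML file
#' @param cfg Configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a configuration YAML, filling unset keys with defaults
#' @param path YAML path.
#' @return Configuration list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_config(user$profile %||% "paper")
  merge_cfg <- function(b, u) {
    for (nm in names(u))
      b[[nm]] <- if (is.list(u[[nm]]) && is.list(b[[nm]]))
        merge_cfg(b[[nm]], u[[nm]]) else u[[nm]]
    b
  }
  merge_cfg(base, user)
}
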