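# Stacked U-Nets: four scale-specific encoder-decoder backbones whose
# per-pixel logit maps are fused by a per-pixel convex combination produced
# by the attention generation module (AGM). All layers are stride-1
# same-padded convolutions, 2x2 max-pooling, and 2x2 stride-2 transposed
# convolutions; forward and backward passes call the compiled kernels.

relu_f <- function(x) {
  x[x < 0] <- 0
  x
}

init_conv <- function(cin, cout, k, gain = 2) {
  sd <- sqrt(gain / (cin * k * k))
  list(W = matrix(rnorm(cout * cin * k * k, sd = sd), cout),
       b = rep(0, cout), k = as.integer(k))
}

init_deconv <- function(cin, cout) {
  sd <- sqrt(2 / cin)
  list(W = matrix(rnorm(cin * 4 * cout, sd = sd), cin), b = rep(0, cout))
}

backbone_widths <- function(base_width, depth) {
  w <- pmin(base_width * 2^(seq_len(depth) - 1), 8 * base_width)
  c(w, min(base_width * 2^depth, 8 * base_width))  # last = bottleneck
}

#' Configuration of one U-Net backbone
#'
#' VGG16-style encoder (two 3x3 conv+ReLU layers per block, channel width
#' doubling capped at `8 * base_width`, 2x2 max-pooling between blocks),
#' mirrored decoder with 2x2 transposed-convolution upsampling and skip
#' copy-and-concatenation, and a single-channel 1x1 logit head. Spatial size
#' is preserved end to end.
#'
#' @param in_channels 3 (stage one, RGB) or 4 (stage two, RGB + mask).
#' @param base_width Channel count of the first block (paper-scale: 64).
#' @param depth Number of down-sampling stages (paper-scale: 4).
#' @return List of class `backbone_config`.
#' @export
backbone_config <- function(in_channels = 3L, base_width = 64L, depth = 4L) {
  stopifnot(in_channels %in% c(3L, 4L), base_width >= 4, depth >= 2)
  structure(list(in_channels = as.integer(in_channels),
                 base_width = as.integer(base_width),
                 depth = as.integer(depth)),
            class = "backbone_config")
}

#' Build (initialize) one U-Net backbone
#'
#' @param cfg A [backbone_config]. Weights are drawn from the current RNG
#'   state (He-normal), so seed before calling for reproducibility.
#' @return List of class `sun_backbone` with elements `cfg` and `par`.
#' @export
build_backbone <- function(cfg) {
  w <- backbone_widths(cfg$base_width, cfg$depth)
  d <- cfg$depth
  enc <- vector("list", d)
  cin <- cfg$in_channels
  for (i in seq_len(d)) {
    enc[[i]] <- list(c1 = init_conv(cin, w[i], 3), c2 = init_conv(w[i], w[i], 3))
    cin <- w[i]
  }
  bott <- list(c1 = init_conv(w[d], w[d + 1], 3),
               c2 = init_conv(w[d + 1], w[d + 1], 3))
  dec <- vector("list", d)
  for (i in seq_len(d)) {
    cdeep <- if (i == d) w[d + 1] else w[i + 1]
    dec[[i]] <- list(up = init_deconv(cdeep, w[i]),
                     c1 = init_conv(2 * w[i], w[i], 3),
                     c2 = init_conv(w[i], w[i], 3))
  }
  head <- init_conv(w[1], 1L, 1)
  structure(list(cfg = cfg,
                 par = list(enc = enc, bott = bott, dec = dec, head = head)),
            class = "sun_backbone")
}

conv_relu_f <- function(x, nd) {
  y <- relu_f(cpp_conv2d_fwd(x, nd$W, nd$b, nd$k))
  list(y = y, x = x, mask = y > 0)
}

conv_relu_b <- function(cache, nd, dy) {
  dy[!cache$mask] <- 0
  cpp_conv2d_bwd(cache$x, nd$W, dy, nd$k)
}

#' Run a backbone forward
#'
#' @param model A `sun_backbone`.
#' @param x Normalized `S x S x C` input array; `S` must be divisible by
#'   `2^depth`.
#' @param want_cache Keep intermediate activations for a backward pass.
#' @return `list(logits = S x S matrix, cache)`.
#' @export
backbone_forward <- function(model, x, want_cache = FALSE) {
  cfg <- model$cfg; par <- model$par
  x <- as_hwc(x)
  if (dim(x)[3] != cfg$in_channels)
    stop_sunseg(sprintf("backbone expects %d channels, got %d",
                        cfg$in_channels, dim(x)[3]), "sunseg_input_error")
  S <- dim(x)[1]
  if (dim(x)[2] != S || S %% 2^cfg$depth != 0)
    stop_sunseg(sprintf(
      "input size %d x %d not square or not divisible by 2^%d",
      dim(x)[1], dim(x)[2], cfg$depth), "sunseg_shape_error")
  cache <- list(enc = vector("list", cfg$depth), dec = vector("list", cfg$depth))
  a <- x
  skips <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth)) {
    r1 <- conv_relu_f(a, par$enc[[i]]$c1)
    r2 <- conv_relu_f(r1$y, par$enc[[i]]$c2)
    skips[[i]] <- r2$y
    p <- cpp_maxpool2_fwd(r2$y)
    cache$enc[[i]] <- list(r1 = r1, r2 = r2, idx = p$idx)
    a <- p$y
  }
  b1 <- conv_relu_f(a, par$bott$c1)
  b2 <- conv_relu_f(b1$y, par$bott$c2)
  cache$bott <- list(r1 = b1, r2 = b2)
  a <- b2$y
  for (i in rev(seq_len(cfg$depth))) {
    up <- cpp_deconv2_fwd(a, par$dec[[i]]$up$W, par$dec[[i]]$up$b)
    cat_in <- array(c(up, skips[[i]]), c(dim(up)[1:2], dim(up)[3] * 2L))
    r1 <- conv_relu_f(cat_in, par$dec[[i]]$c1)
    r2 <- conv_relu_f(r1$y, par$dec[[i]]$c2)
    cache$dec[[i]] <- list(up_in = a, r1 = r1, r2 = r2, cup = dim(up)[3])
    a <- r2$y
  }
  logits <- cpp_conv2d_fwd(a, par$head$W, par$head$b, 1L)
  cache$head_in <- a
  list(logits = logits[, , 1],
       cache = if (want_cache) cache else NULL)
}

backbone_backward <- function(model, cache, dlogits) {
  par <- model$par; d <- model$cfg$depth
  g <- list(enc = vector("list", d), bott = NULL, dec = vector("list", d),
            head = NULL)
  dl <- array(dlogits, c(dim(dlogits), 1L))
  hb <- cpp_conv2d_bwd(cache$head_in, par$head$W, dl, 1L)
  g$head <- list(W = hb$dW, b = hb$db)
  # decoder stages were applied in order d..1, so backprop runs 1..d;
  # stage i's up_in is the output of stage i+1 (bottleneck for i = d)
  da <- hb$dx
  dbott <- NULL
  for (i in seq_len(d)) {
    cc <- cache$dec[[i]]
    b2 <- conv_relu_b(cc$r2, par$dec[[i]]$c2, da)
    b1 <- conv_relu_b(cc$r1, par$dec[[i]]$c1, b2$dx)
    cup <- cc$cup
    dup <- b1$dx[, , seq_len(cup), drop = FALSE]
    dskip <- b1$dx[, , cup + seq_len(cup), drop = FALSE]
    ub <- cpp_deconv2_bwd(cc$up_in, par$dec[[i]]$up$W, dup)
    g$dec[[i]] <- list(up = list(W = ub$dW, b = ub$db),
                       c1 = list(W = b1$dW, b = b1$db),
                       c2 = list(W = b2$dW, b = b2$db))
    cache$enc[[i]]$dskip <- dskip  # via the skip copy into this decoder stage
    if (i == d) dbott <- ub$dx else da <- ub$dx
  }
  db2 <- conv_relu_b(cache$bott$r2, par$bott$c2, dbott)
  db1 <- conv_relu_b(cache$bott$r1, par$bott$c1, db2$dx)
  g$bott <- list(c1 = list(W = db1$dW, b = db1$db),
                 c2 = list(W = db2$dW, b = db2$db))
  da <- db1$dx
  for (i in rev(seq_len(d))) {
    cc <- cache$enc[[i]]
    dpool <- cpp_maxpool2_bwd(da, cc$idx)
    dpost <- dpool + cc$dskip
    b2 <- conv_relu_b(cc$r2, par$enc[[i]]$c2, dpost)
    b1 <- conv_relu_b(cc$r1, par$enc[[i]]$c1, b2$dx)
    g$enc[[i]] <- list(c1 = list(W = b1$dW, b = b1$db),
                       c2 = list(W = b2$dW, b = b2$db))
    da <- b1$dx
  }
  g
}

#' Build (initialize) the attention generation module
#'
#' Eight convolution layers in a ResNet-34 flavor: a 3x3 stem taking the
#' four concatenated backbone prediction maps, three two-convolution
#' residual basic blocks (stride 1, resolution preserved, ReLU), and a 1x1
#' head emitting four per-pixel scores normalized by softmax so the four
#' attention weights sum to one at every pixel.
#'
#' @param n_nets Number of fused backbones; must be 4.
#' @param width Channel width of the residual blocks.
#' @return List of class `sun_agm`.
#' @export
build_agm <- function(n_nets = 4L, width = 16L) {
  stopifnot(n_nets == 4L)
  par <- list(stem = init_conv(n_nets, width, 3),
              blocks = lapply(1:3, function(i)
                list(c1 = init_conv(width, width, 3),
                     c2 = init_conv(width, width, 3))),
              head = init_conv(width, n_nets, 1))
  structure(list(n_nets = as.integer(n_nets), width = as.integer(width),
                 par = par), class = "sun_agm")
}

#' Attention weights for a stack of prediction maps
#'
#' @param agm A `sun_agm`.
#' @param U `H x W x 4` array of backbone prediction (logit) maps, all
#'   resampled to the base resolution.
#' @param want_cache Keep activations for a backward pass.
#' @return `list(weights = H x W x 4 array summing to 1 over the 4th
#'   backbone axis at every pixel, cache)`.
#' @export
agm_forward <- function(agm, U, want_cache = FALSE) {
  if (length(dim(U)) != 3L || dim(U)[3] != agm$n_nets)
    stop_sunseg("AGM expects an H x W x 4 stack of prediction maps",
                "sunseg_shape_error")
  par <- agm$par
  st <- conv_relu_f(U, par$stem)
  a <- st$y
  bl <- vector("list", length(par$blocks))
  for (i in seq_along(par$blocks)) {
    r1 <- conv_relu_f(a, par$blocks[[i]]$c1)
    z <- cpp_conv2d_fwd(r1$y, par$blocks[[i]]$c2$W, par$blocks[[i]]$c2$b, 3L)
    y <- relu_f(z + a)
    bl[[i]] <- list(r1 = r1, x2 = r1$y, skip = a, mask = y > 0)
    a <- y
  }
  Z <- cpp_conv2d_fwd(a, par$head$W, par$head$b, 1L)
  zm <- pmax(Z[, , 1], Z[, , 2], Z[, , 3], Z[, , 4])
  e <- exp(Z - array(zm, dim(Z)))
  sm <- e / array(e[, , 1] + e[, , 2] + e[, , 3] + e[, , 4], dim(e))
  cache <- if (want_cache) list(st = st, bl = bl, head_in = a, w = sm) else NULL
  list(weights = sm, cache = cache)
}

agm_backward <- function(agm, cache, dweights) {
  par <- agm$par
  w <- cache$w
  # softmax backward per pixel: dz_k = w_k * (dw_k - sum_j w_j dw_j)
  wd <- w * dweights
  s <- array(wd[, , 1] + wd[, , 2] + wd[, , 3] + wd[, , 4], dim(w))
  dZ <- w * (dweights - s)
  hb <- cpp_conv2d_bwd(cache$head_in, par$head$W, dZ, 1L)
  g <- list(stem = NULL, blocks = vector("list", length(par$blocks)),
            head = list(W = hb$dW, b = hb$db))
  da <- hb$dx
  for (i in rev(seq_along(par$blocks))) {
    cc <- cache$bl[[i]]
    dz <- da
    dz[!cc$mask] <- 0
    b2 <- cpp_conv2d_bwd(cc$x2, par$blocks[[i]]$c2$W, dz, 3L)
    b1 <- conv_relu_b(cc$r1, par$blocks[[i]]$c1, b2$dx)
    g$blocks[[i]] <- list(c1 = list(W = b1$dW, b = b1$db),
                          c2 = list(W = b2$dW, b = b2$db))
    da <- b1$dx + dz  # residual skip
  }
  sb <- conv_relu_b(cache$st, par$stem, da)
  g$stem <- list(W = sb$dW, b = sb$db)
  list(grads = g, dU = sb$dx)
}

#' Build a full Stacked U-Nets model
#'
#' Four scale-specific backbones with identical architecture but
#' independent parameters (one per pyramid factor), plus the attention
#' generation module that fuses their predictions.
#'
#' @param in_channels 3 (stage one) or 4 (stage two).
#' @param base_width,depth Backbone size; see [backbone_config()].
#' @param agm_width AGM residual-block width.
#' @param seed Optional RNG seed for reproducible initialization.
#' @return List of class `sunets` with `cfg` and `par`
#'   (`par$backbones[[k]]`, `par$agm`).
#' @export
build_sunets <- function(in_channels = 3L, base_width = 64L, depth = 4L,
                         agm_width = 16L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bcfg <- backbone_config(in_channels, base_width, depth)
  backbones <- lapply(1:4, function(k) build_backbone(bcfg)$par)
  agm <- build_agm(4L, agm_width)
  structure(list(
    cfg = list(in_channels = bcfg$in_channels, base_width = bcfg$base_width,
               depth = bcfg$depth, agm_width = agm$width,
               factors = pyramid_factors()),
    par = list(backbones = backbones, agm = agm$par)), class = "sunets")
}

sunets_backbone_handle <- function(model) {
  cfg <- backbone_config(model$cfg$in_channels, model$cfg$base_width,
                         model$cfg$depth)
  function(k) structure(list(cfg = cfg, par = model$par$backbones[[k]]),
                        class = "sun_backbone")
}

sunets_agm_handle <- function(model)
  structure(list(n_nets = 4L, width = model$cfg$agm_width,
                 par = model$par$agm), class = "sun_agm")

reflect_idx <- function(n, np) {
  if (np == n) return(seq_len(n))
  pad <- np - n
  if (pad > n - 1)
    stop_sunseg("reflection padding wider than the image", "sunseg_shape_error")
  c(seq_len(n), n - seq_len(pad))
}

sunets_forward_full <- function(model, patch, want_cache = FALSE) {
  px <- if (inherits(patch, "rgb_patch")) patch$pixels else as_hwc(patch)
  if (dim(px)[3] != model$cfg$in_channels)
    stop_sunseg(sprintf("model expects %d input channels, got %d",
                        model$cfg$in_channels, dim(px)[3]),
                "sunseg_input_error")
  if (dim(px)[1] != dim(px)[2])
    stop_sunseg("input patch must be square", "sunseg_shape_error")
  S <- dim(px)[1]
  mult <- 2^model$cfg$depth
  pyr <- build_pyramid(px)
  bk <- sunets_backbone_handle(model)
  levs <- vector("list", 4)
  for (k in 1:4) {
    xn <- pyr[[k]]$pixels / 255 - 0.5
    s <- dim(xn)[1]
    sp <- as.integer(ceiling(s / mult) * mult)
    ridx <- reflect_idx(s, sp)
    xp <- xn[ridx, ridx, , drop = FALSE]
    fw <- backbone_forward(bk(k), xp, want_cache = want_cache)
    logits <- fw$logits[seq_len(s), seq_len(s)]
    u <- cpp_resize_bilinear(array(logits, c(s, s, 1L)), S, S)
    levs[[k]] <- list(size = s, padded = sp, cache = fw$cache, u = u[, , 1])
  }
  U <- array(vapply(levs, function(l) l$u, matrix(0, S, S)), c(S, S, 4L))
  ag <- agm_forward(sunets_agm_handle(model), U, want_cache = want_cache)
  wts <- ag$weights
  fused <- matrix(0, S, S)
  for (k in 1:4) fused <- fused + wts[, , k] * U[, , k]
  prob <- 1 / (1 + exp(-fused))
  list(prob = prob, fused = fused, U = U, weights = wts,
       levels = levs, agm_cache = ag$cache)
}

sunets_backward_full <- function(model, fw, dfused) {
  S <- nrow(dfused)
  dU <- array(0, c(S, S, 4L))
  dw <- array(0, c(S, S, 4L))
  for (k in 1:4) {
    dU[, , k] <- fw$weights[, , k] * dfused
    dw[, , k] <- fw$U[, , k] * dfused
  }
  ab <- agm_backward(sunets_agm_handle(model), fw$agm_cache, dw)
  dU <- dU + ab$dU
  bk <- sunets_backbone_handle(model)
  gb <- vector("list", 4)
  for (k in 1:4) {
    lv <- fw$levels[[k]]
    dlev <- cpp_resize_bilinear_bwd(array(dU[, , k], c(S, S, 1L)),
                                    lv$size, lv$size)[, , 1]
    dpad <- matrix(0, lv$padded, lv$padded)
    dpad[seq_len(lv$size), seq_len(lv$size)] <- dlev
    gb[[k]] <- backbone_backward(bk(k), lv$cache, dpad)
  }
  list(backbones = gb, agm = ab$grads)
}

#' Stacked U-Nets forward pass
#'
#' Builds the four-level scale pyramid of the patch, runs each level through
#' its own backbone, resamples the four logit maps back to the base
#' resolution (bilinear), obtains the per-pixel attention weights from the
#' AGM, and returns `sigmoid(sum_k w_k * logit_k)` as a probability map.
#' Levels whose size is not divisible by `2^depth` are reflection-padded
#' internally and cropped after decoding.
#'
#' @param model A `sunets` model.
#' @param patch [rgb_patch] or `S x S x C` array on the 0--255 scale with
#'   `C` matching the model's `in_channels` (for stage two, the fourth
#'   channel is the stage-one mask scaled to \{0, 255\}).
#' @param return_weights Also return the `S x S x 4` attention weights as
#'   attribute `"weights"`.
#' @return `S x S` probability matrix in `[0, 1]`.
#' @export
sunets_forward <- function(model, patch, return_weights = FALSE) {
  fw <- sunets_forward_full(model, patch, want_cache = FALSE)
  out <- fw$prob
  if (return_weights) attr(out, "weights") <- fw$weights
  out
}
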