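#' Training configuration
#'
#' Defaults are the full-scale settings: learning rate 1e-4, SGD momentum
#' 0.9, batch size 4, 20 epochs, 384-pixel patches, right-angle rotation and
#' flip augmentation. Stage one uses cross-entropy loss; stage two uses
#' focal loss (gamma 2, alpha 0.25, the canonical focal-loss defaults).
#'
#' @param lr Learning rate (> 0).
#' @param momentum SGD momentum in `[0, 1)`.
#' @param batch_size Samples per gradient step.
#' @param epochs Number of passes over the training set.
#' @param loss `"cross_entropy"` or `"focal"`.
#' @param focal_gamma Focusing exponent (>= 0).
#' @param focal_alpha Foreground class weight in `(0, 1]`.
#' @param seed RNG seed controlling shuffling and augmentation.
#' @param augment Subset of `c("rot90s", "vflip", "hflip")`; the identity
#'   is always a candidate.
#' @param verbose Log per-epoch losses to stderr.
#' @return List of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, momentum = 0.9, batch_size = 4L,
                         epochs = 20L, loss = c("cross_entropy", "focal"),
                         focal_gamma = 2, focal_alpha = 0.25, seed = 1L,
                         augment = c("rot90s", "vflip", "hflip"),
                         verbose = FALSE) {
  loss <- match.arg(loss)
  stopifnot(lr > 0, momentum >= 0, momentum < 1, batch_size >= 1,
            focal_gamma >= 0, focal_alpha > 0, focal_alpha <= 1)
  structure(list(lr = lr, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), loss = loss,
                 focal_gamma = focal_gamma, focal_alpha = focal_alpha,
                 seed = as.integer(seed), augment = augment,
                 verbose = verbose), class = "train_config")
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a)[1:2], dim(b)[1:2]))
    stop_sunseg("probability map and target shapes differ",
                "sunseg_shape_error")
}

#' Mean binary cross-entropy loss
#'
#' Mean over pixels of `-(t log p + (1 - t) log(1 - p))`, with `p` clamped
#' to `[eps, 1 - eps]`.
#'
#' @param prob Probability map in `[0, 1]`.
#' @param target Binary target of the same shape.
#' @param eps Clamping constant.
#' @return Non-negative scalar.
#' @export
cross_entropy_loss <- function(prob, target, eps = 1e-7) {
  check_same_shape(prob, target)
  p <- pmin(pmax(prob, eps), 1 - eps)
  t <- as.numeric(target > 0)
  mean(-(t * log(p) + (1 - t) * log(1 - p)))
}

#' Mean focal loss
#'
#' Mean over pixels of `-alpha_t (1 - p_t)^gamma log(p_t)` with
#' `p_t = p` for foreground and `1 - p` for background, `alpha_t = alpha`
#' for foreground and `1 - alpha` for background. With `gamma = 0` and
#' `alpha = 0.5` this reduces to half the cross-entropy.
#'
#' @inheritParams cross_entropy_loss
#' @param gamma Focusing exponent (>= 0); larger down-weights easy pixels.
#' @param alpha Foreground class weight.
#' @return Non-negative scalar.
#' @export
focal_loss <- function(prob, target, gamma = 2, alpha = 0.25, eps = 1e-7) {
  check_same_shape(prob, target)
  stopifnot(gamma >= 0)
  t <- as.numeric(target > 0)
  p <- pmin(pmax(prob, eps), 1 - eps)
  pt <- ifelse(t == 1, p, 1 - p)
  at <- ifelse(t == 1, alpha, 1 - alpha)
  mean(-at * (1 - pt)^gamma * log(pt))
}

# Gradients of the mean losses with respect to the fused pre-sigmoid logit.
ce_grad_logit <- function(prob, target) {
  t <- as.numeric(target > 0)
  matrix(prob - t, nrow(prob)) / length(prob)
}

focal_grad_logit <- function(prob, target, gamma, alpha, eps = 1e-7) {
  t <- as.numeric(target > 0)
  p <- pmin(pmax(as.vector(prob), eps), 1 - eps)
  pt <- ifelse(t == 1, p, 1 - p)
  at <- ifelse(t == 1, alpha, 1 - alpha)
  s <- ifelse(t == 1, 1, -1)
  term1 <- if (gamma > 0) gamma * (1 - pt)^(gamma - 1) * log(pt) else 0
  dl_dpt <- at * (term1 - (1 - pt)^gamma / pt)
  matrix(dl_dpt * s * p * (1 - p), nrow(prob)) / length(prob)
}

rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

apply_transform_mat <- function(m, tr) {
  switch(tr,
         identity = m,
         rot90 = rot90cw(m),
         rot180 = m[nrow(m):1, ncol(m):1, drop = FALSE],
         rot270 = rot90cw(rot90cw(rot90cw(m))),
         vflip = m[nrow(m):1, , drop = FALSE],
         hflip = m[, ncol(m):1, drop = FALSE])
}

apply_transform <- function(x, tr) {
  if (is.matrix(x)) return(apply_transform_mat(x, tr))
  slices <- lapply(seq_len(dim(x)[3]), function(c)
    apply_transform_mat(x[, , c], tr))
  array(unlist(slices), c(dim(slices[[1]]), dim(x)[3]))
}

#' Randomly augment an image together with its masks
#'
#' Samples one transform uniformly from the identity plus the configured
#' set (right-angle rotations, vertical flip, horizontal flip) and applies
#' the identical transform to the image and to every mask, so the pixel
#' correspondence is preserved. Uses the current RNG state.
#'
#' @param image `H x W (x C)` array.
#' @param masks List of matrices sharing the image's spatial shape.
#' @param augment Character subset of `c("rot90s", "vflip", "hflip")`.
#' @return `list(image, masks, transform)`.
#' @export
augment_pair <- function(image, masks,
                         augment = c("rot90s", "vflip", "hflip")) {
  cands <- "identity"
  if ("rot90s" %in% augment) cands <- c(cands, "rot90", "rot180", "rot270")
  if ("vflip" %in% augment) cands <- c(cands, "vflip")
  if ("hflip" %in% augment) cands <- c(cands, "hflip")
  tr <- cands[sample.int(length(cands), 1)]
  list(image = apply_transform(image, tr),
       masks = lapply(masks, apply_transform, tr = tr),
       transform = tr)
}

# Parameter (de)serialization. Conv nodes carry a constant `k` (kernel
# size) next to their W/b arrays; it is metadata, not a trainable value,
# and is skipped when flattening and preserved when unflattening.
strip_k <- function(p) {
  if (!is.list(p)) return(p)
  nm <- names(p)
  if (!is.null(nm)) p <- p[nm != "k"]
  lapply(p, strip_k)
}

flatten_par <- function(p) unlist(strip_k(p), use.names = FALSE)

unflatten_par <- function(flat, skel) {
  pos <- 0L
  rec <- function(s) {
    if (is.list(s)) {
      out <- s
      nm <- names(s)
      for (i in seq_along(s)) {
        if (!is.null(nm) && nm[i] == "k") next
        out[[i]] <- rec(s[[i]])
      }
      return(out)
    }
    n <- length(s)
    v <- flat[pos + seq_len(n)]
    pos <<- pos + n
    if (!is.null(dim(s))) dim(v) <- dim(s)
    v
  }
  rec(skel)
}

#' Train one stage of the pipeline
#'
#' Runs SGD with momentum over shuffled, augmented mini-batches. Stage one
#' (`target_channel = "semantic"`) trains a 3-channel model against the
#' nucleus/background mask with cross-entropy; stage two
#' (`target_channel = "overlap"`) trains a 4-channel model against the
#' overlap mask, feeding the ground-truth semantic mask as the fourth input
#' channel (teacher forcing; at inference the stage-one prediction is used
#' instead). Fully reproducible under a fixed `cfg$seed` in single-threaded
#' BLAS mode.
#'
#' @param model A `sunets` model (see [build_sunets()]).
#' @param dataset List of samples (as from [generate_sample()] or
#'   [load_dataset()]), or a manifest path / data frame.
#' @param target_channel `"semantic"` or `"overlap"`.
#' @param cfg A [train_config].
#' @return `list(model, history)` where `history` is the per-epoch mean
#'   training loss.
#' @export
train_stage <- function(model, dataset,
                        target_channel = c("semantic", "overlap"),
                        cfg = train_config()) {
  target_channel <- match.arg(target_channel)
  force(model)  # model construction may consume RNG; force it before seeding
  if (is.character(dataset) || is.data.frame(dataset))
    dataset <- load_dataset(dataset)
  n <- length(dataset)
  if (n == 0) stop_sunseg("empty training dataset", "sunseg_data_error")
  set.seed(cfg$seed)
  skel <- model$par
  flat <- flatten_par(skel)
  mom <- numeric(length(flat))
  history <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_losses <- numeric(n)
    pos <- 1L
    for (b0 in seq(1L, n, by = cfg$batch_size)) {
      idxs <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
      gsum <- numeric(length(flat))
      for (ii in seq_along(idxs)) {
        smp <- dataset[[idxs[ii]]]
        target <- if (target_channel == "semantic") smp$semantic_mask
                  else smp$overlap_mask
        img <- if (inherits(smp$image, "rgb_patch")) smp$image$pixels
               else smp$image
        x <- if (model$cfg$in_channels == 4L)
          make_stage2_input(img, smp$semantic_mask)
        else img
        aug <- augment_pair(x, list(target * 1), cfg$augment)
        x <- aug$image
        tgt <- aug$masks[[1]]
        fw <- sunets_forward_full(model, x, want_cache = TRUE)
        loss <- if (cfg$loss == "cross_entropy")
          cross_entropy_loss(fw$prob, tgt)
        else focal_loss(fw$prob, tgt, cfg$focal_gamma, cfg$focal_alpha)
        if (!is.finite(loss))
          stop_sunseg(sprintf("training diverged (non-finite loss) at epoch %d",
                              ep), "sunseg_divergence_error")
        dfused <- if (cfg$loss == "cross_entropy")
          ce_grad_logit(fw$prob, tgt)
        else focal_grad_logit(fw$prob, tgt, cfg$focal_gamma, cfg$focal_alpha)
        g <- sunets_backward_full(model, fw, dfused)
        gsum <- gsum + flatten_par(g)
        ep_losses[pos] <- loss
        pos <- pos + 1L
      }
      mom <- cfg$momentum * mom - cfg$lr * (gsum / length(idxs))
      flat <- flat + mom
      model$par <- unflatten_par(flat, skel)
    }
    history[ep] <- mean(ep_losses)
    if (cfg$verbose)
      message(sprintf("[train %s] epoch %d/%d  loss %.5f",
                      target_channel, ep, cfg$epochs, history[ep]))
  }
  list(model = model, history = history)
}

#' Threshold a probability map into a binary mask
#' @param prob Probability matrix in `[0, 1]`.
#' @param threshold Cut point; the pipeline's stage outputs are hard 0/1
#'   masks, realized as `prob >= 0.5` by default.
#' @return Logical matrix.
#' @export
binarize <- function(prob, threshold = 0.5) prob >= threshold
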