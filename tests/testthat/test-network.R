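test_that("backbone preserves spatial shape and validates input", {
  set.seed(1)
  bk <- build_backbone(backbone_config(3L, 8L, 3L))
  out <- backbone_forward(bk, array(rnorm(64 * 64 * 3), c(64, 64, 3)))
  expect_equal(dim(out$logits), c(64L, 64L))

  bk4 <- build_backbone(backbone_config(4L, 8L, 3L))
  out4 <- backbone_forward(bk4, array(rnorm(64 * 64 * 4), c(64, 64, 4)))
  expect_equal(dim(out4$logits), c(64L, 64L))

  expect_error(backbone_forward(bk, array(0, c(50, 50, 3))),
               class = "sunseg_shape_error")
  expect_error(backbone_forward(bk, array(0, c(64, 64, 4))),
               class = "sunseg_input_error")
})

test_that("attention weights are a per-pixel convex combination", {
  set.seed(2)
  agm <- build_agm(4L, 8L)
  U <- array(rnorm(48 * 48 * 4), c(48, 48, 4))
  w <- agm_forward(agm, U)$weights
  expect_true(all(w >= 0))
  sums <- w[, , 1] + w[, , 2] + w[, , 3] + w[, , 4]
  expect_lt(max(abs(sums - 1)), 1e-12)

  # identical input maps: the fused map equals each input regardless of
  # how the weights split, because they sum to one
  u <- matrix(rnorm(48 * 48), 48)
  Ueq <- array(rep(u, 4), c(48, 48, 4))
  weq <- agm_forward(agm, Ueq)$weights
  fused <- weq[, , 1] * u + weq[, , 2] * u + weq[, , 3] * u + weq[, , 4] * u
  expect_equal(fused, u, tolerance = 1e-12)

  expect_error(agm_forward(agm, array(0, c(8, 8, 3))),
               class = "sunseg_shape_error")
})

test_that("stacked forward emits a bounded deterministic probability map", {
  m <- tiny_sunets(3L)
  x <- array(runif(64 * 64 * 3) * 255, c(64, 64, 3))
  t0 <- Sys.time()
  p <- sunets_forward(m, x, return_weights = TRUE)
  elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  expect_lt(elapsed, 1)
  expect_equal(dim(p), c(64L, 64L))
  expect_true(all(p >= 0 & p <= 1))
  w <- attr(p, "weights")
  expect_lt(max(abs(w[, , 1] + w[, , 2] + w[, , 3] + w[, , 4] - 1)), 1e-12)

  expect_identical(as.vector(p), as.vector(sunets_forward(m, x)))
  expect_error(sunets_forward(m, array(0, c(64, 64, 4))),
               class = "sunseg_input_error")
})

test_that("analytic gradients match finite differences", {
  m <- micro_sunets(3L)
  set.seed(3)
  x <- array(runif(16 * 16 * 3) * 255, c(16, 16, 3))
  tgt <- matrix(runif(256) > 0.7, 16)
  for (loss in c("ce", "focal")) {
    lf <- if (loss == "ce") cross_entropy_loss
          else function(p, t) focal_loss(p, t, 2, 0.25)
    gf <- if (loss == "ce") sunseg:::ce_grad_logit
          else function(p, t) sunseg:::focal_grad_logit(p, t, 2, 0.25)
    fw <- sunseg:::sunets_forward_full(m, x, want_cache = TRUE)
    gr <- sunseg:::sunets_backward_full(m, fw, gf(fw$prob, tgt))
    gflat <- sunseg:::flatten_par(gr)
    flat <- sunseg:::flatten_par(m$par)
    lossat <- function(v) {
      m2 <- m; m2$par <- sunseg:::unflatten_par(v, m$par)
      lf(sunseg:::sunets_forward_full(m2, x)$prob, tgt)
    }
    idx <- sample(length(flat), 12)
    for (i in idx) {
      vp <- flat; vp[i] <- vp[i] + 1e-5
      vm <- flat; vm[i] <- vm[i] - 1e-5
      num <- (lossat(vp) - lossat(vm)) / 2e-5
      expect_lt(abs(num - gflat[i]) / max(1e-6, abs(num) + abs(gflat[i])),
                1e-4)
    }
  }
})
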