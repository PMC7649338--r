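test_that("AJI matches its worked example and degenerate cases", {
  g <- rect_mask(32, 32, 11, 20, 11, 20)              # 100 px square
  p1 <- rect_mask(32, 32, 11, 20, 11, 16)             # left 10x6 half
  p2 <- rect_mask(32, 32, 25, 27, 1, 10)              # disjoint 30 px blob
  gt <- instance_map(list(list(label_id = 1L, mask = g)))
  pr <- instance_map(list(list(label_id = 1L, mask = p1),
                          list(label_id = 2L, mask = p2)))
  # best match J = 60/100 -> numerator 60; union 100; unmatched blob 30
  expect_equal(aji(gt, pr), 60 / 130)
  expect_equal(aji_bruteforce(gt, pr), 60 / 130)

  expect_equal(aji(gt, gt), 1)
  far <- instance_map(list(list(label_id = 1L, mask = p2)))
  expect_equal(aji(gt, far), 0)

  empty <- instance_map(list(), shape = c(32L, 32L))
  expect_equal(aji(empty, empty), 1)
  expect_equal(aji(gt, empty), 0)
  expect_equal(aji(empty, gt), 0)
  expect_equal(aji_bruteforce(gt, empty), 0)

  expect_error(aji(gt, instance_map(list(), shape = c(16L, 16L))),
               class = "sunseg_shape_error")
})

test_that("AJI equals the brute-force oracle on random maps", {
  set.seed(101)
  for (i in 1:40) {
    gt <- random_instance_map()
    pr <- random_instance_map()
    expect_identical(aji(gt, pr), aji_bruteforce(gt, pr))
    expect_identical(aji(gt, pr, variant = "used_flag"),
                     aji_bruteforce(gt, pr, variant = "used_flag"))
  }
})

test_that("used_flag variant never exceeds the printed variant", {
  set.seed(202)
  for (i in 1:20) {
    gt <- random_instance_map()
    pr <- random_instance_map()
    expect_lte(aji(gt, pr, "used_flag"), aji(gt, pr, "printed"))
  }
})

test_that("pixel scores match the printed formulas and conventions", {
  # TP = 60, FP = 0, FN = 40
  gtm <- rect_mask(20, 20, 1, 10, 1, 10)
  prm <- rect_mask(20, 20, 1, 10, 1, 6)
  sc <- pixel_scores(gtm, prm)
  expect_equal(sc$precision, 1)
  expect_equal(sc$recall, 0.6)
  expect_equal(sc$f1, 120 / 160)
  expect_equal(sc$confusion$TP, 60)
  expect_equal(sc$confusion$TP + sc$confusion$FP + sc$confusion$FN +
                 sc$confusion$TN, 400)

  perfect <- pixel_scores(gtm, gtm)
  expect_equal(c(perfect$precision, perfect$recall, perfect$f1), c(1, 1, 1))

  both_empty <- pixel_scores(matrix(FALSE, 4, 4), matrix(FALSE, 4, 4))
  expect_equal(c(both_empty$precision, both_empty$recall, both_empty$f1),
               c(1, 1, 1))
  one_empty <- pixel_scores(gtm, matrix(FALSE, 20, 20))
  expect_equal(c(one_empty$precision, one_empty$recall, one_empty$f1),
               c(0, 0, 0))

  # F1 is symmetric in FP and FN
  sc_swap <- pixel_scores(prm, gtm)
  expect_equal(sc$f1, sc_swap$f1)

  expect_error(pixel_scores(gtm, matrix(FALSE, 4, 4)),
               class = "sunseg_shape_error")
})

test_that("set evaluation averages per-image scores", {
  gt <- instance_map(list(list(label_id = 1L,
                               mask = rect_mask(16, 16, 2, 9, 2, 9))))
  pr_half <- instance_map(list(list(label_id = 1L,
                                    mask = rect_mask(16, 16, 2, 9, 2, 5))))
  single <- evaluate_set(list(list(gt = gt, pred = gt)))
  expect_equal(single$overall$aji, 1)
  expect_equal(single$overall$f1, 1)

  two <- evaluate_set(list(list(gt = gt, pred = gt),
                           list(gt = gt, pred = pr_half)))
  a2 <- aji(gt, pr_half)
  expect_equal(two$overall$aji, mean(c(1, a2)))

  rev2 <- evaluate_set(list(list(gt = gt, pred = pr_half),
                            list(gt = gt, pred = gt)))
  expect_equal(two$overall$aji, rev2$overall$aji)
  expect_equal(two$overall$f1, rev2$overall$f1)

  expect_error(evaluate_set(list()), class = "sunseg_data_error")
})
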