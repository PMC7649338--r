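test_that("watershed handles empty and single-object masks", {
  empty <- watershed_instances(matrix(FALSE, 32, 32))
  expect_equal(n_objects(empty), 0L)

  disk <- disk_mask(64, 64, 32, 32, 20)
  one <- watershed_instances(disk)
  expect_equal(n_objects(one), 1L)
  expect_identical(one$objects[[1]]$mask, disk)
})

test_that("watershed separates touching disks and preserves their union", {
  mask <- disk_mask(64, 64, 32, 20, 15) | disk_mask(64, 64, 32, 44, 15)
  ws <- watershed_instances(mask)
  expect_equal(n_objects(ws), 2L)
  expect_identical(semantic_from_instances(ws), mask)
  # disjoint partition
  expect_true(all(coverage_from_instances(ws) <= 1L))
})

test_that("watershed output partitions the size-filtered input mask", {
  for (s in 1:5) {
    smp <- generate_sample(scene_spec(seed = s, overlap_fraction = 0.5))
    ws <- watershed_instances(smp$semantic_mask, min_size = 20L)
    cov <- coverage_from_instances(ws)
    expect_true(all(cov <= 1L))
    expect_true(all((cov > 0) <= smp$semantic_mask))  # subset of input
    sizes <- vapply(ws$objects, function(o) sum(o$mask), numeric(1))
    if (length(sizes)) expect_true(all(sizes >= 20))
  }
})

test_that("stage-two input stacks the mask as a binary 4th channel", {
  px <- array(runif(16 * 16 * 3) * 255, c(16, 16, 3))
  mask <- matrix(runif(256) > 0.5, 16)
  x <- make_stage2_input(px, mask)
  expect_equal(dim(x), c(16L, 16L, 4L))
  expect_true(all(x[, , 4] %in% c(0, 255)))
  expect_equal(x[, , 4] > 0, mask)
  x0 <- make_stage2_input(px, matrix(FALSE, 16, 16))
  expect_true(all(x0[, , 4] == 0))
  expect_error(make_stage2_input(px, matrix(FALSE, 8, 8)),
               class = "sunseg_shape_error")
})

test_that("overlap components use 8-connectivity", {
  m <- matrix(FALSE, 20, 20)
  m[2:6, 2:6] <- TRUE; m[12:16, 12:16] <- TRUE
  comps <- extract_overlap_components(m)
  expect_length(comps, 2L)
  expect_equal(vapply(comps, function(cm) sum(cm$mask), numeric(1)),
               c(25, 25))

  expect_length(extract_overlap_components(matrix(FALSE, 5, 5)), 0L)

  diag2 <- matrix(FALSE, 4, 4); diag2[1, 1] <- TRUE; diag2[2, 2] <- TRUE
  expect_length(extract_overlap_components(diag2), 1L)
})

test_that("merge respects the 10-pixel threshold and multi-assignment", {
  H <- 32
  instA <- rect_mask(H, H, 1, 10, 1, 10)
  instB <- rect_mask(H, H, 1, 10, 16, 30)
  inst <- instance_map(list(list(label_id = 1L, mask = instA),
                            list(label_id = 2L, mask = instB)))

  # component sharing exactly 10 px with A: absorbed into A
  comp10 <- rect_mask(H, H, 1, 10, 10, 10) | rect_mask(H, H, 12, 14, 6, 10)
  expect_equal(sum(comp10 & instA), 10)
  oc <- structure(list(list(component_id = 1L, mask = comp10)),
                  shape = c(H, H), class = "overlap_components")
  merged <- merge_overlaps(inst, oc, min_overlap = 10L)
  expect_identical(merged$objects[[1]]$mask, instA | comp10)
  expect_identical(merged$objects[[2]]$mask, instB)

  # 9 shared px: nothing changes
  comp9 <- rect_mask(H, H, 2, 10, 10, 10) | rect_mask(H, H, 12, 14, 6, 10)
  expect_equal(sum(comp9 & instA), 9)
  oc9 <- structure(list(list(component_id = 1L, mask = comp9)),
                   shape = c(H, H), class = "overlap_components")
  expect_identical(merge_overlaps(inst, oc9, 10L)$objects,
                   inst$objects)

  # component sharing 12 px with A and 15 px with B joins both
  comp2 <- rect_mask(H, H, 5, 8, 8, 10) | rect_mask(H, H, 5, 9, 16, 18) |
    rect_mask(H, H, 5, 5, 11, 15)
  expect_equal(sum(comp2 & instA), 12)
  expect_equal(sum(comp2 & instB), 15)
  oc2 <- structure(list(list(component_id = 1L, mask = comp2)),
                   shape = c(H, H), class = "overlap_components")
  m2 <- merge_overlaps(inst, oc2, 10L)
  expect_identical(m2$objects[[1]]$mask, instA | comp2)
  expect_identical(m2$objects[[2]]$mask, instB | comp2)
  # A and B were disjoint, so the shared region is exactly the component
  shared <- m2$objects[[1]]$mask & m2$objects[[2]]$mask
  expect_identical(shared, comp2)

  # empty component list is the identity; pixels are never removed
  oc0 <- structure(list(), shape = c(H, H), class = "overlap_components")
  expect_identical(merge_overlaps(inst, oc0)$objects, inst$objects)
  for (o in seq_along(m2$objects))
    expect_true(all(inst$objects[[o]]$mask <= m2$objects[[o]]$mask))
})
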