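test_that("Grad-CAM reproduces the class activation map on GAP-head nets", {
  for (seed in 1:5) {
    net <- tiny_net(n_labels = 2, seed = seed)
    img <- random_image(16, seed = 100 + seed)
    for (j in 1:2) {
      cam <- suppressWarnings(grad_cam(net, img, j))
      ref <- oracle_cam(net, img, j)
      expect_lt(max(abs(cam - ref)), 1e-5)
    }
  }
})

test_that("Grad-CAM is deterministic and handles all-negative contributions", {
  net <- tiny_net(n_labels = 1, seed = 3)
  img <- random_image(16, seed = 2)
  expect_identical(suppressWarnings(grad_cam(net, img, 1)),
                   suppressWarnings(grad_cam(net, img, 1)))
  # force every channel weight negative: rectified map is identically zero
  net$head$W[, 1] <- -abs(net$head$W[, 1]) - 0.1
  expect_warning(z <- grad_cam(net, img, 1), "identically zero")
  expect_true(all(z == 0))
  expect_true(attr(z, "degenerate"))
})

test_that("map averaging normalizes, averages and flags degeneracy", {
  m <- matrix(runif(64), 8, 8)
  avg <- average_maps(list(m, m, m))
  expect_equal(avg, cxrtransfer:::.minmax_normalize(m), ignore_attr = TRUE)
  # a map and its complement average to a constant
  n <- cxrtransfer:::.minmax_normalize(m)
  avg2 <- average_maps(list(n, 1 - n))
  expect_true(attr(avg2, "degenerate"))
  expect_error(average_maps(list(m, matrix(0, 4, 4))), "shape")
})

test_that("quantile mask covers the expected pixel fraction", {
  set.seed(20)
  map <- matrix(sample(seq_len(224 * 224)) / (224 * 224), 224, 224)
  mask <- quantile_mask(map, 0.8)
  frac <- mean(mask)
  expect_gte(frac, 0.199)
  expect_lte(frac, 0.201)
  # monotone: larger q shrinks the mask
  expect_true(all(quantile_mask(map, 0.9) <= mask))
  expect_warning(empty <- quantile_mask(matrix(1, 5, 5), 0.8), "constant")
  expect_false(any(empty))
  expect_error(quantile_mask(map, 1), "scalar")
})

test_that("bounding boxes cover true pixels in union and component mode", {
  mask <- matrix(FALSE, 10, 10)
  mask[2, 3] <- TRUE
  mask[5, 7] <- TRUE
  bb <- bounding_box(mask, "union")
  expect_equal(unlist(bb), c(row_min = 2, row_max = 5, col_min = 3,
                             col_max = 7))
  one <- matrix(FALSE, 4, 4); one[3, 2] <- TRUE
  bb1 <- bounding_box(one, "union")
  expect_equal(unlist(bb1), c(row_min = 3, row_max = 3, col_min = 2,
                              col_max = 2))
  # two distant blobs: one box per component, matching each blob extent
  two <- matrix(FALSE, 12, 12)
  two[2:3, 2:4] <- TRUE
  two[9:11, 8:9] <- TRUE
  bbs <- bounding_box(two, "components")
  expect_equal(nrow(bbs), 2L)
  bbs <- bbs[order(bbs$row_min), ]
  expect_equal(unlist(bbs[1, ]), c(row_min = 2, row_max = 3, col_min = 2,
                                   col_max = 4))
  expect_equal(unlist(bbs[2, ]), c(row_min = 9, row_max = 11, col_min = 8,
                                   col_max = 9))
  expect_equal(nrow(bounding_box(matrix(FALSE, 3, 3))), 0L)
})

test_that("component labeling is 8-connected and matches the flood-fill oracle", {
  # diagonal touch is one component
  diag2 <- matrix(FALSE, 4, 4)
  diag2[2, 2] <- TRUE
  diag2[3, 3] <- TRUE
  expect_equal(nrow(bounding_box(diag2, "components")), 1L)
  set.seed(21)
  for (rep in 1:10) {
    mask <- matrix(runif(15 * 15) < 0.25, 15, 15)
    if (!any(mask)) next
    comps <- oracle_components(mask)
    bbs <- bounding_box(mask, "components")
    expect_equal(nrow(bbs), length(comps))
    ref <- do.call(rbind, lapply(comps, function(cm) {
      idx <- which(cm, arr.ind = TRUE)
      c(min(idx[, 1]), max(idx[, 1]), min(idx[, 2]), max(idx[, 2]))
    }))
    got <- as.matrix(bbs)
    expect_equal(got[order(got[, 1], got[, 3]), , drop = FALSE],
                 ref[order(ref[, 1], ref[, 3]), , drop = FALSE],
                 ignore_attr = TRUE)
  }
})

test_that("agreement is intersection over expert area and monotone", {
  expert <- matrix(FALSE, 20, 20)
  expert[5:14, 5:14] <- TRUE # 100 expert pixels
  pred <- matrix(FALSE, 20, 20)
  pred[5:14, 5:11] <- TRUE # overlaps 70
  pred[1:2, 1:2] <- TRUE # spurious extra pixels do not count against
  expect_equal(agreement(pred, expert), 0.7)
  expect_equal(agreement(expert | pred, expert), 1) # superset
  expect_equal(agreement(!expert & !pred, expert), 0) # disjoint
  # 75 of 100 expert pixels hit -> 0.75
  pred75 <- matrix(FALSE, 20, 20)
  pred75[5:14, 5:14] <- TRUE
  pred75[which(expert)[76:100]] <- FALSE
  expect_equal(agreement(pred75, expert), 0.75)
  # monotone: adding predicted pixels never decreases agreement
  set.seed(22)
  p <- matrix(runif(400) < 0.3, 20, 20)
  base <- agreement(p, expert)
  p2 <- p
  p2[sample(which(!p), 30)] <- TRUE
  expect_gte(agreement(p2, expert), base)
  expect_warning(na <- agreement(p, matrix(FALSE, 20, 20)), "empty expert")
  expect_true(is.na(na))
  # box-based variant is at least as permissive as the mask
  expect_gte(agreement(p, expert, on = "box"), agreement(p, expert))
})

test_that("population-level maps concentrate saliency in the signature region", {
  fix <- blob_fixture()
  pos <- which(fix$dat$labels[, 1] == 1L)[1:100]
  maps <- lapply(pos, function(i) {
    suppressWarnings(grad_cam(fix$model, fix$x[[i]], 1))
  })
  avg <- average_maps(maps)
  truth <- cxrtransfer:::.signature_mask(fix$spec$geometry$blob, 32, 32)
  border <- matrix(FALSE, 32, 32)
  border[c(1:2, 31:32), ] <- TRUE
  border[, c(1:2, 31:32)] <- TRUE
  expect_gt(mean(avg[truth]), mean(avg[border & !truth]))
})
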