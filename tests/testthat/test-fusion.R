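test_that("test-time augmentation views are involutions with known index geometry", {
  x <- array(as.numeric(1:6), dim = c(2, 3, 1))
  for (v in tta_views())
    expect_identical(invert_view(apply_view(x, v), v), x, label = v)

  ## hand-checked index permutations on the 2 x 3 pattern [1 3 5; 2 4 6]
  expect_identical(apply_view(x, "hflip")[, , 1], matrix(c(5, 6, 3, 4, 1, 2), 2, 3))
  expect_identical(apply_view(x, "vflip")[, , 1], matrix(c(2, 1, 4, 3, 6, 5), 2, 3))
  expect_identical(apply_view(x, "rot180")[, , 1], matrix(c(6, 5, 4, 3, 2, 1), 2, 3))
  expect_error(apply_view(x, "rot90"), "unknown view")
})

test_that("gaussian weight map peaks at the centre, is symmetric, and matches the closed form", {
  w9 <- gaussian_weight_map(c(9L, 9L))
  expect_equal(w9[5, 5], 1)
  expect_equal(w9, w9[9:1, ], tolerance = 1e-15)
  expect_equal(w9, w9[, 9:1], tolerance = 1e-15)
  ## 9 x 9, sigma = 9/8: corner offset 4 from the centre pixel
  expect_equal(w9[1, 1], exp(-(4^2 + 4^2) / (2 * (9 / 8)^2)), tolerance = 1e-12)

  ## 8 x 8 default sigma = 1: corner at continuous offset 3.5, sampled peak at 0.5
  w8 <- gaussian_weight_map(c(8L, 8L))
  expect_equal(max(w8), 1)
  expect_equal(w8[1, 1],
               exp(-(3.5^2 + 3.5^2) / 2) / exp(-(0.5^2 + 0.5^2) / 2),
               tolerance = 1e-12)
  expect_true(all(w8 > 0))
  expect_error(gaussian_weight_map(c(8L, 8L), sigma_scale = 0), "positive")
})

test_that("tile plans have the documented strides and always cover the image", {
  p1 <- tile_plan(c(512L, 512L), c(512L, 512L), overlap = 0.5)
  expect_identical(nrow(p1), 1L)
  p2 <- tile_plan(c(768L, 768L), c(512L, 512L), overlap = 0.5)
  expect_identical(sort(unique(p2$r0)), c(1L, 257L))
  expect_identical(max(p2$r1), 768L)

  set.seed(5)
  for (i in 1:10) {
    H <- sample(40:130, 1); W <- sample(40:130, 1)
    th <- sample(20:40, 1); tw <- sample(20:40, 1)
    plan <- tile_plan(c(H, W), c(th, tw), overlap = runif(1, 0, 0.6))
    cover <- matrix(0L, H, W)
    for (j in seq_len(nrow(plan)))
      cover[plan$r0[j]:plan$r1[j], plan$c0[j]:plan$c1[j]] <- 1L
    expect_true(all(cover == 1L))
    expect_true(all(plan$r1 <= H) && all(plan$c1 <= W))
  }
  expect_error(tile_plan(c(0L, 10L), c(4L, 4L)), "zero-size")
})

test_that("stitching is a weighted average that conserves constants", {
  wm <- gaussian_weight_map(c(4L, 4L))
  windows <- tile_plan(c(6L, 4L), c(4L, 4L), overlap = 0.5)
  tiles <- lapply(seq_len(nrow(windows)), function(i)
    array(c(matrix(0.3, 4, 4), matrix(0.7, 4, 4)), dim = c(4, 4, 2)))
  out <- stitch(tiles, windows, wm, c(6L, 4L))
  expect_equal(out[, , 1], matrix(0.3, 6, 4), tolerance = 1e-12)

  ## two tiles overlapping one row: hand-computed weighted mean
  win2 <- data.frame(r0 = c(1L, 4L), r1 = c(4L, 7L), c0 = 1L, c1 = 4L)
  t1 <- array(c(matrix(0.2, 4, 4), matrix(0.8, 4, 4)), dim = c(4, 4, 2))
  t2 <- array(c(matrix(0.6, 4, 4), matrix(0.4, 4, 4)), dim = c(4, 4, 2))
  out2 <- stitch(list(t1, t2), win2, wm, c(7L, 4L))
  w_bottom <- wm[4, 2]  # tile 1 contributes its last row at the overlap row 4
  w_top <- wm[1, 2]     # tile 2 its first row
  expect_equal(out2[4, 2, 1], (w_bottom * 0.2 + w_top * 0.6) / (w_bottom + w_top),
               tolerance = 1e-12)
  expect_equal(out2[1, 1, 1], 0.2)  # covered by tile 1 alone

  ## single covering tile is the identity
  single <- stitch(list(t1), data.frame(r0 = 1L, r1 = 4L, c0 = 1L, c1 = 4L),
                   wm, c(4L, 4L))
  expect_equal(single, t1, tolerance = 1e-12)
})

test_that("fusion is the uniform mixture with background-favouring argmax", {
  p <- matrix(c(0.2, 0.8, 0.5, 0.1), 2, 2)
  e1 <- mk_ensemble(list(p))
  f1 <- fuse(e1)
  expect_equal(f1$p[, , 2], p, tolerance = 1e-15)

  ## two members at 0.2 and 0.8 fuse to 0.5, argmax tie -> background
  e2 <- mk_const_ensemble(c(0.2, 0.8))
  f2 <- fuse(e2)
  expect_equal(f2$p[, , 2], matrix(0.5, 2, 2), tolerance = 1e-15)
  expect_true(all(f2$yhat == 0L))
})

test_that("fusion is invariant to permuting members and views", {
  set.seed(9)
  probs <- lapply(1:6, function(i) matrix(runif(12), 3, 4))
  e <- mk_ensemble(probs, M = 3L, T = 2L)
  ep <- ensemble_output(e$maps[c(2, 3, 1)], view_ids = e$view_ids)
  ev <- ensemble_output(lapply(e$maps, function(vm) vm[c(2, 1)]),
                        view_ids = e$view_ids)
  expect_equal(fuse(e)$p, fuse(ep)$p, tolerance = 1e-15)
  expect_equal(fuse(e)$p, fuse(ev)$p, tolerance = 1e-15)
})

test_that("tiled prediction with a mask-thresholding predictor reproduces the mask", {
  sc <- generate_scene(test_scene_config(c(48L, 40L)), seed = 3)
  truth <- unclass(sc$mask)
  img <- array((truth > 0) * 1.0, dim = c(dim(truth), 1L))
  onehot_predictor <- function(m, tile) {
    p1 <- (tile[, , 1] > 0.5) * 1.0
    array(c(1 - p1, p1), dim = c(dim(p1), 2L))
  }
  res <- predict_image(onehot_predictor, img, M = 3L, tile_shape = c(32L, 32L),
                       overlap = 0.5)
  expect_identical(unclass(res$fused$yhat)[, ], truth[, ])
  expect_identical(res$ensemble$M, 3L)
  expect_identical(res$ensemble$T, 4L)
})

test_that("view-equivariant predictors make TTA a no-op; others average over inverted views", {
  set.seed(21)
  img <- array(runif(16 * 16), dim = c(16L, 16L, 1L))
  ## pixel-wise (hence equivariant) soft predictor
  equi <- function(m, tile) {
    p1 <- stats::plogis(6 * (tile[, , 1] - 0.5))
    array(c(1 - p1, p1), dim = c(dim(p1), 2L))
  }
  with_tta <- predict_image(equi, img, M = 1L, tile_shape = c(16L, 16L))
  no_tta <- predict_image(equi, img, M = 1L, tile_shape = c(16L, 16L), tta = FALSE)
  expect_equal(with_tta$fused$p, no_tta$fused$p, tolerance = 1e-12)

  ## row-position-sensitive predictor: fused map must equal the hand-computed
  ## average of the four inverted single-view outputs
  rowpos <- function(m, tile) {
    bias <- matrix(seq_len(nrow(tile)) / nrow(tile), nrow(tile), ncol(tile))
    p1 <- stats::plogis(4 * (tile[, , 1] - 0.5) + bias)
    array(c(1 - p1, p1), dim = c(dim(p1), 2L))
  }
  res <- predict_image(rowpos, img, M = 1L, tile_shape = c(16L, 16L))
  manual <- Reduce(`+`, lapply(tta_views(), function(v)
    invert_view(rowpos(1L, apply_view(img, v)), v))) / 4
  expect_equal(res$fused$p, manual, tolerance = 1e-12)
})

test_that("images smaller than the tile are reflection-padded to a single window", {
  img <- array(runif(10 * 12), dim = c(10L, 12L, 1L))
  const <- function(m, tile)
    array(c(matrix(0.25, nrow(tile), ncol(tile)),
            matrix(0.75, nrow(tile), ncol(tile))),
          dim = c(nrow(tile), ncol(tile), 2L))
  res <- predict_image(const, img, M = 2L, tile_shape = c(16L, 16L))
  expect_identical(dim(res$fused$p), c(10L, 12L, 2L))
  expect_equal(res$fused$p[, , 2], matrix(0.75, 10, 12), tolerance = 1e-12)
})
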