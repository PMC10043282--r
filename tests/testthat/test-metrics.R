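test_that("Dice score matches hand-computed overlaps and is symmetric", {
  a <- matrix(0L, 4, 4); a[1, 1:4] <- 1L            # 4 fg pixels
  b <- matrix(0L, 4, 4); b[1, 1:2] <- 1L; b[2, 1] <- 1L  # 3 fg, overlap 2
  ya <- mk_mask(a); yb <- mk_mask(b)
  expect_equal(dice_score(ya, yb), 4 / 7)
  expect_equal(dice_score(yb, ya), dice_score(ya, yb))
  expect_equal(dice_score(ya, ya), 1)

  disjoint <- mk_mask(matrix(c(rep(0L, 8), rep(1L, 8)), 4, 4))
  other <- mk_mask(matrix(c(rep(1L, 8), rep(0L, 8)), 4, 4))
  expect_equal(dice_score(disjoint, other), 0)
})

test_that("macro Dice averages per class and scores empty-vs-empty classes as 1", {
  a <- label_mask(matrix(c(0L, 1L, 0L, 1L), 2, 2), K = 3L)  # class 2 absent in both
  b <- label_mask(matrix(c(0L, 1L, 1L, 1L), 2, 2), K = 3L)
  per <- dice_score(a, b, K = 3L, average = "per-class")
  expect_equal(unname(per["class2"]), 1)
  expect_equal(unname(per["class1"]), 2 * 2 / (2 * 2 + 1))
  expect_equal(dice_score(a, b, K = 3L), mean(per))
  ## background inclusion is opt-in
  with_bg <- dice_score(a, b, K = 3L, include_background = TRUE,
                        average = "per-class")
  expect_length(with_bg, 3L)
  expect_error(dice_score(a, b, classes = integer(0)), "empty class")
})

test_that("IoU follows set arithmetic and rejects the empty-empty case", {
  expect_equal(iou(1:4, 1:4), 1)
  expect_equal(iou(1:4, 5:8), 0)
  expect_equal(iou(1:4, 3:6), 2 / 6)
  expect_error(iou(integer(0), integer(0)), "undefined")
})

test_that("instance matching is greedy one-to-one in descending IoU", {
  ## identical maps: all matched
  im <- random_instance_map()
  mm <- match_instances(im, im, 0.5)
  expect_identical(mm$tp, max(im$instances, 0L))
  expect_identical(mm$fp + mm$fn, 0L)

  ## one pair below threshold
  g <- matrix(0L, 6, 6); g[1:2, 1:5] <- 1L          # 10 px
  p <- matrix(0L, 6, 6); p[1, 1:4] <- 1L            # 4 px, inter 4, union 10
  mm2 <- match_instances(instance_map(g), instance_map(p), 0.5)
  expect_identical(c(mm2$tp, mm2$fp, mm2$fn), c(0L, 1L, 1L))

  ## one prediction overlapping two references: best IoU wins, one FN remains
  g2 <- matrix(0L, 8, 8); g2[1:4, 1:4] <- 1L; g2[1:4, 5:8] <- 2L
  p2 <- matrix(0L, 8, 8); p2[1:4, 2:6] <- 1L
  ## IoU(ref1) = 12/20 = 0.6, IoU(ref2) = 8/24 = 1/3; eta = 0.3
  mm3 <- match_instances(instance_map(g2), instance_map(p2), 0.3)
  expect_identical(c(mm3$tp, mm3$fp, mm3$fn), c(1L, 0L, 1L))
  expect_identical(mm3$matches$a, 1L)
})

test_that("greedy matching equals exhaustive optimal matching on random maps", {
  set.seed(71)
  for (i in 1:40) {
    g <- random_instance_map(); p <- random_instance_map()
    eta <- sample(default_iou_thresholds(), 1)
    expect_identical(match_instances(g, p, eta)$tp,
                     brute_force_match(g, p, eta),
                     label = paste("case", i))
  }
})

test_that("the default threshold grid and the worked mAP example are exact", {
  H <- default_iou_thresholds()
  expect_length(H, 10L)
  expect_equal(H, c(0.50, 0.55, 0.60, 0.65, 0.70, 0.75, 0.80, 0.85, 0.90, 0.95))

  ## perfect prediction
  im <- random_instance_map()
  expect_equal(mean_average_precision(im, im)$mAP, 1)

  ## single pair at IoU exactly 0.60: AP = 1 at eta in {0.50, 0.55, 0.60}
  g <- matrix(0L, 6, 6); g[1:2, 1:4] <- 1L                   # 8 px
  p <- matrix(0L, 6, 6); p[1:2, 2:4] <- 1L; p[3, 2:3] <- 1L  # 8 px, inter 6
  mt <- mean_average_precision(instance_map(g), instance_map(p))
  expect_equal(mt$per_threshold$ap, c(1, 1, 1, rep(0, 7)))
  expect_equal(mt$mAP, 0.3)
})

test_that("average precision is non-increasing in the IoU threshold", {
  set.seed(73)
  for (i in 1:15) {
    g <- random_instance_map(); p <- random_instance_map()
    ap <- mean_average_precision(g, p)$per_threshold$ap
    expect_true(all(diff(ap) <= 1e-12))
  }
})

test_that("mAP is invariant to instance id relabelling", {
  set.seed(79)
  g <- random_instance_map(); p <- random_instance_map()
  n <- max(p$instances)
  perm <- sample(n)
  relab <- p$instances
  relab[relab > 0L] <- perm[relab[relab > 0L]]
  p2 <- instance_map(ambiseg:::relabel_raster_order(relab))
  expect_equal(mean_average_precision(g, p)$mAP,
               mean_average_precision(g, p2)$mAP)
})

test_that("multiclass mAP macro-averages per-class matching", {
  g <- matrix(0L, 8, 8); g[1:3, 1:3] <- 1L; g[5:7, 5:7] <- 2L
  gm <- instance_map(g, class_of = c(1L, 2L))
  ## class 1 perfect, class 2 entirely missed
  p <- matrix(0L, 8, 8); p[1:3, 1:3] <- 1L
  pm <- instance_map(p, class_of = 1L)
  mt <- mean_average_precision(gm, pm)
  expect_equal(mt$mAP, 0.5)
})

test_that("expert-range classification applies boundary-inclusive comparison", {
  experts <- data.frame(image_id = rep(c("a", "b", "c"), each = 2),
                        score = c(0.7, 0.8, 0.7, 0.8, 0.7, 0.8))
  model <- c(a = 0.8, b = 0.9, c = 0.5)
  res <- expert_range_classification(model, experts)
  expect_identical(res$labels$label, c("in_range", "above_best", "below_worst"))
  expect_equal(unname(res$shares), rep(1 / 3, 3))
  expect_error(expert_range_classification(c(zz = 0.5), experts), "no expert")
})

test_that("perfect one-to-one overlap gives DS = 1 and mAP = 1 simultaneously", {
  sc <- generate_scene(test_scene_config(), seed = 81)
  expect_equal(dice_score(sc$mask, sc$mask), 1)
  expect_equal(mean_average_precision(sc$instances, sc$instances)$mAP, 1)
})
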