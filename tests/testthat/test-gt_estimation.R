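test_that("majority vote counts votes and applies the background-favouring tie rule", {
  m1 <- mk_mask(matrix(c(1, 1, 0, 0), 2, 2))
  expect_identical(unclass(majority_vote(list(m1, m1, m1)))[, ], unclass(m1)[, ])

  ## votes (fg, fg, bg) at every pixel -> fg
  fg <- mk_mask(matrix(1, 2, 2)); bg <- mk_mask(matrix(0, 2, 2), K = 2L)
  expect_true(all(majority_vote(list(fg, fg, bg)) == 1L))

  ## three-way tie (class1, class2, bg) -> background under default policy
  a <- label_mask(matrix(1L, 2, 2), K = 3L)
  b <- label_mask(matrix(2L, 2, 2), K = 3L)
  z <- label_mask(matrix(0L, 2, 2), K = 3L)
  expect_true(all(majority_vote(list(a, b, z)) == 0L))
  expect_true(all(majority_vote(list(a, b, z), tie_policy = "highest") == 2L))
})

test_that("majority vote is invariant to rater order", {
  set.seed(42)
  masks <- lapply(1:5, function(i) mk_mask(matrix(rbinom(64, 1, 0.4), 8, 8)))
  v1 <- majority_vote(masks)
  v2 <- majority_vote(masks[c(3, 1, 5, 2, 4)])
  expect_identical(unclass(v1)[, ], unclass(v2)[, ])
})

test_that("binary STAPLE handles unanimous and single-rater degenerate cases", {
  m <- mk_mask(matrix(c(rep(1, 10), rep(0, 22)), 4, 8))
  st <- staple_binary(list(m, m, m))
  expect_identical(unclass(st$gt)[, ], unclass(m)[, ])
  expect_true(all(st$p >= 0.999))
  expect_true(all(st$q >= 0.999))

  st1 <- staple_binary(list(m))
  expect_identical(unclass(st1$gt)[, ], unclass(m)[, ])
})

test_that("STAPLE EM log-likelihood is non-decreasing and estimates are rater-permutation-equivariant", {
  sc <- generate_scene(test_scene_config(), seed = 7)
  raters <- data.frame(sensitivity = c(0.95, 0.9, 0.85, 0.9),
                       specificity = c(0.95, 0.97, 0.96, 0.94),
                       jitter = 0L)
  masks <- simulate_raters(sc$mask, raters, seed = 8)
  st <- staple_binary(masks)
  expect_true(all(diff(st$loglik) >= -1e-7))

  perm <- c(3, 1, 4, 2)
  stp <- staple_binary(masks[perm])
  expect_equal(stp$p, st$p[perm], tolerance = 1e-9)
  expect_equal(stp$q, st$q[perm], tolerance = 1e-9)
  expect_identical(unclass(stp$gt)[, ], unclass(st$gt)[, ])
})

test_that("a single E-step posterior is monotone in the foreground prior", {
  set.seed(11)
  masks <- lapply(1:3, function(i) mk_mask(matrix(rbinom(100, 1, 0.3), 10, 10)))
  lo <- staple_binary(masks, prior = 0.2, max_iter = 0L)
  hi <- staple_binary(masks, prior = 0.8, max_iter = 0L)
  expect_true(all(hi$posterior[, , 2] >= lo$posterior[, , 2] - 1e-12))
  ## foreground set never shrinks when the prior rises
  expect_true(all(unclass(hi$gt)[unclass(lo$gt) == 1L] == 1L))
})

test_that("STAPLE recovers known rater parameters and error shrinks with image size", {
  sizes <- list(c(64L, 64L), c(128L, 128L), c(256L, 256L))
  errs <- vapply(seq_along(sizes), function(i) {
    cfg <- synthetic_config(image_shape = sizes[[i]],
                            objects_per_class = c(3L, 6L) * i,
                            radius = c(3L, 6L) + i)
    sc <- generate_scene(cfg, seed = 20 + i)
    masks <- simulate_raters(sc$mask,
                             data.frame(sensitivity = rep(0.9, 5),
                                        specificity = rep(0.95, 5), jitter = 0L),
                             seed = 30 + i)
    st <- staple_binary(masks)
    mean(abs(c(st$p - 0.9, st$q - 0.95)))
  }, numeric(1))
  expect_lt(errs[3], 0.02)
  expect_lt(errs[3], errs[1])
})

test_that("multiclass STAPLE reduces to binary STAPLE for K = 2", {
  sc <- generate_scene(test_scene_config(), seed = 13)
  masks <- simulate_raters(sc$mask,
                           data.frame(sensitivity = rep(0.9, 4),
                                      specificity = rep(0.96, 4), jitter = 0L),
                           seed = 14)
  mb <- staple_binary(masks)
  mm <- staple_multiclass(masks, K = 2L)
  expect_identical(unclass(mm$gt)[, ], unclass(mb$gt)[, ])
})

test_that("unanimous multiclass masks are reproduced with zero undecided pixels", {
  m <- label_mask(matrix(c(0L, 1L, 2L, 0L, 1L, 2L, 2L, 1L, 0L), 3, 3), K = 3L)
  mm <- staple_multiclass(list(m, m, m))
  expect_identical(unclass(mm$gt)[, ], unclass(m)[, ])
  expect_identical(mm$undecided_pixels, 0L)
})

test_that("undecided posterior ties are resolved by the highest-scoring rater", {
  ## one conflicting pixel: rater 1 says class 1, rater 2 says class 2;
  ## with the symmetric per-pixel prior both one-vs-rest posteriors tie exactly
  a <- label_mask(matrix(c(0L, 0L, 0L, 1L), 2, 2), K = 3L)
  b <- label_mask(matrix(c(0L, 0L, 0L, 2L), 2, 2), K = 3L)
  mm <- staple_multiclass(list(a, b), K = 3L, rater_scores = c(0.2, 0.9),
                          prior = "rater-mean")
  expect_identical(mm$undecided_pixels, 1L)
  expect_identical(unclass(mm$gt)[2, 2], 2L)
  mm2 <- staple_multiclass(list(a, b), K = 3L, rater_scores = c(0.9, 0.2),
                           prior = "rater-mean")
  expect_identical(unclass(mm2$gt)[2, 2], 1L)
  mm3 <- staple_multiclass(list(a, b), K = 3L, undecided_policy = "background",
                           prior = "rater-mean")
  expect_identical(unclass(mm3$gt)[2, 2], 0L)
})

test_that("inter-rater scores drop monotonically with rater noise", {
  sc <- generate_scene(test_scene_config(), seed = 17)
  masks <- lapply(c(0.98, 0.85, 0.7), function(s)
    simulate_raters(sc$mask, data.frame(sensitivity = s, specificity = 0.999,
                                        jitter = 0L), seed = 18)[[1]])
  res <- inter_rater_scores(masks, sc$mask, task = "semantic")
  expect_true(all(diff(res$scores$value) < 0))
  expect_equal(res$range[["min"]], min(res$scores$value))
  expect_equal(res$range[["max"]], max(res$scores$value))

  ## identical and complementary raters hit the Dice extremes
  m <- mk_mask(matrix(c(1, 0, 1, 0), 2, 2))
  comp <- mk_mask(1 - unclass(m))
  res2 <- inter_rater_scores(list(m, comp), m, task = "semantic")
  expect_equal(res2$scores$value, c(1, 0))
})
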