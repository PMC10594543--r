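test_that("pixel confusion enumerates the grid and matches the loop oracle", {
  gt <- matrix(0L, 3, 3); gt[c(1, 2, 3)] <- 255L
  pr <- matrix(0L, 3, 3); pr[c(2, 3, 4)] <- 255L
  cc <- pixel_confusion(pr, gt)
  expect_equal(cc[c("tp", "fp", "fn", "tn")],
               list(tp = 2L, fp = 1L, fn = 1L, tn = 5L), ignore_attr = TRUE)

  withr::local_seed(23)
  for (rep in 1:10) {
    a <- random_mask(9, 11); b <- random_mask(9, 11)
    cc <- pixel_confusion(a, b)
    orc <- oracle_confusion(a, b)
    expect_equal(cc[c("tp", "tn", "fp", "fn")], orc, ignore_attr = TRUE)
    expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, 99)
  }

  expect_error(pixel_confusion(matrix(0L, 2, 2), matrix(0L, 3, 3)), "differ")
})

test_that("pixel metrics match hand arithmetic and degrade to NA, never 0", {
  pm <- pixel_metrics(list(tp = 2, tn = 5, fp = 1, fn = 1))
  expect_equal(pm$accuracy, 7 / 9)
  expect_equal(pm$precision, 2 / 3)
  expect_equal(pm$recall, 2 / 3)
  expect_equal(pm$specificity, 5 / 6)
  expect_equal(pm$dice, 4 / 6)
  expect_equal(pm$iou, 1 / 2)

  perfect <- pixel_metrics(pixel_confusion(random_mask(6, 6), k <- random_mask(6, 6)))
  # pred == gt: all six metrics are 1 (k reused as its own prediction)
  pm1 <- pixel_metrics(pixel_confusion(k, k))
  expect_true(all(unlist(pm1) == 1))

  z <- matrix(0L, 4, 4)
  pm0 <- pixel_metrics(pixel_confusion(z, z))
  expect_equal(pm0$accuracy, 1)
  expect_true(is.na(pm0$precision) && is.na(pm0$recall) &&
              is.na(pm0$dice) && is.na(pm0$iou))
})

test_that("iou and dice satisfy their algebraic identity on random masks", {
  withr::local_seed(29)
  for (rep in 1:25) {
    pm <- pixel_metrics(pixel_confusion(random_mask(14, 10), random_mask(14, 10)))
    if (!is.na(pm$dice) && !is.na(pm$iou))
      expect_lt(abs(pm$iou - pm$dice / (2 - pm$dice)), 1e-12)
    expect_true(all(unlist(pm) >= 0 & unlist(pm) <= 1, na.rm = TRUE))
  }
})

test_that("region-level confusion follows the any-overlap rule with mixed units", {
  withr::local_seed(37)
  gt <- matrix(0L, 20, 20)
  gt[3:5, 3:5] <- 255L        # region A
  gt[12:14, 12:16] <- 255L    # region B
  pred_eq <- gt
  rc <- region_confusion(pred_eq, gt)
  expect_equal(rc[c("tp_regions", "fn_regions", "fp_regions")],
               list(tp_regions = 2L, fn_regions = 0L, fp_regions = 0L),
               ignore_attr = TRUE)
  expect_equal(rc$precision, 1); expect_equal(rc$recall, 1); expect_equal(rc$dice, 1)

  # one pixel of A detected + one spurious blob: TP 1, FN 1, FP 1
  pred <- matrix(0L, 20, 20)
  pred[3, 3] <- 255L
  pred[18:19, 2:3] <- 255L
  rc2 <- region_confusion(pred, gt)
  expect_equal(unlist(rc2[1:3], use.names = FALSE), c(1L, 1L, 1L))
  expect_equal(rc2$precision, 0.5)
  expect_equal(rc2$recall, 0.5)
  expect_equal(rc2$dice, 0.5)

  # a dilated prediction overlaps every GT region: recall 1
  rc3 <- region_confusion(dilate_mask(gt, 2), gt)
  expect_equal(rc3$recall, 1)

  # one predicted blob spanning both GT regions credits each (mixed units)
  bridge <- matrix(0L, 20, 20)
  bridge[4, 3:13] <- 255L     # through region A ...
  bridge[4:13, 13] <- 255L    # ... and down into region B: one L-shaped blob
  rc4 <- region_confusion(bridge, gt)
  expect_equal(rc4$tp_regions, 2L)
  expect_equal(rc4$fp_regions, 0L)
})

test_that("region recall is monotone under dilation of the prediction", {
  withr::local_seed(41)
  for (rep in 1:5) {
    gt <- dilate_mask(random_mask(24, 24, 0.04), 1)
    pred <- random_mask(24, 24, 0.05)
    r_prev <- -1
    for (it in 0:2) {
      p <- if (it == 0) pred else dilate_mask(pred, it)
      r <- region_confusion(p, gt)$recall
      if (is.na(r)) r <- 0
      expect_gte(r, r_prev)
      r_prev <- r
    }
  }
})

test_that("region counts survive relabeling order and joint translation", {
  withr::local_seed(43)
  gt <- matrix(0L, 16, 16); gt[2:3, 2:3] <- 255L; gt[10:11, 9] <- 255L
  pr <- matrix(0L, 16, 16); pr[2, 2] <- 255L; pr[14, 14] <- 255L
  shift <- function(m, d) {
    out <- matrix(0L, nrow(m), ncol(m))
    out[(1 + d):nrow(m), (1 + d):ncol(m)] <- m[1:(nrow(m) - d), 1:(ncol(m) - d)]
    out
  }
  a <- region_confusion(pr, gt)
  b <- region_confusion(shift(pr, 2), shift(gt, 2))
  expect_identical(a, b)
})

test_that("Bland-Altman reproduces the worked triple and its identities", {
  ba <- bland_altman(c(10, 20, 30), c(12, 19, 33))
  # exact closed form: differences {2, -1, 3}, mean 4/3, sd sqrt(13/3)
  expect_equal(ba$mean_diff, 4 / 3)
  expect_equal(ba$sd_diff, sqrt(13 / 3))
  expect_equal(ba$loa_low, 4 / 3 - 1.96 * sqrt(13 / 3))
  expect_equal(ba$loa_high, 4 / 3 + 1.96 * sqrt(13 / 3))
  # agreement with the 4-decimal reference values, which carry a rounded
  # intermediate sd (2.0817), so allow one unit in the fourth decimal
  expect_equal(round(ba$mean_diff, 4), 1.3333)
  expect_lt(abs(ba$loa_low - (-2.7468)), 2e-4)
  expect_lt(abs(ba$loa_high - 5.4135), 2e-4)

  same <- bland_altman(1:5, 1:5)
  expect_equal(same$mean_diff, 0)
  expect_equal(c(same$loa_low, same$loa_high), c(0, 0))

  withr::local_seed(47)
  g <- rnorm(20, 50, 5); p <- g + rnorm(20)
  b2 <- bland_altman(g, p)
  expect_equal(b2$loa_high - b2$loa_low, 2 * 1.96 * b2$sd_diff)
  b3 <- bland_altman(g, p, sign = "gt_minus_pred")
  expect_equal(b3$mean_diff, -b2$mean_diff)
  expect_equal(nrow(b2$points), 20)

  expect_error(bland_altman(1, 2), "at least 2")
  expect_error(bland_altman(1:3, 1:4), "differ")
})

test_that("mask-set evaluation averages per image with equal weights", {
  withr::local_seed(53)
  gts <- list(random_mask(10, 10, 0.3), random_mask(10, 10, 0.3))
  preds <- list(gts[[1]], random_mask(10, 10, 0.3))
  ev <- evaluate_masks(preds, gts)
  expect_equal(nrow(ev$per_image), 2)
  expect_equal(ev$per_image$accuracy[1], 1)
  a2 <- pixel_metrics(pixel_confusion(preds[[2]], gts[[2]]))$accuracy
  expect_equal(ev$mean[["accuracy"]], mean(c(1, a2)))
})
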