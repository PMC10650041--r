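test_that("soft dice loss matches hand-computed values and limits", {
  # identical prediction and target: numerator equals denominator
  m <- random_mask(6, 6)
  expect_equal(soft_dice_loss(m, m, smooth = 1), 0)
  # 4 pixels at 0.5 against an empty target, smooth 1:
  # 1 - 1 / (4 * 0.25 + 0 + 1) = 0.5
  expect_equal(soft_dice_loss(matrix(0.5, 2, 2), matrix(0, 2, 2), smooth = 1), 0.5)
  # disjoint one-pixel masks, smooth -> 0+: loss -> 1
  expect_equal(soft_dice_loss(c(1, 0), c(0, 1), smooth = 1e-12), 1, tolerance = 1e-9)
  expect_error(soft_dice_loss(matrix(0.5, 2, 2), matrix(0, 3, 2)), "shapes differ")
  expect_error(soft_dice_loss(matrix(1.5, 2, 2), matrix(0, 2, 2)), "\\[0, 1\\]")
})

test_that("soft dice loss stays in [0, 1) and vanishes on perfect predictions", {
  set.seed(61)
  for (trial in 1:20) {
    t <- random_mask(8, 8, runif(1, 0.05, 0.6))
    p <- matrix(runif(64), 8, 8)
    l <- soft_dice_loss(p, t)
    expect_gte(l, 0)
    expect_lt(l, 1)
    expect_equal(soft_dice_loss(t, t), 0)
  }
})

test_that("dsc matches set arithmetic and is symmetric", {
  a <- matrix(0, 3, 3); a[1, 1] <- 1
  b <- matrix(0, 3, 3); b[1, 1] <- 1; b[2, 2] <- 1
  expect_equal(as.numeric(dsc(a, b)), 2 / 3)   # |A∩B|=1, |A|=1, |B|=2
  m <- random_mask(5, 5)
  expect_equal(as.numeric(dsc(m, m)), if (sum(m) > 0) 1 else 1)
  d1 <- matrix(0, 4, 4); d1[1, 1] <- 1
  d2 <- matrix(0, 4, 4); d2[4, 4] <- 1
  expect_equal(as.numeric(dsc(d1, d2)), 0)
  set.seed(62)
  for (trial in 1:10) {
    x <- random_mask(6, 6); y <- random_mask(6, 6)
    expect_equal(as.numeric(dsc(x, y)), as.numeric(dsc(y, x)))
  }
  z <- matrix(0, 3, 3)
  r <- dsc(z, z)
  expect_equal(as.numeric(r), 1)
  expect_true(attr(r, "both_empty"))
  expect_error(dsc(matrix(0, 2, 2), matrix(0, 3, 3)), "shapes differ")
})

test_that("dsc equals 1 - soft_dice_loss for binary masks in the smooth -> 0 limit", {
  set.seed(63)
  for (trial in 1:200) {
    a <- random_mask(7, 7, runif(1, 0.1, 0.7))
    b <- random_mask(7, 7, runif(1, 0.1, 0.7))
    if (sum(a) + sum(b) == 0) next
    expect_equal(as.numeric(dsc(a, b)), 1 - soft_dice_loss(a, b, smooth = 1e-12),
                 tolerance = 1e-8)
  }
})

test_that("hausdorff matches hand values, symmetry, spacing, and brute force", {
  a <- matrix(0, 5, 5); a[1, 1] <- 1
  b <- matrix(0, 5, 5); b[4, 5] <- 1     # offset (3, 4) -> distance 5
  expect_equal(hausdorff(a, b), 5)
  expect_equal(hausdorff(binary_mask(a, c(2, 2)), binary_mask(b, c(2, 2))), 10)
  m <- random_mask(6, 6, 0.4)
  if (sum(m) > 0) expect_equal(hausdorff(m, m), 0)
  expect_true(is.na(hausdorff(matrix(0, 3, 3), a[1:3, 1:3])))
  expect_error(hausdorff(binary_mask(a, c(1, 1)), binary_mask(b, c(1, 2))),
               "spacings")

  set.seed(64)
  for (trial in 1:25) {
    h <- sample(5:20, 1); w <- sample(5:20, 1)
    x <- random_mask(h, w, 0.15); y <- random_mask(h, w, 0.15)
    if (sum(x) == 0 || sum(y) == 0) next
    expect_equal(hausdorff(x, y), hausdorff_bruteforce(x, y))
    expect_equal(hausdorff(x, y), hausdorff(y, x))
  }
  # anisotropic spacing against the oracle
  sp <- c(0.7, 1.9)
  x <- random_mask(12, 9, 0.2); y <- random_mask(12, 9, 0.2)
  if (sum(x) > 0 && sum(y) > 0)
    expect_equal(hausdorff(binary_mask(x, sp), binary_mask(y, sp)),
                 hausdorff_bruteforce(x, y, sp))
})

test_that("binary_mask validates its contents", {
  expect_error(binary_mask(matrix(c(0, 2), 1, 2)), "0 or 1")
  expect_error(binary_mask(matrix(0, 2, 2), spacing = c(1, -1)), "positive")
})

test_that("evaluate_dataset aggregates per-case metrics with the empty-mask policy", {
  set.seed(65)
  gts <- lapply(1:4, function(i) binary_mask(random_mask(8, 8, 0.2)))
  # perfect predictions
  rep0 <- evaluate_dataset(gts, gts)
  expect_equal(rep0$mean_dsc, 1)
  expect_equal(rep0$mean_hd, 0)
  expect_equal(rep0$n_excluded_from_hd, 0)

  # one empty prediction: excluded from HD, counted
  preds <- gts
  preds[[2]] <- binary_mask(matrix(0, 8, 8))
  rep1 <- evaluate_dataset(preds, gts)
  expect_equal(rep1$n_excluded_from_hd, 1)
  expect_true(is.na(rep1$per_case$hd_mm[2]))
  expect_true(rep1$per_case$pred_empty[2])
  # report means recompute from the per-case table
  expect_equal(rep1$mean_dsc, mean(rep1$per_case$dsc))
  expect_equal(rep1$mean_hd, mean(rep1$per_case$hd_mm, na.rm = TRUE))

  expect_error(evaluate_dataset(preds[1:2], gts), "2 predictions vs 4")

  # CSV export appends an aggregate row
  f <- tempfile(fileext = ".csv")
  write_metrics_csv(rep1, f)
  df <- read.csv(f)
  expect_equal(nrow(df), 5)
  expect_equal(df$case_id[5], "aggregate")
  expect_equal(df$dsc[5], rep1$mean_dsc)
})
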