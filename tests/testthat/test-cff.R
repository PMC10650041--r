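test_that("the CFF bank has three modules with the documented wiring", {
  bank <- make_cff_bank()
  expect_length(bank, 3)
  expect_equal(vapply(bank, `[[`, integer(1), "out_channels"), c(cff1 = 64L, cff2 = 128L, cff3 = 256L))
  expect_equal(vapply(bank, `[[`, integer(1), "n_inputs"), c(cff1 = 3L, cff2 = 3L, cff3 = 2L))
  expect_length(bank$cff1$unify, 3)
  expect_length(bank$cff3$unify, 2)
  expect_error(make_cff_bank(c(64, 128)), "4 encoder stage")
})

test_that("cff_forward output matches the shallowest input's shape", {
  set.seed(31)
  bank <- make_cff_bank()
  feats <- list(array(rnorm(16 * 16 * 64), c(16, 16, 64, 1)),
                array(rnorm(8 * 8 * 128), c(8, 8, 128, 1)),
                array(rnorm(4 * 4 * 256), c(4, 4, 256, 1)))
  out <- cff_forward(feats, bank$cff1)
  expect_equal(dim(out), c(16, 16, 64, 1))

  # property: random valid pyramids at other levels/sizes
  for (trial in 1:3) {
    h <- sample(c(8, 12, 16), 1)
    f2 <- list(array(rnorm(h * h * 256), c(h, h, 256, 2)),
               array(rnorm(h * h / 4 * 512), c(h / 2, h / 2, 512, 2)))
    expect_equal(dim(cff_forward(f2, bank$cff3)), c(h, h, 256, 2))
  }
})

test_that("mean kernels on constant inputs give the mean of the constants", {
  # with every convolution set to an averaging kernel (replicate padding makes
  # constants exact fixed points even at borders) and BN configured as the
  # exact identity (init stats, eps = 0, inference mode), the output is the
  # mean of the input constants to machine precision
  set_mean_kernels <- function(mod) {
    mean_fill <- function(layer) {
      d <- dim(layer$w$v)
      layer$w$v <- array(1 / (d[1] * d[2] * d[3]), d)
      if (!is.null(layer$b)) layer$b$v <- array(0, cfanet:::dim_of(layer$b$v))
    }
    for (u in mod$unify) { mean_fill(u$conv); u$bn$eps <- 0 }
    for (b in mod$branches) { mean_fill(b$conv); b$bn$eps <- 0 }
    mean_fill(mod$fuse)
    mod
  }
  bank <- make_cff_bank()
  mod <- set_mean_kernels(bank$cff1)
  # nonnegative constants: the interleaved ReLUs are then transparent
  consts <- list(c(3, 6, 9), c(1, 0, 4), c(2.5, 2.5, 2.5))
  for (cc in consts) {
    feats <- list(array(cc[1], c(8, 8, 64, 1)),
                  array(cc[2], c(4, 4, 128, 1)),
                  array(cc[3], c(2, 2, 256, 1)))
    out <- cff_forward(feats, mod)
    expect_equal(max(abs(out - mean(cc))), 0, tolerance = 1e-12)
  }
  # grouped branches see per-group means, but the final 1x1 restores the
  # global mean; check the 2-input module too
  mod3 <- set_mean_kernels(bank$cff3)
  out3 <- cff_forward(list(array(4, c(4, 4, 256, 1)),
                           array(8, c(2, 2, 512, 1))), mod3)
  expect_equal(max(abs(out3 - 6)), 0, tolerance = 1e-12)
})

test_that("single-input degenerate case is identity-scale", {
  mod <- cfanet:::cff_module(64L)
  x <- array(rnorm(8 * 8 * 64), c(8, 8, 64, 1))
  expect_equal(dim(cff_forward(list(x), mod)), c(8, 8, 64, 1))
})

test_that("cff_forward validates its input cascade", {
  bank <- make_cff_bank()
  good <- list(array(0, c(16, 16, 64, 1)), array(0, c(8, 8, 128, 1)),
               array(0, c(4, 4, 256, 1)))
  bad <- good
  bad[[2]] <- array(0, c(9, 9, 128, 1))
  expect_error(cff_forward(bad, bank$cff1), "exactly 1/2")
  expect_error(cff_forward(list(), bank$cff1), "empty")
  expect_error(cff_forward(good[1:2], bank$cff1), "fuses 3 inputs")
})

test_that("cff_forward is deterministic", {
  set.seed(32)
  bank <- make_cff_bank()
  feats <- list(array(rnorm(8 * 8 * 64), c(8, 8, 64, 1)),
                array(rnorm(4 * 4 * 128), c(4, 4, 128, 1)),
                array(rnorm(2 * 2 * 256), c(2, 2, 256, 1)))
  expect_identical(cff_forward(feats, bank$cff1), cff_forward(feats, bank$cff1))
})
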