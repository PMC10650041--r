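# The reverse-mode engine is validated op by op against central finite
# differences; everything downstream (network training) rests on these.

grad_check <- function(build, value_of, params, tol = 1e-6) {
  # build() runs a taped forward returning list(loss=..., tracked=...)
  r <- cfanet:::with_tape(build())
  cfanet:::backward(r$result$loss, r$tape)
  for (nm in names(params)) {
    p <- params[[nm]]
    gn <- numeric_grad(function(v) value_of(nm, v), p$v)
    expect_lt(max(abs(p$g - gn)), tol, label = paste0("grad[", nm, "] error"))
  }
}

test_that("conv2d gradients match finite differences (plain, strided, grouped)", {
  set.seed(11)
  cases <- list(list(k = 3, stride = 1, pad = 1, g = 1, pm = 0),
                list(k = 3, stride = 2, pad = 1, g = 2, pm = 0),
                list(k = 5, stride = 1, pad = 2, g = 1, pm = 0),
                list(k = 1, stride = 1, pad = 0, g = 2, pm = 0),
                list(k = 3, stride = 1, pad = 1, g = 1, pm = 1),   # replicate pad
                list(k = 5, stride = 1, pad = 2, g = 2, pm = 1))
  for (cs in cases) {
    x <- array(rnorm(6 * 5 * 4 * 2), c(6, 5, 4, 2))
    w <- array(rnorm(cs$k^2 * (4 / cs$g) * 4, sd = 0.5), c(cs$k, cs$k, 4 / cs$g, 4))
    b <- array(rnorm(4), 4)
    out0 <- cfanet:::cpp_conv2d_fwd(x, w, b, cs$stride, cs$pad, cs$g, cs$pm)
    r <- array(rnorm(length(out0)), dim(out0))
    loss <- function(xx, ww, bb)
      sum(cfanet:::cpp_conv2d_fwd(xx, ww, bb, cs$stride, cs$pad, cs$g, cs$pm) * r)
    bw <- cfanet:::cpp_conv2d_bwd(x, w, r, cs$stride, cs$pad, cs$g, cs$pm, TRUE, TRUE)
    expect_lt(max(abs(bw$gx - numeric_grad(function(v) loss(v, w, b), x))), 1e-6)
    expect_lt(max(abs(bw$gw - numeric_grad(function(v) loss(x, v, b), w))), 1e-6)
    expect_lt(max(abs(bw$gb - numeric_grad(function(v) loss(x, w, v), b))), 1e-6)
  }
})

test_that("batch-norm training-mode gradients match finite differences", {
  set.seed(12)
  x <- array(rnorm(4 * 3 * 3 * 2), c(4, 3, 3, 2))
  rmask <- array(rnorm(length(x)), dim(x))
  make_bn <- function(gv, bv) {
    l <- cfanet:::bn_layer(3)
    l$w$v <- array(gv, 3); l$b$v <- array(bv, 3)
    l
  }
  gv <- rnorm(3) + 1; bv <- rnorm(3)
  fwd_val <- function(xx, gg, bb) {
    l <- make_bn(gg, bb)
    r <- cfanet:::with_tape(cfanet:::fwd_bn(l, cfanet:::as_tensor(xx), TRUE))
    sum(r$result$v * rmask)
  }
  l <- make_bn(gv, bv)
  xt <- cfanet:::new_param(x)
  r <- cfanet:::with_tape({
    y <- cfanet:::fwd_bn(l, xt, TRUE)
    cfanet:::node(array(sum(y$v * rmask), c(1, 1, 1, 1)), list(y),
                  function(g) list(array(as.numeric(g)[1] * rmask, dim(rmask))))
  })
  cfanet:::backward(r$result, r$tape)
  expect_lt(max(abs(xt$g - numeric_grad(function(v) fwd_val(v, gv, bv), x))), 1e-5)
  expect_lt(max(abs(l$w$g - numeric_grad(function(v) fwd_val(x, v, bv), array(gv, 3)))), 1e-5)
  expect_lt(max(abs(l$b$g - numeric_grad(function(v) fwd_val(x, gv, v), array(bv, 3)))), 1e-5)
})

test_that("pooling and reduction ops agree with loop oracles and differentiate", {
  set.seed(13)
  x <- array(rnorm(2 * 3 * 4 * 4), c(2, 3, 4, 4))
  xt <- cfanet:::new_param(x)
  expect_equal(cfanet:::op_gavgpool(xt)$v, global_pool_oracle(x, mean))
  expect_equal(cfanet:::op_gmaxpool(xt)$v, global_pool_oracle(x, max))
  expect_equal(cfanet:::op_channel_mean(xt)$v, channel_pool_oracle(x, mean))
  expect_equal(cfanet:::op_channel_max(xt)$v, channel_pool_oracle(x, max))

  for (op in list(cfanet:::op_gavgpool, cfanet:::op_gmaxpool,
                  cfanet:::op_channel_mean, cfanet:::op_channel_max,
                  function(t) cfanet:::op_bilinear(t, 4L, 6L),
                  cfanet:::op_maxpool3x3s2,
                  cfanet:::op_relu, cfanet:::op_sigmoid)) {
    xt <- cfanet:::new_param(x)
    r <- cfanet:::with_tape({
      y <- op(xt)
      rmask <- array(seq_len(length(y$v)) %% 5 - 2, dim(y$v))
      cfanet:::node(array(sum(y$v * rmask), c(1, 1, 1, 1)), list(y),
                    function(g) list(array(as.numeric(g)[1] * rmask, dim(rmask))))
    })
    cfanet:::backward(r$result, r$tape)
    f <- function(v) {
      y <- op(cfanet:::as_tensor(v))$v
      rmask <- array(seq_len(length(y)) %% 5 - 2, dim(y))
      sum(y * rmask)
    }
    expect_lt(max(abs(xt$g - numeric_grad(f, x))), 1e-5)
  }
})

test_that("broadcast scaling ops differentiate correctly", {
  set.seed(14)
  x <- array(rnorm(3 * 4 * 5 * 2), c(3, 4, 5, 2))
  wch <- array(runif(5 * 2), c(1, 1, 5, 2))
  map <- array(runif(3 * 4 * 2), c(3, 4, 1, 2))
  for (cs in list(list(other = wch, op = cfanet:::op_scale_channels),
                  list(other = map, op = cfanet:::op_scale_spatial))) {
    xt <- cfanet:::new_param(x)
    ot <- cfanet:::new_param(cs$other)
    r <- cfanet:::with_tape({
      y <- cs$op(xt, ot)
      cfanet:::node(array(sum(y$v), c(1, 1, 1, 1)), list(y),
                    function(g) list(array(as.numeric(g)[1], dim(y$v))))
    })
    cfanet:::backward(r$result, r$tape)
    expect_lt(max(abs(xt$g - numeric_grad(function(v)
      sum(cs$op(cfanet:::as_tensor(v), cfanet:::as_tensor(cs$other))$v), x))), 1e-5)
    expect_lt(max(abs(ot$g - numeric_grad(function(v)
      sum(cs$op(cfanet:::as_tensor(x), cfanet:::as_tensor(v))$v), cs$other))), 1e-5)
  }
})

test_that("soft dice loss node gradient matches finite differences", {
  set.seed(15)
  p <- array(runif(4 * 4 * 1 * 3), c(4, 4, 1, 3))
  y <- array(rbinom(4 * 4 * 3, 1, 0.2), c(4, 4, 1, 3))
  pt <- cfanet:::new_param(p)
  r <- cfanet:::with_tape(cfanet:::op_soft_dice_loss(pt, y, smooth = 1))
  cfanet:::backward(r$result, r$tape)
  gn <- numeric_grad(function(v)
    as.numeric(cfanet:::op_soft_dice_loss(cfanet:::as_tensor(v), y, 1)$v), p)
  expect_lt(max(abs(pt$g - gn)), 1e-6)
})

test_that("gradients accumulate when a tensor feeds two consumers", {
  x <- cfanet:::new_param(array(1:8 / 8, c(2, 2, 2, 1)))
  r <- cfanet:::with_tape({
    y <- cfanet:::op_add(x, x)  # dy/dx = 2
    cfanet:::node(array(sum(y$v), c(1, 1, 1, 1)), list(y),
                  function(g) list(array(as.numeric(g)[1], dim(y$v))))
  })
  cfanet:::backward(r$result, r$tape)
  expect_equal(x$g, array(2, dim(x$v)))
})
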