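test_that("count_parameters equals an independent architecture enumeration", {
  expect_equal(count_parameters(network_config()), expected_param_count())
  expect_equal(count_parameters(network_config(use_cff = FALSE)),
               expected_param_count(use_cff = FALSE))
  expect_equal(count_parameters(network_config(use_ecsa = FALSE)),
               expected_param_count(use_ecsa = FALSE))
  expect_equal(count_parameters(network_config(use_cff = FALSE, use_ecsa = FALSE)),
               expected_param_count(use_cff = FALSE, use_ecsa = FALSE))
  expect_equal(count_parameters(network_config(cff_branch_groups = 1L)),
               expected_param_count(groups = 1))
  expect_equal(count_parameters(network_config(num_classes = 3L)),
               expected_param_count(num_classes = 3))
})

test_that("ablation toggles strictly decrease the parameter count", {
  full <- count_parameters(network_config())
  no_cff <- count_parameters(network_config(use_cff = FALSE))
  no_ecsa <- count_parameters(network_config(use_ecsa = FALSE))
  base <- count_parameters(network_config(use_cff = FALSE, use_ecsa = FALSE))
  expect_lt(no_cff, full)
  expect_lt(no_ecsa, full)
  expect_lt(base, no_cff)
  expect_lt(base, no_ecsa)
  expect_length(unique(c(full, no_cff, no_ecsa, base)), 4)
})

test_that("decoder_block follows conv -> upsample -> sum-skip", {
  set.seed(51)
  net <- cfanet(network_config())
  x <- array(rnorm(8 * 8 * 512), c(8, 8, 512, 1))
  skip <- array(rnorm(16 * 16 * 256), c(16, 16, 256, 1))
  out <- decoder_block(x, skip, net$decoder$block1)
  expect_equal(dim(out), c(16, 16, 256, 1))
  # the sum is elementwise: shifting the skip shifts the output identically
  out2 <- decoder_block(x, skip + 1, net$decoder$block1)
  expect_equal(out2, out + 1)
  # skip-free path is a pure upsample after the conv
  out3 <- decoder_block(array(rnorm(16 * 16 * 64), c(16, 16, 64, 1)),
                        params = net$decoder$block4)
  expect_equal(dim(out3), c(32, 32, 64, 1))
  expect_error(decoder_block(x, array(0, c(8, 8, 256, 1)), net$decoder$block1),
               "skip shape")
})

test_that("forward pass preserves spatial dims and honors num_classes", {
  set.seed(52)
  net <- cfanet(network_config())
  for (hw in list(c(32, 32), c(64, 32))) {
    x <- array(rnorm(prod(hw) * 3), c(hw, 3, 1))
    expect_equal(dim(cfanet_forward(x, net)), c(hw, 1, 1))
  }
  net3 <- cfanet(network_config(num_classes = 3L))
  x <- array(rnorm(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  expect_equal(dim(cfanet_forward(x, net3)), c(32, 32, 3, 2))
  expect_error(cfanet_forward(array(0, c(50, 64, 3, 1)), net), "height 50")
})

test_that("forward is deterministic in inference mode", {
  set.seed(53)
  net <- cfanet(network_config())
  x <- array(rnorm(64 * 64 * 3), c(64, 64, 3, 1))
  expect_identical(cfanet_forward(x, net), cfanet_forward(x, net))
})

test_that("ablations change the graph: baseline output is CFF/ECSA independent", {
  set.seed(54)
  cfg_base <- network_config(use_cff = FALSE, use_ecsa = FALSE)
  net <- cfanet(cfg_base)
  expect_null(net$cff)
  expect_null(net$ecsa)
  x <- array(rnorm(32 * 32 * 3), c(32, 32, 3, 1))
  expect_equal(dim(cfanet_forward(x, net)), c(32, 32, 1, 1))
})

test_that("every trainable parameter receives a gradient (no dead subgraph)", {
  set.seed(55)
  net <- cfanet(network_config())
  params <- cfanet:::collect_params(net[c("encoder", "ecsa", "cff", "decoder", "head")])
  x <- array(rnorm(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  y <- array(0, c(64, 64, 1, 2))
  y[20:24, 30:34, 1, 1] <- 1
  y[40:42, 10:12, 1, 2] <- 1
  r <- cfanet:::with_tape({
    logits <- cfanet:::cfanet_forward_tensors(net, cfanet:::as_tensor(x), training = TRUE)
    cfanet:::op_soft_dice_loss(cfanet:::op_sigmoid(logits), y, 1)
  })
  cfanet:::backward(r$result, r$tape)
  missing <- vapply(params, function(p) is.null(p$g), logical(1))
  expect_false(any(missing))
  nonzero <- vapply(params, function(p) any(p$g != 0), logical(1))
  expect_true(all(nonzero))
})
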