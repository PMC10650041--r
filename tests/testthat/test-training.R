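test_that("lr_schedule is the exponential decay closed form", {
  tc <- train_config()
  expect_equal(lr_schedule(0, tc), 0.01)
  expect_equal(lr_schedule(1, tc), 0.0095)
  eps <- 0:150
  expect_equal(lr_schedule(eps, tc), 0.01 * 0.95^eps)
  expect_true(all(diff(lr_schedule(eps, tc)) < 0))
  expect_error(lr_schedule(-1, tc), ">= 0")
})

test_that("train_config validates its invariants", {
  expect_error(train_config(base_lr = 0), "base_lr")
  expect_error(train_config(decline_rate = 1.2), "decline_rate")
  expect_error(train_config(batch_size = 0), "batch_size")
  expect_error(train_config(epochs = 0), "epochs")
})

test_that("kfold_split is a deterministic partition with balanced sizes", {
  f <- kfold_split(10, 5, seed = 1)
  expect_length(f, 5)
  expect_true(all(lengths(f) == 2))
  expect_setequal(unlist(f), 1:10)

  f11 <- kfold_split(11, 5, seed = 1)
  expect_setequal(sort(lengths(f11)), c(2, 2, 2, 2, 3))

  expect_identical(kfold_split(23, 4, seed = 9), kfold_split(23, 4, seed = 9))

  set.seed(91)
  for (trial in 1:10) {
    n <- sample(5:40, 1)
    k <- sample(2:min(n, 6), 1)
    fs <- kfold_split(n, k, seed = trial)
    expect_setequal(unlist(fs), seq_len(n))
    expect_equal(sum(lengths(fs)), n)           # disjoint by pigeonhole
    expect_lte(diff(range(lengths(fs))), 1)
  }
  expect_error(kfold_split(3, 5), "exceeds")
  expect_error(kfold_split(10, 1), ">= 2")
})

test_that("one training epoch logs one row and the checkpoint round-trips", {
  data <- tiny_dataset(4)
  tc <- train_config(epochs = 1L, batch_size = 4L, seed = 3L)
  ck <- train(tc, network_config(), data)
  expect_s3_class(ck, "cfanet_checkpoint")
  expect_equal(nrow(ck$log), 1)
  expect_equal(ck$log$epoch, 0)
  expect_equal(ck$log$lr, 0.01)
  expect_true(is.finite(ck$log$loss))

  f <- tempfile(fileext = ".rds")
  save_checkpoint(ck, f)
  ck2 <- load_checkpoint(f)
  imgs <- lapply(data, `[[`, "image")
  expect_identical(predict(ck, imgs), predict(ck2, imgs))
  expect_error(load_checkpoint(tempfile()), "not found")
  expect_error(train(tc, network_config(), list()), "empty")
})

test_that("training is deterministic under a fixed seed", {
  data <- tiny_dataset(4)
  tc <- train_config(epochs = 2L, batch_size = 2L, seed = 11L)
  ck1 <- train(tc, network_config(use_cff = FALSE, use_ecsa = FALSE), data)
  ck2 <- train(tc, network_config(use_cff = FALSE, use_ecsa = FALSE), data)
  expect_identical(ck1$log$loss, ck2$log$loss)
  expect_identical(ck1$state, ck2$state)
})

test_that("all four ablation variants train without error and count distinctly", {
  data <- tiny_dataset(2)
  tc <- train_config(epochs = 1L, batch_size = 2L, seed = 5L)
  counts <- integer(0)
  for (cfg in list(network_config(use_cff = FALSE, use_ecsa = FALSE),
                   network_config(use_cff = TRUE, use_ecsa = FALSE),
                   network_config(use_cff = FALSE, use_ecsa = TRUE),
                   network_config())) {
    ck <- train(tc, cfg, data)
    expect_true(is.finite(ck$log$loss))
    counts <- c(counts, count_parameters(cfg))
  }
  expect_length(unique(counts), 4)
})

test_that("predict applies the >= threshold convention in logit space", {
  data <- tiny_dataset(2)
  ck <- train(train_config(epochs = 1L, batch_size = 2L, seed = 13L),
              network_config(use_cff = FALSE, use_ecsa = FALSE), data)
  imgs <- lapply(data, `[[`, "image")
  # a logit of exactly 0 has probability 0.5 and maps to foreground:
  # force it by zeroing the head
  ck0 <- ck
  ck0$state[["head.weight"]][] <- 0
  ck0$state[["head.bias"]][] <- 0
  pred0 <- predict(ck0, imgs[[1]], threshold = 0.5)
  expect_true(all(pred0[[1]]$values == 1))
  # threshold 1 gives an empty mask for any finite logits
  pred1 <- predict(ck0, imgs[[1]], threshold = 1)
  expect_true(all(pred1[[1]]$values == 0))
  # shapes preserved
  expect_equal(dim(pred0[[1]]$values), dim(imgs[[1]]))
})

test_that("resize_pair: bilinear image, strictly binary nearest-neighbour mask", {
  sp <- generate_sample(scene_config(image_size = 64L, seed = 15L))
  half <- resize_pair(sp, 32L)
  expect_equal(dim(half$image), c(32, 32))
  expect_equal(dim(half$mask), c(32, 32))
  expect_true(all(half$mask %in% c(0, 1)))
  expect_equal(half$spacing, c(2, 2))
  expect_identical(resize_pair(sp, 64L), sp)
  expect_error(resize_pair(sp, 48L), "multiple of 32")
})

test_that("cross-validation runs per fold and aggregates", {
  data <- tiny_dataset(6)
  tc <- train_config(epochs = 1L, batch_size = 3L, folds = 3L, seed = 17L)
  cv <- crossval(tc, network_config(use_cff = FALSE, use_ecsa = FALSE), data)
  expect_length(cv$fold_reports, 3)
  expect_equal(sum(vapply(cv$fold_reports, function(r) nrow(r$per_case), numeric(1))), 6)
  expect_true(cv$mean_dsc >= 0 && cv$mean_dsc <= 1)
})
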