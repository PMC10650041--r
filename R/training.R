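#' Training configuration
#'
#' The optimizer recipe: Adam with weight decay 1e-5, base learning rate 0.01
#' decayed exponentially by a factor 0.95 per epoch, batch size 8, 150
#' epochs, soft dice loss on sigmoid outputs.
#'
#' @param base_lr base learning rate, in (0, 1].
#' @param decline_rate per-epoch multiplicative decay, in (0, 1].
#' @param batch_size mini-batch size (>= 1).
#' @param epochs number of passes over the training set (>= 1).
#' @param weight_decay Adam L2 weight decay.
#' @param seed integer seed for initialization and shuffling.
#' @param folds number of cross-validation folds.
#' @param smooth soft-dice smoothing constant.
#' @return object of class `train_config`.
#' @export
train_config <- function(base_lr = 0.01, decline_rate = 0.95, batch_size = 8L,
                         epochs = 150L, weight_decay = 1e-5, seed = 42L,
                         folds = 5L, smooth = 1) {
  if (base_lr <= 0 || base_lr > 1) stop("base_lr must lie in (0, 1]")
  if (decline_rate <= 0 || decline_rate > 1) stop("decline_rate must lie in (0, 1]")
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(base_lr = base_lr, decline_rate = decline_rate,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 weight_decay = weight_decay, seed = as.integer(seed),
                 folds = as.integer(folds), smooth = smooth),
            class = "train_config")
}

#' Exponentially decayed learning rate
#'
#' `lr = base_lr * decline_rate ^ epoch` with a 0-based epoch index, so epoch
#' 0 trains at the base learning rate.
#'
#' @param epoch integer >= 0.
#' @param config a [train_config()].
#' @return the learning rate.
#' @export
lr_schedule <- function(epoch, config = train_config()) {
  if (any(epoch < 0)) stop("epoch must be >= 0")
  config$base_lr * config$decline_rate^epoch
}

#' Deterministic k-fold partition
#'
#' @param n_items number of items (>= k).
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return list of `k` disjoint 1-based index vectors whose union is
#'   `1:n_items`; fold sizes differ by at most 1.
#' @export
kfold_split <- function(n_items, k, seed = 1L) {
  if (k < 2) stop("kfold_split: k must be >= 2")
  if (k > n_items) stop("kfold_split: k (", k, ") exceeds n_items (", n_items, ")")
  perm <- with_seed(seed, sample.int(n_items))
  unname(split(perm, rep_len(seq_len(k), n_items)))
}

# stack a list of sample pairs into image (H,W,C,N) and mask (H,W,1,N) arrays,
# replicating grayscale images to the channel count the stem expects
stack_batch <- function(data, input_channels = 3L) {
  d1 <- dim(as.matrix(data[[1]]$image))
  n <- length(data)
  x <- array(0, c(d1[1], d1[2], input_channels, n))
  y <- array(0, c(d1[1], d1[2], 1L, n))
  for (i in seq_len(n)) {
    img <- data[[i]]$image
    if (is.matrix(img)) {
      for (c in seq_len(input_channels)) x[, , c, i] <- img
    } else {
      if (dim(img)[3] != input_channels)
        stop("sample ", i, " has ", dim(img)[3], " channels; expected ",
             input_channels)
      x[, , , i] <- img
    }
    y[, , 1L, i] <- mask_values(data[[i]]$mask)
  }
  list(x = x, y = y)
}

#' Train the network
#'
#' Runs the full recipe: Adam (weight decay from the config), per-epoch
#' learning rate from [lr_schedule()], soft dice loss on sigmoid outputs.
#' Logs loss, learning rate and training DSC (predictions thresholded at 0.5)
#' per epoch.  A non-finite loss aborts with a diagnostic.
#'
#' @param config a [train_config()].
#' @param net_config a [network_config()].
#' @param data non-empty list of `sample_pair`s with identical dimensions,
#'   divisible by 32 (see [resize_pair()]).
#' @param verbose print a line per epoch.
#' @return object of class `cfanet_checkpoint`: flat `$state` mapping,
#'   `$network_config`, `$train_config`, `$final_epoch` and `$log`
#'   (data.frame epoch/lr/loss/train_dsc).
#' @export
train <- function(config, net_config, data, verbose = FALSE) {
  if (length(data) == 0) stop("train: empty data")
  d <- dim(as.matrix(data[[1]]$image))
  check_div32(d[1], d[2])
  batches <- stack_batch(data, net_config$input_channels)
  n <- length(data)

  model <- with_seed(config$seed, cfanet(net_config))
  params <- collect_params(model[c("encoder", "ecsa", "cff", "decoder", "head")])
  opt <- adam_new(params, weight_decay = config$weight_decay)

  log_rows <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs) - 1L) {
    lr <- lr_schedule(epoch, config)
    ord <- with_seed(config$seed + 7919L * (epoch + 1L), sample.int(n))
    epoch_loss <- 0
    dsc_sum <- 0
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      xb <- batches$x[, , , idx, drop = FALSE]
      yb <- batches$y[, , , idx, drop = FALSE]
      r <- with_tape({
        logits <- cfanet_forward_tensors(model, as_tensor(xb), training = TRUE)
        p <- op_sigmoid(logits)
        list(p = p, loss = op_soft_dice_loss(p, yb, smooth = config$smooth))
      })
      loss_val <- as.numeric(r$result$loss$v)
      if (!is.finite(loss_val))
        stop("train: non-finite loss at epoch ", epoch, " (lr = ", lr,
             "); try a lower base_lr")
      backward(r$result$loss, r$tape)
      adam_step(opt, lr)
      zero_grads(params)
      epoch_loss <- epoch_loss + loss_val * length(idx)
      pred <- r$result$p$v >= 0.5
      for (j in seq_along(idx))
        dsc_sum <- dsc_sum + as.numeric(dsc(pred[, , 1, j] * 1, yb[, , 1, j]))
    }
    log_rows[[epoch + 1L]] <- data.frame(epoch = epoch, lr = lr,
                                         loss = epoch_loss / n,
                                         train_dsc = dsc_sum / n)
    if (verbose)
      message(sprintf("epoch %3d  lr %.5f  loss %.4f  train DSC %.4f",
                      epoch, lr, epoch_loss / n, dsc_sum / n))
  }
  structure(list(state = collect_state(model[c("encoder", "ecsa", "cff",
                                               "decoder", "head")]),
                 network_config = net_config,
                 train_config = config,
                 final_epoch = config$epochs - 1L,
                 log = do.call(rbind, log_rows)),
            class = "cfanet_checkpoint")
}

#' Rebuild a network from a checkpoint
#'
#' @param checkpoint a `cfanet_checkpoint` (or a path to one saved with
#'   [save_checkpoint()]).
#' @return a `cfanet` model with the stored weights.
#' @export
restore_model <- function(checkpoint) {
  if (is.character(checkpoint)) checkpoint <- load_checkpoint(checkpoint)
  if (!inherits(checkpoint, "cfanet_checkpoint"))
    stop("restore_model: not a cfanet checkpoint")
  model <- cfanet(checkpoint$network_config)
  assign_state(model[c("encoder", "ecsa", "cff", "decoder", "head")],
               checkpoint$state, strict = TRUE)
  model
}

#' @rdname restore_model
#' @param path file path for the serialized checkpoint (.rds).
#' @export
save_checkpoint <- function(checkpoint, path) {
  if (!inherits(checkpoint, "cfanet_checkpoint"))
    stop("save_checkpoint: not a cfanet checkpoint")
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname restore_model
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("load_checkpoint: file not found: ", path)
  ck <- readRDS(path)
  if (!inherits(ck, "cfanet_checkpoint"))
    stop("load_checkpoint: ", path, " does not contain a cfanet checkpoint")
  ck
}

#' Predict binary masks
#'
#' Applies the network in inference mode and thresholds
#' `sigmoid(logits) >= threshold`.  Note the `>=` convention: a logit of
#' exactly 0 (probability 0.5) maps to foreground at the default threshold.
#'
#' @param object a `cfanet_checkpoint`.
#' @param images list of image matrices/arrays (or a single one); dimensions
#'   must be multiples of 32.
#' @param threshold probability cutoff in \[0, 1\].
#' @param batch_size images per forward pass.
#' @param ... unused.
#' @return list of [binary_mask()] objects matching the input dimensions.
#' @export
predict.cfanet_checkpoint <- function(object, images, threshold = 0.5,
                                      batch_size = 8L, ...) {
  model <- restore_model(object)
  if (!is.list(images)) images <- list(images)
  data <- lapply(images, function(im) list(image = im, mask = matrix(0, nrow(as.matrix(im)), ncol(as.matrix(im)))))
  d <- dim(as.matrix(images[[1]]))
  check_div32(d[1], d[2])
  out <- vector("list", length(images))
  for (start in seq(1L, length(images), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(images))
    xb <- stack_batch(data[idx], object$network_config$input_channels)$x
    logits <- cfanet_forward_tensors(model, as_tensor(xb), training = FALSE)$v
    # threshold in logit space: prob >= threshold <=> logits >= qlogis(threshold),
    # exact even where the sigmoid saturates in double precision
    cut <- stats::qlogis(threshold)
    for (j in seq_along(idx))
      out[[idx[j]]] <- binary_mask(1 * (logits[, , 1, j] >= cut))
  }
  out
}

#' Resize an image/mask pair
#'
#' The image is resized bilinearly (half-pixel convention); the mask with
#' nearest-neighbour sampling so it stays strictly binary.
#'
#' @param sample a `sample_pair` (list with `image`, `mask`, `spacing`).
#' @param target_size scalar or `c(H, W)`, each a positive multiple of 32.
#' @return the resized `sample_pair`; `spacing` is rescaled accordingly.
#' @export
resize_pair <- function(sample, target_size) {
  ts <- rep(as.integer(target_size), length.out = 2L)
  check_div32(ts[1], ts[2])
  img <- sample$image
  d <- dim(as.matrix(img))
  if (identical(as.integer(d), ts) ) return(sample)
  if (is.matrix(img)) {
    x <- array(img, c(d, 1L, 1L))
  } else x <- array(img, c(dim(img), 1L))
  ri <- cpp_bilinear_fwd(x, ts[1], ts[2])
  image_out <- if (is.matrix(img)) matrix(ri, ts[1], ts[2]) else
    array(ri, c(ts[1], ts[2], dim(img)[3]))
  mv <- mask_values(sample$mask)
  # nearest neighbour with the same half-pixel mapping as the bilinear path
  src_idx <- function(n_out, n_in) pmin(pmax(round((seq_len(n_out) - 0.5) *
                                                     n_in / n_out + 0.5), 1L), n_in)
  mask_out <- mv[src_idx(ts[1], d[1]), src_idx(ts[2], d[2])]
  sp <- sample$spacing
  if (is.null(sp)) sp <- c(1, 1)
  structure(list(image = image_out, mask = mask_out,
                 spacing = sp * d / ts),
            class = "sample_pair")
}

#' k-fold cross-validation
#'
#' Trains one model per fold on the complementary folds and evaluates on the
#' held-out fold with [evaluate_dataset()].
#'
#' @param config a [train_config()] (`folds` sets k).
#' @param net_config a [network_config()].
#' @param data list of `sample_pair`s.
#' @param verbose passed to [train()].
#' @return list with `fold_reports` (one `metrics_report` per fold),
#'   `mean_dsc` and `mean_hd` across folds.
#' @export
crossval <- function(config, net_config, data, verbose = FALSE) {
  folds <- kfold_split(length(data), config$folds, config$seed)
  reports <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    hold <- folds[[f]]
    ck <- train(config, net_config, data[-hold], verbose = verbose)
    preds <- predict(ck, lapply(data[hold], `[[`, "image"))
    gts <- lapply(data[hold], function(s) binary_mask(mask_values(s$mask)))
    reports[[f]] <- evaluate_dataset(preds, gts,
                                     case_ids = sprintf("fold%d_case%03d", f, hold))
  }
  hds <- vapply(reports, function(r) r$mean_hd, numeric(1))
  list(fold_reports = reports,
       mean_dsc = mean(vapply(reports, function(r) r$mean_dsc, numeric(1))),
       mean_hd = if (all(is.na(hds))) NA_real_ else mean(hds, na.rm = TRUE))
}
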