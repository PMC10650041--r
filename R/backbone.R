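#' ResNet34-style encoder
#'
#' Feature extractor used on the contracting path: the standard 34-layer
#' residual network with the classification head (global average pool and
#' fully connected layer) removed.  [encode()] exposes one feature map per
#' stage so the skip connections and the attention bottleneck can consume the
#' whole pyramid.
#'
#' Layer naming in checkpoints follows the conventional ResNet34 scheme
#' (`conv1`, `bn1`, `layer1.0.conv1`, ..., `layer4.2.bn2`), so externally
#' produced weight dumps can be loaded with [load_pretrained_weights()].
#'
#' @param input_channels number of image channels expected by the stem
#'   (grayscale inputs are replicated to 3 channels upstream).
#' @return an encoder module (opaque list of layers).
#' @keywords internal
#' @noRd
resnet34_encoder <- function(input_channels = 3L) {
  basic_block <- function(in_ch, out_ch, stride) {
    blk <- list(
      conv1 = conv_layer(in_ch, out_ch, 3L, stride = stride, bias = FALSE),
      bn1 = bn_layer(out_ch),
      conv2 = conv_layer(out_ch, out_ch, 3L, bias = FALSE),
      bn2 = bn_layer(out_ch)
    )
    if (stride != 1L || in_ch != out_ch) {
      blk$downsample <- list(
        "0" = conv_layer(in_ch, out_ch, 1L, stride = stride, pad = 0L, bias = FALSE),
        "1" = bn_layer(out_ch)
      )
    }
    blk
  }
  stage <- function(in_ch, out_ch, n_blocks, stride) {
    blocks <- vector("list", n_blocks)
    for (i in seq_len(n_blocks))
      blocks[[i]] <- basic_block(if (i == 1) in_ch else out_ch, out_ch,
                                 if (i == 1) stride else 1L)
    names(blocks) <- as.character(seq_len(n_blocks) - 1L)
    blocks
  }
  list(
    conv1 = conv_layer(input_channels, 64L, 7L, stride = 2L, pad = 3L, bias = FALSE),
    bn1 = bn_layer(64L),
    layer1 = stage(64L, 64L, 3L, 1L),
    layer2 = stage(64L, 128L, 4L, 2L),
    layer3 = stage(128L, 256L, 6L, 2L),
    layer4 = stage(256L, 512L, 3L, 2L)
  )
}

fwd_basic_block <- function(blk, x, training) {
  out <- fwd_bn(blk$bn1, fwd_conv(blk$conv1, x), training)
  out <- op_relu(out)
  out <- fwd_bn(blk$bn2, fwd_conv(blk$conv2, out), training)
  identity <- if (!is.null(blk$downsample)) {
    fwd_bn(blk$downsample[["1"]], fwd_conv(blk$downsample[["0"]], x), training)
  } else x
  op_relu(op_add(out, identity))
}

fwd_stage <- function(stage, x, training) {
  for (blk in stage) x <- fwd_basic_block(blk, x, training)
  x
}

#' @noRd
check_div32 <- function(h, w) {
  if (h %% 32 != 0 || h < 32)
    stop("input height ", h, " must be a positive multiple of 32")
  if (w %% 32 != 0 || w < 32)
    stop("input width ", w, " must be a positive multiple of 32")
  invisible(NULL)
}

#' Run the encoder and return the feature pyramid
#'
#' @param encoder an encoder module built by the network constructor.
#' @param x input tensor (or array) with dim `c(H, W, 3, N)`, `H` and `W`
#'   positive multiples of 32.
#' @param training logical; batch-norm mode.
#' @return a list `s0`..`s4` of feature tensors with channel counts
#'   (64, 64, 128, 256, 512) at strides (2, 4, 8, 16, 32).
#' @keywords internal
#' @noRd
encode_tensors <- function(encoder, x, training = FALSE) {
  d <- dim(x$v)
  check_div32(d[1], d[2])
  if (d[3] != dim(encoder$conv1$w$v)[3])
    stop("encoder expects ", dim(encoder$conv1$w$v)[3], " input channels, got ", d[3])
  s0 <- op_relu(fwd_bn(encoder$bn1, fwd_conv(encoder$conv1, x), training))
  s1 <- fwd_stage(encoder$layer1, op_maxpool3x3s2(s0), training)
  s2 <- fwd_stage(encoder$layer2, s1, training)
  s3 <- fwd_stage(encoder$layer3, s2, training)
  s4 <- fwd_stage(encoder$layer4, s3, training)
  list(s0 = s0, s1 = s1, s2 = s2, s3 = s3, s4 = s4)
}

#' Encode an image batch into the multi-resolution feature pyramid
#'
#' Applies the ResNet34-style backbone of a network to an image batch and
#' returns the five stage outputs as plain arrays.  Stage `s_i` has spatial
#' dimensions exactly `input / stride_i` with strides (2, 4, 8, 16, 32) and
#' channel counts (64, 64, 128, 256, 512).
#'
#' @param model a network built with [cfanet()].
#' @param image array with dim `c(H, W, C, N)` (a single `c(H, W, C)` image is
#'   promoted to a batch of one); `H`, `W` positive multiples of 32.
#' @return named list of arrays `s0`..`s4`.
#' @examples
#' net <- cfanet(network_config())
#' pyr <- encode(net, array(0, c(64, 64, 3, 1)))
#' vapply(pyr, function(s) dim(s)[1], numeric(1))  # 32 16 8 4 2
#' @export
encode <- function(model, image) {
  if (length(dim(image)) == 3L) dim(image) <- c(dim(image), 1L)
  pyr <- encode_tensors(model$encoder, as_tensor(image), training = FALSE)
  lapply(pyr, function(t) t$v)
}

#' Load backbone weights from a flat checkpoint
#'
#' Replaces the encoder parameters of `model` with tensors taken from a flat
#' name-to-array mapping using standard ResNet34 layer names.  Entries for the
#' removed classification head (`fc.*`, `avgpool*`) are skipped and counted; a
#' shape mismatch on any retained layer is an error naming the layer.  Weight
#' arrays may be stored either in this package's native layout
#' `(KH, KW, Cin, Cout)` or in the common `(Cout, Cin, KH, KW)` convention,
#' which is transposed on load.
#'
#' @param model a network built with [cfanet()].
#' @param weights_source path to an `.rds` file containing a named list, or
#'   the named list itself.
#' @return `model`, invisibly, with updated encoder weights.
#' @export
load_pretrained_weights <- function(model, weights_source) {
  state <- if (is.character(weights_source)) {
    if (!file.exists(weights_source))
      stop("weights file not found: ", weights_source)
    readRDS(weights_source)
  } else weights_source
  if (!is.list(state) || is.null(names(state)))
    stop("weights_source must be (a path to) a named list of arrays")

  skipped <- grep("^(fc|avgpool)", names(state), value = TRUE)
  kept <- setdiff(names(state), skipped)
  # drop torch-style bookkeeping entries that have no analogue here
  kept <- kept[!grepl("num_batches_tracked$", kept)]

  wanted <- collect_state(model$encoder)
  for (nm in kept) {
    if (!nm %in% names(wanted)) {
      skipped <- c(skipped, nm)
      next
    }
    val <- state[[nm]]
    target_dim <- dim_of(wanted[[nm]])
    vd <- dim_of(val)
    if (length(vd) == 4L && length(target_dim) == 4L &&
        !identical(as.integer(vd), as.integer(target_dim)) &&
        identical(as.integer(vd), as.integer(target_dim[c(4, 3, 1, 2)]))) {
      val <- aperm(val, c(3, 4, 2, 1))  # (Cout,Cin,KH,KW) -> (KH,KW,Cin,Cout)
      vd <- dim(val)
    }
    if (length(val) != length(wanted[[nm]]) ||
        (length(vd) == 4L && !identical(as.integer(vd), as.integer(target_dim))))
      stop("shape mismatch on retained layer '", nm, "': checkpoint ",
           paste(vd, collapse = "x"), " vs model ",
           paste(target_dim, collapse = "x"))
    state[[nm]] <- val
  }
  kept <- setdiff(kept, skipped)
  missing <- setdiff(names(wanted), kept)
  if (length(missing) > 0)
    stop("checkpoint does not cover retained encoder layers (wrong depth?); ",
         "first missing: '", missing[1], "' (", length(missing), " total)")
  assign_state(model$encoder, state[kept], strict = FALSE)
  message("loaded ", length(setdiff(kept, skipped)), " tensors; skipped ",
          length(skipped), " head/unmatched entries")
  invisible(model)
}
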