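#' Network configuration
#'
#' All architecture hyperparameters and the two ablation toggles.  The
#' parameter count of the assembled network is a pure function of this
#' configuration.
#'
#' @param num_classes number of output logit channels (1 = binary).
#' @param use_cff if `FALSE`, skip connections carry raw encoder features
#'   (the "Baseline + ECSA" / "Baseline" ablations).
#' @param use_ecsa if `FALSE`, the bottleneck attention block is replaced by
#'   the identity.
#' @param ecsa_reduction channel-bottleneck reduction ratio of ECSA.
#' @param decoder_channels output channels of the five decoder blocks; the
#'   first three must equal the CFF output widths (256, 128, 64) because the
#'   skip combination is an elementwise sum.
#' @param cff_branch_groups group count of the CFF multi-scale convolutions
#'   (2 reproduces the published ~30 M parameter budget; 1 gives dense
#'   branches, ~33 M).
#' @param pretrained if `TRUE`, the caller is expected to load backbone
#'   weights with [load_pretrained_weights()]; initialization is always
#'   Kaiming-style random so nothing is downloaded.
#' @param input_channels image channels fed to the stem (grayscale inputs are
#'   replicated to 3 upstream by the training pipeline).
#' @return object of class `cfanet_config`.
#' @export
network_config <- function(num_classes = 1L,
                           use_cff = TRUE,
                           use_ecsa = TRUE,
                           ecsa_reduction = 16L,
                           decoder_channels = c(256L, 128L, 64L, 64L, 32L),
                           cff_branch_groups = 2L,
                           pretrained = FALSE,
                           input_channels = 3L) {
  if (length(decoder_channels) != 5L)
    stop("decoder_channels must list 5 block widths (one per x2 upsampling step)")
  cfg <- list(num_classes = as.integer(num_classes),
              use_cff = isTRUE(use_cff),
              use_ecsa = isTRUE(use_ecsa),
              ecsa_reduction = as.integer(ecsa_reduction),
              decoder_channels = as.integer(decoder_channels),
              cff_branch_groups = as.integer(cff_branch_groups),
              pretrained = isTRUE(pretrained),
              input_channels = as.integer(input_channels))
  class(cfg) <- "cfanet_config"
  cfg
}

ENCODER_CHANNELS <- c(64L, 128L, 256L, 512L)  # s1..s4

#' Build the segmentation network
#'
#' Assembles the encoder-decoder: ResNet34-style backbone, optional ECSA
#' bottleneck, optional bank of three CFF skip modules, five decoder blocks
#' (3x3 conv + BN + ReLU, bilinear x2 upsampling, elementwise sum with the
#' skip where one exists) and a final 1x1 convolution producing logits.
#'
#' @param config a [network_config()].
#' @return object of class `cfanet` (module tree plus `$config`).
#' @examples
#' net <- cfanet(network_config())
#' round(count_parameters(net) / 1e6)  # 30
#' @export
cfanet <- function(config = network_config()) {
  dc <- config$decoder_channels
  if (config$use_cff && !identical(dc[1:3], ENCODER_CHANNELS[3:1]))
    stop("with CFF enabled the first three decoder widths must be (256, 128, 64) ",
         "so the sum-skips align with the CFF output channels")
  skip_in <- c(512L, dc[1:4])  # input channels of decoder blocks 1..5
  decoder <- list()
  for (i in 1:5) decoder[[paste0("block", i)]] <- cbr_block(skip_in[i], dc[i], 3L)
  model <- list(
    encoder = resnet34_encoder(config$input_channels),
    ecsa = if (config$use_ecsa) ecsa_module(512L, config$ecsa_reduction) else NULL,
    cff = if (config$use_cff) make_cff_bank(ENCODER_CHANNELS, config$cff_branch_groups) else NULL,
    decoder = decoder,
    head = conv_layer(dc[5], config$num_classes, 1L, pad = 0L, bias = TRUE)
  )
  # prior-bias initialization: start near "all background" so the dice
  # gradient concentrates on the rare foreground from the first step
  model$head$b$v[] <- stats::qlogis(0.01)
  model$config <- config
  class(model) <- "cfanet"
  model
}

#' One decoder block
#'
#' 3x3 convolution (`in_ch -> out_ch`, BN + ReLU), bilinear x2 upsampling,
#' then an elementwise sum with the skip feature map when one is supplied.
#' Exposed mainly for inspection and testing; [cfanet_forward()] wires the
#' blocks together.
#'
#' @param x array `c(H, W, in_ch, N)`.
#' @param skip optional array; must match the post-upsample shape exactly.
#' @param params one `$decoder$blockN` entry of a [cfanet()] model.
#' @return array `c(2H, 2W, out_ch, N)`.
#' @export
decoder_block <- function(x, skip = NULL, params) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  out <- decoder_block_tensors(params, as_tensor(x),
                               if (is.null(skip)) NULL else {
                                 if (length(dim(skip)) == 3L) dim(skip) <- c(dim(skip), 1L)
                                 as_tensor(skip)
                               })
  out$v
}

decoder_block_tensors <- function(blk, x, skip = NULL, training = FALSE) {
  d <- dim(x$v)
  out <- op_bilinear(fwd_cbr(blk, x, training), 2L * d[1], 2L * d[2])
  if (!is.null(skip)) {
    ds <- dim(skip$v)
    do <- dim(out$v)
    if (!identical(as.integer(ds), as.integer(do)))
      stop("decoder skip shape ", paste(ds, collapse = "x"),
           " does not match upsampled shape ", paste(do, collapse = "x"))
    out <- op_add(out, skip)
  }
  out
}

cfanet_forward_tensors <- function(model, x, training = FALSE) {
  cfg <- model$config
  pyr <- encode_tensors(model$encoder, x, training)
  bottom <- if (cfg$use_ecsa) ecsa_forward_tensors(model$ecsa, pyr$s4, training) else pyr$s4
  skips <- if (cfg$use_cff) {
    list(
      cff_forward_tensors(model$cff$cff3, list(pyr$s3, pyr$s4), training),
      cff_forward_tensors(model$cff$cff2, list(pyr$s2, pyr$s3, pyr$s4), training),
      cff_forward_tensors(model$cff$cff1, list(pyr$s1, pyr$s2, pyr$s3), training)
    )
  } else list(pyr$s3, pyr$s2, pyr$s1)
  h <- decoder_block_tensors(model$decoder$block1, bottom, skips[[1]], training)
  h <- decoder_block_tensors(model$decoder$block2, h, skips[[2]], training)
  h <- decoder_block_tensors(model$decoder$block3, h, skips[[3]], training)
  h <- decoder_block_tensors(model$decoder$block4, h, NULL, training)
  h <- decoder_block_tensors(model$decoder$block5, h, NULL, training)
  fwd_conv(model$head, h)
}

#' Full forward pass
#'
#' Runs the assembled network on an image batch and returns raw logits (no
#' activation); output spatial dimensions equal the input's.
#'
#' @param image array with dim `c(H, W, C, N)` (or a single `c(H, W, C)`
#'   image); `H`, `W` positive multiples of 32.
#' @param model a [cfanet()] network (alternatively a `cfanet_config`, from
#'   which a freshly initialized network is built).
#' @return logits array with dim `c(H, W, num_classes, N)`.
#' @export
cfanet_forward <- function(image, model) {
  if (inherits(model, "cfanet_config")) model <- cfanet(model)
  if (length(dim(image)) == 3L) dim(image) <- c(dim(image), 1L)
  cfanet_forward_tensors(model, as_tensor(image), training = FALSE)$v
}

#' Count trainable parameters
#'
#' Sums the element counts of every trainable tensor (convolution weights and
#' biases, batch-norm scale and shift; running statistics are buffers and are
#' not counted).
#'
#' @param x a `cfanet` model or a `cfanet_config` (a network is then built
#'   just for counting).
#' @return integer-valued total; the millions figure is `round(total / 1e6)`.
#' @export
count_parameters <- function(x) {
  if (inherits(x, "cfanet_config")) x <- cfanet(x)
  if (!inherits(x, "cfanet")) stop("count_parameters expects a cfanet or cfanet_config")
  n_params(x[c("encoder", "ecsa", "cff", "decoder", "head")])
}

#' @export
print.cfanet <- function(x, ...) {
  cfg <- x$config
  n <- count_parameters(x)
  cat("CFANet segmentation network\n")
  cat("  encoder: ResNet34-style, stages (64, 64, 128, 256, 512)\n")
  cat("  ECSA bottleneck:", if (cfg$use_ecsa) sprintf("on (r = %d)", cfg$ecsa_reduction) else "off", "\n")
  cat("  CFF skips:", if (cfg$use_cff) sprintf("3 modules (branch groups = %d)", cfg$cff_branch_groups) else "off", "\n")
  cat("  decoder widths:", paste(cfg$decoder_channels, collapse = " -> "), "\n")
  cat(sprintf("  trainable parameters: %s (%.2f M)\n", format(n, big.mark = ","), n / 1e6))
  invisible(x)
}

#' @export
print.cfanet_config <- function(x, ...) {
  cat("cfanet network configuration\n")
  for (nm in names(x)) cat(" ", nm, "=", paste(x[[nm]], collapse = ","), "\n")
  invisible(x)
}
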