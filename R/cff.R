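#' Context Feature Fusion (CFF)
#'
#' A CFF module replaces a plain skip connection.  It fuses the feature map of
#' the current encoder stage with the feature maps of the deeper stages:
#' every input is first passed through a 3x3 convolution that unifies its
#' channel count to that of the shallowest input (`C_t`), deeper inputs are
#' bilinearly upsampled to the shallowest resolution, and everything is
#' concatenated (`C1`).  Multi-scale context is then extracted from `C1` by
#' three parallel convolutions with kernel sizes 1, 3 and 5; their outputs are
#' concatenated and projected back to `C_t` by a final (linear) 1x1
#' convolution.
#'
#' The three multi-scale convolutions are grouped convolutions
#' (`branch_groups`, default 2), following the split-and-conv design of the
#' pyramid-split attention family of blocks from which this stage is derived;
#' the grouping keeps the parameter budget of the assembled network at its
#' published size.  Every convolution except the final projection is followed
#' by batch normalization and ReLU.
#'
#' @param in_channels integer vector of input channel counts, shallowest
#'   first (length 2 or 3).
#' @param branch_groups group count for the 1/3/5 multi-scale convolutions.
#' @return a CFF module whose output channel count equals `in_channels[1]`.
#' @keywords internal
#' @noRd
cff_module <- function(in_channels, branch_groups = 2L) {
  n <- length(in_channels)
  if (n < 1L) stop("CFF needs at least one input")
  if (n > 3L) stop("CFF fuses at most 3 stages")
  ct <- in_channels[1]
  unify <- lapply(in_channels, function(ci) cbr_block(ci, ct, 3L, pad_mode = "replicate"))
  names(unify) <- paste0("unify", seq_len(n) - 1L)
  c1 <- n * ct
  branches <- lapply(c(1L, 3L, 5L), function(k)
    cbr_block(c1, ct, k, groups = branch_groups, pad_mode = "replicate"))
  names(branches) <- c("scale1", "scale3", "scale5")
  list(unify = unify, branches = branches,
       fuse = conv_layer(3L * ct, ct, 1L, pad = 0L, bias = TRUE),
       n_inputs = n, out_channels = ct)
}

cff_forward_tensors <- function(mod, features, training = FALSE) {
  n <- length(features)
  if (n == 0L) stop("cff_forward: empty feature list")
  if (n != mod$n_inputs)
    stop("cff_forward: module fuses ", mod$n_inputs, " inputs, got ", n)
  d1 <- dim(features[[1]]$v)
  for (i in seq_len(n)[-1]) {
    di <- dim(features[[i]]$v)
    if (di[1] * 2^(i - 1) != d1[1] || di[2] * 2^(i - 1) != d1[2])
      stop("cff_forward: input ", i, " is ", di[1], "x", di[2],
           " but must be exactly 1/", 2^(i - 1), " of the shallowest input (",
           d1[1], "x", d1[2], ")")
  }
  unified <- vector("list", n)
  for (i in seq_len(n)) {
    u <- fwd_cbr(mod$unify[[i]], features[[i]], training)
    if (i > 1L) u <- op_bilinear(u, d1[1], d1[2])
    unified[[i]] <- u
  }
  c1 <- if (n == 1L) unified[[1]] else op_concat_c(unified)
  ms <- lapply(mod$branches, function(b) fwd_cbr(b, c1, training))
  fwd_conv(mod$fuse, op_concat_c(ms))
}

#' Apply a Context Feature Fusion module
#'
#' Runs a single CFF module (see [make_cff_bank()]) on an ordered list of
#' encoder feature maps, shallowest first; each deeper input must have exactly
#' half the spatial size of its predecessor.  The output has the spatial size
#' and channel count of the shallowest input.
#'
#' @param features list of arrays with dim `c(H, W, C, N)`, shallowest first.
#' @param params a CFF module created by [make_cff_bank()] (one bank entry).
#' @return an array with the shape of `features[[1]]` except for channels,
#'   which equal the module's `out_channels`.
#' @export
cff_forward <- function(features, params) {
  if (length(features) == 0L) stop("cff_forward: empty feature list")
  features <- lapply(features, function(f) {
    if (length(dim(f)) == 3L) dim(f) <- c(dim(f), 1L)
    as_tensor(f)
  })
  cff_forward_tensors(params, features, training = FALSE)$v
}

#' Build the bank of three CFF skip modules
#'
#' The network keeps exactly three CFF modules, one per skip level:
#' level 1 fuses encoder stages (s1, s2, s3), level 2 fuses (s2, s3, s4) and
#' level 3 — the deepest skip, where only one deeper stage exists — fuses
#' (s3, s4).  Output channel counts are therefore
#' `(encoder_channels[1:3])`.
#'
#' @param encoder_channels channel counts of encoder stages s1..s4
#'   (default `c(64, 128, 256, 512)`).
#' @param branch_groups group count of the multi-scale convolutions.
#' @return list of 3 CFF modules.
#' @export
make_cff_bank <- function(encoder_channels = c(64L, 128L, 256L, 512L),
                          branch_groups = 2L) {
  if (length(encoder_channels) != 4L)
    stop("make_cff_bank: need the 4 encoder stage channel counts (s1..s4)")
  list(
    cff1 = cff_module(encoder_channels[1:3], branch_groups),
    cff2 = cff_module(encoder_channels[2:4], branch_groups),
    cff3 = cff_module(encoder_channels[3:4], branch_groups)
  )
}
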