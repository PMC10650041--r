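#' Effective Channel Spatial Attention (ECSA)
#'
#' Attention block applied to the deepest encoder feature map.  Channel
#' attention first: global max- and average-pooled channel vectors are pushed
#' through a shared two-layer 1x1-convolution bottleneck (reduction ratio
#' `r`), the two branch outputs are summed and squashed by a sigmoid, and the
#' resulting per-channel weights rescale the input.  Spatial attention next:
#' per-location channel-wise max and mean maps are concatenated and passed
#' through a 7x7 convolution and a sigmoid, giving a single-channel map that
#' rescales the channel-attended features.  The block output adds the original
#' input back (residual), so attention modulates rather than replaces the
#' bottleneck features.
#'
#' @param n_ch input channel count.
#' @param reduction bottleneck reduction ratio `r`; must divide `n_ch`.
#' @return an ECSA module.
#' @keywords internal
#' @noRd
ecsa_module <- function(n_ch, reduction = 16L) {
  if (n_ch %% reduction != 0)
    stop("ECSA: channels (", n_ch, ") not divisible by reduction ratio (",
         reduction, ")")
  list(
    fc1 = conv_layer(n_ch, n_ch %/% reduction, 1L, pad = 0L, bias = FALSE),
    fc2 = conv_layer(n_ch %/% reduction, n_ch, 1L, pad = 0L, bias = FALSE),
    spatial = conv_layer(2L, 1L, 7L, pad = 3L, bias = TRUE),
    n_ch = n_ch, reduction = as.integer(reduction)
  )
}

ecsa_channel_tensors <- function(mod, x, training = FALSE) {
  mlp <- function(p) fwd_conv(mod$fc2, op_relu(fwd_conv(mod$fc1, p)))
  logits <- op_add(mlp(op_gmaxpool(x)), mlp(op_gavgpool(x)))
  weights <- op_sigmoid(logits)
  list(weights = weights, a_channel = op_scale_channels(x, weights))
}

ecsa_spatial_tensors <- function(mod, a_channel, training = FALSE) {
  pooled <- op_concat_c(list(op_channel_max(a_channel), op_channel_mean(a_channel)))
  map <- op_sigmoid(fwd_conv(mod$spatial, pooled))
  list(map = map, a_spatial = op_scale_spatial(a_channel, map))
}

ecsa_forward_tensors <- function(mod, x, training = FALSE) {
  ch <- ecsa_channel_tensors(mod, x, training)
  sp <- ecsa_spatial_tensors(mod, ch$a_channel, training)
  op_add(x, sp$a_spatial)
}

#' Channel attention half of ECSA
#'
#' @param x array with dim `c(H, W, C, N)` (3-D input promoted to batch 1).
#' @param params an ECSA module (see [cfanet()]'s `$ecsa` component).
#' @return list with `weights` (dim `c(1, 1, C, N)`, entries strictly in
#'   (0, 1)) and `a_channel` (`weights` broadcast-multiplied with `x`).
#' @export
channel_attention <- function(x, params) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  r <- ecsa_channel_tensors(params, as_tensor(x))
  list(weights = r$weights$v, a_channel = r$a_channel$v)
}

#' Spatial attention half of ECSA
#'
#' @param a_channel array with dim `c(H, W, C, N)`, normally the output of
#'   [channel_attention()].
#' @param params an ECSA module.
#' @return list with `map` (dim `c(H, W, 1, N)`, entries strictly in (0, 1))
#'   and `a_spatial` (`map` broadcast-multiplied with `a_channel`).
#' @export
spatial_attention <- function(a_channel, params) {
  if (length(dim(a_channel)) == 3L) dim(a_channel) <- c(dim(a_channel), 1L)
  r <- ecsa_spatial_tensors(params, as_tensor(a_channel))
  list(map = r$map$v, a_spatial = r$a_spatial$v)
}

#' Full ECSA block: channel attention, spatial attention, residual addition
#'
#' Computes `x + map * (weights * x)`; with all attention parameters zeroed
#' both sigmoids output exactly 0.5, so the block reduces to `1.25 * x`.
#'
#' @param x array with dim `c(H, W, C, N)`.
#' @param params an ECSA module.
#' @return array with the shape of `x`.
#' @export
ecsa_forward <- function(x, params) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  ecsa_forward_tensors(params, as_tensor(x))$v
}
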