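# Layer objects.  Each layer is an environment (so running statistics can be
# updated in place) carrying parameter tensors; composite modules are named
# lists of layers.  The helpers at the bottom walk a module tree to collect
# parameters or a flat name -> array state mapping.

conv_layer <- function(in_ch, out_ch, kernel, stride = 1L, pad = NULL,
                       groups = 1L, bias = TRUE, pad_mode = c("zero", "replicate")) {
  pad_mode <- match.arg(pad_mode)
  if (in_ch %% groups != 0 || out_ch %% groups != 0)
    stop("conv_layer: channels (", in_ch, " -> ", out_ch,
         ") not divisible by groups = ", groups)
  if (is.null(pad)) pad <- (kernel - 1L) %/% 2L
  l <- new.env(parent = emptyenv())
  l$kind <- "conv"
  l$stride <- as.integer(stride)
  l$pad <- as.integer(pad)
  l$groups <- as.integer(groups)
  l$pad_mode <- if (identical(pad_mode, "replicate")) 1L else 0L
  # Kaiming-normal (fan_out, ReLU gain) initialization
  fan_out <- kernel * kernel * out_ch
  l$w <- new_param(array(stats::rnorm(kernel * kernel * (in_ch %/% groups) * out_ch,
                                      sd = sqrt(2 / fan_out)),
                         c(kernel, kernel, in_ch %/% groups, out_ch)))
  l$b <- if (bias) new_param(array(0, out_ch)) else NULL
  class(l) <- "cfa_layer"
  l
}

bn_layer <- function(n_ch, eps = 1e-5, momentum = 0.1) {
  l <- new.env(parent = emptyenv())
  l$kind <- "bn"
  l$eps <- eps
  l$momentum <- momentum
  l$w <- new_param(array(1, n_ch))
  l$b <- new_param(array(0, n_ch))
  l$running_mean <- rep(0, n_ch)
  l$running_var <- rep(1, n_ch)
  class(l) <- "cfa_layer"
  l
}

fwd_conv <- function(l, x) op_conv2d(x, l$w, l$b, l$stride, l$pad, l$groups, l$pad_mode)
fwd_bn <- function(l, x, training) op_batchnorm(x, l$w, l$b, l, training)

# conv -> BN -> ReLU, the standard block used throughout the decoder and CFF
cbr_block <- function(in_ch, out_ch, kernel, stride = 1L, groups = 1L,
                      pad_mode = "zero") {
  list(conv = conv_layer(in_ch, out_ch, kernel, stride, groups = groups,
                         bias = FALSE, pad_mode = pad_mode),
       bn = bn_layer(out_ch))
}

fwd_cbr <- function(blk, x, training) {
  op_relu(fwd_bn(blk$bn, fwd_conv(blk$conv, x), training))
}

# ---- module tree walkers ----------------------------------------------------

#' @noRd
collect_params <- function(m) {
  if (inherits(m, "cfa_layer")) {
    ps <- list(m$w)
    if (!is.null(m$b)) ps <- c(ps, list(m$b))
    return(ps)
  }
  if (is.list(m)) return(do.call(c, c(lapply(m, collect_params), list(list()))))
  list()
}

#' @noRd
collect_state <- function(m, prefix = "") {
  join <- function(a, b) if (nzchar(a)) paste0(a, ".", b) else b
  if (inherits(m, "cfa_layer")) {
    out <- list()
    # `* 1` forces a copy: the optimizer updates parameter arrays in place,
    # and a checkpoint must not alias live weights
    out[[join(prefix, "weight")]] <- m$w$v * 1
    if (!is.null(m$b)) out[[join(prefix, "bias")]] <- m$b$v * 1
    if (identical(m$kind, "bn")) {
      out[[join(prefix, "running_mean")]] <- m$running_mean
      out[[join(prefix, "running_var")]] <- m$running_var
    }
    return(out)
  }
  if (is.list(m)) {
    nms <- names(m)
    out <- list()
    for (i in seq_along(m)) {
      if (is.null(m[[i]])) next
      out <- c(out, collect_state(m[[i]], join(prefix, nms[i])))
    }
    return(out)
  }
  list()
}

#' @noRd
assign_state <- function(m, state, prefix = "", strict = TRUE) {
  join <- function(a, b) if (nzchar(a)) paste0(a, ".", b) else b
  if (inherits(m, "cfa_layer")) {
    take <- function(field, slot) {
      nm <- join(prefix, field)
      if (!nm %in% names(state)) {
        if (strict) stop("checkpoint is missing entry '", nm, "'")
        return(invisible(NULL))
      }
      val <- state[[nm]]
      cur <- if (identical(slot, "running_mean")) m$running_mean
             else if (identical(slot, "running_var")) m$running_var
             else m[[slot]]$v
      if (!identical(as.integer(dim_of(cur)), as.integer(dim_of(val))) &&
          length(cur) != length(val))
        stop("shape mismatch for layer '", nm, "': checkpoint ",
             paste(dim_of(val), collapse = "x"), " vs model ",
             paste(dim_of(cur), collapse = "x"))
      val <- array(as.numeric(val), dim_of(cur))
      if (identical(slot, "running_mean")) m$running_mean <- as.numeric(val)
      else if (identical(slot, "running_var")) m$running_var <- as.numeric(val)
      else m[[slot]]$v <- val
      invisible(NULL)
    }
    take("weight", "w")
    if (!is.null(m$b)) take("bias", "b")
    if (identical(m$kind, "bn")) {
      take("running_mean", "running_mean")
      take("running_var", "running_var")
    }
    return(invisible(NULL))
  }
  if (is.list(m)) {
    nms <- names(m)
    for (i in seq_along(m)) {
      if (is.null(m[[i]])) next
      assign_state(m[[i]], state, join(prefix, nms[i]), strict)
    }
  }
  invisible(NULL)
}

#' @noRd
n_params <- function(m) {
  sum(vapply(collect_params(m), function(p) length(p$v), numeric(1)))
}

zero_grads <- function(params) {
  for (p in params) p$g <- NULL
  invisible(NULL)
}

# ---- Adam -------------------------------------------------------------------

adam_new <- function(params, weight_decay = 1e-5, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  for (p in params) {
    p$m <- numeric(length(p$v))
    p$vv <- numeric(length(p$v))
  }
  env <- new.env(parent = emptyenv())
  env$params <- params
  env$weight_decay <- weight_decay
  env$beta1 <- beta1
  env$beta2 <- beta2
  env$eps <- eps
  env$t <- 0L
  env
}

adam_step <- function(opt, lr) {
  opt$t <- opt$t + 1L
  for (p in opt$params) {
    if (is.null(p$g)) next
    cpp_adam_step(p$v, p$g, p$m, p$vv, lr, opt$beta1, opt$beta2,
                  opt$eps, opt$weight_decay, opt$t)
  }
  invisible(NULL)
}
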