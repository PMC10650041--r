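# Minimal reverse-mode automatic differentiation over 4-D feature maps.
#
# A tensor is an environment holding $v (the value, an array with
# dim = c(H, W, C, N)), $g (the accumulated gradient or NULL), and — while a
# tape is active and the node depends on a parameter — $parents and $bk, a
# closure mapping the node's output gradient to a list of parent gradients.
# Node creation order is a valid topological order of the (dynamic) graph, so
# backward() is a single reverse sweep over the tape.
#
# Parameters are tensors with $param = TRUE; their $g persists across the
# sweep so an optimizer can consume it.

.cfa <- new.env(parent = emptyenv())
.cfa$tape <- NULL

#' @noRd
new_tensor <- function(v) {
  t <- new.env(parent = emptyenv())
  t$v <- v
  t$g <- NULL
  t$req <- FALSE
  t$param <- FALSE
  class(t) <- "cfa_tensor"
  t
}

#' Create a trainable parameter tensor
#' @noRd
new_param <- function(v) {
  t <- new_tensor(v)
  t$req <- TRUE
  t$param <- TRUE
  class(t) <- c("cfa_param", "cfa_tensor")
  t
}

as_tensor <- function(x) {
  if (inherits(x, "cfa_tensor")) x else new_tensor(x)
}

# Record an op result. `parents` is a list of tensors (or NULLs); `bk(g)` must
# return a list of gradients aligned with `parents` (NULL entries allowed).
node <- function(v, parents, bk) {
  t <- new_tensor(v)
  tape <- .cfa$tape
  if (!is.null(tape)) {
    req <- any(vapply(parents, function(p) !is.null(p) && p$req, logical(1)))
    if (req) {
      t$req <- TRUE
      t$parents <- parents
      t$bk <- bk
      tape$n <- tape$n + 1L
      tape$nodes[[tape$n]] <- t
    }
  }
  t
}

with_tape <- function(expr) {
  old <- .cfa$tape
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 512L)
  tape$n <- 0L
  .cfa$tape <- tape
  on.exit(.cfa$tape <- old)
  res <- force(expr)
  list(result = res, tape = tape)
}

# Reverse sweep: seeds `loss` with gradient 1 and propagates along the tape.
backward <- function(loss, tape) {
  if (is.null(loss$g)) loss$g <- array(1, dim = dim_of(loss$v))
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$g)) next
    gs <- nd$bk(nd$g)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (is.null(p) || !p$req || is.null(gs[[j]])) next
      p$g <- if (is.null(p$g)) gs[[j]] else p$g + gs[[j]]
    }
    if (!nd$param) nd$g <- NULL
    # release the subgraph so activation memory can be reclaimed early
    nd$parents <- NULL
    nd$bk <- NULL
  }
  invisible(NULL)
}

dim_of <- function(v) {
  d <- dim(v)
  if (is.null(d)) length(v) else d
}

# ---- primitive ops ----------------------------------------------------------

op_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L, groups = 1L,
                      pad_mode = 0L) {
  bv <- if (is.null(b)) NULL else as.numeric(b$v)
  v <- cpp_conv2d_fwd(x$v, w$v, bv, stride, pad, groups, pad_mode)
  need_x <- x$req
  node(v, list(x, w, b), function(g) {
    r <- cpp_conv2d_bwd(x$v, w$v, g, stride, pad, groups, pad_mode, need_x, !is.null(b))
    gb <- r$gb
    if (!is.null(gb) && !is.null(b)) dim(gb) <- dim_of(b$v)
    list(r$gx, r$gw, gb)
  })
}

op_relu <- function(x) {
  node(cpp_relu_fwd(x$v), list(x), function(g) list(cpp_relu_bwd(g, x$v)))
}

op_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$v))
  node(s, list(x), function(g) list(g * s * (1 - s)))
}

op_add <- function(x, y) {
  stopifnot(identical(dim_of(x$v), dim_of(y$v)))
  node(x$v + y$v, list(x, y), function(g) list(g, g))
}

# Batch normalization over (H, W, N) per channel.  `layer` carries running
# stats, updated by side effect in training mode.
op_batchnorm <- function(x, gamma, beta, layer, training) {
  d <- dim(x$v)
  m <- d[1] * d[2] * d[4]
  r <- cpp_bn_fwd(x$v, as.numeric(gamma$v), as.numeric(beta$v),
                  layer$running_mean, layer$running_var, layer$eps, training)
  if (training) {
    ub <- if (m > 1) r$var * m / (m - 1) else r$var  # running stats: unbiased
    layer$running_mean <- (1 - layer$momentum) * layer$running_mean + layer$momentum * r$mean
    layer$running_var <- (1 - layer$momentum) * layer$running_var + layer$momentum * ub
  }
  node(r$y, list(x, gamma, beta), function(g) {
    b <- cpp_bn_bwd(g, r$xhat, r$invstd, as.numeric(gamma$v), training)
    dgamma <- b$dgamma
    dbeta <- b$dbeta
    dim(dgamma) <- dim_of(gamma$v)
    dim(dbeta) <- dim_of(beta$v)
    list(b$gx, dgamma, dbeta)
  })
}

op_maxpool3x3s2 <- function(x) {
  d <- dim(x$v)
  r <- cpp_maxpool3x3s2_fwd(x$v)
  node(r$out, list(x), function(g) list(cpp_maxpool3x3s2_bwd(g, r$idx, d[1], d[2])))
}

op_bilinear <- function(x, h_out, w_out) {
  d <- dim(x$v)
  v <- cpp_bilinear_fwd(x$v, as.integer(h_out), as.integer(w_out))
  node(v, list(x), function(g) list(cpp_bilinear_bwd(g, d[1], d[2])))
}

# concatenate along the channel dimension
op_concat_c <- function(xs) {
  ds <- lapply(xs, function(x) dim(x$v))
  H <- ds[[1]][1]; W <- ds[[1]][2]; N <- ds[[1]][4]
  cs <- vapply(ds, `[`, integer(1), 3L)
  v <- array(0, c(H, W, sum(cs), N))
  off <- 0L
  for (i in seq_along(xs)) {
    v[, , off + seq_len(cs[i]), ] <- xs[[i]]$v
    off <- off + cs[i]
  }
  node(v, xs, function(g) {
    out <- vector("list", length(xs))
    off <- 0L
    for (i in seq_along(xs)) {
      out[[i]] <- g[, , off + seq_len(cs[i]), , drop = FALSE]
      off <- off + cs[i]
    }
    out
  })
}

# global average pool -> (1, 1, C, N)
op_gavgpool <- function(x) {
  d <- dim(x$v)
  HW <- d[1] * d[2]
  xm <- matrix(x$v, nrow = HW)
  v <- array(.colMeans(xm, HW, d[3] * d[4]), c(1, 1, d[3], d[4]))
  node(v, list(x), function(g) {
    gx <- array(rep(as.numeric(g) / HW, each = HW), d)
    list(gx)
  })
}

# global max pool -> (1, 1, C, N)
op_gmaxpool <- function(x) {
  d <- dim(x$v)
  HW <- d[1] * d[2]
  xm <- matrix(x$v, nrow = HW)
  idx <- max.col(t(xm), ties.method = "first")
  v <- array(xm[cbind(idx, seq_along(idx))], c(1, 1, d[3], d[4]))
  node(v, list(x), function(g) {
    gm <- matrix(0, HW, d[3] * d[4])
    gm[cbind(idx, seq_along(idx))] <- as.numeric(g)
    list(array(gm, d))
  })
}

# per-location mean over channels -> (H, W, 1, N)
op_channel_mean <- function(x) {
  d <- dim(x$v)
  C <- d[3]
  xm <- matrix(aperm(x$v, c(1, 2, 4, 3)), ncol = C)  # (H*W*N) x C
  v <- array(aperm(array(.rowMeans(xm, nrow(xm), C), c(d[1], d[2], d[4], 1)),
                   c(1, 2, 4, 3)), c(d[1], d[2], 1, d[4]))
  node(v, list(x), function(g) {
    gv <- as.numeric(aperm(g, c(1, 2, 4, 3))) / C
    gm <- matrix(gv, nrow = d[1] * d[2] * d[4], ncol = C)
    list(aperm(array(gm, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3)))
  })
}

# per-location max over channels -> (H, W, 1, N)
op_channel_max <- function(x) {
  d <- dim(x$v)
  C <- d[3]
  xm <- matrix(aperm(x$v, c(1, 2, 4, 3)), ncol = C)
  idx <- max.col(xm, ties.method = "first")
  vals <- xm[cbind(seq_along(idx), idx)]
  v <- array(aperm(array(vals, c(d[1], d[2], d[4], 1)), c(1, 2, 4, 3)),
             c(d[1], d[2], 1, d[4]))
  node(v, list(x), function(g) {
    gv <- as.numeric(aperm(g, c(1, 2, 4, 3)))
    gm <- matrix(0, nrow = length(gv), ncol = C)
    gm[cbind(seq_along(idx), idx)] <- gv
    list(aperm(array(gm, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3)))
  })
}

# x (H,W,C,N) scaled per channel by w (1,1,C,N)
op_scale_channels <- function(x, w) {
  d <- dim(x$v)
  HW <- d[1] * d[2]
  wexp <- rep(as.numeric(w$v), each = HW)
  node(array(x$v * wexp, d), list(x, w), function(g) {
    gx <- array(g * wexp, d)
    gw <- array(.colSums(matrix(g * x$v, nrow = HW), HW, d[3] * d[4]),
                c(1, 1, d[3], d[4]))
    list(gx, gw)
  })
}

# x (H,W,C,N) scaled per location by map (H,W,1,N)
op_scale_spatial <- function(x, map) {
  d <- dim(x$v)
  C <- d[3]
  m3 <- array(map$v, c(d[1], d[2], d[4]))
  mexp <- aperm(array(rep(as.numeric(m3), C), c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  node(array(x$v * mexp, d), list(x, map), function(g) {
    gx <- array(g * mexp, d)
    gm_full <- aperm(g * x$v, c(1, 2, 4, 3))
    gmap <- array(.rowSums(matrix(gm_full, nrow = d[1] * d[2] * d[4]),
                           d[1] * d[2] * d[4], C),
                  c(d[1], d[2], 1, d[4]))
    list(gx, gmap)
  })
}

# Soft dice loss as a single differentiable node.  `p` holds probabilities in
# [0,1] with dim (H, W, K, N); `target` is a plain array of the same dim.
op_soft_dice_loss <- function(p, target, smooth = 1) {
  d <- dim(p$v)
  N <- d[4]
  per <- prod(d[1:3])
  pm <- matrix(p$v, nrow = per)
  tm <- matrix(target, nrow = per)
  inter <- .colSums(pm * tm, per, N)
  denom <- .colSums(pm * pm, per, N) + .colSums(tm * tm, per, N) + smooth
  num <- 2 * inter + smooth
  loss <- mean(1 - num / denom)
  node(array(loss, c(1, 1, 1, 1)), list(p), function(g) {
    gs <- as.numeric(g)[1] / N
    # d/dp of -(2*sum(pt)+s)/D + (num/D^2) * 2p
    gp <- sweep(-2 * tm, 2, denom, "/") +
      sweep(2 * pm, 2, num / denom^2, "*")
    list(array(gp * gs, d))
  })
}
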