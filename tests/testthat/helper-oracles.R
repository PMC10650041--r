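# Independent oracles used across the suite.  These deliberately use naive
# loop-based computation so they share no code path with the implementation.

# central finite differences of a scalar-valued function
numeric_grad <- function(f, x, eps = 1e-6) {
  g <- array(0, dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# O(|A| * |B|) double-loop Hausdorff oracle
hausdorff_bruteforce <- function(a, b, spacing = c(1, 1)) {
  pa <- which(a == 1, arr.ind = TRUE)
  pb <- which(b == 1, arr.ind = TRUE)
  if (nrow(pa) == 0 || nrow(pb) == 0) return(NA_real_)
  directed <- function(p, q) {
    worst <- 0
    for (i in seq_len(nrow(p))) {
      best <- Inf
      for (j in seq_len(nrow(q))) {
        d <- sqrt(((p[i, 1] - q[j, 1]) * spacing[1])^2 +
                    ((p[i, 2] - q[j, 2]) * spacing[2])^2)
        if (d < best) best <- d
      }
      if (best > worst) worst <- best
    }
    worst
  }
  max(directed(pa, pb), directed(pb, pa))
}

# loop-based global pooling oracles over a (H, W, C, N) array
global_pool_oracle <- function(x, fun) {
  d <- dim(x)
  out <- array(0, c(1, 1, d[3], d[4]))
  for (n in seq_len(d[4])) for (c in seq_len(d[3]))
    out[1, 1, c, n] <- fun(x[, , c, n])
  out
}

# loop-based per-location channel reduction -> (H, W, 1, N)
channel_pool_oracle <- function(x, fun) {
  d <- dim(x)
  out <- array(0, c(d[1], d[2], 1, d[4]))
  for (n in seq_len(d[4])) for (h in seq_len(d[1])) for (w in seq_len(d[2]))
    out[h, w, 1, n] <- fun(x[h, w, , n])
  out
}

# Architecture arithmetic: an enumeration of every trainable tensor size,
# written from the layer ladder alone (independent of the module tree walk).
expected_param_count <- function(use_cff = TRUE, use_ecsa = TRUE,
                                 reduction = 16, groups = 2,
                                 decoder = c(256, 128, 64, 64, 32),
                                 num_classes = 1, input_channels = 3) {
  conv <- function(k, cin, cout, bias = FALSE, g = 1)
    k * k * (cin / g) * cout + (if (bias) cout else 0)
  bn <- function(c) 2 * c
  res_block <- function(cin, cout, stride) {
    n <- conv(3, cin, cout) + bn(cout) + conv(3, cout, cout) + bn(cout)
    if (stride != 1 || cin != cout) n <- n + conv(1, cin, cout) + bn(cout)
    n
  }
  encoder <- conv(7, input_channels, 64) + bn(64) +
    3 * res_block(64, 64, 1) +
    res_block(64, 128, 2) + 3 * res_block(128, 128, 1) +
    res_block(128, 256, 2) + 5 * res_block(256, 256, 1) +
    res_block(256, 512, 2) + 2 * res_block(512, 512, 1)
  cff_level <- function(cins) {
    ct <- cins[1]
    c1 <- length(cins) * ct
    sum(sapply(cins, function(ci) conv(3, ci, ct) + bn(ct))) +
      sum(sapply(c(1, 3, 5), function(k) conv(k, c1, ct, g = groups) + bn(ct))) +
      conv(1, 3 * ct, ct, bias = TRUE)
  }
  cff <- if (use_cff)
    cff_level(c(64, 128, 256)) + cff_level(c(128, 256, 512)) + cff_level(c(256, 512))
  else 0
  ecsa <- if (use_ecsa)
    conv(1, 512, 512 / reduction) + conv(1, 512 / reduction, 512) +
      conv(7, 2, 1, bias = TRUE)
  else 0
  dec_in <- c(512, decoder[1:4])
  dec <- sum(sapply(1:5, function(i) conv(3, dec_in[i], decoder[i]) + bn(decoder[i])))
  head <- conv(1, decoder[5], num_classes, bias = TRUE)
  encoder + cff + ecsa + dec + head
}

# small deterministic sample set for training tests: 32x32 scenes with a
# foreground budget the small radii can satisfy
tiny_scene <- function(seed = 1L) {
  scene_config(image_size = 32L, n_targets = c(1L, 1L), target_radius = c(1, 2),
               max_foreground_fraction = 0.02, seed = seed)
}

tiny_dataset <- function(n, seed0 = 100L, config = tiny_scene()) {
  lapply(seq_len(n), function(i) generate_sample(config, seed = seed0 + i))
}

random_mask <- function(h, w, p = 0.3) matrix(as.numeric(rbinom(h * w, 1, p)), h, w)
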