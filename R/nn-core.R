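# Shared neural-network primitives. Feature maps are (Nvox x C) matrices in
# native R array order (x fastest); spatial ops run in the compiled kernels,
# everything per-channel runs as vectorized matrix algebra here.

he_weights <- function(n_in, n_out, rows) {
  matrix(rnorm(rows * n_out, sd = sqrt(2 / n_in)), rows, n_out)
}

conv_block_init <- function(c_in, c_out, prefix) {
  p <- list()
  p[[paste0(prefix, "_W")]] <- he_weights(27 * c_in, c_out, 27 * c_in)
  p[[paste0(prefix, "_b")]] <- numeric(c_out)
  p[[paste0(prefix, "_g")]] <- rep(1, c_out)
  p[[paste0(prefix, "_be")]] <- numeric(c_out)
  p
}

# conv(3x3x3, pad 1) + batch-norm + ReLU, fused in compiled code. The
# normalization uses the statistics of the current volume (batch size is
# one volume), so inference is deterministic and identical to training
# mode. The forward pass hands back opaque float caches (input copy,
# normalized activations) that the backward pass reuses.
conv_bn_relu_fw <- function(x, dims, params, prefix) {
  f <- cpp_cbr_fw(x, dims, params[[paste0(prefix, "_W")]],
                  params[[paste0(prefix, "_b")]],
                  params[[paste0(prefix, "_g")]],
                  params[[paste0(prefix, "_be")]])
  list(y = f$Y, cache = list(y = f$Y, xin = f$xin, xhat = f$xhat,
                             inv = f$inv, dims = dims, prefix = prefix))
}

conv_bn_relu_bw <- function(dy, cache, params, want_dx = TRUE) {
  prefix <- cache$prefix
  bw <- cpp_cbr_bw(dy, cache$y, cache$xin, cache$xhat, cache$inv,
                   params[[paste0(prefix, "_g")]],
                   params[[paste0(prefix, "_W")]], cache$dims, want_dx)
  grads <- list()
  grads[[paste0(prefix, "_W")]] <- bw$dW
  grads[[paste0(prefix, "_b")]] <- bw$db
  grads[[paste0(prefix, "_g")]] <- bw$dg
  grads[[paste0(prefix, "_be")]] <- bw$dbe
  list(dx = if (want_dx) bw$dX else NULL, grads = grads)
}

softmax_rows <- function(z) {
  m <- z[, 1]
  for (j in seq_len(ncol(z))[-1]) m <- pmax(m, z[, j])
  e <- exp(z - m)
  e / rowSums(e)
}

# gradient through a row-wise softmax: dz = p * (dp - rowSums(dp * p))
softmax_bw <- function(p, dp) {
  p * (dp - rowSums(dp * p))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(grads)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# accumulate gradient lists (sums shared names)
merge_grads <- function(a, b) {
  for (k in names(b)) a[[k]] <- if (is.null(a[[k]])) b[[k]] else a[[k]] + b[[k]]
  a
}

one_hot_labels <- function(labels, categories) {
  lab <- as.integer(labels)
  K <- length(categories)
  out <- matrix(0, length(lab), K)
  idx <- match(lab, as.integer(categories))
  if (anyNA(idx)) stop("labels outside the category table")
  out[cbind(seq_along(lab), idx)] <- 1
  out
}
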