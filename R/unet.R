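#' 3D U-Net configuration
#'
#' A four-level (by default) encoder-decoder with, per level, two
#' convolution (3,3,3) + batch-normalization + ReLU blocks, max-pooling
#' (2,2,2) between encoder levels, nearest-neighbour upsampling followed by
#' a (3,3,3) up-convolution block in the decoder, and skip concatenation
#' from each encoder level to its decoder counterpart. Channel widths
#' double per level from `base_channels`. The default width (4) is a
#' desk-scale choice for CPU training; widths are fully configurable.
#'
#' @param depth Number of resolution levels (>= 2, default 4).
#' @param base_channels Channels at the top level (default 4).
#' @param out_categories Number of output categories (default 6).
#' @param epsilon Dice-loss smoothing constant (default 1e-4).
#' @param learning_rate Adam step size (default 1e-2).
#' @param max_iterations Training iterations, batch = one volume (default
#'   300; the reference regime of roughly a thousand repetitions is reached
#'   by raising this).
#' @param augment Apply random rigid+scale augmentation during training.
#' @param val_every Compute internal-validation metrics every this many
#'   iterations (a rotating single validation subject is scored; rows in
#'   between carry the last value forward).
#' @param grid_shape Optional expected grid; checked divisible by
#'   `2^(depth-1)` at build time.
#' @param seed Seed for parameter initialization and training order.
#' @return List of class `desh_unet_config`.
#' @export
unet_config <- function(depth = 4L, base_channels = 4L, out_categories = 6L,
                        epsilon = 1e-4, learning_rate = 1e-2,
                        max_iterations = 300L, augment = TRUE,
                        val_every = 1L, grid_shape = NULL, seed = 1L) {
  stopifnot(depth >= 2, base_channels >= 1, out_categories >= 2)
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 out_categories = as.integer(out_categories),
                 epsilon = epsilon, learning_rate = learning_rate,
                 max_iterations = as.integer(max_iterations),
                 augment = isTRUE(augment), val_every = as.integer(val_every),
                 grid_shape = grid_shape, seed = as.integer(seed)),
            class = "desh_unet_config")
}

check_unet_grid <- function(dims, depth) {
  f <- 2^(depth - 1)
  if (any(dims %% f != 0))
    stop("grid ", paste(dims, collapse = "x"), " is not divisible by ", f,
         " as required by a depth-", depth, " U-Net")
}

#' Build a 3D U-Net segmenter
#'
#' @param config A [unet_config()].
#' @return List of class `desh_segmenter` with seeded initial parameters.
#' @export
build_unet <- function(config = unet_config()) {
  stopifnot(inherits(config, "desh_unet_config"))
  if (!is.null(config$grid_shape))
    check_unet_grid(as.integer(rep_len(config$grid_shape, 3L)), config$depth)
  D <- config$depth
  ch <- config$base_channels * 2^(0:(D - 1))
  params <- with_seed(substream_seed(config$seed, "unet-init"), {
    p <- list()
    for (l in seq_len(D)) {
      c_in <- if (l == 1) 1L else ch[l - 1]
      p <- c(p, conv_block_init(c_in, ch[l], paste0("e", l, "c1")))
      p <- c(p, conv_block_init(ch[l], ch[l], paste0("e", l, "c2")))
    }
    for (l in seq_len(D - 1)) {
      p <- c(p, conv_block_init(ch[l + 1], ch[l], paste0("d", l, "up")))
      p <- c(p, conv_block_init(2 * ch[l], ch[l], paste0("d", l, "c1")))
      p <- c(p, conv_block_init(ch[l], ch[l], paste0("d", l, "c2")))
    }
    p$out_W <- matrix(rnorm(ch[1] * config$out_categories,
                            sd = sqrt(1 / ch[1])),
                      ch[1], config$out_categories)
    p$out_b <- numeric(config$out_categories)
    p
  })
  structure(list(config = config, params = params),
            class = "desh_segmenter")
}

unet_forward <- function(model, x, dims, want_cache = FALSE) {
  cfg <- model$config
  check_unet_grid(dims, cfg$depth)
  p <- model$params
  D <- cfg$depth
  caches <- list()
  skips <- list()
  level_dims <- list()
  cur <- x
  d <- dims
  for (l in seq_len(D)) {
    f1 <- conv_bn_relu_fw(cur, d, p, paste0("e", l, "c1"))
    f2 <- conv_bn_relu_fw(f1$y, d, p, paste0("e", l, "c2"))
    caches[[paste0("e", l)]] <- list(f1$cache, f2$cache)
    level_dims[[l]] <- d
    if (l < D) {
      skips[[l]] <- f2$y
      pool <- cpp_maxpool_fw(f2$y, d)
      caches[[paste0("p", l)]] <- list(idx = pool$idx, n_in = nrow(f2$y))
      cur <- pool$Y
      d <- d %/% 2L
    } else cur <- f2$y
  }
  for (l in seq(D - 1, 1)) {
    up <- cpp_upsample_fw(cur, d)
    d <- level_dims[[l]]
    fu <- conv_bn_relu_fw(up, d, p, paste0("d", l, "up"))
    cat_in <- cbind(skips[[l]], fu$y)
    f1 <- conv_bn_relu_fw(cat_in, d, p, paste0("d", l, "c1"))
    f2 <- conv_bn_relu_fw(f1$y, d, p, paste0("d", l, "c2"))
    caches[[paste0("d", l)]] <- list(up_cache = fu$cache, c1 = f1$cache,
                                     c2 = f2$cache,
                                     n_skip = ncol(skips[[l]]))
    cur <- f2$y
  }
  logits <- sweep(cur %*% p$out_W, 2, p$out_b, "+")
  if (want_cache) list(logits = logits, top = cur, caches = caches)
  else logits
}

unet_backward <- function(model, fw, dlogits) {
  cfg <- model$config
  p <- model$params
  D <- cfg$depth
  grads <- list(out_W = t(fw$top) %*% dlogits, out_b = colSums(dlogits))
  dcur <- dlogits %*% t(p$out_W)
  for (l in seq_len(D - 1)) {
    cc <- fw$caches[[paste0("d", l)]]
    b2 <- conv_bn_relu_bw(dcur, cc$c2, p)
    grads <- merge_grads(grads, b2$grads)
    b1 <- conv_bn_relu_bw(b2$dx, cc$c1, p)
    grads <- merge_grads(grads, b1$grads)
    n_skip <- cc$n_skip
    dskip <- b1$dx[, seq_len(n_skip), drop = FALSE]
    dup_out <- b1$dx[, -seq_len(n_skip), drop = FALSE]
    bu <- conv_bn_relu_bw(dup_out, cc$up_cache, p)
    grads <- merge_grads(grads, bu$grads)
    ddown <- cpp_upsample_bw(bu$dx, cc$up_cache$dims %/% 2L)
    # store for the encoder sweep
    fw$caches[[paste0("dskip", l)]] <- dskip
    dcur <- ddown
  }
  for (l in seq(D, 1)) {
    ec <- fw$caches[[paste0("e", l)]]
    if (l < D) {
      pc <- fw$caches[[paste0("p", l)]]
      dcur <- cpp_maxpool_bw(pc$idx, dcur, pc$n_in)
      dcur <- dcur + fw$caches[[paste0("dskip", l)]]
    }
    b2 <- conv_bn_relu_bw(dcur, ec[[2]], p)
    grads <- merge_grads(grads, b2$grads)
    b1 <- conv_bn_relu_bw(b2$dx, ec[[1]], p)
    grads <- merge_grads(grads, b1$grads)
    dcur <- b1$dx
  }
  grads
}

#' Smoothed soft Dice loss
#'
#' Per-category smoothed Dice of predicted probabilities against one-hot
#' truth, `D_c = (2 * sum(p_c t_c) + eps) / (sum(p_c) + sum(t_c) + eps)`;
#' the loss is `1 - mean(D_c)` over the foreground categories (background,
#' code 0, is excluded from the mean). A category empty in both prediction
#' and truth contributes `eps/eps = 1`, i.e. no penalty.
#'
#' @param pred Matrix (voxels x categories) of per-voxel probabilities;
#'   rows must sum to 1 within 1e-5.
#' @param truth A [desh_labelmap()] or integer vector of category codes.
#' @param epsilon Smoothing constant (default 1e-4).
#' @param categories Category codes matching `pred` columns.
#' @return Scalar loss (>= 0); attribute `dice` holds per-category D_c.
#' @export
soft_dice_loss <- function(pred, truth, epsilon = 1e-4,
                           categories = desh_categories()) {
  truth_codes <- if (inherits(truth, "desh_labelmap")) as.vector(truth$data)
                 else as.integer(truth)
  if (nrow(pred) != length(truth_codes))
    stop("prediction and truth shapes do not match")
  if (max(abs(rowSums(pred) - 1)) > 1e-5)
    stop("probability rows are not normalized within 1e-5")
  tmat <- one_hot_labels(truth_codes, categories)
  S <- colSums(pred * tmat)
  P <- colSums(pred)
  Tt <- colSums(tmat)
  d <- (2 * S + epsilon) / (P + Tt + epsilon)
  fg <- which(as.integer(categories) != 0L)
  loss <- 1 - mean(d[fg])
  attr(loss, "dice") <- stats::setNames(d, names(categories))
  loss
}

# gradient of soft_dice_loss with respect to pred (same shape as pred)
soft_dice_loss_grad <- function(pred, tmat, epsilon, fg) {
  S <- colSums(pred * tmat)
  P <- colSums(pred)
  Tt <- colSums(tmat)
  den <- P + Tt + epsilon
  num <- 2 * S + epsilon
  dP <- rep(0, ncol(pred))
  scale_t <- rep(0, ncol(pred))
  dP[fg] <- num[fg] / den[fg]^2 / length(fg)      # from -d/dP of -D_c
  scale_t[fg] <- -2 / den[fg] / length(fg)
  sweep(tmat, 2, scale_t, "*") + matrix(dP, nrow(pred), ncol(pred),
                                        byrow = TRUE)
}

hard_metrics <- function(pred_codes, truth_codes, categories, epsilon = 1e-4) {
  fg <- as.integer(categories)[as.integer(categories) != 0L]
  per <- t(vapply(fg, function(code) {
    p <- pred_codes == code
    t <- truth_codes == code
    tp <- sum(p & t)
    dice <- (2 * tp + epsilon) / (sum(p) + sum(t) + epsilon)
    prec <- if (sum(p) > 0) tp / sum(p) else if (sum(t) == 0) 1 else 0
    rec <- if (sum(t) > 0) tp / sum(t) else if (sum(p) == 0) 1 else 0
    c(dice = dice, precision = prec, recall = rec)
  }, c(dice = 0, precision = 0, recall = 0)))
  colMeans(per)
}

#' Train the U-Net segmenter on a phantom cohort
#'
#' Iterative Adam optimization of the smoothed Dice loss, one volume per
#' iteration, with on-the-fly rigid+scale augmentation and
#' percentile-normalized intensities. Per-iteration training loss, Dice,
#' precision and recall are logged; internal-validation metrics are scored
#' on a rotating validation subject every `val_every` iterations.
#'
#' @param cohort A [sample_cohort()] result (or list of phantom subjects).
#' @param config A [unet_config()].
#' @param train_ids,val_ids Integer subject indices for the training and
#'   internal-validation splits; defaults to the first 85% / last 15%.
#' @return List of class `desh_segmenter` with elements `params`, `config`
#'   and `log` (a data frame, one row per iteration).
#' @export
train_segmenter <- function(cohort, config = unet_config(),
                            train_ids = NULL, val_ids = NULL) {
  subjects <- if (inherits(cohort, "desh_cohort")) cohort$subjects else cohort
  n <- length(subjects)
  if (is.null(train_ids)) train_ids <- seq_len(max(1, floor(0.85 * n)))
  if (is.null(val_ids)) val_ids <- setdiff(seq_len(n), train_ids)
  if (length(train_ids) == 0) stop("training split is empty")
  dims <- dim(subjects[[train_ids[1]]]$volume$data)
  check_unet_grid(dims, config$depth)
  model <- build_unet(config)
  cats <- desh_categories()
  fgcols <- which(as.integer(cats) != 0L)
  opt <- adam_init(model$params)
  iters <- config$max_iterations
  log <- data.frame(iteration = seq_len(iters), train_loss = NA_real_,
                    train_dice = NA_real_, train_precision = NA_real_,
                    train_recall = NA_real_, val_loss = NA_real_,
                    val_dice = NA_real_, val_precision = NA_real_,
                    val_recall = NA_real_)
  order_seed <- substream_seed(config$seed, "train-order")
  epoch_order <- integer(0)
  vi <- 0L
  for (it in seq_len(iters)) {
    if (length(epoch_order) == 0)
      epoch_order <- with_seed(order_seed + it,
                               sample(train_ids, length(train_ids)))
    sid <- epoch_order[1]
    epoch_order <- epoch_order[-1]
    s <- subjects[[sid]]
    if (config$augment) {
      ap <- augment_params(seed = substream_seed(config$seed,
                                                 paste0("aug-", it)))
      aug <- augment_pair(s$volume, s$labelmap, ap)
      vol <- aug$volume; labm <- aug$labelmap
    } else { vol <- s$volume; labm <- s$labelmap }
    x <- matrix(as.vector(percentile_normalize(vol)$data), ncol = 1)
    truth_codes <- as.vector(labm$data)
    tmat <- one_hot_labels(truth_codes, cats)
    fw <- unet_forward(model, x, dims, want_cache = TRUE)
    probs <- softmax_rows(fw$logits)
    S <- colSums(probs * tmat); P <- colSums(probs); Tt <- colSums(tmat)
    d <- (2 * S + config$epsilon) / (P + Tt + config$epsilon)
    loss <- 1 - mean(d[fgcols])
    dp <- soft_dice_loss_grad(probs, tmat, config$epsilon, fgcols)
    dlogits <- softmax_bw(probs, dp)
    grads <- unet_backward(model, fw, dlogits)
    st <- adam_step(model$params, grads, opt, lr = config$learning_rate)
    model$params <- st$params; opt <- st$state
    pred_codes <- as.integer(cats)[max.col(probs, ties.method = "first")]
    m <- hard_metrics(pred_codes, truth_codes, cats)
    log[it, 2:5] <- c(loss, m["dice"], m["precision"], m["recall"])
    if (length(val_ids) && (it %% config$val_every == 0 || it == iters)) {
      vi <- vi %% length(val_ids) + 1L
      vs <- subjects[[val_ids[vi]]]
      vx <- matrix(as.vector(percentile_normalize(vs$volume)$data), ncol = 1)
      vlog <- unet_forward(model, vx, dims)
      vprobs <- softmax_rows(vlog)
      vtruth <- as.vector(vs$labelmap$data)
      vl <- soft_dice_loss(vprobs, vtruth, config$epsilon, cats)
      vp <- as.integer(cats)[max.col(vprobs, ties.method = "first")]
      vm <- hard_metrics(vp, vtruth, cats)
      log[it, 6:9] <- c(as.numeric(vl), vm["dice"], vm["precision"],
                        vm["recall"])
    } else if (it > 1) log[it, 6:9] <- log[it - 1, 6:9]
  }
  model$log <- log
  model
}

#' Segment a volume with a trained U-Net
#'
#' The input is expected to be percentile-normalized (see
#' [percentile_normalize()]). Each voxel gets the arg-max category of the
#' softmax scores; ties resolve to the lowest category code.
#'
#' @param model A trained `desh_segmenter`.
#' @param v A [desh_volume()].
#' @return A [desh_labelmap()] on the same grid.
#' @export
segment_volume <- function(model, v) {
  stopifnot(inherits(model, "desh_segmenter"), inherits(v, "desh_volume"))
  dims <- dim(v$data)
  check_unet_grid(dims, model$config$depth)
  x <- matrix(as.vector(v$data), ncol = 1)
  logits <- unet_forward(model, x, dims)
  cats <- desh_categories()
  if (ncol(logits) != length(cats))
    stop("model output categories do not match the category table")
  codes <- as.integer(cats)[max.col(logits, ties.method = "first")]
  desh_labelmap(array(codes, dims), v$voxel_size_mm, v$origin_mm)
}

#' Evaluate a predicted segmentation against ground truth
#'
#' Hard-mask smoothed Dice (epsilon 1e-4), precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)` and signed volume difference (predicted minus truth, mL)
#' per foreground category.
#'
#' @param pred,truth [desh_labelmap()]s on the same grid and spacing.
#' @param epsilon Dice smoothing constant.
#' @return Data frame with one row per foreground category.
#' @export
evaluate_segmentation <- function(pred, truth, epsilon = 1e-4) {
  stopifnot(inherits(pred, "desh_labelmap"), inherits(truth, "desh_labelmap"))
  if (!identical(dim(pred$data), dim(truth$data)))
    stop("prediction and truth grids differ")
  if (max(abs(pred$voxel_size_mm - truth$voxel_size_mm)) > 1e-9)
    stop("prediction and truth voxel spacings differ")
  cats <- desh_categories()
  fg <- cats[as.integer(cats) != 0L]
  vox_ml <- prod(pred$voxel_size_mm) / 1000
  rows <- lapply(names(fg), function(nm) {
    code <- fg[[nm]]
    p <- pred$data == code
    t <- truth$data == code
    tp <- sum(p & t)
    data.frame(category = nm,
               dice = (2 * tp + epsilon) / (sum(p) + sum(t) + epsilon),
               precision = if (sum(p) > 0) tp / sum(p) else if (sum(t) == 0) 1 else 0,
               recall = if (sum(t) > 0) tp / sum(t) else if (sum(p) == 0) 1 else 0,
               volume_diff_ml = (sum(p) - sum(t)) * vox_ml)
  })
  do.call(rbind, rows)
}

#' Save / load a segmenter or classifier checkpoint
#'
#' Single-file archive embedding parameters, configuration and seed.
#'
#' @param model Model object.
#' @param path Checkpoint path (`.rds`).
#' @return `path` (save) or the model (load).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
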