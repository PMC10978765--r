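#' Multimodal classifier configuration
#'
#' One small convolutional network per determination task (DESH, VD, THC,
#' SFD), each seeing its own task-specific CSF mask: convolution (3,3,3) +
#' batch-normalization + ReLU + channel self-attention
#' (squeeze-excitation) + max-pooling per block, then global average
#' pooling, concatenation with an embedded age/sex covariate vector, and a
#' fully connected head ending in a two-way softmax.
#'
#' @param channels Channels per conv block (default c(4, 8, 16)).
#' @param embed_dim Covariate embedding width (default 8).
#' @param hidden Fully-connected hidden width (default 16).
#' @param tasks Ordered task list (default desh, vd, thc, sfd).
#' @param learning_rate Adam step size.
#' @param iterations Training iterations per task (batch = 1 subject).
#' @param augment Apply rigid+scale augmentation to the input mask.
#' @param seed Integer seed.
#' @return List of class `desh_classifier_config`.
#' @export
classifier_config <- function(channels = c(4L, 8L, 16L), embed_dim = 8L,
                              hidden = 16L,
                              tasks = c("desh", "vd", "thc", "sfd"),
                              learning_rate = 1e-3, iterations = 200L,
                              augment = TRUE, seed = 1L) {
  stopifnot(length(channels) >= 1, length(tasks) >= 1, embed_dim >= 1)
  structure(list(channels = as.integer(channels),
                 embed_dim = as.integer(embed_dim), hidden = as.integer(hidden),
                 tasks = tasks, learning_rate = learning_rate,
                 iterations = as.integer(iterations), augment = isTRUE(augment),
                 seed = as.integer(seed)),
            class = "desh_classifier_config")
}

#' Assemble the classifier input for one task
#'
#' Task-to-mask mapping: `desh` uses the whole intracranial CSF space
#' (ventricles plus all SAS compartments); `vd` the total-ventricle mask;
#' `thc` the high-convexity SAS mask; `sfd` the Sylvian fissure + basal
#' cistern mask. The mask volume is min-max normalized to \[0, 1\] and the
#' covariates are the subject's age and sex.
#'
#' @param subject A phantom subject (or any list with `labelmap`,
#'   `age_years`, `sex`).
#' @param task One of `"desh"`, `"vd"`, `"thc"`, `"sfd"`.
#' @return List with `mask` (a [desh_volume()]), `age_years` and `sex`.
#' @export
assemble_classifier_input <- function(subject, task) {
  cats <- desh_categories()
  codes <- switch(task,
                  desh = cats[c("ventricles", "sylvian_basal",
                                "high_convexity_sas", "other_sas")],
                  vd = cats["ventricles"],
                  thc = cats["high_convexity_sas"],
                  sfd = cats["sylvian_basal"],
                  stop("unknown task: ", task))
  m <- subject$labelmap
  if (is.null(m)) stop("subject has no label map")
  if (is.null(subject$age_years) || is.na(subject$age_years))
    stop("missing covariate: age_years")
  if (is.null(subject$sex) || !subject$sex %in% c("male", "female"))
    stop("missing covariate: sex")
  mask <- array(as.numeric(m$data %in% as.integer(codes)), dim(m$data))
  mask <- minmax_normalize(mask)
  list(mask = desh_volume(mask, m$voxel_size_mm, m$origin_mm),
       age_years = subject$age_years, sex = subject$sex)
}

clf_init_params <- function(config) {
  ch <- config$channels
  p <- list()
  for (i in seq_along(ch)) {
    c_in <- if (i == 1) 1L else ch[i - 1]
    p <- c(p, conv_block_init(c_in, ch[i], paste0("b", i)))
    r <- max(1L, ch[i] %/% 2L)
    p[[paste0("se", i, "_W1")]] <- he_weights(ch[i], r, ch[i])
    p[[paste0("se", i, "_b1")]] <- numeric(r)
    p[[paste0("se", i, "_W2")]] <- he_weights(r, ch[i], r)
    p[[paste0("se", i, "_b2")]] <- numeric(ch[i])
  }
  cl <- ch[length(ch)]
  p$emb_W <- he_weights(3, config$embed_dim, 3)
  p$emb_b <- numeric(config$embed_dim)
  p$fc1_W <- he_weights(cl + config$embed_dim, config$hidden,
                        cl + config$embed_dim)
  p$fc1_b <- numeric(config$hidden)
  p$fc2_W <- he_weights(config$hidden, 2L, config$hidden)
  p$fc2_b <- numeric(2L)
  p
}

#' Build the four-task classifier
#'
#' Four separate task networks with seeded initial parameters (the task
#' inputs differ, so sharing a backbone would conflate them).
#'
#' @param config A [classifier_config()].
#' @return List of class `desh_classifier` with one parameter set per task.
#' @export
build_classifier <- function(config = classifier_config()) {
  stopifnot(inherits(config, "desh_classifier_config"))
  models <- lapply(seq_along(config$tasks), function(i)
    with_seed(substream_seed(config$seed, paste0("clf-", config$tasks[i])),
              clf_init_params(config)))
  names(models) <- config$tasks
  structure(list(config = config, models = models,
                 age_mean = NA_real_, age_sd = NA_real_),
            class = "desh_classifier")
}

se_fw <- function(x, params, prefix) {
  W1 <- params[[paste0(prefix, "_W1")]]; b1 <- params[[paste0(prefix, "_b1")]]
  W2 <- params[[paste0(prefix, "_W2")]]; b2 <- params[[paste0(prefix, "_b2")]]
  z <- colMeans(x)
  h <- pmax(as.numeric(z %*% W1) + b1, 0)
  s <- 1 / (1 + exp(-(as.numeric(h %*% W2) + b2)))
  list(y = sweep(x, 2, s, "*"),
       cache = list(x = x, z = z, h = h, s = s, prefix = prefix))
}

se_bw <- function(dy, cache, params) {
  prefix <- cache$prefix
  W1 <- params[[paste0(prefix, "_W1")]]
  W2 <- params[[paste0(prefix, "_W2")]]
  x <- cache$x; s <- cache$s; h <- cache$h; z <- cache$z
  ds <- colSums(dy * x)
  dx <- sweep(dy, 2, s, "*")
  dpre2 <- ds * s * (1 - s)
  dW2 <- outer(h, dpre2)
  db2 <- dpre2
  dh <- as.numeric(W2 %*% dpre2) * (h > 0)
  dW1 <- outer(z, dh)
  db1 <- dh
  dz <- as.numeric(W1 %*% dh)
  dx <- dx + matrix(dz / nrow(x), nrow(x), ncol(x), byrow = TRUE)
  grads <- list()
  grads[[paste0(prefix, "_W1")]] <- dW1
  grads[[paste0(prefix, "_b1")]] <- db1
  grads[[paste0(prefix, "_W2")]] <- dW2
  grads[[paste0(prefix, "_b2")]] <- db2
  list(dx = dx, grads = grads)
}

clf_forward <- function(params, x, dims, cov, config, want_cache = FALSE) {
  nb <- length(config$channels)
  if (any(dims < 2^nb))
    stop("input grid ", paste(dims, collapse = "x"),
         " is smaller than the network's pooling footprint (", 2^nb, ")")
  caches <- list()
  cur <- x; d <- dims
  for (i in seq_len(nb)) {
    f <- conv_bn_relu_fw(cur, d, params, paste0("b", i))
    se <- se_fw(f$y, params, paste0("se", i))
    pool <- cpp_maxpool_fw(se$y, d)
    caches[[i]] <- list(conv = f$cache, se = se$cache, idx = pool$idx,
                        n_in = nrow(se$y))
    cur <- pool$Y
    d <- d %/% 2L
  }
  g <- colMeans(cur)
  emb_pre <- as.numeric(cov %*% params$emb_W) + params$emb_b
  emb <- pmax(emb_pre, 0)
  f <- c(g, emb)
  h_pre <- as.numeric(f %*% params$fc1_W) + params$fc1_b
  h <- pmax(h_pre, 0)
  logits <- as.numeric(h %*% params$fc2_W) + params$fc2_b
  p <- exp(logits - max(logits))
  p <- p / sum(p)
  if (!want_cache) return(p)
  list(p = p, caches = caches, g = g, emb = emb, f = f, h = h,
       n_last = nrow(cur), cov = cov, d_last = d)
}

clf_backward <- function(params, fw, dlogits, config) {
  grads <- list(fc2_W = outer(fw$h, dlogits), fc2_b = dlogits)
  dh <- as.numeric(params$fc2_W %*% dlogits) * (fw$h > 0)
  grads$fc1_W <- outer(fw$f, dh)
  grads$fc1_b <- dh
  df <- as.numeric(params$fc1_W %*% dh)
  nl <- length(fw$g)
  dg <- df[seq_len(nl)]
  demb <- df[-seq_len(nl)] * (fw$emb > 0)
  grads$emb_W <- outer(as.numeric(fw$cov), demb)
  grads$emb_b <- demb
  dcur <- matrix(dg / fw$n_last, fw$n_last, nl, byrow = TRUE)
  for (i in rev(seq_along(config$channels))) {
    cc <- fw$caches[[i]]
    dcur <- cpp_maxpool_bw(cc$idx, dcur, cc$n_in)
    sb <- se_bw(dcur, cc$se, params)
    grads <- merge_grads(grads, sb$grads)
    cb <- conv_bn_relu_bw(sb$dx, cc$conv, params)
    grads <- merge_grads(grads, cb$grads)
    dcur <- cb$dx
  }
  grads
}

clf_covariates <- function(age_years, sex, age_mean, age_sd) {
  age_std <- if (is.finite(age_sd) && age_sd > 0) (age_years - age_mean) / age_sd
             else 0
  matrix(c(age_std, as.numeric(sex == "male"), as.numeric(sex == "female")),
         nrow = 1)
}

subject_flag <- function(subject, task) isTRUE(subject$phenotype[[task]])

#' Train the four-task classifier on a phantom cohort
#'
#' Cross-entropy optimization with Adam, one subject per iteration per
#' task, with optional rigid+scale augmentation of the input mask. Age is
#' standardized by the training-split mean and SD. A training split where
#' any task has a single class is rejected with an instruction to resample.
#'
#' @param cohort A [sample_cohort()] result.
#' @param config A [classifier_config()].
#' @param train_ids Integer subject indices of the training split (default
#'   all subjects).
#' @return A `desh_classifier` with trained parameters and a `log` data
#'   frame (task, iteration, loss, correct, running accuracy).
#' @export
train_classifier <- function(cohort, config = classifier_config(),
                             train_ids = NULL) {
  subjects <- if (inherits(cohort, "desh_cohort")) cohort$subjects else cohort
  if (is.null(train_ids)) train_ids <- seq_along(subjects)
  if (length(train_ids) == 0) stop("training split is empty")
  model <- build_classifier(config)
  ages <- vapply(subjects[train_ids], function(s) s$age_years, 0)
  model$age_mean <- mean(ages)
  model$age_sd <- sd(ages)
  logs <- list()
  for (task in config$tasks) {
    flags <- vapply(subjects[train_ids], subject_flag, TRUE, task = task)
    if (length(unique(flags)) < 2)
      stop("task '", task, "' has a single class in the training split; ",
           "resample the split or the cohort")
    params <- model$models[[task]]
    opt <- adam_init(params)
    tl <- data.frame(task = task, iteration = seq_len(config$iterations),
                     loss = NA_real_, correct = NA_real_,
                     accuracy = NA_real_)
    order_seed <- substream_seed(config$seed, paste0("order-", task))
    epoch_order <- integer(0)
    for (it in seq_len(config$iterations)) {
      if (length(epoch_order) == 0)
        epoch_order <- with_seed(order_seed + it,
                                 sample(train_ids, length(train_ids)))
      sid <- epoch_order[1]; epoch_order <- epoch_order[-1]
      s <- subjects[[sid]]
      inp <- assemble_classifier_input(s, task)
      vol <- inp$mask
      if (config$augment) {
        ap <- augment_params(seed = substream_seed(config$seed,
                                                   paste0("aug-", task, "-", it)))
        draw <- with_seed(ap$seed, list(
          rot = runif(3, ap$rotation_deg_range[1], ap$rotation_deg_range[2]),
          s = runif(1, ap$scale_range[1], ap$scale_range[2]),
          t = runif(3, ap$translation_mm_range[1], ap$translation_mm_range[2])))
        R <- rotation_matrix(draw$rot * pi / 180)
        dims <- dim(vol$data)
        M <- affine_voxel_map(dims, vol$voxel_size_mm, vol$origin_mm, R,
                              draw$s, draw$t)
        vol$data <- resample_volume_affine(vol$data, dims, M, nearest = TRUE,
                                           fill = 0)
      }
      dims <- dim(vol$data)
      x <- matrix(as.vector(vol$data), ncol = 1)
      cov <- clf_covariates(inp$age_years, inp$sex, model$age_mean,
                            model$age_sd)
      fw <- clf_forward(params, x, dims, cov, config, want_cache = TRUE)
      y <- if (subject_flag(s, task)) 2L else 1L
      loss <- -log(max(fw$p[y], 1e-12))
      dlogits <- fw$p
      dlogits[y] <- dlogits[y] - 1
      grads <- clf_backward(params, fw, dlogits, config)
      st <- adam_step(params, grads, opt, lr = config$learning_rate)
      params <- st$params; opt <- st$state
      tl$loss[it] <- loss
      tl$correct[it] <- as.numeric(which.max(fw$p) == y)
      tl$accuracy[it] <- mean(tl$correct[max(1, it - 19):it])
    }
    model$models[[task]] <- params
    logs[[task]] <- tl
  }
  model$log <- do.call(rbind, logs)
  model
}

#' Classify one subject on all four tasks
#'
#' @param model A trained `desh_classifier`.
#' @param subject A phantom subject (label map + covariates).
#' @return Data frame of class `desh_classification`: per task the softmax
#'   probabilities of the negative and positive categories and the boolean
#'   label (positive probability >= 0.5).
#' @export
classify_subject <- function(model, subject) {
  stopifnot(inherits(model, "desh_classifier"))
  config <- model$config
  rows <- lapply(config$tasks, function(task) {
    inp <- assemble_classifier_input(subject, task)
    dims <- dim(inp$mask$data)
    x <- matrix(as.vector(inp$mask$data), ncol = 1)
    cov <- clf_covariates(inp$age_years, inp$sex, model$age_mean, model$age_sd)
    p <- clf_forward(model$models[[task]], x, dims, cov, config)
    data.frame(task = task, prob_negative = p[1], prob_positive = p[2],
               label = p[2] >= 0.5)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("desh_classification", class(out))
  out
}

#' Evaluate classifications against ground-truth flags
#'
#' Accuracy is the fraction of label agreements per task. The primary mean
#' softmax probability score averages, over all subjects, the probability
#' the model assigned to its own predicted category; the score restricted
#' to predicted-positive cases is reported alongside. Disagreements are
#' listed per subject and task.
#'
#' @param results List of [classify_subject()] outputs, one per subject.
#' @param truth Data frame with logical columns `desh`, `vd`, `thc`, `sfd`
#'   (one row per subject, aligned with `results`).
#' @return List with `summary` (per-task data frame) and `discrepancies`.
#' @export
evaluate_classification <- function(results, truth) {
  if (length(results) != nrow(truth))
    stop("results and truth have different lengths")
  tasks <- unique(results[[1]]$task)
  summ <- lapply(tasks, function(task) {
    pred <- vapply(results, function(r) r$label[r$task == task], TRUE)
    score <- vapply(results, function(r) {
      row <- r[r$task == task, ]
      if (row$label) row$prob_positive else row$prob_negative
    }, 0)
    tr <- truth[[task]]
    data.frame(task = task, n = length(pred),
               n_truth_positive = sum(tr), n_pred_positive = sum(pred),
               accuracy = mean(pred == tr),
               mean_predicted_score = mean(score),
               mean_score_pred_positive = if (any(pred))
                 mean(score[pred]) else NA_real_)
  })
  disc <- list()
  for (task in tasks) {
    pred <- vapply(results, function(r) r$label[r$task == task], TRUE)
    bad <- which(pred != truth[[task]])
    if (length(bad))
      disc[[task]] <- data.frame(task = task, subject = bad,
                                 predicted = pred[bad],
                                 truth = truth[[task]][bad])
  }
  list(summary = do.call(rbind, summ),
       discrepancies = if (length(disc)) do.call(rbind, disc)
                       else data.frame())
}
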