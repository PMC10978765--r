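test_that("U-Net forward honours the shape contract", {
  cfg <- unet_config(depth = 4, base_channels = 2, seed = 1)
  model <- build_unet(cfg)
  dims <- c(24L, 24L, 24L)
  x <- matrix(rnorm(prod(dims)), ncol = 1)
  logits <- deshkit:::unet_forward(model, x, dims)
  expect_equal(dim(logits), c(prod(dims), 6L))
})

test_that("grids indivisible by 2^(depth-1) are rejected at build time", {
  expect_error(build_unet(unet_config(depth = 4, grid_shape = c(50, 50, 50))),
               "not divisible by 8")
  expect_silent(model <- build_unet(unet_config(depth = 4, base_channels = 2,
                                                grid_shape = c(48, 48, 48))))
  m <- build_unet(unet_config(depth = 4, base_channels = 2, seed = 1))
  expect_error(deshkit:::unet_forward(m, matrix(0, 50^3, 1), c(50L, 50L, 50L)),
               "not divisible")
})

test_that("parameter initialization is seeded", {
  a <- build_unet(unet_config(base_channels = 2, seed = 5))
  b <- build_unet(unet_config(base_channels = 2, seed = 5))
  c <- build_unet(unet_config(base_channels = 2, seed = 6))
  expect_identical(a$params, b$params)
  expect_false(identical(a$params$e1c1_W, c$params$e1c1_W))
})

test_that("soft Dice loss matches hand algebra", {
  cats <- c(background = 0L, fg = 1L)
  n <- 200
  truth <- rep(1L, n)
  onehot <- cbind(0, rep(1, n))
  expect_equal(as.numeric(soft_dice_loss(onehot, truth, categories = cats)),
               0, tolerance = 1e-9)

  unif <- matrix(0.5, n, 2)
  l <- soft_dice_loss(unif, truth, categories = cats)
  eps <- 1e-4
  expect_equal(as.numeric(l), 1 - (n + eps) / (1.5 * n + eps),
               tolerance = 1e-12)
  expect_equal(as.numeric(l), 1 / 3, tolerance = 1e-3)

  # category empty in both prediction and truth: eps/eps = 1, no penalty
  cats3 <- c(background = 0L, a = 1L, b = 2L)
  truth3 <- rep(1L, n)
  pred3 <- cbind(0, 1, 0)[rep(1, n), ]
  l3 <- soft_dice_loss(pred3, truth3, categories = cats3)
  expect_equal(unname(attr(l3, "dice")["b"]), 1)
  expect_equal(as.numeric(l3), 0, tolerance = 1e-9)

  bad <- matrix(c(0.6, 0.6), n, 2, byrow = TRUE)
  expect_error(soft_dice_loss(bad, truth, categories = cats), "normalized")
})

test_that("analytic gradients agree with finite differences", {
  dims <- c(8L, 8L, 8L)
  cfg <- unet_config(depth = 2, base_channels = 2, out_categories = 3,
                     seed = 3)
  model <- build_unet(cfg)
  cats <- c(background = 0L, a = 1L, b = 2L)
  set.seed(4)
  x <- matrix(rnorm(prod(dims)), ncol = 1)
  truth <- sample(0:2, prod(dims), replace = TRUE)
  tmat <- deshkit:::one_hot_labels(truth, cats)
  loss_of <- function(m) {
    fw <- deshkit:::unet_forward(m, x, dims, want_cache = TRUE)
    probs <- deshkit:::softmax_rows(fw$logits)
    as.numeric(soft_dice_loss(probs, truth, categories = cats))
  }
  fw <- deshkit:::unet_forward(model, x, dims, want_cache = TRUE)
  probs <- deshkit:::softmax_rows(fw$logits)
  dp <- deshkit:::soft_dice_loss_grad(probs, tmat, 1e-4, 2:3)
  grads <- deshkit:::unet_backward(model, fw,
                                   deshkit:::softmax_bw(probs, dp))
  set.seed(9)
  for (pn in c("e1c1_W", "e2c2_g", "d1c1_W", "d1up_be", "out_W")) {
    idx <- sample(length(model$params[[pn]]), 1)
    h <- 1e-2
    mp <- model; mp$params[[pn]][idx] <- mp$params[[pn]][idx] + h
    mm <- model; mm$params[[pn]][idx] <- mm$params[[pn]][idx] - h
    num <- (loss_of(mp) - loss_of(mm)) / (2 * h)
    ana <- grads[[pn]][idx]
    expect_equal(ana, num, tolerance = 0.05,
                 label = paste("gradient of", pn))
  }
})

test_that("evaluate_segmentation matches hand arithmetic and symmetry", {
  dims <- c(10, 10, 10)
  truth_arr <- array(0L, dims); truth_arr[1:100] <- 2L
  pred_arr <- array(0L, dims); pred_arr[1:50] <- 2L
  truth <- desh_labelmap(truth_arr, 1)
  pred <- desh_labelmap(pred_arr, 1)
  ev <- evaluate_segmentation(pred, truth)
  row <- ev[ev$category == "ventricles", ]
  expect_equal(row$dice, (100 + 1e-4) / (150 + 1e-4), tolerance = 1e-12)
  expect_equal(row$precision, 1)
  expect_equal(row$recall, 0.5)
  expect_equal(row$volume_diff_ml, -0.05)

  # disjoint masks: eps-smoothed near-zero Dice
  pred2_arr <- array(0L, dims); pred2_arr[101:200] <- 2L
  ev2 <- evaluate_segmentation(desh_labelmap(pred2_arr, 1), truth)
  expect_equal(ev2$dice[ev2$category == "ventricles"], 1e-4 / (200 + 1e-4))

  # identity
  ev3 <- evaluate_segmentation(truth, truth)
  expect_true(all(ev3$dice[ev3$category == "ventricles"] == 1))
  expect_true(all(ev3$volume_diff_ml == 0))

  # swapping arguments swaps precision and recall, keeps Dice
  ev_swap <- evaluate_segmentation(truth, pred)
  expect_equal(ev_swap$dice, ev$dice)
  expect_equal(ev_swap$precision[ev_swap$category == "ventricles"],
               row$recall)
  expect_equal(ev_swap$recall[ev_swap$category == "ventricles"],
               row$precision)

  expect_error(evaluate_segmentation(desh_labelmap(pred_arr, 2), truth),
               "spacing")
})

test_that("hard Dice agrees with the voxel-set oracle on random masks", {
  set.seed(13)
  for (i in 1:10) {
    d <- sample(3:8, 3, replace = TRUE)
    pred <- desh_labelmap(array(sample(c(0L, 2L), prod(d), TRUE), d), 1)
    truth <- desh_labelmap(array(sample(c(0L, 2L), prod(d), TRUE), d), 1)
    ev <- evaluate_segmentation(pred, truth)
    expect_identical(ev$dice[ev$category == "ventricles"],
                     dice_oracle(pred$data == 2, truth$data == 2))
  }
})

test_that("a small U-Net overfits one phantom and the loss trends down", {
  s <- get_phantom(desh = TRUE, seed = 2, grid = c(32L, 32L, 32L),
                   vox = c(5, 5, 5))
  cfg <- unet_config(base_channels = 4, max_iterations = 200,
                     augment = FALSE, val_every = 100, seed = 2)
  m <- train_segmenter(list(s), cfg, train_ids = 1, val_ids = integer(0))
  pred <- segment_volume(m, percentile_normalize(s$volume))
  ev <- evaluate_segmentation(pred, s$labelmap)
  expect_gte(ev$dice[ev$category == "ventricles"], 0.95)

  # training loss decreases between smoothed 50-iteration windows
  first <- mean(m$log$train_loss[1:50])
  last <- mean(m$log$train_loss[151:200])
  expect_lt(last, first)

  # inference is deterministic and stays within the category table
  pred2 <- segment_volume(m, percentile_normalize(s$volume))
  expect_identical(pred$data, pred2$data)
  expect_true(all(pred$data %in% desh_categories()))

  # a different seed gives different trained parameters
  cfg2 <- unet_config(base_channels = 4, max_iterations = 5,
                      augment = FALSE, seed = 21)
  cfg3 <- unet_config(base_channels = 4, max_iterations = 5,
                      augment = FALSE, seed = 22)
  m2 <- train_segmenter(list(s), cfg2, train_ids = 1, val_ids = integer(0))
  m3 <- train_segmenter(list(s), cfg3, train_ids = 1, val_ids = integer(0))
  expect_false(identical(m2$params$e1c1_W, m3$params$e1c1_W))
})

test_that("training rejects an empty split and logs every iteration", {
  s <- get_phantom(desh = FALSE, seed = 2, grid = c(32L, 32L, 32L),
                   vox = c(5, 5, 5))
  expect_error(train_segmenter(list(s), unet_config(max_iterations = 1),
                               train_ids = integer(0)), "empty")
  cfg <- unet_config(base_channels = 2, max_iterations = 4, augment = FALSE,
                     seed = 1)
  m <- train_segmenter(list(s), cfg, train_ids = 1, val_ids = integer(0))
  expect_equal(nrow(m$log), 4)
  expect_true(all(is.finite(m$log$train_loss)))
  expect_true(all(m$log$train_dice >= 0 & m$log$train_dice <= 1))
})
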