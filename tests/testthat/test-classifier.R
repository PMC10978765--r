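small_cohort <- function(n = 8, seed = 5)
  get_cohort(n, 0.5, seed = seed, grid_shape = c(32L, 32L, 32L),
             voxel_size_mm = c(5, 5, 5))

test_that("task-to-mask assembly follows the prescribed input mapping", {
  s <- get_phantom(desh = TRUE, seed = 1)
  cats <- desh_categories()
  vd <- assemble_classifier_input(s, "vd")
  expect_identical(vd$mask$data != 0, s$labelmap$data == cats[["ventricles"]])
  desh <- assemble_classifier_input(s, "desh")
  expect_equal(sum(desh$mask$data != 0),
               sum(s$labelmap$data %in% 2:5))  # whole intracranial CSF space
  thc <- assemble_classifier_input(s, "thc")
  expect_identical(thc$mask$data != 0,
                   s$labelmap$data == cats[["high_convexity_sas"]])
  sfd <- assemble_classifier_input(s, "sfd")
  expect_identical(sfd$mask$data != 0,
                   s$labelmap$data == cats[["sylvian_basal"]])
  expect_true(all(desh$mask$data %in% c(0, 1)))
  expect_error(assemble_classifier_input(s, "evans"), "unknown task")

  # an empty high-convexity label is a legal, all-zero THC input
  s2 <- s
  s2$labelmap$data[s2$labelmap$data == 4L] <- 5L
  thc0 <- assemble_classifier_input(s2, "thc")
  expect_true(all(thc0$mask$data == 0))

  s3 <- s; s3$age_years <- NA
  expect_error(assemble_classifier_input(s3, "vd"), "age")
  s4 <- s; s4$sex <- NULL
  expect_error(assemble_classifier_input(s4, "vd"), "sex")
})

test_that("classifier initialization is seeded and outputs are softmax pairs", {
  cfg <- classifier_config(channels = c(2L, 4L), iterations = 2L, seed = 7)
  a <- build_classifier(cfg)
  b <- build_classifier(cfg)
  expect_identical(a$models, b$models)
  d <- build_classifier(classifier_config(channels = c(2L, 4L), seed = 8))
  expect_false(identical(a$models$desh$b1_W, d$models$desh$b1_W))

  s <- get_phantom(desh = TRUE, seed = 1, grid = c(32L, 32L, 32L),
                   vox = c(5, 5, 5))
  a$age_mean <- 60; a$age_sd <- 10
  res <- classify_subject(a, s)
  expect_equal(nrow(res), 4)
  expect_equal(res$prob_negative + res$prob_positive, rep(1, 4),
               tolerance = 1e-6)
  expect_true(all(res$prob_positive >= 0 & res$prob_positive <= 1))
  res2 <- classify_subject(a, s)
  expect_identical(res, res2)
})

test_that("covariates are wired in: age perturbation changes the output", {
  cfg <- classifier_config(channels = c(2L, 4L), seed = 3)
  model <- build_classifier(cfg)
  model$age_mean <- 60; model$age_sd <- 10
  s <- get_phantom(desh = FALSE, seed = 2, grid = c(32L, 32L, 32L),
                   vox = c(5, 5, 5))
  p1 <- classify_subject(model, s)
  s$age_years <- s$age_years + 15
  p2 <- classify_subject(model, s)
  expect_gt(max(abs(p1$prob_positive - p2$prob_positive)), 1e-8)
})

test_that("input grids below the pooling footprint are rejected", {
  cfg <- classifier_config(channels = c(2L, 4L, 8L), seed = 1)
  model <- build_classifier(cfg)
  expect_error(
    deshkit:::clf_forward(model$models$desh, matrix(0, 4^3, 1), c(4L, 4L, 4L),
                          matrix(c(0, 1, 0), 1), cfg),
    "pooling footprint")
})

test_that("classifier training lowers the loss and is logged per iteration", {
  co <- small_cohort()
  cfg <- classifier_config(channels = c(2L, 4L), iterations = 30L,
                           tasks = "desh", augment = FALSE, seed = 2)
  m <- train_classifier(co, cfg)
  expect_equal(nrow(m$log), 30)
  expect_lt(mean(tail(m$log$loss, 10)), mean(head(m$log$loss, 10)))
  expect_true(all(m$log$accuracy >= 0 & m$log$accuracy <= 1))
  # age standardization comes from the training split
  expect_equal(m$age_mean, mean(co$manifest$age_years))
})

test_that("a single-class task in the training split is rejected", {
  co <- small_cohort()
  ids <- which(!co$manifest$desh)
  cfg <- classifier_config(channels = c(2L, 4L), iterations = 2L,
                           tasks = "desh", seed = 1)
  expect_error(train_classifier(co, cfg, train_ids = ids),
               "single class.*resample")
})

test_that("classification evaluation computes accuracy and mean scores", {
  fake <- function(p_pos) {
    data.frame(task = "desh", prob_negative = 1 - p_pos,
               prob_positive = p_pos, label = p_pos >= 0.5)
  }
  results <- lapply(c(0.9, 0.8, 0.2, 0.1), fake)
  truth <- data.frame(desh = c(TRUE, TRUE, FALSE, FALSE))
  ev <- evaluate_classification(results, truth)
  expect_equal(ev$summary$accuracy, 1)
  expect_equal(ev$summary$mean_predicted_score, mean(c(0.9, 0.8, 0.8, 0.9)))
  expect_equal(nrow(ev$discrepancies), 0)

  # one disagreement in 30 subjects
  results30 <- lapply(c(rep(0.9, 15), rep(0.1, 14), 0.6), fake)
  truth30 <- data.frame(desh = c(rep(TRUE, 15), rep(FALSE, 15)))
  ev30 <- evaluate_classification(results30, truth30)
  expect_equal(ev30$summary$accuracy, 29 / 30, tolerance = 1e-12)
  expect_equal(ev30$discrepancies$subject, 30)

  # uninformative scores give mean predicted score 0.5
  flat <- lapply(rep(0.5, 4), fake)
  evf <- evaluate_classification(flat, truth)
  expect_equal(evf$summary$mean_predicted_score, 0.5)

  expect_error(evaluate_classification(results, truth30), "length")
})

test_that("classifier gradients agree with finite differences", {
  cfg <- classifier_config(channels = c(2L), iterations = 1L, seed = 11)
  params <- with_seed(1, deshkit:::clf_init_params(cfg))
  dims <- c(8L, 8L, 8L)
  set.seed(2)
  x <- matrix(runif(prod(dims)), ncol = 1)
  cov <- matrix(c(0.5, 1, 0), 1)
  loss_of <- function(p) {
    pr <- deshkit:::clf_forward(p, x, dims, cov, cfg)
    -log(pr[2])
  }
  fw <- deshkit:::clf_forward(params, x, dims, cov, cfg, want_cache = TRUE)
  dlogits <- fw$p; dlogits[2] <- dlogits[2] - 1
  grads <- deshkit:::clf_backward(params, fw, dlogits, cfg)
  for (pn in c("b1_W", "se1_W1", "emb_W", "fc1_W", "fc2_b")) {
    idx <- 1
    h <- 1e-3
    pp <- params; pp[[pn]][idx] <- pp[[pn]][idx] + h
    pm <- params; pm[[pn]][idx] <- pm[[pn]][idx] - h
    num <- (loss_of(pp) - loss_of(pm)) / (2 * h)
    expect_equal(grads[[pn]][idx], num, tolerance = 0.05,
                 label = paste("gradient of", pn))
  }
})
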