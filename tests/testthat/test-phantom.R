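test_that("phenotype flags enforce the DESH definition", {
  expect_error(phenotype_flags(desh = TRUE, thc = FALSE, sfd = TRUE),
               "THC and SFD")
  expect_error(phenotype_flags(desh = TRUE, thc = TRUE, sfd = FALSE),
               "THC and SFD")
  ok <- phenotype_flags(desh = TRUE, vd = FALSE, thc = TRUE, sfd = TRUE)
  expect_true(ok$desh)
})

test_that("targets are seeded, phenotype-calibrated draws", {
  desh <- phenotype_flags(TRUE, TRUE, TRUE, TRUE)
  norm <- phenotype_flags()
  t1 <- phenotype_to_targets(desh, 75, 11)
  t2 <- phenotype_to_targets(desh, 75, 11)
  expect_identical(t1, t2)
  expect_false(identical(t1, phenotype_to_targets(desh, 75, 12)))

  # marginal calibration: sample means approach the table means/SDs
  vent_desh <- vapply(1:300, function(s)
    phenotype_to_targets(desh, 75, s)$total_ventricles_ml, 0)
  hc_norm <- vapply(1:300, function(s)
    phenotype_to_targets(norm, 55, s)$high_convexity_sas_ml, 0)
  expect_lt(abs(mean(vent_desh) - 129.2), 6)    # mean 129.2, SD 35.1
  expect_lt(abs(sd(vent_desh) - 35.1), 6)
  expect_lt(abs(mean(hc_norm) - 42.5), 2.5)     # mean 42.5, SD 12.1
  expect_gt(min(vent_desh), 0)

  # T2 calibration column differs
  t2like <- phenotype_to_targets(desh, 75, 11, contrast = "T2_like")
  expect_false(identical(t1$total_ventricles_ml, t2like$total_ventricles_ml))
})

test_that("phantom spec validates grid, spacing and targets", {
  ph <- phenotype_flags()
  expect_error(phantom_spec(grid_shape = c(16, 64, 64), phenotype = ph),
               "at least 32")
  expect_error(phantom_spec(voxel_size_mm = c(0, 1, 1), phenotype = ph),
               "positive")
})

test_that("realized compartment volumes match targets within 5%", {
  for (desh in c(TRUE, FALSE)) {
    s <- get_phantom(desh = desh, seed = 1)
    tg <- s$spec$targets
    for (k in c("total_ventricles_ml", "sylvian_basal_ml",
                "high_convexity_sas_ml", "other_sas_ml")) {
      rel <- abs(s$true_volumes[[k]] - tg[[k]]) / tg[[k]]
      expect_lt(rel, 0.05)
    }
  }
})

test_that("labels partition the grid and true volumes come from counting", {
  s <- get_phantom(desh = TRUE, seed = 1)
  counts <- table(factor(as.vector(s$labelmap$data), levels = 0:5))
  expect_equal(sum(counts), prod(dim(s$labelmap$data)))
  expect_true(all(counts[c("2", "3", "4", "5")] > 0))
  expect_equal(s$true_volumes$total_ventricles_ml,
               sum(s$labelmap$data == 2) * prod(s$labelmap$voxel_size_mm) / 1000)
})

test_that("rendering is bit-identical under a fixed seed", {
  ph <- phenotype_flags(TRUE, TRUE, TRUE, TRUE)
  tg <- phenotype_to_targets(ph, 70, 9)
  sp <- phantom_spec(phenotype = ph, targets = tg, seed = 9)
  a <- render_phantom(sp); b <- render_phantom(sp)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$labelmap$data, b$labelmap$data)
  expect_identical(a$landmarks, b$landmarks)
})

test_that("contrast renders CSF dark on T1-like, bright on T2-like", {
  ph <- phenotype_flags(TRUE, TRUE, TRUE, TRUE)
  tg <- phenotype_to_targets(ph, 70, 4)
  t1 <- render_phantom(phantom_spec(phenotype = ph, targets = tg,
                                    contrast = "T1_like", seed = 4))
  tg2 <- phenotype_to_targets(ph, 70, 4, contrast = "T2_like")
  t2 <- render_phantom(phantom_spec(phenotype = ph, targets = tg2,
                                    contrast = "T2_like", seed = 4))
  csf1 <- mean(t1$volume$data[t1$labelmap$data == 2])
  par1 <- mean(t1$volume$data[t1$labelmap$data == 1])
  csf2 <- mean(t2$volume$data[t2$labelmap$data == 2])
  par2 <- mean(t2$volume$data[t2$labelmap$data == 1])
  expect_lt(csf1, par1)
  expect_gt(csf2, par2)
})

test_that("unachievable targets fail loudly", {
  ph <- phenotype_flags()
  tg <- phenotype_to_targets(ph, 50, 1)
  tg$total_ventricles_ml <- 5000  # larger than the cranial interior
  expect_error(render_phantom(phantom_spec(phenotype = ph, targets = tg)),
               "unachievable")
})

test_that("cohorts hit the requested DESH count and are reproducible", {
  co <- get_cohort(20, 0.25, seed = 3)
  expect_equal(sum(co$manifest$desh), 5)
  expect_equal(nrow(co$manifest), 20)
  co2 <- sample_cohort(20, 0.25, seed = 3)
  expect_identical(co$manifest, co2$manifest)
  expect_identical(co$subjects[[7]]$volume$data, co2$subjects[[7]]$volume$data)

  solo <- sample_cohort(1, 0, seed = 1)
  expect_false(solo$manifest$desh)
  # isolated non-DESH flags are rare: none across a small cohort majority
  expect_lt(mean(unlist(get_cohort(20, 0.25, seed = 3)$manifest[
    !get_cohort(20, 0.25, seed = 3)$manifest$desh, c("vd", "thc", "sfd")])),
    0.25)

  tiny <- sample_cohort(2, 0.1, seed = 1)
  expect_match(attr(tiny$manifest, "warning"), "rounds to zero")
})

test_that("DESH phantoms have larger ventricles and older ages", {
  co <- get_cohort(20, 0.25, seed = 3)
  m <- co$manifest
  expect_gt(min(m$total_ventricles_ml[m$desh]),
            mean(m$total_ventricles_ml[!m$desh]))
  expect_gt(mean(m$age_years[m$desh]), mean(m$age_years[!m$desh]))
  # Venthi separation from true volumes: every DESH above every non-DESH
  venthi <- m$total_ventricles_ml / m$high_convexity_sas_ml
  expect_gt(min(venthi[m$desh]), max(venthi[!m$desh]))
})

test_that("cohort export writes NIfTI, landmarks and manifest", {
  d <- withr::local_tempdir()
  co <- sample_cohort(2, 0.5, seed = 2, grid_shape = c(32, 32, 32),
                      voxel_size_mm = 5, out_dir = d)
  expect_true(file.exists(file.path(d, "manifest.csv")))
  man <- read.csv(file.path(d, "manifest.csv"))
  expect_equal(nrow(man), 2)
  lab <- read_labelmap(man$labelmap_path[1])
  expect_identical(lab$data, co$subjects[[1]]$labelmap$data)
  lm <- read_landmarks(man$landmarks_path[1])
  expect_equal(lm$ac_mm, co$subjects[[1]]$landmarks$ac_mm)
})

test_that("targets-level phenotype separation holds at cohort scale", {
  desh <- phenotype_flags(TRUE, TRUE, TRUE, TRUE)
  norm <- phenotype_flags()
  venthi_d <- vapply(1:100, function(s) {
    tg <- phenotype_to_targets(desh, 75, s)
    tg$total_ventricles_ml / tg$high_convexity_sas_ml
  }, 0)
  venthi_n <- vapply(101:200, function(s) {
    tg <- phenotype_to_targets(norm, 55, s)
    tg$total_ventricles_ml / tg$high_convexity_sas_ml
  }, 0)
  expect_gt(min(venthi_d), max(venthi_n))
})
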