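# Shared fixtures: small phantoms are expensive enough to build once per
# test run and reuse across tests.

fixture_env <- new.env()

get_phantom <- function(desh = TRUE, seed = 1L, contrast = "T1_like",
                        grid = c(64L, 64L, 64L), vox = c(2.5, 2.5, 2.5)) {
  key <- paste("ph", desh, seed, contrast, paste(grid, collapse = "x"),
               paste(vox, collapse = "x"), sep = "-")
  if (is.null(fixture_env[[key]])) {
    ph <- if (desh) phenotype_flags(TRUE, TRUE, TRUE, TRUE)
          else phenotype_flags()
    age <- if (desh) 75 else 50
    tg <- phenotype_to_targets(ph, age, seed, contrast)
    fixture_env[[key]] <- render_phantom(
      phantom_spec(grid, vox, ph, tg, contrast, seed = seed), age)
  }
  fixture_env[[key]]
}

get_cohort <- function(n, desh_fraction = 0.25, seed = 1L, ...) {
  key <- paste("co", n, desh_fraction, seed, sep = "-")
  if (is.null(fixture_env[[key]]))
    fixture_env[[key]] <- sample_cohort(n, desh_fraction, seed = seed, ...)
  fixture_env[[key]]
}

# brute-force smoothed Dice over explicit voxel loops (independent oracle)
dice_oracle <- function(x, y, epsilon = 1e-4) {
  nx <- dim(x)[1]; ny <- dim(x)[2]; nz <- dim(x)[3]
  inter <- 0; sx <- 0; sy <- 0
  for (i in seq_len(nx)) for (j in seq_len(ny)) for (k in seq_len(nz)) {
    a <- x[i, j, k] != 0; b <- y[i, j, k] != 0
    if (a && b) inter <- inter + 1
    if (a) sx <- sx + 1
    if (b) sy <- sy + 1
  }
  (2 * inter + epsilon) / (sx + sy + epsilon)
}

# brute-force AUC: concordant pairs + half ties over all (pos, neg) pairs
auc_oracle <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# exhaustive Youden scan over every candidate cut (positive: score >= t)
youden_oracle <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  best <- -Inf; best_t <- NA
  for (t in cand) {
    sens <- mean(scores[labels] >= t)
    spec <- mean(scores[!labels] < t)
    if (sens + spec > best + 1e-12) { best <- sens + spec; best_t <- t }
  }
  list(threshold = best_t, youden = best)
}

# Independent per-voxel evaluator of the four high-convexity predicates.
hc_oracle <- function(sas, lm, vox, origin = c(0, 0, 0), lateral = 30) {
  dims <- dim(sas)
  out <- array(FALSE, dims)
  a <- lm$ac_mm - lm$pc_mm; a <- a / sqrt(sum(a^2))
  tg <- sum((lm$genu_front_mm - lm$ac_mm) * a)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      if (!sas[i, j, k]) next
      p <- origin + (c(i, j, k) - 1) * vox
      tt <- sum((p - lm$ac_mm) * a)
      keep <- p[3] >= lm$ventricle_body_top_z_mm &&
        abs(sum((p - lm$midsagittal_point_mm) * lm$midsagittal_normal)) <= lateral &&
        tt <= tg && tt >= lm$callosomarginal_posterior_mm
      out[i, j, k] <- keep
    }
  out
}

test_lm <- function() {
  desh_landmarks(ac_mm = c(20, 26, 18), pc_mm = c(20, 14, 18),
                 midsagittal_point_mm = c(20, 20, 20),
                 midsagittal_normal = c(1, 0, 0),
                 genu_front_mm = c(20, 33, 20),
                 ventricle_body_top_z_mm = 22,
                 callosomarginal_posterior_mm = -20)
}


with_seed <- deshkit:::with_seed
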