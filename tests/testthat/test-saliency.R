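test_that("featureless images produce a null saliency map", {
  m <- compute_saliency_map(matrix(0.5, 256, 256))
  expect_true(all(m$map >= 0))
  expect_lt(max(m$map), 1e-9)
})

test_that("a unique contrast source wins the map and symmetry is respected", {
  v <- seq(-1, 1, length.out = 256)
  xx <- matrix(v, 256, 256, byrow = TRUE); yy <- matrix(v, 256, 256)
  disc <- ifelse((xx + 0.4)^2 + (yy - 0.3)^2 < 0.04, 0.95, 0.1)
  m <- compute_saliency_map(disc)$map
  am <- which(m == max(m), arr.ind = TRUE)[1, ]
  expect_true((xx[am[1], am[2]] + 0.4)^2 + (yy[am[1], am[2]] - 0.3)^2 < 0.04)

  # two mirror-placed discs activate equally (1% discretization tolerance)
  two <- 0.1 + 0.8 * (((xx - 0.5)^2 + yy^2 < 0.03) |
                      ((xx + 0.5)^2 + yy^2 < 0.03))
  m2 <- compute_saliency_map(two)$map
  left <- sum(m2[, 1:128]); right <- sum(m2[, 129:256])
  expect_lt(abs(left - right) / max(left, right), 0.01)
})

test_that("saliency map input validation rejects bad rasters", {
  expect_error(compute_saliency_map(matrix(0.5, 32, 32)), "too small")
  bad <- matrix(0.5, 256, 256); bad[1] <- NA
  expect_error(compute_saliency_map(bad), "NA")
  expect_error(compute_saliency_map(matrix(1.5, 256, 256)), "\\[0, 1\\]")
})

test_that("nine identical patches give saliency index 1", {
  pp <- patch_set(1, "neutral", seed = 3)[[1]]
  disp <- generate_display(grid_layout(jitter = 0, target_slot = 5),
                           rep(list(pp), 9), rng_seed = 1)
  # regions are pixel-identical
  r <- disp$layout$rects
  patch1 <- disp$image[r$row0[1]:r$row1[1], r$col0[1]:r$col1[1]]
  patch9 <- disp$image[r$row0[9]:r$row1[9], r$col0[9]:r$col1[9]]
  expect_identical(patch1, patch9)
  si <- saliency_index(compute_saliency_map(disp$image), disp$layout)
  expect_equal(si$saliency_index, 1, tolerance = 0.01)
})

test_that("constructed activations give exact index ratios", {
  # build a map by hand: target rectangle carries double each distractor sum
  lay <- grid_layout(raster_size = 192, patch_size = 48, jitter = 0,
                     target_slot = 1)
  m <- matrix(0, 192, 192)
  r <- lay$rects
  for (s in 1:9) m[r$row0[s]:r$row1[s], r$col0[s]:r$col1[s]] <- if (s == 1) 2 else 1
  si <- saliency_index(m, lay)
  expect_equal(si$saliency_index, 2)
  lay_na <- grid_layout(target_slot = NA)
  expect_error(saliency_index(m, lay_na), "no target slot")
})

test_that("a high-contrast target is more salient than its distractors", {
  distr <- patch_set(8, "neutral", contrast = 0.6, seed = 2)
  tgt <- patch_set(1, "angry", contrast = 1.8, seed = 9)[[1]]
  params <- vector("list", 9)
  params[setdiff(1:9, 3)] <- distr
  params[[3]] <- tgt
  disp <- generate_display(grid_layout(target_slot = 3), params, rng_seed = 4)
  si <- saliency_index(compute_saliency_map(disp$image), disp$layout)
  expect_gt(si$saliency_index, 1)
})

test_that("saliency index is stable under global intensity rescaling", {
  distr <- patch_set(8, "neutral", seed = 5)
  tgt <- patch_set(1, "happy", contrast = 1.5, seed = 6)[[1]]
  params <- vector("list", 9)
  params[setdiff(1:9, 7)] <- distr
  params[[7]] <- tgt
  disp <- generate_display(grid_layout(target_slot = 7), params, rng_seed = 8)
  i1 <- saliency_index(compute_saliency_map(disp$image), disp$layout)$saliency_index
  i2 <- saliency_index(compute_saliency_map(disp$image * 0.55), disp$layout)$saliency_index
  expect_equal(i2, i1, tolerance = 0.02)
})

test_that("display generation is deterministic, jitter-bounded and overlap-free", {
  params <- patch_set(9, "neutral", seed = 10)
  d1 <- generate_display(small_layout(target_slot = 2), params, rng_seed = 3)
  d2 <- generate_display(small_layout(target_slot = 2), params, rng_seed = 3)
  expect_identical(d1$image, d2$image)
  # zero jitter puts patch centers exactly on the regular grid
  d0 <- generate_display(small_layout(target_slot = 2, jitter = 0L), params,
                         rng_seed = 3)
  lay <- small_layout(target_slot = 2, jitter = 0L)
  expect_identical(d0$layout$rects[, c("row0", "col0")],
                   lay$rects[, c("row0", "col0")])
  # layouts that cannot fit overlap-free placements error out
  big <- grid_layout(raster_size = 192, patch_size = 62, jitter = 20)
  expect_error(generate_display(big, params, rng_seed = 1), "non-overlapping")
})

test_that("target slots are drawn uniformly across simulation replicates", {
  ang <- patch_set(4, "angry", seed = 11)
  neu <- patch_set(10, "neutral", seed = 13)
  sim <- run_salience_simulation(list(angry = ang, happy = ang), neu,
                                 n_reps_per_emotion = 135,
                                 layout = small_layout(), rng_seed = 5,
                                 n_boot = 200)
  tab <- table(factor(sim$results$target_slot, levels = 1:9))
  p <- chisq.test(tab)$p.value
  expect_gt(p, 0.001)
  # deterministic given the seed
  sim2 <- run_salience_simulation(list(angry = ang, happy = ang), neu,
                                  n_reps_per_emotion = 10,
                                  layout = small_layout(), rng_seed = 9,
                                  n_boot = 50)
  sim3 <- run_salience_simulation(list(angry = ang, happy = ang), neu,
                                  n_reps_per_emotion = 10,
                                  layout = small_layout(), rng_seed = 9,
                                  n_boot = 50)
  expect_identical(sim2$results, sim3$results)
})

test_that("motion metric matches closed-form single-block perturbations", {
  f <- matrix(0.5, 200, 200)
  g <- f; g[1:20, 1:20] <- g[1:20, 1:20] + 0.1
  expect_equal(image_motion(f, f), 0)
  expect_equal(image_motion(f, g), 0.1 * 400)
  expect_equal(image_motion(g, f), image_motion(f, g))
  expect_equal(image_motion(f, g, normalize = TRUE), 40 / 100)
  expect_error(image_motion(f, matrix(0.5, 100, 100)), "identical dimensions")
  expect_error(image_motion(matrix(0.5, 30, 30), matrix(0.5, 30, 30)), "divisible")
})

test_that("motion metric satisfies symmetry and the triangle bound on random frames", {
  set.seed(17)
  for (i in 1:8) {
    a <- matrix(runif(3600), 60, 60)
    b <- matrix(runif(3600), 60, 60)
    c <- matrix(runif(3600), 60, 60)
    mab <- image_motion(a, b); mbc <- image_motion(b, c); mac <- image_motion(a, c)
    expect_equal(mab, image_motion(b, a))
    expect_lte(mac, mab + mbc + 1e-9)
  }
})

test_that("display PNG output round-trips with its layout sidecar", {
  params <- patch_set(9, "neutral", seed = 20)
  disp <- generate_display(small_layout(target_slot = 4), params, rng_seed = 2)
  png <- tempfile(fileext = ".png")
  write_display(disp, png)
  expect_true(file.exists(png))
  side <- jsonlite::read_json(sub("\\.png$", ".json", png), simplifyVector = TRUE)
  expect_equal(side$target_slot, 4)
  expect_equal(nrow(side$rects), 9)
  img <- EBImage::readImage(png)
  expect_equal(dim(img)[1:2], c(192, 192))
  unlink(c(png, sub("\\.png$", ".json", png)))
})
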