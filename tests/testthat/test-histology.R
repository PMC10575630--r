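# Detector checks on phantoms with exact ground truth. Smaller images than
# the full phantom defaults keep the suite fast; scales are unchanged.

straight_tube <- function(len_um = 300, n_boutons = 6, image_size = 512,
                          seed = 1, pixel_size = 0.65) {
  npx <- ceiling(len_um / pixel_size)
  row0 <- image_size / 2
  path <- cbind(row = rep(row0, npx + 1), col = 15 + 0:npx)
  pos <- seq(len_um * 0.05, len_um * 0.95, length.out = n_boutons)
  sp <- phantom_spec(image_size = image_size, pixel_size = pixel_size,
                     seed = seed)
  ph <- render_histology(list(path), list(pos), sp)
  roi <- matrix(FALSE, image_size, image_size)
  roi[(row0 - 12):(row0 + 12), 5:(image_size - 5)] <- TRUE
  list(ph = ph, roi = roi, len = len_um, n = n_boutons)
}

test_that("planted boutons are recovered exactly with sub-pixel centers", {
  tb <- straight_tube(seed = 3)
  bd <- detect_boutons(tb$ph$green, 0.65, roi = tb$roi)
  expect_equal(bd$count, tb$n)
  truth <- tb$ph$ground_truth$bouton_centers
  for (i in seq_len(nrow(truth))) {
    d <- sqrt((bd$centers[, 1] - truth[i, 1])^2 +
                (bd$centers[, 2] - truth[i, 2])^2)
    expect_lt(min(d), 1)
  }
  # blank noisy image: no false positives
  blank <- simulate_histology(phantom_spec(n_axons = 0, image_size = 256,
                                           seed = 5))
  expect_equal(detect_boutons(blank$green, 0.65)$count, 0)
  expect_error(detect_boutons(blank$green, 0.65,
                              roi = matrix(FALSE, 256, 256)), "ROI")
})

test_that("blobs closer than the separation rule merge into one", {
  # boutons alone on an invisible centerline, so only blob merging is
  # in play
  sp <- phantom_spec(image_size = 128, axon_intensity = 0, seed = 1)
  path <- cbind(row = rep(64, 101), col = 14:114)
  sigma_um <- 0.5
  # two boutons 1 sigma apart at arc position ~32.5 um
  ph <- render_histology(list(path), list(c(32.5, 32.5 + sigma_um)), sp)
  bd <- detect_boutons(ph$green, 0.65)
  expect_equal(bd$count, 1)
})

test_that("axon skeleton length is accurate and rotation-invariant", {
  tb <- straight_tube(seed = 2)
  ax <- detect_axons(tb$ph$red, 0.65, roi = tb$roi)
  expect_lt(abs(ax$length_um - tb$len) / tb$len, 0.05)
  # 45-degree tube
  n <- 400
  pd <- cbind(row = 70 + (0:n) * 0.7071, col = 70 + (0:n) * 0.7071)
  phd <- render_histology(list(pd), list(numeric(0)),
                          phantom_spec(image_size = 420, seed = 6))
  axd <- detect_axons(phd$red, 0.65)
  truth <- n * 0.7071 * sqrt(2) * 0.65
  expect_lt(abs(axd$length_um - truth) / truth, 0.05)
  # blank image: essentially zero length
  blank <- simulate_histology(phantom_spec(n_axons = 0, image_size = 256,
                                           seed = 7))
  expect_lt(detect_axons(blank$red, 0.65)$length_um, 5)
})

test_that("skeletonization yields one-pixel-wide subsets of the mask", {
  m <- matrix(0, 40, 40); m[18:22, 5:35] <- 1
  sk <- skeletonize(m)
  expect_true(all(m[sk] == 1))
  # a single one-pixel-wide contiguous line (thinning trims a few end
  # pixels of the rectangle)
  occ <- which(colSums(sk) > 0)
  expect_true(all(colSums(sk)[occ] == 1))
  expect_identical(occ, occ[1]:occ[length(occ)])
  expect_gte(length(occ), 25)
  expect_equal(skeleton_length(sk, 1), sum(sk) - 1)
})

test_that("cell counting is accurate and gain-invariant", {
  cf <- simulate_cell_field(15, image_size = 400, seed = 3)
  n1 <- count_cells(cf$image, 0.65)
  expect_lte(abs(n1 - 15), 1)
  n2 <- count_cells(cf$image * 2.5, 0.65)
  expect_equal(as.integer(n2), as.integer(n1))
  # an empty noise-free field has no blobs at all
  blank <- simulate_cell_field(0, image_size = 128, background_sd = 0,
                               seed = 1)
  expect_equal(as.integer(count_cells(blank$image, 0.65)), 0)
})

test_that("detected bouton counts scale linearly with planted density", {
  dens <- c(2, 4, 6, 8, 10)
  counts <- sapply(seq_along(dens), function(i) {
    sum(sapply(1:2, function(s) {   # two sections per density point
      ph <- simulate_histology(
        phantom_spec(n_axons = 3, image_size = 384,
                     bouton_density_per_100um = dens[i],
                     seed = 30 + 10 * s + i))
      detect_boutons(ph$green, 0.65)$count
    }))
  })
  fit <- lm(counts ~ dens)
  expect_gt(summary(fit)$r.squared, 0.95)
})

test_that("density doubling doubles detections within Poisson error", {
  n1 <- detect_boutons(simulate_histology(
    phantom_spec(n_axons = 3, image_size = 384, bouton_density_per_100um = 3,
                 seed = 41))$green, 0.65)$count
  n2 <- detect_boutons(simulate_histology(
    phantom_spec(n_axons = 3, image_size = 384, bouton_density_per_100um = 6,
                 seed = 41))$green, 0.65)$count
  expect_lt(abs(n2 - 2 * n1), 4 * sqrt(n2 + 4 * n1))
})

test_that("innervation metrics normalize counts, lengths and controls", {
  m <- innervation_metrics(50, 1000, 10)
  expect_equal(m$boutons_per_100um, 5)
  expect_equal(m$axon_len_per_cell, 100)
  ctrl <- list(boutons_per_100um = 5, axon_len_per_cell = 100)
  m2 <- innervation_metrics(50, 1000, 10, control_means = ctrl)
  expect_equal(m2$pct_of_control$boutons_per_100um, 100)
  expect_error(innervation_metrics(50, 1000, 0), "n_cells")
  expect_error(innervation_metrics(10, 0, 5), "zero axon length")
})

test_that("detections are invariant to affine intensity changes", {
  tb <- straight_tube(seed = 4)
  img <- tb$ph$green
  bd1 <- detect_boutons(img, 0.65, roi = tb$roi)
  bd2 <- detect_boutons(2.4 * img + 17, 0.65, roi = tb$roi)
  expect_equal(bd2$count, bd1$count)
  ax1 <- detect_axons(tb$ph$red, 0.65, roi = tb$roi)
  ax2 <- detect_axons(1.8 * tb$ph$red + 40, 0.65, roi = tb$roi)
  expect_equal(ax2$length_um, ax1$length_um, tolerance = 0.02)
})
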