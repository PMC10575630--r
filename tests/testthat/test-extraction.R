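test_that("dF/F0 is zero-mean per pixel and flags dead pixels", {
  const <- array(7, c(4, 4, 10))
  expect_true(all(compute_dff(const)$dff == 0))
  m <- array(10, c(2, 2, 5))
  m[1, 1, 3] <- 20   # F0 = 12; (20-12)/12
  d <- compute_dff(m)
  expect_equal(d$dff[1, 1, 3], (20 - 12) / 12)
  expect_lt(max(abs(apply(d$dff, c(1, 2), mean))), 1e-12)
  dead <- array(1, c(2, 2, 4)); dead[2, 2, ] <- 0
  expect_warning(dd <- compute_dff(dead), "F0")
  expect_true(all(dd$dff[2, 2, ] == 0))
})

test_that("block-mean downsampling pools correctly", {
  m <- array(3, c(8, 8, 2))
  expect_equal(dim(downsample_movie(m, 4)), c(2, 2, 2))
  expect_true(all(downsample_movie(m, 4) == 3))
  chk <- array(0, c(8, 8, 1))
  chk[, , 1] <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  expect_true(all(downsample_movie(chk, 2) == 0.5))
  expect_identical(downsample_movie(m, 1), m)
  expect_error(downsample_movie(m, 0), "factor")
  # trailing partial blocks dropped
  m9 <- array(1, c(9, 9, 1))
  expect_equal(dim(downsample_movie(m9, 4)), c(2, 2, 1))
})

test_that("PCA/ICA recovers planted sources with high trace fidelity", {
  pm <- planted_movie(n_src = 3)
  dff <- compute_dff(pm$movie)
  cc <- pca_ica(dff, n_pcs = 9, seed = 1)
  sel <- select_components(cc, vessel_mask = vessel_mask_from_f0(dff$f0))
  acc <- attr(sel, "accepted_idx")
  expect_equal(length(acc), 3)
  cors <- sapply(acc, function(i)
    max(cor(extract_trace(dff, sel[[i]])$dff, pm$traces)))
  expect_true(all(cors > 0.99))
  # each recovered filter peaks inside a true footprint
  for (i in acc) {
    pk <- which(sel[[i]]$spatial == max(sel[[i]]$spatial), arr.ind = TRUE)[1, ]
    d <- sqrt(rowSums((pm$footprints$centers -
                         matrix(pk, 3, 2, byrow = TRUE))^2))
    expect_lt(min(d), 2)
  }
  expect_error(pca_ica(dff, n_pcs = 1e6), "n_pcs")
})

test_that("decomposition is invariant under intensity rescaling", {
  pm <- planted_movie(n_src = 2, n_frames = 400)
  d1 <- compute_dff(pm$movie)
  d2 <- compute_dff(pm$movie * 3)   # dF/F0 unchanged by gain
  c1 <- select_components(pca_ica(d1, n_pcs = 6, seed = 2))
  c2 <- select_components(pca_ica(d2, n_pcs = 6, seed = 2))
  a1 <- attr(c1, "accepted_idx"); a2 <- attr(c2, "accepted_idx")
  expect_equal(length(a1), length(a2))
  cm <- abs(cor(sapply(c1[a1], `[[`, "temporal"),
                sapply(c2[a2], `[[`, "temporal")))
  expect_true(all(apply(cm, 1, max) > 0.999))
})

test_that("pure-noise movies produce no accepted components", {
  mv <- render_movie(array(0, c(32, 32, 1)), matrix(0, 500, 1),
                     baseline = 100, noise_sd = 1, seed = 9)
  cc <- suppressWarnings(pca_ica(compute_dff(mv), n_pcs = 5, seed = 1))
  sel <- select_components(cc)
  expect_equal(length(attr(sel, "accepted_idx")), 0)
  expect_true(all(sapply(sel, `[[`, "reject_reason") == "low_skewness"))
})

test_that("selection applies skewness and vessel rules with reasons", {
  dim_hw <- c(20, 20)
  mk <- function(spatial, temporal) {
    structure(list(list(spatial = spatial, temporal = temporal,
                        skewness = mesoframe:::skewness_adj(temporal),
                        accepted = NA, reject_reason = "none")),
              class = "neuron_components", dim_hw = dim_hw)
  }
  set.seed(1)
  spiky <- kernel_trace(500, c(100, 300))
  flat_sp <- matrix(abs(rnorm(400)), 20, 20)
  # low-skewness temporal signal
  low <- mk(flat_sp, rnorm(500))
  expect_equal(select_components(low)[[1]]$reject_reason, "low_skewness")
  # high skewness, filter centered on a vessel
  sp <- matrix(0, 20, 20); sp[8:12, 8:12] <- 1
  vm <- matrix(FALSE, 20, 20); vm[8:12, 8:12] <- TRUE
  hit <- select_components(mk(sp, spiky), vessel_mask = vm)
  expect_equal(hit[[1]]$reject_reason, "vessel_overlap")
  clear <- select_components(mk(sp, spiky),
                             vessel_mask = matrix(FALSE, 20, 20))
  expect_true(clear[[1]]$accepted)
})

test_that("rejection rules are order-independent", {
  pm <- planted_movie(n_src = 3)
  dff <- compute_dff(pm$movie)
  cc <- pca_ica(dff, n_pcs = 9, seed = 1)
  sel1 <- select_components(cc)
  rev_cc <- structure(rev(unclass(cc)), class = "neuron_components",
                      dim_hw = attr(cc, "dim_hw"))
  sel2 <- select_components(rev_cc)
  expect_equal(rev(sapply(sel2, `[[`, "accepted")),
               sapply(sel1, `[[`, "accepted"))
})

test_that("donut subtraction removes shared background", {
  H <- 30; W <- 30; T. <- 300
  s_t <- kernel_trace(T., c(50, 180))
  b_t <- 0.3 * sin(seq_len(T.) / 10)       # shared contamination
  sp <- matrix(0, H, W); sp[14:17, 14:17] <- 1
  arr <- array(rep(b_t, each = H * W), c(H, W, T.))  # background everywhere
  for (t in seq_len(T.)) arr[, , t] <- arr[, , t] + sp * s_t[t]
  tr <- extract_trace(arr, sp)
  expect_gt(cor(tr$dff, s_t), 0.999)
  expect_lt(max(abs(tr$dff - s_t)), 0.05)
  expect_false(any(tr$soma_mask & tr$annulus_mask))
  # empty annulus falls back with a warning
  tiny <- matrix(1, 5, 5)
  expect_warning(extract_trace(array(0, c(5, 5, 10)), tiny), "annulus")
})
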