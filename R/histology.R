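# Histology quantification: Laplacian-of-Gaussian bouton/cell detection,
# Hessian ridge detection with skeletonization for axons, and the
# normalized innervation metrics.

# Zero-padded matrix shift by (dr, dc).
shift_mat <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

gaussian_smooth <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  as.matrix(EBImage::gblur(img, sigma = sigma_px))
}

# Scale-normalized negative Laplacian-of-Gaussian response (bright blobs
# give positive peaks).
log_response <- function(img, sigma_px) {
  g <- gaussian_smooth(img, sigma_px)
  lap <- shift_mat(g, 1, 0) + shift_mat(g, -1, 0) +
    shift_mat(g, 0, 1) + shift_mat(g, 0, -1) - 4 * g
  -sigma_px^2 * lap
}

# Ridge strength: negative smaller Hessian eigenvalue of the smoothed
# image (signed; bright tubular structures are strongly positive).
ridge_strength <- function(img, sigma_px) {
  g <- gaussian_smooth(img, sigma_px)
  gxx <- shift_mat(g, 1, 0) + shift_mat(g, -1, 0) - 2 * g
  gyy <- shift_mat(g, 0, 1) + shift_mat(g, 0, -1) - 2 * g
  gxy <- (shift_mat(g, 1, 1) + shift_mat(g, -1, -1) -
            shift_mat(g, 1, -1) - shift_mat(g, -1, 1)) / 4
  disc <- sqrt((gxx - gyy)^2 + 4 * gxy^2)
  lam_min <- (gxx + gyy - disc) / 2
  -sigma_px^2 * lam_min
}

# Local maxima of a response image (8-neighborhood, strictly greater than
# at least one side to survive plateaus).
local_maxima <- function(r) {
  ge <- r >= pmax(shift_mat(r, 1, 0), shift_mat(r, -1, 0),
                  shift_mat(r, 0, 1), shift_mat(r, 0, -1),
                  shift_mat(r, 1, 1), shift_mat(r, 1, -1),
                  shift_mat(r, -1, 1), shift_mat(r, -1, -1))
  gt <- r > pmin(shift_mat(r, 1, 0), shift_mat(r, -1, 0),
                 shift_mat(r, 0, 1), shift_mat(r, 0, -1))
  ge & gt
}

# Interior mask excluding a border band where finite-difference filters
# see the zero padding.
interior_mask <- function(dim_hw, border) {
  m <- matrix(FALSE, dim_hw[1L], dim_hw[2L])
  if (dim_hw[1L] > 2 * border && dim_hw[2L] > 2 * border)
    m[(border + 1L):(dim_hw[1L] - border),
      (border + 1L):(dim_hw[2L] - border)] <- TRUE
  m
}

# Shared blob detector behind detect_boutons and count_cells.
detect_blobs <- function(img, pixel_size, sigma_um, thresh_sd, roi,
                         min_sep_factor = 2) {
  stopifnot(pixel_size > 0)
  if (is.null(roi)) roi <- matrix(TRUE, nrow(img), ncol(img))
  if (!any(roi)) stop("empty ROI", call. = FALSE)
  sigma_px <- max(sigma_um / pixel_size, 0.8)
  roi <- roi & interior_mask(dim(img), ceiling(3 * sigma_px) + 2L)
  r <- log_response(img, sigma_px)
  bg_med <- stats::median(r[roi])
  bg_sd <- stats::mad(r[roi])
  thr <- bg_med + thresh_sd * bg_sd
  cand <- which(local_maxima(r) & roi & r > thr, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(list(centers = cbind(x = numeric(0), y = numeric(0)),
                count = 0L, response = r, threshold = thr))
  ord <- order(r[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  min_sep <- min_sep_factor * sigma_px
  keep <- logical(nrow(cand))
  kept <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (nrow(kept) == 0L ||
        min(sqrt((kept[, 1] - p[1])^2 + (kept[, 2] - p[2])^2)) >= min_sep) {
      keep[i] <- TRUE
      kept <- rbind(kept, p)
    }
  }
  cand <- cand[keep, , drop = FALSE]
  # sub-pixel refinement: 1-D quadratic fit along rows and columns
  refine <- function(i) {
    rr <- cand[i, 1]; cc <- cand[i, 2]
    dr <- dc <- 0
    if (rr > 1 && rr < nrow(r)) {
      den <- r[rr - 1, cc] - 2 * r[rr, cc] + r[rr + 1, cc]
      if (den < 0) dr <- 0.5 * (r[rr - 1, cc] - r[rr + 1, cc]) / den
    }
    if (cc > 1 && cc < ncol(r)) {
      den <- r[rr, cc - 1] - 2 * r[rr, cc] + r[rr, cc + 1]
      if (den < 0) dc <- 0.5 * (r[rr, cc - 1] - r[rr, cc + 1]) / den
    }
    c(rr + max(min(dr, 0.5), -0.5), cc + max(min(dc, 0.5), -0.5))
  }
  ctr <- t(vapply(seq_len(nrow(cand)), refine, numeric(2)))
  list(centers = cbind(x = ctr[, 1], y = ctr[, 2]),
       count = nrow(ctr), response = r, threshold = thr)
}

#' Detect synaptic boutons as Laplacian blobs
#'
#' Boutons appear as compact bright puncta; they are detected as local
#' maxima of the Laplacian-of-Gaussian response at scale `log_sigma_um`
#' exceeding the robust background (median + `thresh_sd` x MAD-SD of the
#' response inside the ROI; default 5 SD), with a minimum separation of
#' 2 sigma and sub-pixel center refinement.
#'
#' @param img 2-D intensity image (the SypGFP/green channel).
#' @param pixel_size Microns per pixel.
#' @param log_sigma_um Blob scale, microns (default 0.5, for ~1 um
#'   boutons).
#' @param thresh_sd Threshold in background SDs (default 5).
#' @param roi Optional logical mask restricting the analysis region.
#' @return A list of class `bouton_detections`: `centers` (n x 2, row/col
#'   pixel coordinates), `count`, `threshold`.
#' @export
detect_boutons <- function(img, pixel_size, log_sigma_um = 0.5,
                           thresh_sd = 5, roi = NULL) {
  d <- detect_blobs(img, pixel_size, log_sigma_um, thresh_sd, roi)
  structure(list(centers = d$centers, count = d$count,
                 threshold = d$threshold),
            class = "bouton_detections")
}

#' Count labeled cells as Laplacian blobs
#'
#' Same detector as [detect_boutons()] but at soma scale and the 2-SD
#' threshold used for cell counting.
#'
#' @inheritParams detect_boutons
#' @param log_sigma_um Soma scale, microns (default 6).
#' @param thresh_sd Threshold in background SDs (default 2).
#' @return Integer count (with detection centers as attribute `centers`).
#' @export
count_cells <- function(img, pixel_size, log_sigma_um = 6,
                        thresh_sd = 2, roi = NULL) {
  d <- detect_blobs(img, pixel_size, log_sigma_um, thresh_sd, roi)
  structure(d$count, centers = d$centers)
}

#' Morphological thinning to a one-pixel skeleton
#'
#' Parallel Zhang-Suen thinning iterated to convergence, followed by a
#' sequential simple-point cleanup that removes the two-pixel diagonal
#' staircases the parallel algorithm can leave (deleting only pixels
#' whose removal preserves 8-connectivity and that are not endpoints).
#' Implemented in compiled code.
#'
#' @param mask Logical or 0/1 matrix.
#' @return Logical matrix of the same size.
#' @export
skeletonize <- function(mask) {
  m <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  .cpp_thin(m) > 0
}

# Remove spur branches shorter than max_len: walk in from each endpoint
# and delete the walked pixels if a junction is reached within max_len
# steps.
prune_spurs <- function(skel, max_len = 3L) {
  nb_count <- function(m) {
    shift_mat(m, 1, 0) + shift_mat(m, -1, 0) + shift_mat(m, 0, 1) +
      shift_mat(m, 0, -1) + shift_mat(m, 1, 1) + shift_mat(m, 1, -1) +
      shift_mat(m, -1, 1) + shift_mat(m, -1, -1)
  }
  m <- skel * 1L
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  cnt <- nb_count(m)
  ends <- which(m == 1L & cnt == 1L, arr.ind = TRUE)
  for (i in seq_len(nrow(ends))) {
    path <- list()
    cur <- ends[i, ]
    prev <- c(NA, NA)
    hit_junction <- FALSE
    for (step in seq_len(max_len)) {
      path[[step]] <- cur
      nb <- cbind(cur[1] + offs$dr, cur[2] + offs$dc)
      nb <- nb[nb[, 1] >= 1 & nb[, 1] <= nrow(m) &
                 nb[, 2] >= 1 & nb[, 2] <= ncol(m), , drop = FALSE]
      nb <- nb[m[nb] == 1L, , drop = FALSE]
      if (!is.na(prev[1]) && nrow(nb) > 0L) {
        nb <- nb[!(nb[, 1] == prev[1] & nb[, 2] == prev[2]), ,
                 drop = FALSE]
      }
      if (nrow(nb) == 0L) break            # isolated short fragment
      if (nrow(nb) > 1L || cnt[nb[1, 1], nb[1, 2]] >= 3L) {
        hit_junction <- TRUE
        break
      }
      prev <- cur
      cur <- nb[1, ]
    }
    if (hit_junction) for (p in path) m[p[1], p[2]] <- 0L
  }
  m > 0
}

#' Skeleton path length
#'
#' Sums unique 8-neighbor adjacencies: 1 pixel for horizontal/vertical
#' steps, sqrt(2) for diagonal steps, times `pixel_size`.
#'
#' @param skel Logical skeleton mask.
#' @param pixel_size Microns per pixel.
#' @return Length in microns.
#' @export
skeleton_length <- function(skel, pixel_size) {
  m <- skel * 1
  hv <- sum(m * shift_mat(m, 0, 1)) + sum(m * shift_mat(m, 1, 0))
  dg <- sum(m * shift_mat(m, 1, 1)) + sum(m * shift_mat(m, 1, -1))
  (hv + sqrt(2) * dg) * pixel_size
}

#' Detect axons as Hessian ridges and skeletonize
#'
#' Tubular (axonal) structure is scored by the negative smaller eigenvalue
#' of the image Hessian at scale `hessian_sigma_um`; pixels whose ridge
#' strength exceeds the robust background (median + `thresh_sd` x MAD-SD
#' within the ROI; default 2 SD) form the axon mask, which is thinned to
#' a one-pixel skeleton with spurs shorter than 3 px pruned. Length is
#' measured with [skeleton_length()]. A blank image returns a zero-length
#' skeleton.
#'
#' @param img 2-D intensity image (the tdTomato/red channel).
#' @param pixel_size Microns per pixel.
#' @param hessian_sigma_um Ridge scale, microns (default 0.75).
#' @param thresh_sd Threshold in background SDs (default 2).
#' @param roi Optional logical mask.
#' @param prune_px Maximum spur length removed (default 3).
#' @param min_object_px Connected components smaller than this are
#'   discarded as suprathreshold speckle before thinning (default 10).
#' @return A list of class `axon_skeleton`: `skeleton_mask`, `length_um`,
#'   `threshold`.
#' @export
detect_axons <- function(img, pixel_size, hessian_sigma_um = 0.75,
                         thresh_sd = 2, roi = NULL, prune_px = 3L,
                         min_object_px = 10L) {
  stopifnot(pixel_size > 0)
  if (is.null(roi)) roi <- matrix(TRUE, nrow(img), ncol(img))
  sigma_px <- max(hessian_sigma_um / pixel_size, 0.8)
  roi <- roi & interior_mask(dim(img), ceiling(3 * sigma_px) + 2L)
  r <- ridge_strength(img, sigma_px)
  thr <- stats::median(r[roi]) + thresh_sd * stats::mad(r[roi])
  mask <- r > thr & roi
  if (any(mask) && min_object_px > 1L) {
    # drop speckle: connected components smaller than min_object_px are
    # isolated suprathreshold noise, not axon segments
    lab <- EBImage::bwlabel(mask)
    sz <- tabulate(lab[lab > 0])
    mask <- lab > 0 & sz[pmax(lab, 1L)] >= min_object_px
  }
  if (any(mask)) {
    # 3x3 majority vote smooths the ragged threshold boundary so the
    # skeleton does not zig-zag (which would inflate the length)
    acc <- matrix(0, nrow(mask), ncol(mask))
    for (dr in -1:1) for (dc in -1:1)
      acc <- acc + shift_mat(mask * 1, dr, dc)
    mask <- acc > 4.5
  }
  if (!any(mask)) {
    return(structure(list(skeleton_mask = mask, length_um = 0,
                          threshold = thr),
                     class = "axon_skeleton"))
  }
  skel <- prune_spurs(skeletonize(mask), prune_px)
  structure(list(skeleton_mask = skel,
                 length_um = skeleton_length(skel, pixel_size),
                 threshold = thr),
            class = "axon_skeleton")
}

#' Normalized innervation metrics
#'
#' Per-animal metrics after pooling sections: bouton density normalized by
#' total axon length (`boutons_per_100um`), axon length normalized by the
#' dopamine cell count (`axon_len_per_cell`), and each optionally
#' expressed as percent of the control-group mean.
#'
#' @param bouton_count Total boutons across the animal's cortical
#'   sections.
#' @param axon_length_um Total axon skeleton length, microns (> 0 when
#'   boutons are present).
#' @param n_cells Total labeled midbrain cells across sections (> 0).
#' @param control_means Optional list with elements `boutons_per_100um`
#'   and/or `axon_len_per_cell` giving the control group means.
#' @return A list of class `innervation_metrics`.
#' @export
innervation_metrics <- function(bouton_count, axon_length_um, n_cells,
                                control_means = NULL) {
  if (n_cells <= 0) stop("n_cells must be > 0", call. = FALSE)
  if (axon_length_um <= 0 && bouton_count > 0)
    stop("zero axon length with nonzero boutons", call. = FALSE)
  bp100 <- if (axon_length_um > 0) bouton_count / axon_length_um * 100 else 0
  alpc <- axon_length_um / n_cells
  out <- list(n_cells = n_cells, axon_len_per_cell = alpc,
              boutons_per_100um = bp100)
  if (!is.null(control_means)) {
    out$pct_of_control <- list(
      boutons_per_100um = if (!is.null(control_means$boutons_per_100um))
        100 * bp100 / control_means$boutons_per_100um,
      axon_len_per_cell = if (!is.null(control_means$axon_len_per_cell))
        100 * alpc / control_means$axon_len_per_cell)
  }
  structure(out, class = "innervation_metrics")
}
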