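# Histology phantoms: curvilinear axons with superimposed Gaussian
# boutons at known positions, rendered into two confocal-style channels.

#' Specification of a histology phantom
#'
#' @param n_axons Number of axons per image.
#' @param bouton_density_per_100um Mean boutons per 100 um of axon
#'   (Poisson-placed along the centerline); must be >= 0.
#' @param psf_sigma Point-spread sigma, microns (default 0.5; boutons are
#'   ~1 um puncta).
#' @param background_mean,background_sd Background intensity and Gaussian
#'   noise SD (defaults 10 and 2).
#' @param pixel_size Microns per pixel (default 0.65).
#' @param image_size Image side length, pixels (default 512).
#' @param axon_intensity,bouton_intensity Peak intensities of the axon
#'   tube (red channel) and bouton puncta (green channel) above
#'   background.
#' @param target_len_um Arc length each random axon aims for, microns
#'   (default 350; axons stop early at the image border).
#' @param curvature_sd SD of the per-step direction change, radians per
#'   pixel step (default 0.03; smooth, gently curving axons).
#' @param seed Integer seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_axons = 4, bouton_density_per_100um = 12,
                         psf_sigma = 0.5, background_mean = 10,
                         background_sd = 2, pixel_size = 0.65,
                         image_size = 512, axon_intensity = 30,
                         bouton_intensity = 60, target_len_um = 350,
                         curvature_sd = 0.03, seed = 1) {
  if (bouton_density_per_100um < 0)
    stop("bouton_density_per_100um must be >= 0", call. = FALSE)
  check_pos(pixel_size, "pixel_size")
  check_pos(psf_sigma, "psf_sigma")
  stopifnot(n_axons >= 0, image_size >= 32)
  structure(list(n_axons = as.integer(n_axons),
                 bouton_density_per_100um = bouton_density_per_100um,
                 psf_sigma = psf_sigma, background_mean = background_mean,
                 background_sd = background_sd, pixel_size = pixel_size,
                 image_size = as.integer(image_size),
                 axon_intensity = axon_intensity,
                 bouton_intensity = bouton_intensity,
                 target_len_um = target_len_um,
                 curvature_sd = curvature_sd, seed = seed),
            class = "phantom_spec")
}

# Smooth random axon centerline: unit-pixel steps with Gaussian direction
# increments; stops at the border margin or at the target arc length.
# Returns an n x 2 matrix of (row, col) pixel coordinates.
random_axon_path <- function(spec) {
  sz <- spec$image_size
  margin <- 8
  step_um <- spec$pixel_size
  n_max <- ceiling(spec$target_len_um / step_um)
  p <- stats::runif(2, margin + sz * 0.1, sz * 0.9 - margin)
  theta <- stats::runif(1, 0, 2 * pi)
  out <- matrix(NA_real_, n_max + 1L, 2L)
  out[1L, ] <- p
  for (i in seq_len(n_max)) {
    theta <- theta + stats::rnorm(1, 0, spec$curvature_sd)
    p <- p + c(cos(theta), sin(theta))
    if (any(p < margin) || any(p > sz - margin)) break
    out[i + 1L, ] <- p
  }
  out[!is.na(out[, 1L]), , drop = FALSE]
}

# Bilinear splat of weighted points into an accumulator image.
splat_points <- function(img, pts, w) {
  r0 <- floor(pts[, 1]); c0 <- floor(pts[, 2])
  fr <- pts[, 1] - r0; fc <- pts[, 2] - c0
  H <- nrow(img); W <- ncol(img)
  add <- function(rr, cc, ww) {
    ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W & ww > 0
    if (any(ok)) {
      idx <- (cc[ok] - 1L) * H + rr[ok]
      acc <- rowsum(ww[ok], idx)
      img[as.integer(rownames(acc))] <<- img[as.integer(rownames(acc))] + acc
    }
  }
  add(r0, c0, w * (1 - fr) * (1 - fc))
  add(r0 + 1L, c0, w * fr * (1 - fc))
  add(r0, c0 + 1L, w * (1 - fr) * fc)
  add(r0 + 1L, c0 + 1L, w * fr * fc)
  img
}

#' Render a histology phantom from explicit centerlines
#'
#' Low-level renderer used by [simulate_histology()] and directly by
#' tests that need exact geometry (e.g. one straight 500 um tube with 10
#' equally spaced boutons). Axons are drawn as Gaussian tubes of sigma
#' `psf_sigma` along each path; boutons as Gaussian puncta at given
#' arc-length positions, present in both channels with the green channel
#' dominant.
#'
#' @param paths List of n x 2 matrices of (row, col) pixel coordinates
#'   (consecutive points ~1 px apart).
#' @param bouton_arcpos List (parallel to `paths`) of arc-length positions
#'   in microns at which boutons sit on each axon.
#' @param spec A [phantom_spec()] providing intensities, PSF, pixel size
#'   and noise (its `n_axons`/density fields are ignored here).
#' @return A list of class `histology_phantom`: `red`, `green` (matrices),
#'   and `ground_truth` (`bouton_count`, `bouton_centers`,
#'   `axon_lengths_um`, `total_length_um`).
#' @export
render_histology <- function(paths, bouton_arcpos, spec) {
  sz <- spec$image_size
  sigma_px <- spec$psf_sigma / spec$pixel_size
  axon_acc <- matrix(0, sz, sz)
  bouton_acc <- matrix(0, sz, sz)
  lengths_um <- numeric(length(paths))
  centers <- list()
  sub <- 0.5   # splat spacing along the path, px
  for (i in seq_along(paths)) {
    pth <- paths[[i]]
    if (nrow(pth) < 2L) next
    seg <- sqrt(rowSums(diff(pth)^2))
    arc_px <- c(0, cumsum(seg))
    lengths_um[i] <- arc_px[length(arc_px)] * spec$pixel_size
    s_px <- seq(0, arc_px[length(arc_px)], by = sub)
    pr <- stats::approx(arc_px, pth[, 1], xout = s_px)$y
    pc <- stats::approx(arc_px, pth[, 2], xout = s_px)$y
    # line density chosen so the blurred tube peaks at axon_intensity
    w_line <- spec$axon_intensity * sqrt(2 * pi) * sigma_px * sub
    axon_acc <- splat_points(axon_acc, cbind(pr, pc),
                             rep(w_line, length(pr)))
    bp <- bouton_arcpos[[i]]
    bp <- bp[bp >= 0 & bp <= lengths_um[i]]
    if (length(bp) > 0) {
      s_b <- bp / spec$pixel_size
      br <- stats::approx(arc_px, pth[, 1], xout = s_b)$y
      bc <- stats::approx(arc_px, pth[, 2], xout = s_b)$y
      w_pt <- spec$bouton_intensity * 2 * pi * sigma_px^2
      bouton_acc <- splat_points(bouton_acc, cbind(br, bc),
                                 rep(w_pt, length(br)))
      centers[[length(centers) + 1L]] <- cbind(row = br, col = bc)
    }
  }
  axon_img <- gaussian_smooth(axon_acc, sigma_px)
  bouton_img <- gaussian_smooth(bouton_acc, sigma_px)
  noise <- function() {
    if (spec$background_sd > 0)
      matrix(stats::rnorm(sz * sz, spec$background_mean,
                          spec$background_sd), sz, sz)
    else matrix(spec$background_mean, sz, sz)
  }
  red <- axon_img + 0.5 * bouton_img + noise()
  green <- 0.15 * axon_img + bouton_img + noise()
  ctr <- if (length(centers)) do.call(rbind, centers) else
    cbind(row = numeric(0), col = numeric(0))
  structure(list(red = red, green = green,
                 ground_truth = list(bouton_count = nrow(ctr),
                                     bouton_centers = ctr,
                                     axon_lengths_um = lengths_um,
                                     total_length_um = sum(lengths_um))),
            class = "histology_phantom")
}

#' Simulate a histology phantom with known ground truth
#'
#' Draws `n_axons` smooth random axon centerlines, places boutons along
#' them as a Poisson process at `bouton_density_per_100um`, and renders
#' the red (axon) and green (bouton) channels with [render_histology()].
#'
#' @param spec A [phantom_spec()].
#' @return A `histology_phantom` (see [render_histology()]).
#' @export
simulate_histology <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    paths <- lapply(seq_len(spec$n_axons), function(i)
      random_axon_path(spec))
    arcpos <- lapply(paths, function(p) {
      len_um <- (nrow(p) - 1L) * spec$pixel_size
      n_b <- stats::rpois(1, spec$bouton_density_per_100um * len_um / 100)
      sort(stats::runif(n_b, 0, len_um))
    })
    render_histology(paths, arcpos, spec)
  })
}

#' Simulate a field of labeled somata
#'
#' Non-overlapping Gaussian blobs at soma scale, the phantom used to
#' exercise [count_cells()].
#'
#' @param n_cells Number of somata.
#' @param sigma_um Soma Gaussian sigma, microns (default 6).
#' @param intensity Peak intensity above background (default 40).
#' @param pixel_size Microns per pixel (default 0.65).
#' @param image_size Image side, pixels (default 512).
#' @param background_mean,background_sd Background level and noise SD.
#' @param seed Integer seed.
#' @return List: `image`, `centers` (n x 2 pixel coordinates).
#' @export
simulate_cell_field <- function(n_cells, sigma_um = 6, intensity = 40,
                                pixel_size = 0.65, image_size = 512,
                                background_mean = 10, background_sd = 2,
                                seed = 1) {
  stopifnot(n_cells >= 0)
  with_seed(seed, {
    sz <- image_size
    sigma_px <- sigma_um / pixel_size
    min_sep <- 5 * sigma_px
    centers <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(centers) < n_cells && tries < 20000L) {
      p <- stats::runif(2, 2 * sigma_px, sz - 2 * sigma_px)
      if (nrow(centers) == 0L ||
          min(sqrt((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2)) >
          min_sep) {
        centers <- rbind(centers, p)
      }
      tries <- tries + 1L
    }
    if (nrow(centers) < n_cells)
      stop("could not place somata without overlap; reduce n_cells")
    acc <- matrix(0, sz, sz)
    if (n_cells > 0) {
      w <- intensity * 2 * pi * sigma_px^2
      acc <- splat_points(acc, centers, rep(w, nrow(centers)))
    }
    img <- gaussian_smooth(acc, sigma_px) +
      matrix(stats::rnorm(sz * sz, background_mean, background_sd), sz, sz)
    list(image = img, centers = centers)
  })
}
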