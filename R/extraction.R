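# Movie -> neuron components -> dF/F0 traces, following the classic
# one-photon recipe: per-pixel dF/F0, spatial downsampling, PCA plus
# skewness-maximizing spatiotemporal ICA, rule-based component selection,
# and annulus ("doughnut") background-subtracted trace extraction.

#' Per-pixel dF/F0 of a movie
#'
#' F0 is the session mean of each pixel; dF/F0 at time t is
#' `(F_t - F0) / F0`. Pixels with `F0 <= 0` carry no usable signal and are
#' masked to zero with a warning. By construction every pixel's dF/F0
#' time-mean is zero.
#'
#' @param movie H x W x T array (`calcium_movie` or plain array).
#' @param frame_rate Hz; taken from the movie attribute when present.
#' @return A list of class `dff_movie`: `dff` (H x W x T), `f0` (H x W),
#'   `frame_rate`, `masked` (logical H x W).
#' @export
compute_dff <- function(movie, frame_rate = attr(movie, "frame_rate") %||% 30) {
  d <- dim(movie)
  stopifnot(length(d) == 3L, d[3L] >= 2L)
  M <- matrix(movie, nrow = d[1L] * d[2L])      # P x T
  f0 <- rowMeans(M)
  bad <- f0 <= 0
  if (any(bad)) {
    warning(sprintf("%d pixels have F0 <= 0; masked to zero", sum(bad)))
    f0[bad] <- 1
  }
  dff <- (M - f0) / f0
  dff[bad, ] <- 0
  structure(list(dff = array(dff, d),
                 f0 = as_image(ifelse(bad, 0, f0), d[1:2]),
                 frame_rate = frame_rate,
                 masked = as_image(bad, d[1:2])),
            class = "dff_movie")
}

#' Spatial block-mean downsampling
#'
#' Averages non-overlapping `factor x factor` pixel blocks in each frame;
#' trailing rows/columns that do not fill a block are dropped.
#'
#' @param movie H x W x T array.
#' @param factor Integer >= 1 (default 4, the standard one-photon
#'   preprocessing reduction).
#' @return Downsampled array with attributes preserved.
#' @export
downsample_movie <- function(movie, factor = 4L) {
  if (!is.numeric(factor) || factor < 1) stop("factor must be >= 1")
  factor <- as.integer(factor)
  if (factor == 1L) return(movie)
  d <- dim(movie)
  stopifnot(length(d) == 3L)
  H2 <- d[1L] %/% factor; W2 <- d[2L] %/% factor
  if (H2 < 1L || W2 < 1L) stop("movie smaller than one block")
  crop <- movie[seq_len(H2 * factor), seq_len(W2 * factor), , drop = FALSE]
  # average factor-sized row blocks, then column blocks
  a <- matrix(colMeans(matrix(crop, nrow = factor)), nrow = H2)   # H2 x (W2*f*T)
  a <- array(a, c(H2, factor * W2, d[3L]))
  a <- aperm(a, c(2L, 1L, 3L))
  b <- matrix(colMeans(matrix(a, nrow = factor)), nrow = W2)
  out <- aperm(array(b, c(W2, H2, d[3L])), c(2L, 1L, 3L))
  for (at in c("frame_rate", "baseline")) attr(out, at) <- attr(movie, at)
  class(out) <- class(movie)
  out
}

# Randomized partial SVD (Halko-style, two power iterations). Deterministic
# given the caller's RNG state.
partial_svd <- function(M, k, oversample = 8L, power_iter = 2L) {
  n <- ncol(M)
  l <- min(n, k + oversample)
  omega <- matrix(stats::rnorm(n * l), n, l)
  Y <- M %*% omega
  for (q in seq_len(power_iter)) {
    Y <- qr.Q(qr(Y))
    Y <- M %*% crossprod(M, Y)
  }
  Q <- qr.Q(qr(Y))
  B <- crossprod(Q, M)                 # l x n
  s <- svd(B, nu = k, nv = k)
  list(u = Q %*% s$u, d = s$d[seq_len(k)], v = s$v)
}

#' PCA plus skewness-maximizing spatiotemporal ICA
#'
#' Decomposes a dF/F0 movie into independent components in the style of
#' the CellSort algorithm: the movie matrix (T x pixels) is reduced to
#' `n_pcs` principal components by a randomized partial SVD, then a joint
#' spatiotemporal ICA rotation is found by a fixed-point iteration that
#' maximizes the skewness of the concatenated spatial and temporal
#' signals, weighted `mu` (temporal) vs `1 - mu` (spatial). Calcium
#' sources are sparse and positively skewed, which is what the skewness
#' contrast isolates.
#'
#' Singular values numerically at zero (below `1e-7` of the largest) are
#' dropped, so a noise-free low-rank movie yields exactly its rank in
#' components. Each component's spatial filter has unit norm and its
#' temporal signal is sign-flipped, if needed, so temporal skewness is
#' nonnegative.
#'
#' @param dff A `dff_movie` (from [compute_dff()]) or H x W x T array of
#'   dF/F0 values.
#' @param n_pcs Number of principal components to retain (rule of thumb:
#'   about 3x the expected cell count). Must not exceed `min(T, pixels)`.
#' @param mu Spatiotemporal weighting in `[0, 1]`: 0 = purely spatial ICA,
#'   1 = purely temporal, 0.5 = equal weighting (default).
#' @param max_iter,tol Fixed-point iteration controls; non-convergence
#'   gives a warning and returns the current estimate.
#' @param seed Seed for the randomized SVD and the ICA initialisation
#'   (the decomposition is deterministic given the seed).
#' @return An object of class `neuron_components`: a list of components,
#'   each with `spatial` (H x W), `temporal` (length T), `skewness`,
#'   `accepted` (NA until [select_components()]), `reject_reason`.
#'   Components are ordered by decreasing temporal skewness.
#' @export
pca_ica <- function(dff, n_pcs = 30L, mu = 0.5, max_iter = 500L,
                    tol = 1e-6, seed = 1) {
  check_prob(mu, "mu")
  arr <- if (inherits(dff, "dff_movie")) dff$dff else dff
  d <- dim(arr)
  stopifnot(length(d) == 3L)
  M <- movie_as_matrix(arr)                       # T x P
  if (n_pcs > min(dim(M)))
    stop("n_pcs exceeds min(T, pixels)", call. = FALSE)
  with_seed(seed, {
    sv <- partial_svd(M, as.integer(n_pcs))
    keep <- sv$d > 1e-7 * sv$d[1L]
    U <- sv$u[, keep, drop = FALSE]
    V <- sv$v[, keep, drop = FALSE]
    k <- ncol(U)
    # joint spatiotemporal samples, rows = components (already white)
    Z <- cbind((1 - mu) * t(V), mu * t(U)) /
      sqrt((1 - mu)^2 + mu^2)
    m <- ncol(Z)
    sym_orth <- function(W) {
      e <- eigen(tcrossprod(W), symmetric = TRUE)
      e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), k) %*%
        t(e$vectors) %*% W
    }
    W <- sym_orth(matrix(stats::rnorm(k * k), k, k))
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      S <- W %*% Z
      W1 <- sym_orth((S * S) %*% t(Z) / m)
      delta <- max(abs(abs(rowSums(W1 * W)) - 1))
      W <- W1
      if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged)
      warning("spatiotemporal ICA did not converge; returning partial result")
    spatial <- V %*% t(W)        # P x k
    temporal <- U %*% t(W)       # T x k
    comps <- lapply(seq_len(k), function(i) {
      s <- spatial[, i]; tm <- temporal[, i]
      sk <- skewness_adj(tm)
      if (sk < 0) { s <- -s; tm <- -tm; sk <- skewness_adj(tm) }
      nrm <- sqrt(sum(s^2))
      if (nrm > 0) { tm <- tm * nrm; s <- s / nrm }
      list(spatial = as_image(s, d[1:2]), temporal = tm, skewness = sk,
           accepted = NA, reject_reason = "none")
    })
    comps <- comps[order(vapply(comps, `[[`, numeric(1), "skewness"),
                         decreasing = TRUE)]
    structure(comps, class = "neuron_components",
              dim_hw = d[1:2], converged = converged)
  })
}

#' @export
print.neuron_components <- function(x, ...) {
  sk <- vapply(x, `[[`, numeric(1), "skewness")
  acc <- vapply(x, `[[`, logical(1), "accepted")
  sel <- if (all(is.na(acc))) "not yet selected" else
    sprintf("%d accepted", sum(acc))
  cat(sprintf("%d spatiotemporal components (skewness %.2f..%.2f); %s\n",
              length(x), min(sk), max(sk), sel))
  invisible(x)
}

#' Dark-vessel mask from the mean-fluorescence image
#'
#' Blood vessels cast static dark shadows in the F0 image; the mask marks
#' pixels below the given F0 quantile.
#'
#' @param f0 H x W mean-fluorescence image.
#' @param prob Quantile defining "dark" (default 0.05).
#' @return Logical H x W matrix.
#' @export
vessel_mask_from_f0 <- function(f0, prob = 0.05) {
  f0 < stats::quantile(f0, prob)
}

#' Accept or reject extracted components
#'
#' Implements the two selection rules: components whose temporal skewness
#' is below `skew_min` (default 1) are rejected, and components whose
#' spatial filter concentrates on dark vessel shadows are rejected. The
#' vessel criterion is automated: overlap is the fraction of the filter's
#' top-quantile pixels that fall inside `vessel_mask`, rejected when it
#' exceeds `overlap_max`. Rules are order-independent; skewness is
#' checked first only to pick the recorded `reject_reason`.
#'
#' @param components A `neuron_components` list.
#' @param skew_min Minimum temporal skewness (default 1).
#' @param vessel_mask Optional logical H x W mask (see
#'   [vessel_mask_from_f0()]).
#' @param overlap_max Maximum tolerated vessel overlap (default 0.3).
#' @param top_quantile Quantile of the spatial filter defining its "core"
#'   pixels for the overlap computation (default 0.95).
#' @return The same list with `accepted` / `reject_reason` filled in;
#'   attribute `accepted_idx` gives the accepted indices.
#' @export
select_components <- function(components, skew_min = 1, vessel_mask = NULL,
                              overlap_max = 0.3, top_quantile = 0.95) {
  stopifnot(inherits(components, "neuron_components"))
  out <- lapply(components, function(cp) {
    if (cp$skewness < skew_min) {
      cp$accepted <- FALSE
      cp$reject_reason <- "low_skewness"
    } else {
      ov <- 0
      if (!is.null(vessel_mask)) {
        core <- cp$spatial >= stats::quantile(cp$spatial, top_quantile)
        ov <- mean(vessel_mask[core])
      }
      if (ov > overlap_max) {
        cp$accepted <- FALSE
        cp$reject_reason <- "vessel_overlap"
      } else {
        cp$accepted <- TRUE
        cp$reject_reason <- "none"
      }
    }
    cp
  })
  attributes(out) <- attributes(components)
  attr(out, "accepted_idx") <-
    which(vapply(out, `[[`, logical(1), "accepted"))
  out
}

#' Extract a background-subtracted dF/F0 trace for one component
#'
#' The soma mask is the set of spatial-filter pixels above `soma_frac` of
#' the filter peak; the background annulus is the doughnut of pixels
#' between `annulus_inner` and `annulus_outer` pixels outside the soma
#' boundary, excluding any other component's soma. The trace is, per
#' frame, `mean(soma pixels) - median(annulus pixels)`, which removes
#' shared neuropil/background signal.
#'
#' @param dff A `dff_movie` or H x W x T dF/F0 array.
#' @param component One element of a `neuron_components` list (or a
#'   spatial-filter matrix).
#' @param soma_frac Soma threshold as a fraction of the filter peak
#'   (default 0.3).
#' @param annulus_inner,annulus_outer Annulus distances from the soma
#'   boundary, pixels (defaults 2 and 8).
#' @param other_somas Optional logical H x W mask of pixels claimed by
#'   other somas, excluded from the annulus.
#' @param neuron_id Identifier stored in the result.
#' @return A list of class `calcium_trace`: `dff` (length T), `neuron_id`,
#'   `soma_mask`, `annulus_mask`.
#' @export
extract_trace <- function(dff, component, soma_frac = 0.3,
                          annulus_inner = 2, annulus_outer = 8,
                          other_somas = NULL, neuron_id = NA_integer_) {
  arr <- if (inherits(dff, "dff_movie")) dff$dff else dff
  d <- dim(arr)
  spatial <- if (is.list(component)) component$spatial else component
  stopifnot(identical(dim(spatial), d[1:2]))
  soma <- spatial >= soma_frac * max(spatial)
  dist <- EBImage::distmap(1 - soma)   # distance to nearest soma pixel
  annulus <- dist > annulus_inner & dist <= annulus_outer
  if (!is.null(other_somas)) annulus <- annulus & !other_somas
  M <- matrix(arr, nrow = d[1L] * d[2L])       # P x T
  soma_sig <- colMeans(M[soma, , drop = FALSE])
  if (!any(annulus)) {
    warning("empty background annulus; using global background median")
    bgmask <- !soma & !(other_somas %||% FALSE)
    annulus <- bgmask
  }
  bg <- apply(M[annulus, , drop = FALSE], 2L, stats::median)
  structure(list(dff = soma_sig - bg, neuron_id = neuron_id,
                 soma_mask = soma, annulus_mask = annulus),
            class = "calcium_trace")
}
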