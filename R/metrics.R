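#' Regions of interest derived from the phantom geometry
#'
#' Ghosting from motion replicates the object along the phase-encode
#' (anteroposterior, row) direction, so the ghost ROI is placed in the
#' ghosting band above/below the object (same columns, rows outside
#' the object), while the background ROI sits in the left/right
#' corners outside that band and is unaffected by ghosting.  Wall,
#' lumen and noise ROIs come from the tissue labels.
#'
#' @param phantom a [make_phantom()] result.
#' @param margin_px clearance between the object and the ROIs.
#' @return A `roi_set` of logical masks: `ghost_roi`,
#'   `background_roi`, `wall_roi`, `lumen_roi`, `noise_roi`;
#'   provenance `"generated-from-phantom"`.
#' @export
make_rois <- function(phantom, margin_px = 4L) {
  lab <- phantom$tissue_labels
  ny <- nrow(lab); nx <- ncol(lab)
  obj <- lab > 0L
  rows_obj <- which(apply(obj, 1, any))
  cols_obj <- which(apply(obj, 2, any))
  row_in <- seq(min(rows_obj) - margin_px, max(rows_obj) + margin_px)
  col_in <- seq(min(cols_obj) - margin_px, max(cols_obj) + margin_px)
  ghost <- matrix(FALSE, ny, nx)
  ghost[setdiff(seq_len(ny), pmax(1, pmin(ny, row_in))), cols_obj] <- TRUE
  bg <- matrix(FALSE, ny, nx)
  bg[, setdiff(seq_len(nx), pmax(1, pmin(nx, col_in)))] <- TRUE
  structure(list(
    ghost_roi = ghost,
    background_roi = bg,
    wall_roi = lab == 2L,
    lumen_roi = lab == 3L,
    noise_roi = bg,
    provenance = "generated-from-phantom"
  ), class = "roi_set")
}

#' Ghost level of a reconstruction
#'
#' The median intensity in the ghost ROI minus the median background
#' intensity of the *original* (uncorrected) reconstruction; the
#' reference background median is always computed once on that
#' original image and passed in, so that 0 means "ghosting at the
#' background level".
#'
#' @param image magnitude image.
#' @param rois a [make_rois()] result (uses `ghost_roi`).
#' @param reference_background_median median background intensity of
#'   the original reconstruction.
#' @return scalar ghost level.
#' @export
ghost_level <- function(image, rois, reference_background_median) {
  if (!any(rois$ghost_roi)) stop("empty ghost ROI")
  stats::median(image[rois$ghost_roi]) - reference_background_median
}

#' Ghosting reduction relative to the uncorrected reconstruction
#'
#' `100 * (1 - corrected / uncorrected)` percent: 0% means no change,
#' 100% means ghosting reduced to the background level.
#'
#' @param ghost_level_corrected ghost level of the corrected image.
#' @param ghost_level_swl ghost level of the uncorrected (SWL) image;
#'   must be positive.
#' @return percent reduction.
#' @export
ghosting_reduction <- function(ghost_level_corrected, ghost_level_swl) {
  if (ghost_level_swl <= 0) {
    stop("uncorrected ghost level must be positive (no ghost to reduce)")
  }
  100 * (1 - ghost_level_corrected / ghost_level_swl)
}

#' Wall/lumen contrast-to-noise ratio
#'
#' `(mean(wall) - mean(lumen)) / sd(noise ROI)`.
#'
#' @param image magnitude image.
#' @param wall_roi,lumen_roi,noise_roi logical masks.
#' @return scalar CNR.
#' @export
cnr <- function(image, wall_roi, lumen_roi, noise_roi) {
  if (!any(wall_roi) || !any(lumen_roi) || !any(noise_roi)) {
    stop("empty ROI")
  }
  s <- stats::sd(image[noise_roi])
  if (s <= 0) stop("zero noise standard deviation")
  (mean(image[wall_roi]) - mean(image[lumen_roi])) / s
}

#' Image edge profile acutance (IEPA)
#'
#' Sharpness score of intensity profiles taken across the vessel wall
#' boundary: the mean squared successive difference along each
#' profile, normalised by the squared dynamic range of the profile,
#' averaged over profiles.  In `(0, 1]`; an ideal one-pixel step edge
#' of a length-5 profile scores 0.25, and blurring strictly lowers
#' the score.
#'
#' @param profiles list of numeric vectors (each of length >= 5)
#'   sampled along edge normals.
#' @return scalar acutance.
#' @export
iepa <- function(profiles) {
  if (!length(profiles)) stop("need at least one profile")
  vals <- vapply(profiles, function(p) {
    if (length(p) < 5L) stop("each profile needs >= 5 samples")
    rng <- max(p) - min(p)
    if (rng <= 0) return(NA_real_)   # flat profile: excluded
    mean(diff(p)^2) / rng^2
  }, numeric(1))
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("all profiles are flat")
  mean(vals)
}

#' Edge profiles across the vessel wall of a phantom image
#'
#' Samples horizontal profiles through the centre of each vessel,
#' crossing the lumen-wall-muscle boundary, for use with [iepa()].
#'
#' @param image magnitude image.
#' @param phantom the phantom defining vessel locations.
#' @param half_len half-length of each profile in pixels.
#' @return list of numeric profiles.
#' @export
vessel_edge_profiles <- function(image, phantom, half_len = 6L) {
  lab <- phantom$tissue_labels
  lum <- which(lab == 3L, arr.ind = TRUE)
  if (!nrow(lum)) stop("phantom has no lumen pixels")
  cl <- stats::kmeans(lum, centers = 2, nstart = 5)
  profiles <- list()
  for (k in seq_len(nrow(cl$centers))) {
    cy <- round(cl$centers[k, 1]); cx <- round(cl$centers[k, 2])
    for (dir in c(-1L, 1L)) {
      idx <- cx + dir * seq(0L, 2L * half_len)
      idx <- idx[idx >= 1L & idx <= ncol(image)]
      profiles <- c(profiles, list(image[cy, idx]))
    }
  }
  profiles
}

#' Voxel-wise mono-exponential T2 fit
#'
#' Fits `S0 * exp(-TE / T2)` per pixel by Gauss-Newton nonlinear
#' least squares, initialised from the log-linear regression of the
#' intensities.  Pixels whose signal is below `s0_threshold` times the
#' maximum first-echo intensity, or whose fit fails, are excluded via
#' `valid_mask`; fits hitting the upper T2 bound are flagged in
#' `near_bound`.
#'
#' @param echo_images array `(echoes, ny, nx)` (or `pixels x echoes`
#'   matrix) of magnitude intensities.
#' @param te_list_ms echo times in ms, strictly increasing, length >= 3.
#' @param mask optional logical `ny x nx` mask of pixels to fit.
#' @param s0_threshold relative signal threshold (default 0.05).
#' @param t2_max_ms upper bound flagging threshold (default 1e4).
#' @param max_iter Gauss-Newton iterations (default 50).
#' @return A `t2_fit_result`: `t2_map` (ms), `s0_map`,
#'   `fit_residual` (RMS), `valid_mask`, `near_bound`.
#' @export
fit_t2 <- function(echo_images, te_list_ms, mask = NULL,
                   s0_threshold = 0.05, t2_max_ms = 1e4, max_iter = 50L) {
  if (length(te_list_ms) < 3L) stop("need at least 3 echoes")
  if (any(diff(te_list_ms) <= 0)) stop("TEs must be strictly increasing")
  if (length(dim(echo_images)) == 3L) {
    ne <- dim(echo_images)[1L]
    ny <- dim(echo_images)[2L]; nx <- dim(echo_images)[3L]
    if (is.null(mask)) mask <- matrix(TRUE, ny, nx)
    pix <- which(mask)
    Y <- t(matrix(echo_images, ne, ny * nx)[, pix, drop = FALSE])
  } else {
    Y <- as.matrix(echo_images)
    ne <- ncol(Y)
    ny <- nrow(Y); nx <- 1L
    pix <- seq_len(nrow(Y)); mask <- NULL
  }
  if (ne != length(te_list_ms)) stop("echo count does not match TE list")
  te <- te_list_ms
  npx <- nrow(Y)
  smax <- max(Y[, 1L], 0)
  valid <- rowSums(Y > 0) == ne & Y[, 1L] > s0_threshold * smax
  # log-linear initialisation
  r2 <- rep(1 / 50, npx); ls0 <- rep(0, npx)
  if (any(valid)) {
    L <- log(pmax(Y[valid, , drop = FALSE], .Machine$double.xmin))
    sx <- sum(te); sxx <- sum(te^2); n <- ne
    sy <- rowSums(L); sxy <- as.vector(L %*% te)
    slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
    icpt <- (sy - slope * sx) / n
    r2[valid] <- pmax(-slope, 1e-8)
    ls0[valid] <- icpt
  }
  s0 <- exp(ls0); rr <- r2   # model S0 * exp(-R2 * TE)
  for (it in seq_len(max_iter)) {
    E <- exp(-outer(rr, te))        # npx x ne
    M <- s0 * E
    R <- Y - M
    # Jacobian columns: dS0 = E ; dR2 = -TE * M
    a11 <- rowSums(E * E)
    a12 <- rowSums(E * (-rep(te, each = npx) * M))
    a22 <- rowSums((rep(te, each = npx) * M)^2)
    b1 <- rowSums(E * R)
    b2 <- rowSums(-rep(te, each = npx) * M * R)
    det <- a11 * a22 - a12^2
    det[abs(det) < 1e-300] <- NA
    d_s0 <- (a22 * b1 - a12 * b2) / det
    d_r2 <- (a11 * b2 - a12 * b1) / det
    d_s0[!valid | !is.finite(d_s0)] <- 0
    d_r2[!valid | !is.finite(d_r2)] <- 0
    s0 <- pmax(s0 + d_s0, 0)
    rr <- pmax(rr + d_r2, 1e-9)
    if (max(abs(d_r2) / pmax(rr, 1e-9)) < 1e-10) break
  }
  t2 <- 1 / rr
  resid <- sqrt(rowMeans((Y - s0 * exp(-outer(rr, te)))^2))
  near_bound <- t2 > t2_max_ms
  valid <- valid & is.finite(t2) & t2 > 0
  to_map <- function(v, fill = NA_real_) {
    if (is.null(mask)) return(v)
    m <- matrix(fill, ny, nx); m[pix] <- v; m
  }
  structure(list(
    t2_map = to_map(t2),
    s0_map = to_map(s0),
    fit_residual = to_map(resid),
    valid_mask = to_map(valid, FALSE),
    near_bound = to_map(near_bound, FALSE)
  ), class = "t2_fit_result")
}
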