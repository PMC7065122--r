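#' POCS partial-Fourier completion of one coil k-space
#'
#' Iterates between (a) enforcing the image phase estimated from the
#' symmetric low-frequency band around the centre line and (b)
#' restoring the acquired k-space samples, until the relative change
#' of the image falls below `tol` or `n_iter` is reached.  Acquired
#' samples are exactly preserved in the output; a fully sampled input
#' is returned unchanged.
#'
#' @param kspace complex `ny x nx` matrix with zeros on unacquired
#'   rows (centred convention, ky along rows).
#' @param acquired_ky 1-based grid indices of the acquired ky lines.
#' @param n_iter maximum number of iterations (default 20).
#' @param tol relative-change stopping tolerance (default 1e-6).
#' @return list: `kspace` (completed), `n_iter` (iterations used),
#'   `residuals` (relative change per iteration).
#' @export
pocs_partial_fourier <- function(kspace, acquired_ky, n_iter = 20L,
                                 tol = 1e-6) {
  ny <- nrow(kspace); nx <- ncol(kspace)
  ctr <- ny %/% 2L + 1L
  lo <- min(acquired_ky); hi <- max(acquired_ky)
  halfwidth <- min(hi - ctr, ctr - lo)
  if (halfwidth < 1L) {
    stop("no symmetric low-frequency band around the centre line")
  }
  if (length(acquired_ky) == ny) {
    return(list(kspace = kspace, n_iter = 0L, residuals = numeric(0)))
  }
  # low-frequency phase reference from the symmetric band (smoothly
  # apodised to avoid ringing in the phase map)
  band <- (ctr - halfwidth):(ctr + halfwidth)
  win <- matrix(0, ny, nx)
  hann <- 0.5 * (1 + cos(pi * (band - ctr) / (halfwidth + 1)))
  win[band, ] <- hann
  phase <- Arg(ifft2c(kspace * win))
  ph <- exp(1i * phase)
  est <- kspace
  prev <- ifft2c(est)
  residuals <- numeric(0)
  it <- 0L
  while (it < n_iter) {
    it <- it + 1L
    img <- ifft2c(est)
    img <- Re(img * Conj(ph)) * ph        # project onto the phase constraint
    est <- fft2c(img)
    est[acquired_ky, ] <- kspace[acquired_ky, ]  # data consistency
    cur <- ifft2c(est)
    rel <- sqrt(sum(abs(cur - prev)^2)) / max(sqrt(sum(abs(cur)^2)),
                                              .Machine$double.eps)
    residuals <- c(residuals, rel)
    prev <- cur
    if (rel < tol) break
  }
  list(kspace = est, n_iter = it, residuals = residuals)
}

#' Root-sum-of-squares coil combination
#'
#' @param images_per_coil complex array `(coils, ny, nx)` (or a
#'   matrix for a single coil).
#' @param method only `"rss"` is implemented.
#' @return nonnegative real `ny x nx` magnitude image.
#' @export
coil_combine <- function(images_per_coil, method = "rss") {
  method <- match.arg(method, "rss")
  if (is.matrix(images_per_coil)) {
    return(abs(images_per_coil))
  }
  sqrt(apply(abs(images_per_coil)^2, c(2, 3), sum))
}

#' Reconstruct echo images from a (corrected) dataset
#'
#' Applies the reconstruction arm's corrections, completes partial
#' Fourier per coil and echo with POCS, inverse Fourier transforms,
#' and combines coils with root-sum-of-squares:
#'
#' * `"still"` / `"swl"`: no correction (use on the motion-free or the
#'   motion-corrupted dataset, respectively);
#' * `"reacq"`: every corrupted line replaced by its reacquisition
#'   when the reacquired score is higher ([merge_reacq_all()]);
#' * `"moco"`: corrupted central lines replaced by reacquisitions
#'   ([replace_central_lines()]), remaining corrupted lines estimated
#'   with 1-/2-AMCL GRAPPA ([build_estimation_plan()], [apply_plan()]).
#'
#' @param dataset a `kspace_dataset` with imaging data.
#' @param variant one of `"still"`, `"swl"`, `"reacq"`, `"moco"`.
#' @param qc a [quality_trace()] (computed from the dataset when
#'   `NULL`; required only for `"reacq"`/`"moco"`).
#' @param cap maximum estimated lines for `"moco"` (default 12).
#' @param n_central width of the protected central band (default 7).
#' @param pocs_iter,pocs_tol POCS settings.
#' @param slices,echoes subsets to reconstruct (defaults: all).
#' @return An `echo_image_stack`: `images` (nonnegative array
#'   `slices x echoes x ny x nx`), `provenance` (variant, logs, POCS
#'   iterations), `slices`, `echoes`.
#' @export
reconstruct <- function(dataset, variant = c("still", "swl", "reacq", "moco"),
                        qc = NULL, cap = 12L, n_central = 7L,
                        pocs_iter = 20L, pocs_tol = 1e-6,
                        slices = NULL, echoes = NULL) {
  variant <- match.arg(variant)
  if (is.null(dataset$data)) stop("dataset has no imaging data")
  sch <- dataset$schedule
  logs <- list()
  if (variant %in% c("reacq", "moco")) {
    if (is.null(qc)) qc <- quality_trace(dataset)
    if (variant == "reacq") {
      dataset <- merge_reacq_all(dataset, qc)
      logs$merge <- dataset$merge_log
    } else {
      dataset <- replace_central_lines(dataset, qc, n_central = n_central)
      logs$merge <- dataset$merge_log
      # lines fixed by the central replacement are no longer corrupted
      still_corrupted <- qc$corrupted_mask
      replaced <- unlist(lapply(dataset$merge_log, `[[`, "replaced_trs"))
      still_corrupted[replaced] <- FALSE
      plan <- build_estimation_plan(still_corrupted, qc$adjusted_tr_scores,
                                    cap = cap, acquired_ky = qc$ky_of_tr)
      dataset <- apply_plan(dataset, plan)
      logs$plan <- plan
      logs$estimation <- dataset$estimation_log
    }
  }
  ny <- sch$matrix_size[["ny"]]; nx <- sch$matrix_size[["nx"]]
  acq <- sch$acquired_ky
  if (is.null(slices)) slices <- seq_len(sch$n_slices)
  if (is.null(echoes)) echoes <- seq_len(sch$n_imaging_echoes)
  nc <- dim(dataset$data)[5L]
  images <- array(0, dim = c(length(slices), length(echoes), ny, nx))
  pocs_iters <- integer(0)
  for (si in seq_along(slices)) {
    for (ei in seq_along(echoes)) {
      coil_imgs <- array(0 + 0i, dim = c(nc, ny, nx))
      for (c in seq_len(nc)) {
        full <- matrix(0 + 0i, ny, nx)
        full[acq, ] <- dataset$data[slices[si], echoes[ei], , , c]
        pf <- pocs_partial_fourier(full, acq, n_iter = pocs_iter,
                                   tol = pocs_tol)
        pocs_iters <- c(pocs_iters, pf$n_iter)
        coil_imgs[c, , ] <- ifft2c(pf$kspace)
      }
      images[si, ei, , ] <- coil_combine(coil_imgs)
    }
  }
  structure(list(
    images = images,
    provenance = list(variant = variant, logs = logs,
                      pocs_iter_mean = mean(pocs_iters)),
    slices = slices, echoes = echoes
  ), class = "echo_image_stack")
}

#' @export
print.echo_image_stack <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("echo_image_stack (%s): %d slices x %d echoes x %d x %d\n",
              x$provenance$variant, d[1], d[2], d[3], d[4]))
  invisible(x)
}
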