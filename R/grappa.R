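#' GRAPPA kernel geometry for motion-corrupted line estimation
#'
#' Unlike conventional undersampled GRAPPA, the acquisition here is
#' fully sampled except for isolated corrupted lines, so the source
#' points can sit tightly around the line(s) being synthesized:
#'
#' * `1-AMCL` (one corrupted line, locally R = 2): target offset
#'   `{0}`, source ky offsets `{-2, -1, +1, +2}`.
#' * `2-AMCL` (adjacent pair, locally R = 3): target offsets
#'   `{0, +1}`, source ky offsets `{-2, -1, +2, +3}`.
#'
#' Both use a 5-tap window along kx (offsets `-2..+2`).
#'
#' @param kind `"1-AMCL"` or `"2-AMCL"`.
#' @param kx_halfwidth half-width of the kx tap window (default 2).
#' @return geometry list with `kind`, `target_offsets`,
#'   `source_offsets`, `taps`.
#' @export
grappa_geometry <- function(kind = c("1-AMCL", "2-AMCL"), kx_halfwidth = 2L) {
  kind <- match.arg(kind)
  taps <- seq.int(-kx_halfwidth, kx_halfwidth)
  if (kind == "1-AMCL") {
    list(kind = kind, target_offsets = 0L,
         source_offsets = c(-2L, -1L, 1L, 2L), taps = taps)
  } else {
    list(kind = kind, target_offsets = c(0L, 1L),
         source_offsets = c(-2L, -1L, 2L, 3L), taps = taps)
  }
}

# column index helpers fixing the (coil, tap, source-line) ordering of
# the calibration design matrix
src_col_index <- function(nc, ntap, c, d, l) c + nc * ((d - 1L) + ntap * (l - 1L))

#' Calibrate a GRAPPA kernel from the central k-space region
#'
#' Fits complex linear weights that predict the target line sample(s)
#' of every coil from the surrounding source samples of all coils, by
#' regularized least squares over all valid placements of the kernel
#' pattern inside the calibration region.
#'
#' @param calib_data complex array `(coils, ky, kx)`: the calibration
#'   region (central, high-SNR k-space lines).
#' @param kind `"1-AMCL"` or `"2-AMCL"`.
#' @param geometry kernel geometry (default [grappa_geometry()] of
#'   `kind`).
#' @param regularization Tikhonov factor; the ridge added to the
#'   normal matrix is `regularization * mean(diag(A^H A))`.
#' @param min_eq_ratio required ratio of equations to unknowns
#'   (default 10).
#' @return A `grappa_kernel`: `weights` (matrix, source columns x
#'   target-coil columns), `geometry`, `dims`, `training_residual`
#'   (relative Frobenius residual), `regularization`.
#' @export
calibrate_kernel <- function(calib_data, kind = c("1-AMCL", "2-AMCL"),
                             geometry = NULL, regularization = 1e-6,
                             min_eq_ratio = 10) {
  kind <- match.arg(kind)
  if (is.null(geometry)) geometry <- grappa_geometry(kind)
  dms <- dim(calib_data)
  if (length(dms) != 3L) stop("calib_data must be (coils, ky, kx)")
  nc <- dms[1L]; nky <- dms[2L]; nkx <- dms[3L]
  src <- geometry$source_offsets
  tgt <- geometry$target_offsets
  taps <- geometry$taps
  offs <- c(src, tgt)
  span <- max(offs) - min(offs) + 1L
  r_lo <- 1L - min(offs); r_hi <- nky - max(offs)
  h <- max(abs(taps))
  xs <- seq.int(1L + h, nkx - h)
  nsrc <- length(src); ntap <- length(taps); ntgt <- length(tgt)
  n_unknown <- nc * nsrc * ntap
  if (r_hi < r_lo || length(xs) == 0L) {
    stop(sprintf(
      "calibration region too small for a %s kernel: needs at least %d ky lines and %d kx columns",
      kind, span, 2L * h + 1L))
  }
  rs <- seq.int(r_lo, r_hi)
  n_eq <- length(rs) * length(xs)
  if (n_eq < min_eq_ratio * n_unknown) {
    need_r <- ceiling(min_eq_ratio * n_unknown / length(xs))
    stop(sprintf(
      "under-determined calibration: %d equations for %d unknowns; need a calibration width of >= %d ky lines",
      n_eq, n_unknown, need_r + span - 1L))
  }
  A <- matrix(0 + 0i, n_eq, n_unknown)
  for (l in seq_len(nsrc)) {
    for (d in seq_len(ntap)) {
      for (c in seq_len(nc)) {
        A[, src_col_index(nc, ntap, c, d, l)] <-
          as.vector(calib_data[c, rs + src[l], xs + taps[d]])
      }
    }
  }
  B <- matrix(0 + 0i, n_eq, nc * ntgt)
  for (t in seq_len(ntgt)) {
    for (j in seq_len(nc)) {
      B[, j + nc * (t - 1L)] <- as.vector(calib_data[j, rs + tgt[t], xs])
    }
  }
  AhA <- crossprod(Conj(A), A)
  lam <- regularization * mean(Re(diag(AhA)))
  W <- solve(AhA + diag(lam, n_unknown), crossprod(Conj(A), B))
  resid <- sqrt(sum(Mod(A %*% W - B)^2) / sum(Mod(B)^2))
  structure(list(
    weights = W,
    geometry = geometry,
    dims = list(ncoils = nc, nsrc = nsrc, ntap = ntap, ntgt = ntgt),
    training_residual = resid,
    regularization = regularization
  ), class = "grappa_kernel")
}

# predict the target line(s) of a job for one slice/echo k-space
# `ksp` (lines x kx x coils, rows indexed by acquired position).
# `pos_of` maps grid ky line -> row position.  kx is treated as
# circular (matching the FFT model used by the g-factor propagation).
predict_job_lines <- function(ksp, kernel, r0, pos_of) {
  geom <- kernel$geometry
  nc <- kernel$dims$ncoils
  nx <- dim(ksp)[2L]
  nsrc <- kernel$dims$nsrc; ntap <- kernel$dims$ntap
  A <- matrix(0 + 0i, nx, nc * nsrc * ntap)
  for (l in seq_len(nsrc)) {
    p <- pos_of[r0 + geom$source_offsets[l]]
    for (d in seq_len(ntap)) {
      idx <- ((seq_len(nx) - 1L + geom$taps[d]) %% nx) + 1L
      for (c in seq_len(nc)) {
        A[, src_col_index(nc, ntap, c, d, l)] <- ksp[p, idx, c]
      }
    }
  }
  A %*% kernel$weights   # nx x (nc * ntgt)
}

#' Build the worst-first estimation plan for corrupted lines
#'
#' Isolated corrupted lines become 1-AMCL jobs and adjacent pairs
#' 2-AMCL jobs.  For runs of three or more adjacent corrupted lines
#' only the two worst-scoring lines are estimated (as one adjacent
#' 2-AMCL pair anchored on the worst line); the remaining run lines
#' are skipped.  Jobs are ordered worst score first and the total
#' number of estimated lines is capped (default 12) to bound g-factor
#' noise amplification; jobs that would exceed the cap are skipped
#' with reason `"cap"`.
#'
#' @param corrupted logical vector over acquired lines (TR order).
#' @param line_scores quality score of each line (lower = worse).
#' @param cap maximum number of estimated lines (default 12).
#' @param acquired_ky grid ky index of each position (default
#'   sequential, position = grid line).
#' @return An `estimation_plan`: `jobs` (list of `lines` (grid ky),
#'   `kind`, `score`), `skipped_lines` (data frame `line`, `reason`).
#' @export
build_estimation_plan <- function(corrupted, line_scores, cap = 12L,
                                  acquired_ky = seq_along(corrupted)) {
  stopifnot(length(corrupted) == length(line_scores))
  jobs <- list()
  skipped <- data.frame(line = integer(), reason = character())
  r <- rle(as.logical(corrupted))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    run <- starts[k]:ends[k]
    if (length(run) == 1L) {
      jobs <- c(jobs, list(list(pos = run, kind = "1-AMCL",
                                score = line_scores[run])))
    } else if (length(run) == 2L) {
      jobs <- c(jobs, list(list(pos = run, kind = "2-AMCL",
                                score = min(line_scores[run]))))
    } else {
      # > 2 adjacent: estimate only the two worst as an adjacent pair
      worst <- run[which.min(line_scores[run])]
      nb <- intersect(c(worst - 1L, worst + 1L), run)
      mate <- nb[which.min(line_scores[nb])]
      pair <- sort(c(worst, mate))
      jobs <- c(jobs, list(list(pos = pair, kind = "2-AMCL",
                                score = min(line_scores[pair]))))
      rest <- setdiff(run, pair)
      skipped <- rbind(skipped, data.frame(
        line = acquired_ky[rest], reason = ">2-adjacent"))
    }
  }
  ord <- order(vapply(jobs, `[[`, numeric(1), "score"))
  jobs <- jobs[ord]
  total <- 0L
  kept <- list()
  for (jb in jobs) {
    if (total + length(jb$pos) <= cap) {
      total <- total + length(jb$pos)
      jb$lines <- acquired_ky[jb$pos]
      kept <- c(kept, list(jb))
    } else {
      skipped <- rbind(skipped, data.frame(
        line = acquired_ky[jb$pos], reason = "cap"))
    }
  }
  structure(list(jobs = kept, skipped_lines = skipped,
                 cap = as.integer(cap),
                 n_lines = total,
                 corrupted = as.logical(corrupted),
                 acquired_ky = acquired_ky),
            class = "estimation_plan")
}

#' @export
print.estimation_plan <- function(x, ...) {
  cat(sprintf("estimation_plan: %d jobs, %d lines (cap %d), %d skipped\n",
              length(x$jobs), x$n_lines, x$cap, nrow(x$skipped_lines)))
  invisible(x)
}

#' Extract the calibration region of a dataset
#'
#' The central `width` acquired ky lines (clamped into the acquired
#' range, always containing the centre line) of one slice and echo,
#' as a `(coils, ky, kx)` array for [calibrate_kernel()].
#'
#' @param dataset a `kspace_dataset` with imaging data.
#' @param slice,echo which slice/echo to extract.
#' @param width number of ky lines (default 24).
#' @return complex array `(coils, ky, kx)`.
#' @export
calib_region_data <- function(dataset, slice = 1L, echo = 1L, width = 24L) {
  sch <- dataset$schedule
  ctr <- sch$center_line
  lo <- ctr - (width %/% 2L - 1L) - (width %% 2L)
  # clamp the window into the acquired range (the post-centre part of
  # a partial-Fourier acquisition is short)
  lo <- min(lo, max(sch$acquired_ky) - width + 1L)
  lo <- max(lo, min(sch$acquired_ky))
  lines <- lo:(lo + width - 1L)
  pos <- match(lines, sch$acquired_ky)
  if (anyNA(pos)) stop("calibration region extends outside acquired lines")
  if (!ctr %in% lines) stop("calibration region does not contain the centre line")
  sub <- dataset$data[slice, echo, pos, , , drop = FALSE]
  d <- dim(sub)
  aperm(array(sub, dim = d[3:5]), c(3, 1, 2))
}

#' Calibrate the kernels needed by an estimation plan
#'
#' One kernel per kind per slice, trained on the calibration region of
#' the given echo (GRAPPA weights encode coil geometry and carry over
#' between echoes).
#'
#' @param dataset a `kspace_dataset` (after any central-line
#'   replacement).
#' @param plan an [build_estimation_plan()] result.
#' @param calib_width width of the calibration region in ky lines.
#' @param calib_echo echo used for training (default 1, highest SNR).
#' @param regularization passed to [calibrate_kernel()].
#' @return nested list `kernels[[slice]][[kind]]`.
#' @export
calibrate_plan_kernels <- function(dataset, plan, calib_width = 24L,
                                   calib_echo = 1L, regularization = 1e-6) {
  kinds <- unique(vapply(plan$jobs, `[[`, character(1), "kind"))
  nsl <- dataset$schedule$n_slices
  lapply(seq_len(nsl), function(sl) {
    cd <- calib_region_data(dataset, slice = sl, echo = calib_echo,
                            width = calib_width)
    ks <- lapply(kinds, function(k) {
      calibrate_kernel(cd, kind = k, regularization = regularization)
    })
    names(ks) <- kinds
    ks
  })
}

#' Apply an estimation plan to a dataset
#'
#' Processes jobs in plan (worst-first) order; each job's target lines
#' are overwritten, for every slice and echo, by the GRAPPA kernel
#' prediction from the surrounding source lines.  A job is only
#' executed if all its source lines are clean — acquired and either
#' never corrupted, already replaced, or estimated by an earlier job;
#' otherwise it is moved to the skipped list with a reason.
#'
#' @param dataset a `kspace_dataset` (after central-line replacement).
#' @param plan an `estimation_plan`.
#' @param kernels kernels as returned by [calibrate_plan_kernels()];
#'   calibrated automatically when `NULL`.
#' @param calib_width,calib_echo,regularization calibration settings
#'   used when `kernels` is `NULL`.
#' @return The dataset with estimated lines written into `data`;
#'   `estimation_log` records applied jobs and skipped lines.
#' @export
apply_plan <- function(dataset, plan, kernels = NULL, calib_width = 24L,
                       calib_echo = 1L, regularization = 1e-6) {
  if (length(plan$jobs) == 0L) {
    dataset$estimation_log <- list(applied = list(),
                                   skipped = plan$skipped_lines)
    return(dataset)
  }
  if (is.null(kernels)) {
    kernels <- calibrate_plan_kernels(dataset, plan, calib_width = calib_width,
                                      calib_echo = calib_echo,
                                      regularization = regularization)
  }
  sch <- dataset$schedule
  acq <- sch$acquired_ky
  pos_of <- rep(NA_integer_, sch$matrix_size[["ny"]])
  pos_of[acq] <- seq_along(acq)
  nsl <- sch$n_slices; ne <- sch$n_imaging_echoes
  # line status: TRUE = usable as a source
  clean <- rep(TRUE, length(acq))
  clean[plan$corrupted] <- FALSE
  skipped <- plan$skipped_lines
  applied <- list()
  for (jb in plan$jobs) {
    r0 <- jb$lines[1L]
    if (is.null(kernels[[1L]][[jb$kind]])) {
      stop("no kernel of kind ", jb$kind, " supplied")
    }
    geom <- kernels[[1L]][[jb$kind]]$geometry
    src_lines <- r0 + geom$source_offsets
    if (any(src_lines < 1L | src_lines > length(pos_of))) {
      skipped <- rbind(skipped, data.frame(
        line = jb$lines, reason = "no clean neighbors"))
      next
    }
    src_pos <- pos_of[src_lines]
    if (anyNA(src_pos)) {
      skipped <- rbind(skipped, data.frame(
        line = jb$lines, reason = "no clean neighbors"))
      next
    }
    if (!all(clean[src_pos])) {
      skipped <- rbind(skipped, data.frame(
        line = jb$lines, reason = "corrupted source"))
      next
    }
    for (sl in seq_len(nsl)) {
      kern <- kernels[[sl]][[jb$kind]]
      nc <- kern$dims$ncoils
      for (e in seq_len(ne)) {
        ksp <- dataset$data[sl, e, , , , drop = FALSE]
        ksp <- array(ksp, dim = dim(ksp)[3:5])         # lines x kx x coils
        pred <- predict_job_lines(ksp, kern, r0, pos_of)
        for (t in seq_along(jb$lines)) {
          cols <- seq_len(nc) + nc * (t - 1L)
          dataset$data[sl, e, pos_of[jb$lines[t]], , ] <- pred[, cols]
        }
      }
    }
    clean[pos_of[jb$lines]] <- TRUE
    applied <- c(applied, list(jb))
  }
  dataset$estimation_log <- list(applied = applied, skipped = skipped)
  dataset
}

#' RSS-reference coil combination weights
#'
#' Matched-filter weights evaluated from the clean coil sensitivity
#' maps: `w_j(x) = S_j(x) / sqrt(sum_j |S_j(x)|^2)`, floored off the
#' object so weights stay finite.  Combining coil images as
#' `sum_j Conj(w_j) I_j` reproduces the root-sum-of-squares magnitude
#' on the reference object while remaining a fixed linear map, as
#' required for noise propagation.
#'
#' @param coils a [make_coil_profiles()] result.
#' @return complex array `(ncoils, ny, nx)` with unit per-pixel norm.
#' @export
rss_combine_weights <- function(coils) {
  s <- coils$sensitivities
  rss <- sqrt(apply(abs(s)^2, c(2, 3), sum))
  rss <- pmax(rss, 1e-6 * max(rss))
  sweep(s, c(2, 3), rss, "/")
}
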