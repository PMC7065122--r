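#' Navigator slice score
#'
#' The slice score of one echo train is the sum of the magnitude of
#' the navigator readout over all readout points and all receive
#' channels: `S_sl(ky) = sum_c sum_kx |N_sl(kx, ky, c)|`.  Any motion
#' during the echo train (dephasing, through-plane signal change)
#' reduces this score.
#'
#' @param navigator_readout complex matrix/array (`kx x coils`) of one
#'   navigator readout.
#' @return nonnegative scalar.
#' @examples
#' slice_score(matrix(3 + 4i, 1, 1))  # 5
#' @export
slice_score <- function(navigator_readout) {
  if (length(navigator_readout) == 0L) stop("empty navigator readout")
  sum(abs(navigator_readout))
}

#' Per-TR quality score
#'
#' The quality score of a TR block is the sum of the slice scores of
#' all slices acquired in that TR: `S_TR = sum_sl S_sl(ky)`.
#'
#' @param slice_scores_for_tr numeric vector of length `n_slices`.
#' @param n_slices expected number of slices (length check); `NULL`
#'   skips the check.
#' @return nonnegative scalar.
#' @export
tr_quality_score <- function(slice_scores_for_tr, n_slices = NULL) {
  if (!is.null(n_slices) && length(slice_scores_for_tr) != n_slices) {
    stop("expected one slice score per slice (", n_slices, ")")
  }
  sum(slice_scores_for_tr)
}

# centred truncated sliding window indices; even widths take one more
# element on the left (current + previous), as movmedian does
window_bounds <- function(i, n, width) {
  lo <- i - (width %/% 2L)
  hi <- i + ((width - 1L) %/% 2L)
  c(max(1L, lo), min(n, hi))
}

sliding_median <- function(x, width) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    b <- window_bounds(i, n, width)
    stats::median(x[b[1]:b[2]])
  }, numeric(1))
}

#' Drift adjustment of quality scores
#'
#' Slow drift of the neck position changes the total signal in the
#' slice and therefore the quality score baseline.  It is removed by
#' subtracting the local median score computed over a centred sliding
#' window (truncated at the sequence ends).
#'
#' @param scores numeric sequence of per-TR (or per-slice) scores.
#' @param window sliding window width (default 10).
#' @return drift-adjusted scores (same length).
#' @export
adjust_drift <- function(scores, window = 10L) {
  if (window < 1L) stop("window must be >= 1")
  if (length(scores) < window) stop("sequence shorter than the window")
  scores - sliding_median(scores, window)
}

#' Hampel-style detection of motion-corrupted lines
#'
#' Flags drift-adjusted scores that fall below the local median by
#' more than `n_sd` robust standard deviations, where the robust SD is
#' the scaled median absolute deviation (`1.4826 * MAD`) over a
#' centred sliding window.  The test is one-sided: only low scores
#' (signal loss) are flagged; high outliers are ignored.
#'
#' @param adjusted_scores drift-adjusted score sequence.
#' @param window Hampel window width (default 25).
#' @param n_sd threshold in robust SDs (default 3).
#' @return logical vector, `TRUE` for corrupted lines.
#' @export
detect_corrupted <- function(adjusted_scores, window = 25L, n_sd = 3) {
  if (window < 3L) stop("window must be >= 3")
  n <- length(adjusted_scores)
  flags <- logical(n)
  for (i in seq_len(n)) {
    b <- window_bounds(i, n, window)
    w <- adjusted_scores[b[1]:b[2]]
    med <- stats::median(w)
    sig <- 1.4826 * stats::median(abs(w - med))
    flags[i] <- adjusted_scores[i] < med - n_sd * sig
  }
  flags
}

#' ky weighting function for online quality scores
#'
#' A unimodal weight over ky grid lines peaking at the centre line,
#' used to prioritise central k-space during online reacquisition
#' ranking: raw TR scores are divided by the weight of their ky line,
#' so for equal raw scores a central-ky TR ranks as lower quality and
#' is reacquired first.
#'
#' @param ny full phase-encode matrix size.
#' @param center_line 1-based centre (ky = 0) grid line.
#' @param shape `"gaussian"` (default) or `"triangular"`.
#' @param fwhm_lines full width at half maximum of the Gaussian in
#'   lines (default 48); for `"triangular"`, the half-width of the
#'   triangle base.
#' @param floor minimum weight (keeps weights strictly positive).
#' @return numeric vector of length `ny`, in `(0, 1]`.
#' @export
ky_weighting <- function(ny, center_line = ny %/% 2L + 1L,
                         shape = c("gaussian", "triangular"),
                         fwhm_lines = 48, floor = 0.05) {
  shape <- match.arg(shape)
  d <- abs(seq_len(ny) - center_line)
  w <- switch(shape,
              gaussian = exp(-4 * log(2) * d^2 / fwhm_lines^2),
              triangular = pmax(0, 1 - d / fwhm_lines))
  pmax(w, floor)
}

#' Centre-weighted online quality score
#'
#' @param tr_score raw per-TR quality score(s).
#' @param ky_of_tr ky grid line(s) acquired by the TR(s).
#' @param weighting weight vector over the full ky grid (see
#'   [ky_weighting()]); all weights must be positive.
#' @return weighted score(s) `tr_score / weighting[ky]`; lower means
#'   worse quality.
#' @export
center_weighted_score <- function(tr_score, ky_of_tr, weighting) {
  if (any(ky_of_tr < 1L | ky_of_tr > length(weighting))) {
    stop("ky index outside the grid")
  }
  w <- weighting[ky_of_tr]
  if (any(w <= 0)) stop("weights must be positive")
  tr_score / w
}

#' Quality trace of a simulated or loaded dataset
#'
#' Computes per-(slice, TR) navigator scores, per-TR quality scores,
#' drift-adjusted scores and the corrupted-TR mask in one pass.
#' Detection is at TR granularity (whole TR blocks are reacquired /
#' estimated); per-slice flags are available via `per_slice = TRUE`.
#'
#' @param dataset a `kspace_dataset`.
#' @param drift_window sliding-median window for drift adjustment.
#' @param hampel_window window of the outlier detector.
#' @param n_sd detection threshold in robust SDs.
#' @param per_slice also compute per-slice corruption flags.
#' @return A `quality_trace` object: `slice_scores` (slices x TRs),
#'   `tr_scores`, `adjusted_tr_scores`, `corrupted_mask` (per TR),
#'   `ky_of_tr`, `reacq_tr_scores` (scores of the reacquisition block,
#'   aligned with `dataset$reacq_trs`), and the parameters used.
#' @export
quality_trace <- function(dataset, drift_window = 10L,
                          hampel_window = 25L, n_sd = 3,
                          per_slice = FALSE) {
  nav <- dataset$navigators
  slice_scores <- apply(abs(nav), c(1, 2), sum)
  tr_scores <- colSums(slice_scores)
  adjusted <- adjust_drift(tr_scores, window = drift_window)
  mask <- detect_corrupted(adjusted, window = hampel_window, n_sd = n_sd)
  slice_mask <- NULL
  if (per_slice) {
    slice_mask <- t(apply(slice_scores, 1, function(s) {
      detect_corrupted(adjust_drift(s, window = drift_window),
                       window = hampel_window, n_sd = n_sd)
    }))
  }
  reacq_scores <- NULL
  if (!is.null(dataset$reacq_navigators)) {
    rss <- apply(abs(dataset$reacq_navigators), c(1, 2), sum)
    reacq_scores <- colSums(rss)
  }
  structure(list(
    slice_scores = slice_scores,
    tr_scores = tr_scores,
    adjusted_tr_scores = adjusted,
    corrupted_mask = mask,
    slice_corrupted_mask = slice_mask,
    ky_of_tr = dataset$schedule$acquired_ky,
    reacq_tr_scores = reacq_scores,
    params = list(drift_window = drift_window,
                  hampel_window = hampel_window, n_sd = n_sd)
  ), class = "quality_trace")
}

#' @export
print.quality_trace <- function(x, ...) {
  cat(sprintf("quality_trace: %d TRs, %d flagged corrupted\n",
              length(x$tr_scores), sum(x$corrupted_mask)))
  invisible(x)
}
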