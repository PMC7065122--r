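#' Select TRs for end-of-scan reacquisition
#'
#' Ranks TR blocks by their (optionally centre-weighted) quality
#' scores and selects the `n_reacq` lowest for reacquisition.  Ties
#' are broken by proximity of the TR's ky line to the centre line,
#' then by lower TR index.
#'
#' @param tr_scores per-TR quality scores.
#' @param n_reacq number of TRs to reacquire (`0 <= n_reacq <= n_TRs`).
#' @param weighting optional weight vector over the full ky grid (see
#'   [ky_weighting()]); scores are divided by the weight of the TR's
#'   ky line before ranking.
#' @param ky ky grid line of each TR (needed for weighting and tie
#'   breaks; defaults to the TR index, i.e. sequential ordering).
#' @param center_line centre ky line for tie breaking.
#' @return A `reacq_plan`: `tr_indices` (ordered worst first),
#'   `n_reacq`, `ranked_scores`.
#' @examples
#' select_reacq_trs(c(5, 1, 3), 1)$tr_indices  # 2
#' @export
select_reacq_trs <- function(tr_scores, n_reacq, weighting = NULL,
                             ky = seq_along(tr_scores),
                             center_line = length(tr_scores) %/% 2L + 1L) {
  n <- length(tr_scores)
  if (n_reacq < 0L || n_reacq > n) {
    stop("n_reacq must be between 0 and the number of TRs (", n, ")")
  }
  ranked <- tr_scores
  if (!is.null(weighting)) {
    ranked <- center_weighted_score(tr_scores, ky, weighting)
  }
  ord <- order(ranked, abs(ky - center_line), seq_len(n))
  idx <- ord[seq_len(n_reacq)]
  structure(list(tr_indices = idx, n_reacq = as.integer(n_reacq),
                 ranked_scores = ranked[idx]),
            class = "reacq_plan")
}

# internal: replace line data + navigator of one TR with its
# reacquisition (all slices, all echoes)
swap_in_reacq <- function(dataset, tr, reacq_idx) {
  dataset$data[, , tr, , ] <- dataset$reacq_data[, , reacq_idx, , ]
  dataset$navigators[, tr, , ] <- dataset$reacq_navigators[, reacq_idx, , ]
  dataset
}

# internal: best reacquisition (by score) available for each TR
reacq_lookup <- function(dataset, reacq_scores) {
  if (is.null(dataset$reacq_trs)) {
    return(list(idx = integer(), score = numeric()))
  }
  best_idx <- integer(0); best_score <- numeric(0); trs <- integer(0)
  for (tr in unique(dataset$reacq_trs)) {
    cand <- which(dataset$reacq_trs == tr)
    k <- cand[which.max(reacq_scores[cand])]
    trs <- c(trs, tr); best_idx <- c(best_idx, k)
    best_score <- c(best_score, reacq_scores[k])
  }
  list(trs = trs, idx = best_idx, score = best_score)
}

# shared engine for central-only / all-line reacquisition merges
merge_reacq_impl <- function(dataset, qc, reacq_scores, lines = NULL) {
  if (is.null(reacq_scores)) reacq_scores <- qc$reacq_tr_scores
  if (is.null(reacq_scores)) stop("no reacquisition scores available")
  lut <- reacq_lookup(dataset, reacq_scores)
  corrupted <- which(qc$corrupted_mask)
  if (!is.null(lines)) {
    corrupted <- corrupted[qc$ky_of_tr[corrupted] %in% lines]
  }
  replaced <- integer(0); unavailable <- integer(0); kept <- integer(0)
  for (tr in corrupted) {
    j <- match(tr, lut$trs)
    if (is.na(j)) {
      unavailable <- c(unavailable, tr)
      next
    }
    if (lut$score[j] > qc$tr_scores[tr]) {
      dataset <- swap_in_reacq(dataset, tr, lut$idx[j])
      replaced <- c(replaced, tr)
    } else {
      kept <- c(kept, tr)
    }
  }
  if (length(unavailable)) {
    warning("corrupted line(s) with no reacquisition available: TR ",
            paste(unavailable, collapse = ", "),
            " (left for the estimation plan)")
  }
  log <- list(replaced_trs = replaced,
              replaced_ky = qc$ky_of_tr[replaced],
              kept_lower_score = kept,
              no_reacq_available = unavailable)
  dataset$merge_log <- c(dataset$merge_log, list(log))
  dataset
}

#' Replace corrupted central k-space lines with reacquisitions
#'
#' To protect the GRAPPA calibration region, motion-corrupted data in
#' the `n_central` lines centred on the ky = 0 line are replaced by
#' their reacquisitions, provided the reacquired TR has a higher
#' quality score than the original.  Lines outside the central band,
#' and central lines whose reacquisition scored lower (or is missing),
#' are left for the estimation plan.
#'
#' @param dataset a `kspace_dataset` with a reacquisition block.
#' @param qc a [quality_trace()] of the dataset.
#' @param reacq_scores quality scores of the reacquisition TRs
#'   (default: taken from `qc$reacq_tr_scores`).
#' @param n_central width of the protected central band (default 7).
#' @return The dataset with replaced lines; `merge_log` records which
#'   TRs/lines were replaced, kept, or had no reacquisition.
#' @export
replace_central_lines <- function(dataset, qc, reacq_scores = NULL,
                                  n_central = 7L) {
  ctr <- dataset$schedule$center_line
  half_lo <- n_central %/% 2L
  half_hi <- n_central - half_lo - 1L
  lines <- (ctr - half_lo):(ctr + half_hi)
  merge_reacq_impl(dataset, qc, reacq_scores, lines = lines)
}

#' Replace all corrupted lines with reacquisitions ("Reacq" arm)
#'
#' Every corrupted line, not just the central band, is replaced by its
#' reacquisition under the same higher-score rule.  This is the
#' reacquisition-only comparator reconstruction.
#'
#' @inheritParams replace_central_lines
#' @return The merged dataset with `merge_log`.
#' @export
merge_reacq_all <- function(dataset, qc, reacq_scores = NULL) {
  merge_reacq_impl(dataset, qc, reacq_scores, lines = NULL)
}
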