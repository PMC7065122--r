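#' MESE acquisition schedule
#'
#' Describes the segmented multi-slice multi-echo spin echo (MESE)
#' acquisition: a Cartesian `ny x nx` matrix sampled with 5/8 partial
#' Fourier along the phase-encode (ky) direction, one ky line per TR
#' (all slices within each TR), 14 imaging echoes plus one navigator
#' echo (an unencoded ky = 0 readout) at the end of the echo train.
#'
#' Defaults reproduce a 3T carotid-wall protocol: `192 x 192` matrix,
#' 120 acquired ky lines of which line 97 (the `ny/2 + 1` grid line,
#' ky = 0) is the centre, 5 slices, TR = 2 s, echo spacing 9.1 ms,
#' navigator TE = 15 x 9.1 = 136.5 ms, and 16 end-of-scan
#' reacquisition TRs.
#'
#' ky indices are 1-based positions on the full `ny` grid throughout
#' the public interface; the acquired lines are stored in acquisition
#' (TR) order in `acquired_ky`.
#'
#' @param matrix_size integer length-2, `(ny, nx)`.
#' @param partial_fourier fraction of ky lines acquired (default 5/8).
#' @param n_slices number of slices per TR block.
#' @param tr_s repetition time in seconds.
#' @param echo_spacing_ms spacing of the spin echoes in milliseconds.
#' @param n_imaging_echoes number of imaging echoes (T2-weighted).
#' @param n_reacq_trs number of reacquisition TRs appended at the end
#'   of the scan.
#' @param n_prep_trs preparation/dummy TRs before imaging (counted in
#'   the scan duration only).
#' @return An object of class `mese_schedule`.
#' @examples
#' sch <- mese_schedule()
#' length(sch$acquired_ky)   # 120
#' sch$center_line           # 97
#' navigator_te_ms(sch)      # 136.5
#' @export
mese_schedule <- function(matrix_size = c(192L, 192L),
                          partial_fourier = 5 / 8,
                          n_slices = 5L,
                          tr_s = 2.0,
                          echo_spacing_ms = 9.1,
                          n_imaging_echoes = 14L,
                          n_reacq_trs = 16L,
                          n_prep_trs = 2L) {
  ny <- as.integer(matrix_size[1L])
  nx <- as.integer(matrix_size[2L])
  if (ny < 8L || nx < 8L) {
    stop("matrix_size must be at least 8 x 8")
  }
  if (partial_fourier <= 0.5 || partial_fourier > 1) {
    stop("partial_fourier must be in (0.5, 1] so the centre line is sampled")
  }
  n_acq <- as.integer(round(partial_fourier * ny))
  center_line <- ny %/% 2L + 1L
  if (n_acq < center_line) {
    stop("partial Fourier fraction does not reach the centre line")
  }
  sch <- structure(list(
    matrix_size = c(ny = ny, nx = nx),
    partial_fourier = partial_fourier,
    # sequential bottom-up ordering: TR t acquires grid line t
    acquired_ky = seq_len(n_acq),
    center_line = center_line,
    n_slices = as.integer(n_slices),
    tr_s = tr_s,
    echo_spacing_ms = echo_spacing_ms,
    n_imaging_echoes = as.integer(n_imaging_echoes),
    navigator_echo_index = as.integer(n_imaging_echoes) + 1L,
    n_reacq_trs = as.integer(n_reacq_trs),
    n_prep_trs = as.integer(n_prep_trs),
    slice_order = seq_len(as.integer(n_slices))
  ), class = "mese_schedule")
  sch
}

#' @export
print.mese_schedule <- function(x, ...) {
  cat(sprintf(
    "MESE schedule: %d x %d matrix, %d acquired ky lines (centre %d)\n",
    x$matrix_size["ny"], x$matrix_size["nx"],
    length(x$acquired_ky), x$center_line
  ))
  cat(sprintf(
    "  %d slices, TR %.3g s, %d echoes at %.3g ms + navigator (TE %.4g ms)\n",
    x$n_slices, x$tr_s, x$n_imaging_echoes, x$echo_spacing_ms,
    navigator_te_ms(x)
  ))
  cat(sprintf(
    "  %d reacquisition TRs, total scan %s\n",
    x$n_reacq_trs, format_scan_time(scan_duration_s(x))
  ))
  invisible(x)
}

#' Echo times of the imaging echo train
#'
#' @param schedule a [mese_schedule()].
#' @return numeric vector of TEs in ms (`echo_spacing_ms * 1:n_echoes`).
#' @export
echo_times_ms <- function(schedule) {
  schedule$echo_spacing_ms * seq_len(schedule$n_imaging_echoes)
}

#' Navigator echo time
#'
#' The navigator is one extra unencoded echo after the imaging train,
#' so its TE is `navigator_echo_index * echo_spacing_ms`.
#'
#' @param schedule a [mese_schedule()].
#' @return navigator TE in ms.
#' @export
navigator_te_ms <- function(schedule) {
  schedule$navigator_echo_index * schedule$echo_spacing_ms
}

#' Total scan duration
#'
#' One ky line of all slices is acquired per TR, followed by the
#' reacquisition TRs; preparation TRs are added once.
#'
#' @param schedule a [mese_schedule()].
#' @param n_reacq_trs override of the number of reacquisition TRs
#'   (default taken from the schedule).
#' @return scan duration in seconds.
#' @export
scan_duration_s <- function(schedule, n_reacq_trs = schedule$n_reacq_trs) {
  (length(schedule$acquired_ky) + n_reacq_trs + schedule$n_prep_trs) *
    schedule$tr_s
}

format_scan_time <- function(seconds) {
  sprintf("%d:%02d min", floor(seconds / 60), round(seconds %% 60))
}

#' Map between TR index and ky grid line
#'
#' TR `t` of the imaging block acquires grid line `acquired_ky[t]`
#' for every slice.
#'
#' @param schedule a [mese_schedule()].
#' @param tr TR indices (1-based).
#' @return ky grid line indices (1-based on the full ny grid).
#' @export
ky_of_tr <- function(schedule, tr = seq_along(schedule$acquired_ky)) {
  n <- length(schedule$acquired_ky)
  if (any(tr < 1L | tr > n)) {
    stop("TR index outside the imaging block")
  }
  schedule$acquired_ky[tr]
}

# internal: validate mutual consistency of a schedule
validate_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "mese_schedule"))
  ny <- schedule$matrix_size[["ny"]]
  if (length(schedule$acquired_ky) != round(schedule$partial_fourier * ny)) {
    stop("acquired_ky length inconsistent with partial_fourier")
  }
  if (schedule$center_line != ny %/% 2L + 1L) {
    stop("center_line must be ny/2 + 1")
  }
  if (!schedule$center_line %in% schedule$acquired_ky) {
    stop("centre line not among acquired lines")
  }
  invisible(schedule)
}
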