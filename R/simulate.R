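#' Motion event specification
#'
#' Ground-truth description of injected corruption.  Each event spans a
#' contiguous block of TRs during which the per-TR global amplitude is
#' reduced by `amplitude_drop_fraction` (the navigator-visible
#' signature of swallowing: 10%-25% drops are typical), each acquired
#' line receives a random phase offset with sd `phase_jitter_sd`, and
#' the throat structure is displaced by `throat_shift_px` pixels along
#' the phase-encode (anteroposterior) direction.  A slow scan-long
#' drift of the global amplitude models gradual neck position change.
#'
#' @param events data frame with columns `tr_start`, `tr_end`,
#'   `amplitude_drop_fraction` (in `[0, 1]`), `phase_jitter_sd`
#'   (radians), `throat_shift_px`.
#' @param drift list with `amplitude_fraction` (total fractional signal
#'   change over the scan) and `shape` (`"linear"` or `"smooth"`).
#' @return A `motion_spec` object.
#' @examples
#' motion_spec(data.frame(tr_start = 45, tr_end = 46,
#'                        amplitude_drop_fraction = 0.2,
#'                        phase_jitter_sd = 0.5, throat_shift_px = 3))
#' @export
motion_spec <- function(events = NULL,
                        drift = list(amplitude_fraction = 0, shape = "linear")) {
  if (is.null(events)) {
    events <- data.frame(tr_start = integer(), tr_end = integer(),
                         amplitude_drop_fraction = numeric(),
                         phase_jitter_sd = numeric(),
                         throat_shift_px = numeric())
  }
  need <- c("tr_start", "tr_end", "amplitude_drop_fraction",
            "phase_jitter_sd", "throat_shift_px")
  missing_cols <- setdiff(need, names(events))
  if (length(missing_cols)) {
    stop("events is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(events$amplitude_drop_fraction < 0 |
            events$amplitude_drop_fraction > 1)) {
    stop("amplitude_drop_fraction must be in [0, 1]")
  }
  if (any(events$tr_end < events$tr_start)) stop("tr_end < tr_start")
  drift <- utils::modifyList(list(amplitude_fraction = 0, shape = "linear"),
                             as.list(drift))
  if (!drift$shape %in% c("linear", "smooth")) {
    stop("drift shape must be 'linear' or 'smooth'")
  }
  structure(list(events = events, drift = drift), class = "motion_spec")
}

#' Default swallowing scenario
#'
#' Emulates an instructed-swallowing protocol: 5 swallow-like events in
#' the second part of the scan (lines ~40-120), each lasting 1-2 TRs,
#' with amplitude drops drawn from 10%-25%, phase jitter of ~0.5 rad,
#' throat displacement of ~3 px (~2 mm at 0.67 mm resolution), and a
#' smooth 5% amplitude drift over the scan.
#'
#' @param n_trs number of imaging TRs in the scan.
#' @param n_events number of swallow events.
#' @param rng_seed seed for drawing event times/amplitudes.
#' @param drop_range range of `amplitude_drop_fraction`.
#' @param drift_fraction total drift amplitude fraction.
#' @return A [motion_spec()].
#' @export
default_motion_scenario <- function(n_trs = 120L, n_events = 5L,
                                    rng_seed = 7L,
                                    drop_range = c(0.10, 0.25),
                                    drift_fraction = 0.05) {
  set.seed(rng_seed)
  first <- max(2L, round(n_trs / 3))
  # event start times spread over the motion period, non-overlapping
  slots <- seq(first, n_trs - 2L, length.out = n_events + 1L)
  starts <- round(utils::head(slots, n_events) +
                    stats::runif(n_events, 0, diff(slots)[1] * 0.4))
  len <- sample(1:2, n_events, replace = TRUE)
  events <- data.frame(
    tr_start = as.integer(starts),
    tr_end = as.integer(pmin(starts + len - 1L, n_trs)),
    amplitude_drop_fraction = stats::runif(n_events, drop_range[1], drop_range[2]),
    phase_jitter_sd = 0.5,
    throat_shift_px = stats::runif(n_events, 2, 4) * sample(c(-1, 1), n_events, TRUE)
  )
  motion_spec(events, drift = list(amplitude_fraction = drift_fraction,
                                   shape = "smooth"))
}

# per-TR state implied by a motion_spec: global amplitude, throat
# shift (px), phase jitter sd
motion_state <- function(motion, n_trs) {
  a <- motion$drift$amplitude_fraction
  tt <- if (n_trs > 1L) (seq_len(n_trs) - 1) / (n_trs - 1) else 0
  drift <- switch(motion$drift$shape,
                  linear = 1 - a * tt,
                  smooth = 1 - a * (1 - cos(pi * tt)) / 2)
  amp <- drift
  shift <- numeric(n_trs)
  jitter <- numeric(n_trs)
  ev <- motion$events
  if (nrow(ev)) {
    if (any(ev$tr_start < 1L) || any(ev$tr_end > n_trs)) {
      stop("motion events reference TRs beyond the scan length")
    }
    for (k in seq_len(nrow(ev))) {
      idx <- ev$tr_start[k]:ev$tr_end[k]
      amp[idx] <- amp[idx] * (1 - ev$amplitude_drop_fraction[k])
      shift[idx] <- ev$throat_shift_px[k]
      jitter[idx] <- pmax(jitter[idx], ev$phase_jitter_sd[k])
    }
  }
  event_mask <- logical(n_trs)
  if (nrow(ev)) {
    for (k in seq_len(nrow(ev))) event_mask[ev$tr_start[k]:ev$tr_end[k]] <- TRUE
  }
  list(amp = amp, drift = drift, shift = shift, jitter = jitter,
       event_mask = event_mask)
}

# complex circular Gaussian noise with E|n|^2 = sd^2
cnoise <- function(n, sd) {
  complex(real = stats::rnorm(n, sd = sd / sqrt(2)),
          imaginary = stats::rnorm(n, sd = sd / sqrt(2)))
}

#' Simulate a segmented multi-coil MESE acquisition with navigators
#'
#' Line-by-line simulation of the acquisition in TR order.  Per TR the
#' object state (throat position, global amplitude including drift and
#' any event drop, per-slice random phase offset during events) is
#' applied to all echoes of that TR including the navigator echo.  The
#' navigator readout of a TR is exactly the ky = 0 (centre) line of
#' the navigator-echo k-space simulated for that TR's state.
#' Reacquisition TRs are simulated at the end-of-scan state (final
#' drift level, no event) with an optional residual bulk position
#' offset along the phase-encode direction, emulating a subject who
#' returned to a slightly different position.
#'
#' The per-echo coil image is
#' `sensitivity_c(x) * proton_density(x) * exp(-TE_e / T2(x))`
#' and its k-space is the centred unitary 2D FFT; complex circular
#' white Gaussian noise of sd `noise_sd` (per complex sample) is added
#' to every sample.
#'
#' @param phantom a [make_phantom()] result.
#' @param coils a [make_coil_profiles()] result on the same grid.
#' @param schedule a [mese_schedule()] with matching matrix size.
#' @param motion a [motion_spec()].
#' @param noise_sd complex-noise standard deviation (`E|n|^2 = sd^2`);
#'   `>= 0`.
#' @param rng_seed integer seed; identical seeds give bit-identical
#'   datasets.
#' @param navigators_only if `TRUE`, skip the imaging k-space and
#'   simulate only navigators (fast path for detector studies).
#' @param reacq_offset_px residual bulk anteroposterior offset of the
#'   reacquisition block in pixels (default 0.5 px, ~0.3 mm).
#' @param reacq_weighting optional ky weighting function used for the
#'   online ranking that selects reacquisition TRs (see
#'   [ky_weighting()]); `NULL` ranks by raw TR scores.
#' @return A `kspace_dataset` with fields `data` (complex array
#'   `slices x echoes x ky_acquired x kx x coils`, or `NULL` when
#'   `navigators_only`), `navigators` (`slices x TRs x kx x coils`),
#'   `schedule`, `reacq_data`, `reacq_navigators`, `reacq_trs` (the
#'   original TR index each reacquisition repeats), and `truth`
#'   (event table, per-TR state, corrupted-TR mask).
#' @export
simulate_mese_kspace <- function(phantom, coils, schedule,
                                 motion = motion_spec(),
                                 noise_sd = 0, rng_seed = 0L,
                                 navigators_only = FALSE,
                                 reacq_offset_px = 0.5,
                                 reacq_weighting = NULL) {
  validate_schedule(schedule)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  ny <- schedule$matrix_size[["ny"]]; nx <- schedule$matrix_size[["nx"]]
  if (!all(phantom$grid_shape == c(ny, nx))) {
    stop("phantom grid does not match schedule matrix size")
  }
  nsl <- schedule$n_slices
  nc <- coils$ncoils
  ne <- schedule$n_imaging_echoes
  nav_e <- schedule$navigator_echo_index
  acq <- schedule$acquired_ky
  nt <- length(acq)
  state <- motion_state(motion, nt)

  set.seed(rng_seed)
  # per-(slice, TR) event phase offsets
  phase <- matrix(stats::rnorm(nsl * nt), nsl, nt) * rep(state$jitter, each = nsl)

  comp <- phantom_components(phantom)
  tes <- c(echo_times_ms(schedule), navigator_te_ms(schedule))
  decay <- function(te) exp(-te / phantom$t2_map)

  # navigator row (ky = 0) of the navigator echo, per coil: a y-shift
  # of any component leaves this row untouched (zero ky frequency), so
  # it is state-independent up to the global amplitude factor.
  nav_img_static <- comp$static * decay(tes[nav_e])
  nav_img_throat <- comp$throat * decay(tes[nav_e])
  nav_row <- matrix(0 + 0i, nc, nx)  # per coil, over kx
  for (c in seq_len(nc)) {
    s <- coils$sensitivities[c, , ]
    proj <- colSums((nav_img_static + nav_img_throat) * s) / sqrt(ny)
    nav_row[c, ] <- fftshift_vec(stats::fft(ifftshift_vec(proj))) / sqrt(nx)
  }

  navigators <- array(0 + 0i, dim = c(nsl, nt, nx, nc))
  for (sl in seq_len(nsl)) {
    for (c in seq_len(nc)) {
      # rows scaled by per-TR amplitude and per-(slice,TR) phase
      fac <- state$amp * exp(1i * phase[sl, ])
      navigators[sl, , , c] <- outer(fac, nav_row[c, ])
    }
  }
  if (noise_sd > 0) {
    navigators <- navigators + cnoise(length(navigators), noise_sd)
  }

  data <- NULL
  kstat <- kthr <- NULL
  if (!navigators_only) {
    # per-echo, per-coil k-space of static and mobile components
    kstat <- vector("list", ne)
    kthr <- vector("list", ne)
    for (e in seq_len(ne)) {
      dstat <- comp$static * decay(tes[e])
      dthr <- comp$throat * decay(tes[e])
      ks <- array(0 + 0i, dim = c(nc, nt, nx))
      kt <- array(0 + 0i, dim = c(nc, nt, nx))
      for (c in seq_len(nc)) {
        s <- coils$sensitivities[c, , ]
        ks[c, , ] <- fft2c(dstat * s)[acq, , drop = FALSE]
        kt[c, , ] <- fft2c(dthr * s)[acq, , drop = FALSE]
      }
      kstat[[e]] <- ks; kthr[[e]] <- kt
    }
    # throat-translation phase per TR (depends on that TR's ky row)
    kyi <- freq_index(ny)[acq]
    rowph <- exp(-2i * pi * kyi * state$shift / ny)  # length nt
    data <- array(0 + 0i, dim = c(nsl, ne, nt, nx, nc))
    for (e in seq_len(ne)) {
      for (c in seq_len(nc)) {
        lines <- kstat[[e]][c, , ] + rowph * kthr[[e]][c, , ]
        for (sl in seq_len(nsl)) {
          fac <- state$amp * exp(1i * phase[sl, ])
          data[sl, e, , , c] <- fac * lines
        }
      }
    }
    if (noise_sd > 0) data <- data + cnoise(length(data), noise_sd)
  }

  # ---- reacquisition block: online ranking on raw TR scores ----
  n_reacq <- schedule$n_reacq_trs
  reacq <- NULL
  if (n_reacq > 0L) {
    sscore <- apply(abs(navigators), c(1, 2), sum)   # slices x TRs
    tr_scores <- colSums(sscore)
    plan <- select_reacq_trs(tr_scores, n_reacq, weighting = reacq_weighting,
                             ky = acq, center_line = schedule$center_line)
    rtrs <- plan$tr_indices
    amp_end <- state$drift[nt]
    off_ph <- exp(-2i * pi * freq_index(ny)[acq[rtrs]] * reacq_offset_px / ny)
    reacq_nav <- array(0 + 0i, dim = c(nsl, length(rtrs), nx, nc))
    for (sl in seq_len(nsl)) {
      for (c in seq_len(nc)) {
        reacq_nav[sl, , , c] <- outer(rep(amp_end, length(rtrs)), nav_row[c, ])
      }
    }
    if (noise_sd > 0) reacq_nav <- reacq_nav + cnoise(length(reacq_nav), noise_sd)
    reacq_data <- NULL
    if (!navigators_only) {
      reacq_data <- array(0 + 0i, dim = c(nsl, ne, length(rtrs), nx, nc))
      for (e in seq_len(ne)) {
        for (c in seq_len(nc)) {
          lines <- (kstat[[e]][c, rtrs, , drop = FALSE] +
                      kthr[[e]][c, rtrs, , drop = FALSE])[1, , , drop = TRUE]
          if (length(rtrs) == 1L) lines <- matrix(lines, 1L, nx)
          lines <- (amp_end * off_ph) * lines
          for (sl in seq_len(nsl)) reacq_data[sl, e, , , c] <- lines
        }
      }
      if (noise_sd > 0) {
        reacq_data <- reacq_data + cnoise(length(reacq_data), noise_sd)
      }
    }
    reacq <- list(data = reacq_data, navigators = reacq_nav, trs = rtrs)
  }

  structure(list(
    data = data,
    navigators = navigators,
    schedule = schedule,
    reacq_data = reacq$data,
    reacq_navigators = reacq$navigators,
    reacq_trs = reacq$trs,
    truth = list(motion = motion, state = state,
                 corrupted_trs = state$event_mask),
    noise_sd = noise_sd,
    rng_seed = rng_seed
  ), class = "kspace_dataset")
}

fftshift_vec <- function(x) {
  n <- length(x); c(x[(n %/% 2L + 1L):n], x[seq_len(n %/% 2L)])
}
ifftshift_vec <- function(x) {
  n <- length(x); h <- n - n %/% 2L
  c(x[(h + 1L):n], x[seq_len(h)])
}

#' @export
print.kspace_dataset <- function(x, ...) {
  sch <- x$schedule
  cat(sprintf("kspace_dataset: %d slices x %d echoes x %d lines x %d kx x %s coils\n",
              sch$n_slices, sch$n_imaging_echoes, length(sch$acquired_ky),
              sch$matrix_size[["nx"]],
              if (is.null(x$data)) "(navigators only)" else dim(x$data)[5]))
  cat(sprintf("  %d reacquisition TRs, %d truth motion events\n",
              length(x$reacq_trs), nrow(x$truth$motion$events)))
  invisible(x)
}

#' Ground-truth corrupted-line mask
#'
#' Expands the injected motion events into a per-(slice, line) logical
#' mask: `TRUE` exactly for lines acquired during event TRs.
#'
#' @param dataset a simulated `kspace_dataset` with `truth` present.
#' @return logical matrix `slices x n_acquired_lines`.
#' @export
truth_corrupted_mask <- function(dataset) {
  if (is.null(dataset$truth)) stop("dataset has no ground truth")
  nsl <- dataset$schedule$n_slices
  matrix(rep(dataset$truth$corrupted_trs, each = nsl), nrow = nsl)
}
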