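# independent brute-force oracles for the scoring chain
oracle_slice_score <- function(nav) {
  s <- 0
  for (i in seq_len(nrow(nav))) {
    for (j in seq_len(ncol(nav))) s <- s + Mod(nav[i, j])
  }
  s
}

oracle_median_window <- function(x, width) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - width %/% 2L)
    hi <- min(n, i + (width - 1L) %/% 2L)
    out[i] <- median(x[lo:hi])
  }
  out
}

oracle_hampel_low <- function(x, width, n_sd) {
  n <- length(x)
  flags <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - width %/% 2L)
    hi <- min(n, i + (width - 1L) %/% 2L)
    w <- x[lo:hi]
    m <- median(w)
    s <- 1.4826 * median(abs(w - m))
    flags[i] <- x[i] < m - n_sd * s
  }
  flags
}

test_that("slice and TR scores match their definitions", {
  expect_equal(slice_score(matrix(0 + 0i, 4, 3)), 0)
  nav <- matrix(0 + 0i, 4, 3); nav[2, 2] <- 3 + 4i
  expect_equal(slice_score(nav), 5)
  expect_error(slice_score(complex(0)), "empty")
  set.seed(42)
  r <- matrix(complex(real = rnorm(1920), imaginary = rnorm(1920)), 192, 10)
  expect_equal(slice_score(r), oracle_slice_score(r))
  # scale equivariance
  expect_equal(slice_score((-2.5 + 0i) * r), 2.5 * slice_score(r))
  expect_equal(tr_quality_score(1:5), 15)
  expect_equal(tr_quality_score(rep(0, 5)), 0)
  set.seed(7); v <- runif(5)
  expect_equal(tr_quality_score(v, n_slices = 5), sum(v))
  expect_error(tr_quality_score(1:3, n_slices = 5), "slice")
})

test_that("drift adjustment subtracts the sliding-window median", {
  expect_equal(adjust_drift(rep(7, 50)), rep(0, 50))
  x <- as.numeric(1:50)
  expect_equal(adjust_drift(x), x - oracle_median_window(x, 10L))
  dip <- rep(10, 30); dip[15] <- 0
  ad <- adjust_drift(dip)
  expect_equal(ad[15], -10)
  expect_equal(ad[10], 0)
  set.seed(3)
  y <- cumsum(rnorm(80)) + rnorm(80)
  expect_equal(adjust_drift(y, window = 10),
               y - oracle_median_window(y, 10L))
  expect_error(adjust_drift(1:5, window = 10), "shorter")
})

test_that("corruption detector is a one-sided Hampel filter", {
  expect_false(any(detect_corrupted(rep(5, 60))))
  x <- rep(100, 60); x[30] <- 50
  expect_true(detect_corrupted(x)[30])
  expect_equal(sum(detect_corrupted(x)), 1L)
  # high outliers are ignored (one-sided)
  xh <- rep(100, 60); xh[30] <- 150
  expect_false(any(detect_corrupted(xh)))
  set.seed(11)
  y <- rnorm(120, mean = 100, sd = 1)
  dips <- c(20, 45, 61, 90, 110)
  y[dips] <- y[dips] - 10
  expect_identical(detect_corrupted(y), oracle_hampel_low(y, 25L, 3))
  expect_true(all(detect_corrupted(y)[dips]))
  expect_error(detect_corrupted(y, window = 2), "window")
})

test_that("centre weighting amplifies central-ky deficits", {
  w1 <- rep(1, 192)
  expect_equal(center_weighted_score(c(5, 7), c(10, 97), w1), c(5, 7))
  wg <- ky_weighting(192)
  # equal raw scores: the central-ky TR ranks worse (lower)
  ws <- center_weighted_score(c(5, 5), c(97, 5), wg)
  expect_lt(ws[1], ws[2])
  # ranking equals a brute-force sort of the weighted scores
  set.seed(13)
  sc <- runif(120, 0.5, 1)
  ky <- 1:120
  wt <- ky_weighting(192, shape = "triangular", fwhm_lines = 60)
  got <- order(center_weighted_score(sc, ky, wt))
  brute <- order(sc / wt[ky])
  expect_identical(got, brute)
  expect_error(center_weighted_score(1, 500, wg), "outside")
  expect_error(center_weighted_score(1, 5, rep(0, 192)), "positive")
})

test_that("drift does not change which event TRs are detected", {
  ph <- full_phantom(); co <- full_coils(); sch <- mese_schedule()
  ev <- data.frame(tr_start = c(50L, 80L), tr_end = c(50L, 81L),
                   amplitude_drop_fraction = c(0.20, 0.15),
                   phase_jitter_sd = 0.4, throat_shift_px = 2)
  event_trs <- c(50L, 80L, 81L)
  for (seed in c(2L, 11L)) {
    d0 <- simulate_mese_kspace(ph, co, sch, motion_spec(ev),
                               noise_sd = 2e-3, rng_seed = seed,
                               navigators_only = TRUE)
    d1 <- simulate_mese_kspace(
      ph, co, sch,
      motion_spec(ev, drift = list(amplitude_fraction = 0.10,
                                   shape = "linear")),
      noise_sd = 2e-3, rng_seed = seed, navigators_only = TRUE)
    f0 <- which(quality_trace(d0)$corrupted_mask)
    f1 <- which(quality_trace(d1)$corrupted_mask)
    # all true event TRs detected in both runs
    expect_true(all(event_trs %in% f0))
    expect_true(all(event_trs %in% f1))
    # any differences are sparse false positives outside event runs
    diffs <- union(setdiff(f0, f1), setdiff(f1, f0))
    expect_false(any(diffs %in% event_trs))
    expect_lte(length(diffs), 3L)
  }
})
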