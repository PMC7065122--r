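test_that("noise-free simulation satisfies Fourier identities", {
  ph <- small_phantom(); co <- small_coils(); sch <- small_schedule()
  ds <- small_clean_dataset()
  n <- 64L
  ctr <- sch$center_line
  tes <- echo_times_ms(sch)
  # DC sample of echo 1 = sum of pd * exp(-TE1/T2) * sensitivity / sqrt(N)
  e1 <- ph$proton_density * exp(-tes[1] / ph$t2_map)
  for (c in c(1L, 3L)) {
    dc_expect <- sum(e1 * co$sensitivities[c, , ]) / n
    dc_got <- ds$data[1L, 1L, match(ctr, sch$acquired_ky), n %/% 2L + 1L, c]
    expect_equal(dc_got, dc_expect, tolerance = 1e-12)
  }
  # navigator readout of TR t = centre ky line of the navigator-echo
  # k-space of the same state
  imgN <- ph$proton_density * exp(-navigator_te_ms(sch) / ph$t2_map) *
    co$sensitivities[2L, , ]
  expect_equal(ds$navigators[1L, 7L, , 2L], fft2c(imgN)[ctr, ],
               tolerance = 1e-12)
  # Parseval per echo/coil on the full grid
  K <- fft2c(e1 * co$sensitivities[1L, , ])
  expect_equal(sum(Mod(K)^2), sum(Mod(e1 * co$sensitivities[1L, , ])^2),
               tolerance = 1e-12)
  # monotone echo decay of total k-space magnitude
  energy <- vapply(seq_len(sch$n_imaging_echoes),
                   function(e) sum(Mod(ds$data[1L, e, , , ])), numeric(1))
  expect_true(all(diff(energy) < 0))
})

test_that("event amplitude drop scales the slice score linearly", {
  mo <- motion_spec(data.frame(tr_start = 20L, tr_end = 20L,
                               amplitude_drop_fraction = 0.2,
                               phase_jitter_sd = 0, throat_shift_px = 0))
  ds <- simulate_mese_kspace(small_phantom(), small_coils(),
                             small_schedule(), mo, noise_sd = 0,
                             rng_seed = 0)
  qc <- quality_trace(ds, hampel_window = 13L)
  expect_equal(qc$tr_scores[20L] / qc$tr_scores[21L], 0.8,
               tolerance = 1e-3)
  # linearity across several amplitudes
  for (a in c(0.1, 0.25)) {
    mo2 <- motion_spec(data.frame(tr_start = 20L, tr_end = 20L,
                                  amplitude_drop_fraction = a,
                                  phase_jitter_sd = 0, throat_shift_px = 0))
    ds2 <- simulate_mese_kspace(small_phantom(), small_coils(),
                                small_schedule(), mo2, noise_sd = 0,
                                rng_seed = 0)
    qc2 <- quality_trace(ds2, hampel_window = 13L)
    expect_equal(qc2$tr_scores[20L] / qc2$tr_scores[21L], 1 - a,
                 tolerance = 1e-3)
  }
})

test_that("simulation is deterministic and validates inputs", {
  a <- simulate_mese_kspace(small_phantom(), small_coils(),
                            small_schedule(), small_motion(),
                            noise_sd = 1e-3, rng_seed = 9)
  b <- simulate_mese_kspace(small_phantom(), small_coils(),
                            small_schedule(), small_motion(),
                            noise_sd = 1e-3, rng_seed = 9)
  expect_identical(a$data, b$data)
  expect_identical(a$navigators, b$navigators)
  expect_identical(a$reacq_data, b$reacq_data)
  bad <- motion_spec(data.frame(tr_start = 999L, tr_end = 999L,
                                amplitude_drop_fraction = 0.1,
                                phase_jitter_sd = 0, throat_shift_px = 0))
  expect_error(simulate_mese_kspace(small_phantom(), small_coils(),
                                    small_schedule(), bad),
               "beyond the scan")
  expect_error(simulate_mese_kspace(small_phantom(), small_coils(),
                                    small_schedule(), noise_sd = -1),
               "noise_sd")
  expect_error(motion_spec(data.frame(tr_start = 1, tr_end = 1,
                                      amplitude_drop_fraction = 1.5,
                                      phase_jitter_sd = 0,
                                      throat_shift_px = 0)),
               "amplitude_drop_fraction")
})

test_that("navigators-only fast path matches the full simulation", {
  full <- small_motion_dataset()
  nav <- simulate_mese_kspace(small_phantom(), small_coils(),
                              small_schedule(), small_motion(),
                              noise_sd = 1e-3, rng_seed = 3,
                              navigators_only = TRUE)
  expect_null(nav$data)
  expect_identical(dim(nav$navigators), dim(full$navigators))
  # noise-free navigators agree exactly between the two paths
  f0 <- simulate_mese_kspace(small_phantom(), small_coils(),
                             small_schedule(), small_motion(),
                             noise_sd = 0, rng_seed = 3)
  n0 <- simulate_mese_kspace(small_phantom(), small_coils(),
                             small_schedule(), small_motion(),
                             noise_sd = 0, rng_seed = 3,
                             navigators_only = TRUE)
  expect_equal(n0$navigators, f0$navigators, tolerance = 1e-12)
})

test_that("truth_corrupted_mask equals a brute-force TR membership test", {
  ds <- small_motion_dataset()
  mask <- truth_corrupted_mask(ds)
  ev <- ds$truth$motion$events
  brute <- matrix(FALSE, small_schedule()$n_slices, 40L)
  for (k in seq_len(nrow(ev))) {
    for (tr in ev$tr_start[k]:ev$tr_end[k]) brute[, tr] <- TRUE
  }
  expect_identical(mask, brute)
  # no events -> all-false
  expect_false(any(truth_corrupted_mask(small_clean_dataset())))
  noTruth <- small_clean_dataset(); noTruth$truth <- NULL
  expect_error(truth_corrupted_mask(noTruth), "truth")
})
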