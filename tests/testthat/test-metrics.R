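test_that("ghost level and ghosting reduction follow their definitions", {
  ph <- small_phantom()
  rois <- make_rois(ph)
  expect_false(any(rois$ghost_roi & rois$background_roi))
  img <- matrix(0.5, 64, 64)
  expect_equal(ghost_level(img, rois, 0.5), 0)
  # synthetic ghost of amplitude a on background b
  img2 <- matrix(0.2, 64, 64); img2[rois$ghost_roi] <- 0.2 + 0.07
  expect_equal(ghost_level(img2, rois, 0.2), 0.07)
  # localized statistic: constants added outside both ROIs are ignored
  img3 <- img2
  neither <- !(rois$ghost_roi | rois$background_roi)
  img3[neither] <- img3[neither] + 5
  expect_equal(ghost_level(img3, rois, 0.2), ghost_level(img2, rois, 0.2))
  # brute-force median arithmetic on a noisy case
  set.seed(4); imgn <- matrix(runif(64 * 64), 64, 64)
  expect_equal(ghost_level(imgn, rois, 0.3),
               median(imgn[rois$ghost_roi]) - 0.3)
  expect_error(ghost_level(img, list(ghost_roi = matrix(FALSE, 64, 64)), 0),
               "empty")

  expect_equal(ghosting_reduction(5, 5), 0)
  expect_equal(ghosting_reduction(0, 5), 100)
  expect_equal(ghosting_reduction(2.5, 5), 50)
  expect_error(ghosting_reduction(1, 0), "positive")
})

test_that("CNR matches its definition", {
  w <- matrix(FALSE, 4, 4); w[1, ] <- TRUE
  l <- matrix(FALSE, 4, 4); l[2, ] <- TRUE
  n <- matrix(FALSE, 4, 4); n[3:4, ] <- TRUE
  img <- matrix(0, 4, 4); img[1, ] <- 10; img[2, ] <- 2
  img[3:4, ] <- c(1, 3, 1, 3, 1, 3, 1, 3)
  expect_equal(cnr(img, w, l, n), (10 - 2) / sd(img[n]))
  img[2, ] <- 10
  expect_equal(cnr(img, w, l, n), 0)
  set.seed(9)
  imgn <- matrix(rnorm(16, 5), 4, 4)
  expect_equal(cnr(imgn, w, l, n),
               (mean(imgn[w]) - mean(imgn[l])) / sd(imgn[n]))
  expect_error(cnr(matrix(1, 4, 4), w, l, n), "noise")
})

test_that("IEPA scores sharpness of edge profiles", {
  # hand-computed step edge: diffs {0,1,0,0}, mean 1/4, range 1
  expect_equal(iepa(list(c(0, 0, 1, 1, 1))), 0.25)
  # ramped edge of the same height scores strictly lower
  expect_lt(iepa(list(c(0, 0.25, 0.5, 0.75, 1))), 0.25)
  # flat profiles are excluded; all-flat errors
  expect_equal(iepa(list(c(0, 0, 1, 1, 1), rep(2, 5))), 0.25)
  expect_error(iepa(list(rep(1, 5))), "flat")
  expect_error(iepa(list(c(0, 1, 0))), "5 samples")
  # blurring a synthetic vessel image lowers the acutance
  ph <- small_phantom()
  img <- ph$proton_density
  kern <- outer(dnorm(-2:2), dnorm(-2:2)); kern <- kern / sum(kern)
  blur <- img
  for (i in 3:62) for (j in 3:62) {
    blur[i, j] <- sum(img[(i - 2):(i + 2), (j - 2):(j + 2)] * kern)
  }
  p_sharp <- vessel_edge_profiles(img, ph)
  p_blur <- vessel_edge_profiles(blur, ph)
  expect_gt(iepa(p_sharp), iepa(p_blur))
})

test_that("T2 fitting is exact for noiseless decays and robust to noise", {
  sch <- mese_schedule()
  tes <- echo_times_ms(sch)
  f <- fit_t2(matrix(3 * exp(-tes / 50), 1), tes)
  expect_equal(unname(f$t2_map), 50, tolerance = 0.01 / 50)
  # near-constant decay: very large T2 recovered and flagged
  f2 <- fit_t2(matrix(3 * exp(-tes / 1e6), 1), tes)
  expect_gt(f2$t2_map, 1e4)
  expect_true(f2$near_bound)
  # all-zero pixel: invalid, not an error
  f3 <- fit_t2(matrix(0, 1, 14), tes)
  expect_false(f3$valid_mask)
  expect_error(fit_t2(matrix(1, 1, 2), tes[1:2]), "3 echoes")
  expect_error(fit_t2(matrix(1, 1, 3), c(1, 3, 2)), "increasing")
  # Rician-like magnitude noise at SNR 30: median bias within 3%
  set.seed(5)
  n <- 200L
  s <- 3 * exp(-tes / 50)
  Y <- t(vapply(seq_len(n), function(i) {
    Mod(complex(real = s + rnorm(14, sd = 3 / 30 / sqrt(2)),
                imaginary = rnorm(14, sd = 3 / 30 / sqrt(2))))
  }, numeric(14)))
  fr <- fit_t2(Y, tes)
  expect_lt(abs(median(fr$t2_map) - 50) / 50, 0.03)
  # oracle: per-pixel nls fits agree with the vectorized Gauss-Newton
  for (i in c(1L, 50L, 117L)) {
    df <- data.frame(y = Y[i, ], te = tes)
    o <- nls(y ~ s0 * exp(-te / t2), df, start = list(s0 = 3, t2 = 45))
    expect_equal(fr$t2_map[i], coef(o)[["t2"]], tolerance = 1e-4)
  }
})
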