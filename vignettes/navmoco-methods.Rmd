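---
title: "Navigator-based motion correction for multi-echo spin echo: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Navigator-based motion correction for multi-echo spin echo: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(navmoco)
```

## The problem

Quantitative T2 mapping of the carotid vessel wall uses a segmented
multi-slice multi-echo spin echo (MESE) acquisition: one
phase-encode (ky) line of every slice is acquired per TR, and the ky
index is incremented over successive TRs, so a single slice takes
several minutes.  Brief motion events — above all swallowing —
corrupt the k-space lines acquired during the event.  Because the
phase-encode direction is anteroposterior, the corrupted lines
manifest as ghosting along that axis, and corruption near the centre
of k-space can destroy the vessel-wall depiction entirely.

`navmoco` implements a retrospective correction chain for this
situation, together with a synthetic multi-coil acquisition model
that provides ground truth for every stage:

1. **Detection.** A navigator echo (an unencoded ky = 0 readout,
   appended to the echo train as a 15th echo at TE = 136.5 ms)
   yields a slice score per echo train, `S_sl(ky) = sum_c sum_kx
   |N_sl(kx, ky, c)|`, and a per-TR quality score `S_TR = sum_sl
   S_sl`.  After subtracting a sliding-window median (width 10) to
   remove slow drift, lines whose score falls below the local median
   (window 25) by more than 3 robust standard deviations
   (1.4826 × MAD, one-sided) are flagged as corrupted.
2. **Reacquisition.** The TRs with the lowest (optionally
   centre-weighted) scores are reacquired at the end of the scan.
   Corrupted data in the 7 central k-space lines are replaced by
   their reacquisitions when the reacquired score is higher.
3. **Estimation.** Remaining corrupted lines are synthesized with
   targeted GRAPPA kernels: isolated lines (1-AMCL, locally R = 2)
   and adjacent pairs (2-AMCL, locally R = 3), trained on the
   central calibration region, processed worst-score-first, with at
   most 12 estimated lines and never more than two adjacent targets.
4. **Reconstruction.** POCS partial-Fourier completion per coil,
   inverse FFT, root-sum-of-squares combination.
5. **Evaluation.** Ghost level / ghosting reduction, wall–lumen CNR,
   edge-profile acutance, voxel-wise mono-exponential T2 fits, and
   g-factor noise-amplification maps with a pseudo-multiple-replica
   Monte Carlo cross-check.

## The synthetic world

`simulate_mese_kspace()` models the acquisition as a line-by-line
Fourier sampling of per-echo coil images
`S_c(x) · ρ(x) · exp(−TE_e / T2(x))` on a 192 × 192 grid with 5/8
partial Fourier (120 acquired lines, centre at line 97), 5 slices,
TR = 2 s, 14 echoes at 9.1 ms spacing, 10 receive channels, and the
navigator as a 15th echo.  A swallow event during a TR is modelled
as three simultaneous effects applied to all echoes of that TR:

* a **global amplitude factor** (default drops of 10%–25%),
  standing in for intra-train dephasing and through-plane signal
  loss — this is what the navigator detects, since an in-plane
  translation leaves the magnitude of the ky = 0 readout unchanged;
* a **random per-(slice, TR) phase offset** (default sd 0.5 rad),
  which creates the ghosting that the amplitude factor alone would
  underestimate;
* an **in-plane displacement of the throat structure** (default
  2–4 px ≈ 1.3–2.7 mm), applied via the Fourier shift theorem.

A slow scan-long amplitude drift (default 5%, smooth) models neck
relaxation; reacquisition TRs are simulated at the end-of-scan drift
level with a residual bulk offset of 0.5 px (≈ 0.33 mm at the
0.67 mm resolution — comparable to reported pulsation
displacements), emulating a subject who returned to a slightly
different position.  The default scenario injects 5 events of 1–2
TRs in the later two-thirds of the scan, matching an instructed
swallow every 30–45 s from 1:30 min onward.

What the generator does *not* model: spin-history and
stimulated-echo effects in the echo train, DANTE flow-suppression
physics (the dark lumen is imposed directly in the phantom), slice
profiles, through-plane motion as a geometric effect, and nonrigid
deformation.  A green end-to-end test therefore establishes that the
chain removes the *k-space inconsistencies* this model produces, not
that it handles every physiological motion mechanism.

## Numerical and design choices

* **FFT convention.** Centred and unitary: DC at grid index
  `(ny/2 + 1, nx/2 + 1)`, Parseval without scale factors.  The
  navigator readout of a TR is by construction identical to the
  centre row of that TR's navigator-echo k-space.
* **Kernel geometry** (unstated in the source protocol): 1-AMCL
  sources at ky offsets {−2, −1, +1, +2}; 2-AMCL (targets j, j+1)
  sources at {j−2, j−1, j+2, j+3}; 5 kx taps.  Because the
  acquisition is fully sampled apart from the corrupted lines, the
  sources sit tighter around the targets than in conventional R = 2/3
  GRAPPA.  The geometry is configurable; conventional R = 2
  estimation needs odd offsets {−3, −1, +1, +3}.
* **Calibration** uses the central 24 acquired lines (clamped into
  the acquired range, always containing the centre line), echo 1 by
  default — GRAPPA weights encode coil geometry and carry over
  between echoes; calibration requires ≥ 10× more equations than
  unknowns and errors with the required width otherwise.
* **Regularization.** Tikhonov ridge `λ = 1e-6 × mean diag(AᴴA)`.
  A stronger default (1e-4) over-smooths noise-free estimation
  (NRMSE 5.8e-3 re-estimating an uncorrupted line on the default
  phantom vs 9.3e-4 at 1e-6), so the weaker default was adopted; on
  noisy calibration data the difference is negligible.
* **Runs of ≥ 3 adjacent corrupted lines.** Only the two
  worst-scoring lines are estimated.  When those two are not
  adjacent, the pair is anchored on the worst line and its
  worse-scoring in-run neighbour, so a 2-AMCL kernel always applies;
  the remaining run lines are skipped and any job sourcing them is
  re-flagged rather than silently executed.
* **Cap.** At most 12 estimated lines (greedy worst-first packing;
  a pair that would exceed the cap is skipped, a later single may
  still fit).
* **g-factor.** Computed by exact linear noise propagation through
  the composite k-space-filling operator: per image column, the kx
  taps become scalars after the hybrid transform, each estimated
  line is a small matrix over its source samples (composed through
  previously estimated lines when jobs chain), and the propagation
  through the inverse FFT and a fixed linear coil combination is
  closed-form.  The combination weights are the matched-filter /
  RSS-reference weights `S_j / |S|`; POCS is nonlinear and is
  excluded from this path.  The pseudo-multiple-replica Monte Carlo
  uses paired noise draws for the estimated and fully sampled arms,
  which suppresses the common sampling error and lets 200 replicas
  resolve the comparison to a few percent.  Kernel application is
  circular along kx, matching the Fourier model exactly.
* **POCS.** Phase reference from the symmetric centre band (lines
  74–120 for the default schedule) with a Hann apodization; the
  image is projected onto the phase constraint by
  `Re(I·e^{−iφ})·e^{iφ}`; acquired samples are restored exactly each
  iteration; defaults 20 iterations, 1e-6 relative-change tolerance.
* **T2 fitting.** Mono-exponential magnitude fit `S0·exp(−TE/T2)`
  by vectorized Gauss–Newton from a log-linear start; pixels below
  5% of the maximum first-echo signal are excluded; fits above
  10⁴ ms are flagged near-bound.  No stimulated-echo (EPG)
  correction — the fit is isolated behind one function so an EPG
  variant can be added.
* **Containers.** No HDF5 bindings are available in the target
  environment, so datasets round-trip either as RDS or as a
  directory container (JSON header + raw complex-double binaries,
  one file per group) that mirrors the intended HDF5 group layout.

## Known limitations

* **Detector edge windows.** The truncated sliding median cannot
  track a linear drift within the last half window, so at very high
  navigator SNR the final few TRs can be falsely flagged; at
  realistic noise the 3σ one-sided rule yields ~0.5 false positives
  per 120-TR scan.  Event TRs themselves are detected identically
  with and without ≤ 10% drift.
* **Single-coil limit.** With no coil encoding, uniform R = 2
  undersampling is unrecoverable; for a trained-kernel estimator the
  failure appears as bias (estimated lines ≈ lost) rather than as a
  diverging g-factor, because regularized calibration shrinks the
  degenerate kernel.
* **Rician bias.** Magnitude noise biases the T2 fit upward at low
  SNR; at SNR 30 the median bias on T2 = 50 ms is ≈ 1%.
* The ghosting-reduction percentages measured on synthetic scans are
  not comparable in magnitude to in-vivo values; only orderings
  (corrected vs uncorrected, estimation vs reacquisition-only) are
  meaningful, and those are what the acceptance tests assert.
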