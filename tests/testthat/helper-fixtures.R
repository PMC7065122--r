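# Shared fixtures, built lazily once per test run.
#
# "small" fixtures (64 grid, few coils/echoes) back the unit tests;
# "full" fixtures (192 grid, 10 coils) back the acceptance criteria
# that are stated at protocol scale.

.fx <- new.env(parent = emptyenv())

fx_cached <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

small_phantom <- function() fx_cached("ph64", function() {
  make_phantom(c(64, 64), rng_seed = 0)
})

small_coils <- function() fx_cached("co64", function() {
  make_coil_profiles(small_phantom(), ncoils = 4L, rng_seed = 1)
})

small_schedule <- function() fx_cached("sch64", function() {
  mese_schedule(matrix_size = c(64, 64), n_slices = 2L,
                n_imaging_echoes = 4L, n_reacq_trs = 6L)
})

# clean (no motion, noise-free) small dataset
small_clean_dataset <- function() fx_cached("ds64", function() {
  simulate_mese_kspace(small_phantom(), small_coils(), small_schedule(),
                       noise_sd = 0, rng_seed = 0)
})

small_motion <- function() motion_spec(data.frame(
  tr_start = c(15L, 25L), tr_end = c(15L, 26L),
  amplitude_drop_fraction = c(0.20, 0.15),
  phase_jitter_sd = 0.4, throat_shift_px = 2))

small_motion_dataset <- function() fx_cached("ds64m", function() {
  simulate_mese_kspace(small_phantom(), small_coils(), small_schedule(),
                       small_motion(), noise_sd = 1e-3, rng_seed = 3)
})

full_phantom <- function() fx_cached("ph192", function() {
  make_phantom(c(192, 192), rng_seed = 0)
})

full_coils <- function() fx_cached("co192", function() {
  make_coil_profiles(full_phantom(), ncoils = 10L, rng_seed = 1)
})

# single-slice, single-echo, noise-free full-size dataset for GRAPPA
# and g-factor work
full_clean_dataset <- function() fx_cached("ds192", function() {
  sch <- mese_schedule(n_slices = 1L, n_imaging_echoes = 1L,
                       n_reacq_trs = 0L)
  simulate_mese_kspace(full_phantom(), full_coils(), sch,
                       noise_sd = 0, rng_seed = 0)
})

full_kernels <- function() fx_cached("kern192", function() {
  cd <- calib_region_data(full_clean_dataset())
  list("1-AMCL" = calibrate_kernel(cd, "1-AMCL"),
       "2-AMCL" = calibrate_kernel(cd, "2-AMCL"))
})

full_combine_weights <- function() fx_cached("w192", function() {
  rss_combine_weights(full_coils())
})

nrmse <- function(est, ref) {
  sqrt(sum(Mod(est - ref)^2) / sum(Mod(ref)^2))
}
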