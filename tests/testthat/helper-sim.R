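# shared simulator scenarios

# aspirin-like fixture: precursor C9H7O4- with two true fragments and an
# unrelated decoy ion eluting 3 sigma later
sim_aspirin <- function(seed, decoy_offset = 0.15, peak_sigma = 0.05,
                        ms1_height = 1e6, ...) {
  cs <- compound_spec("C9H7O4", rt_apex = 2.0, peak_sigma = peak_sigma,
                      ms1_height = ms1_height,
                      fragments = c(C6H5O = 0.4, C7H5O3 = 0.6),
                      decoys = data.frame(mz = 77.0146,
                                          rt_offset = decoy_offset,
                                          height = 5e5),
                      label = "aspirin-like")
  simulate_run(list(cs), rt_start = 1, rt_end = 3, seed = seed, ...)
}

# a plain single-compound run without fragments or decoys
sim_single <- function(formula, mz_height = 1e6, seed = 1, rt_apex = 2,
                       ...) {
  cs <- compound_spec(formula, rt_apex = rt_apex, ms1_height = mz_height)
  simulate_run(list(cs), rt_start = 1, rt_end = 3, seed = seed, ...)
}

# remove every centroid inside an m/z window from all scans of a run
# (used to delete a planted isotopologue signal)
delete_mz_window <- function(run, mz, ppm = 20) {
  lo <- mz * (1 - ppm * 1e-6); hi <- mz * (1 + ppm * 1e-6)
  strip <- function(s) {
    keep <- s$mz < lo | s$mz > hi
    new_spectrum(s$ms_level, s$rt, s$mz[keep], s$intensity[keep],
                 s$collision_energies)
  }
  acquisition_run(lapply(run$ms1, strip), lapply(run$aif, strip),
                  run$metadata)
}

# build a synthetic channel of spectra with Gaussian elution profiles:
# ions = data.frame(mz, apex_rt, sigma, height); one spectrum per time point
make_channel <- function(times, ions, ms_level = 1L) {
  lapply(times, function(t) {
    ints <- ions$height * exp(-(t - ions$apex_rt)^2 / (2 * ions$sigma^2))
    o <- order(ions$mz)
    new_spectrum(ms_level, t, ions$mz[o], ints[o])
  })
}

# XIC built directly from a sampled curve (bypasses extraction)
xic_from_curve <- function(times, values, mz = 100) {
  structure(list(times = times, intensities = values, target_mz = mz,
                 tol_ppm = 5, source_channel = "ms1"), class = "xic")
}
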