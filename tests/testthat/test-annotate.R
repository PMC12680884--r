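test_that("true fragments are annotated and the shifted decoy is rejected", {
  sim <- sim_aspirin(seed = 7)
  res <- annotate_precursor(sim$run, peak_entry(179.0350, 2.0, "aspirin"),
                            run_config())
  expect_identical(format(res$precursor_formula), "C9H7O4")
  ann <- res$fragments[!is.na(res$fragments$formula), ]
  expect_setequal(ann$formula, c("C6H5O", "C7H5O3"))
  expect_setequal(ann$neutral_loss, c("C3H2O3", "C2H2O"))
  expect_false(any(abs(res$fragments$mz - 77.0146) < 0.01))
  # fragments are sorted by m/z and every annotation passed both filters
  expect_true(all(diff(res$fragments$mz) > 0))
  expect_true(all(ann$shape_area <= run_config()$shape_threshold))
  p <- chem_formula("C9H7O4", charge = -1)
  for (fs in ann$formula)
    expect_true(is_subformula(chem_formula(fs, charge = -1), p))
})

test_that("a fragment-free compound still gets its precursor formula", {
  sim <- sim_single("C13H17O2", seed = 13)
  res <- annotate_precursor(sim$run,
                            peak_entry(205.1234, 2.0, "ibuprofen-like"),
                            run_config())
  expect_identical(format(res$precursor_formula), "C13H17O2")
  expect_identical(nrow(res$fragments[!is.na(res$fragments$formula), ]), 0L)
})

test_that("an entry outside the run's time range errors", {
  sim <- sim_single("C9H7O4", seed = 1)
  expect_error(annotate_precursor(sim$run, peak_entry(179.0350, 9.0),
                                  run_config()),
               "outside run")
})

test_that("removing the AIF channel degrades to flags, not exceptions", {
  sim <- sim_single("C9H7O4", seed = 3)
  ms1_only <- acquisition_run(sim$run$ms1, list(), sim$run$metadata)
  res <- annotate_precursor(ms1_only, peak_entry(179.0350, 2.0),
                            run_config())
  expect_identical(nrow(res$fragments), 0L)
  expect_true("no-aif-scans" %in% res$flags)
  expect_null(res$quasi_ms2)
})

test_that("coeluting precursors share their fragments as ambiguous", {
  # two precursors with identical elution and a fragment compatible with
  # both ion formulas: the workflow cannot attribute it and marks both
  cs1 <- compound_spec("C9H7O4", rt_apex = 2.0,
                       fragments = c(C6H5O = 0.5), label = "A")
  cs2 <- compound_spec("C8H5O4", rt_apex = 2.0,
                       fragments = c(C6H5O = 0.5), label = "B")
  sim <- simulate_run(list(cs1, cs2), rt_start = 1, rt_end = 3, seed = 17)
  results <- annotate_run(sim$run,
                          data.frame(mz = c(179.0350, 165.0193),
                                     rt = c(2.0, 2.0),
                                     label = c("A", "B")),
                          run_config())
  for (res in results) {
    ann <- res$fragments[!is.na(res$fragments$formula), ]
    shared <- ann[abs(ann$mz - 93.0346) < 0.01, ]
    expect_identical(nrow(shared), 1L)
    expect_true(shared$ambiguous)
    expect_true("coelution-ambiguity" %in% res$flags)
  }
})

test_that("well-separated precursors are not flagged as ambiguous", {
  cs1 <- compound_spec("C9H7O4", rt_apex = 1.6,
                       fragments = c(C6H5O = 0.5), label = "A")
  cs2 <- compound_spec("C8H5O4", rt_apex = 2.4,
                       fragments = c(C6H5O = 0.5), label = "B")
  sim <- simulate_run(list(cs1, cs2), rt_start = 1, rt_end = 3, seed = 18)
  results <- annotate_run(sim$run,
                          data.frame(mz = c(179.0350, 165.0193),
                                     rt = c(1.6, 2.4)),
                          run_config())
  for (res in results)
    expect_false("coelution-ambiguity" %in% res$flags)
})

test_that("the quasi-isolated MS2 spectrum mirrors the apex AIF scan", {
  sim <- sim_aspirin(seed = 7)
  res <- annotate_precursor(sim$run, peak_entry(179.0350, 2.0),
                            run_config())
  q <- res$quasi_ms2
  expect_s3_class(q, "quasi_ms2")
  # intensities equal the stored source scan values
  src <- sim$run$aif[[q$scan_index]]
  expect_identical(q$peaks$mz, src$mz)
  expect_identical(q$peaks$intensity, src$intensity)
  expect_identical(sum(q$peaks$role == "precursor"), 1L)
  expect_identical(sum(q$peaks$role == "annotated_fragment"), 2L)
  expect_true(all(q$peaks$role[!q$peaks$role %in%
                                 c("precursor", "annotated_fragment")] ==
                    "unannotated"))
  # neutral-loss labels ride along with the annotated fragments
  labs <- q$peaks$label[q$peaks$role == "annotated_fragment"]
  expect_true(any(grepl("C3H2O3", labs)))
})

test_that("co-eluting +O ions raise an oxidation flag; shifted ones do not", {
  cs <- compound_spec("C9H7O4", rt_apex = 2.0, oxidation = c(2e5, 0))
  sim <- simulate_run(list(cs), rt_start = 1, rt_end = 3, seed = 23)
  res <- annotate_precursor(sim$run, peak_entry(179.0350, 2.0),
                            run_config())
  expect_true(any(grepl("in-source oxidation", res$flags)))

  sim0 <- sim_single("C9H7O4", seed = 23)
  res0 <- annotate_precursor(sim0$run, peak_entry(179.0350, 2.0),
                             run_config())
  expect_false(any(grepl("in-source oxidation", res0$flags)))

  # +O species present but eluting far from the precursor: shape rejects it
  shifted <- simulate_run(list(
    compound_spec("C9H7O4", rt_apex = 2.0, label = "M"),
    compound_spec("C9H7O5", rt_apex = 2.35, label = "M+O impostor")),
    rt_start = 1, rt_end = 3, seed = 24)
  res_s <- annotate_precursor(shifted$run, peak_entry(179.0350, 2.0),
                              run_config())
  expect_false(any(grepl("in-source oxidation", res_s$flags)))
})
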