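# aifrag — CID fragment annotation for full MS/AIF experiments

Non-target LC-HRMS screening of complex mixtures — organic aerosol
extracts above all — increasingly uses data-independent acquisition:
in a *full MS/AIF* experiment the instrument alternates between an
unfragmented MS¹ scan and an all-ion-fragmentation (AIF) MS² scan in
which every ion reaching the source is dissociated at once, with no
precursor isolation and no inclusion list.  The resulting file holds the
fragmentation information of everything in the sample, but each AIF
spectrum superimposes the fragments of all co-eluting precursors, so the
spectra cannot be read like isolated MS² spectra.

`aifrag` reconstructs that readability.  Given a centroided mzML run and
a peak list of precursor ions (m/z, retention time), it

1. predicts the precursor's molecular formula from the MS¹ channel by
   isotopologue-pattern scoring,
2. links fragment masses to the precursor by chromatographic peak shape:
   fragmentation happens after the column, so a true fragment's AIF-XIC
   must match the precursor's MS¹-XIC.  The criterion is the area between
   the two unit-height-normalized traces,
   *A* = (1/T) ∫ |x̂₁(t) − x̂₂(t)| dt ≤ θ (default θ = 0.15),
3. predicts each surviving fragment's formula the same way and enforces
   the subformula constraint (a fragment cannot contain atoms its
   precursor lacks), attaching the neutral loss
   (precursor − fragment, element-wise),
4. emits a *quasi-isolated MS²* spectrum: the apex AIF scan with the
   precursor, its verified fragments, and everything else labeled.

Formula prediction never trusts exact mass alone: a candidate is
rejected unless its second-most-intense theoretical isotopologue is
actually found in the data — detectable above the trace noise, within
±50 % of the theoretical intensity ratio, and co-eluting with the
reference peak.  When no candidate survives, the answer is "no formula",
not a guess.  An optional punishment score for implausible element
ratios (RDBE, H/C, O/C, …) can be switched on.

A seeded simulator (`simulate_run()`) generates full MS/AIF runs with
known ground truth — Gaussian elution profiles on an alternating scan
grid, isotopologue envelopes for CHNOSI(P) formulas, co-eluting
fragments, retention-shifted decoys, in-source +O/+2O artifacts, mass
jitter and intensity noise — and backs the entire test suite.

## Worked example

Simulate an acetylsalicylic-acid-like compound (ion C9H7O4⁻, m/z
179.0350) with its two CID fragments plus an unrelated decoy ion at m/z
77.0146 eluting 3σ later, then annotate it:

```r
library(aifrag)

cs <- compound_spec("C9H7O4", rt_apex = 2.0, ms1_height = 1e6,
                    fragments = c(C6H5O = 0.4, C7H5O3 = 0.6),
                    decoys = data.frame(mz = 77.0146, rt_offset = 0.15,
                                        height = 5e5))
sim <- simulate_run(list(cs), rt_start = 1, rt_end = 3, seed = 42)
res <- annotate_precursor(sim$run, peak_entry(179.0350, 2.0, "aspirin"))
res
#> <annotation_result> m/z 179.0350 @ 2.00 min -> C9H7O4, 2 fragment(s)
res$fragments
#>          mz formula neutral_loss  shape_area ppm_error    score ambiguous
#> 1  93.03456   C6H5O       C3H2O3 0.007825187 0.3318104 2.951549     FALSE
#> 2 137.02449  C7H5O3        C2H2O 0.007824502 0.4946397 2.940842     FALSE
res$quasi_ms2
#> <quasi_ms2> scan @ 1.983 min, 23 peaks (2 annotated, with precursor)
van_krevelen_table(list(res))
#>     label formula        OC        HC OSc
#> 1 aspirin  C9H8O4 0.4444444 0.8888889   0
```

Both true fragments are recovered with their neutral losses (the
C3H2O3 loss is the aspirin text-book case), the decoy is rejected by the
shape filter (its XIC peaks 0.15 min away), and the neutralized Van
Krevelen coordinates put the compound at OSc = 0.  The file-level
interface is `run_annotation(mzml, peaklist, config, out_dir)`, which
writes a `summary.tsv`, per-entry quasi-MS² tables and a `config.yaml`
echo; `inst/cli/aifrag.R` wraps it for shell use
(`Rscript inst/cli/aifrag.R annotate run.mzML --peaks peaks.csv --out res`).

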