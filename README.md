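# plexcal

Calibration tools for multiplex PCR assays built on **standardised DNA
templates**: known numbers of double-stranded (DS) template molecules per
target, rather than nanograms of total DNA.

Multiplex panels — in molecular diagnostics, gut-content analysis of
predators, community screening — suffer from unequal primer efficiencies:
the best-performing pair amplifies preferentially and biases detection
rates. Balancing a panel requires giving every primer pair the *same number
of template molecules*, which total-DNA extracts cannot provide when genome
sizes or gene copy numbers differ between targets. A cleaned PCR product of
known sequence, however, converts exactly from a fluorometric mass
measurement into molecules per microlitre:

```
MW           = n_AT · 617.4  +  n_GC · 618.4        [g/mol, overridable]
copies / µL  = q · 10⁻⁹ · N_A / MW                  [q in ng/µL]
```

plexcal implements this arithmetic and everything a calibration workflow
needs around it:

* **Quantification** — `count_pairs()`, `molecular_weight()`,
  `copies_per_ul()`, `quantify_stock()`: sequence + replicated ng/µL
  readings → absolute DS copies/µL.
* **Dilution planning** — `plan_serial_dilution()`, `propagate_cv()`,
  `compare_plans()`: minimal-step serial dilutions under a volume-indexed
  pipetting-error model, with CVs combined in quadrature (three 1:10 steps
  propagate ≈1.7% error where one 1:1000 step costs 8%).
* **Panel QC** — `panel_qc()`: melting-temperature balance (Wallace and
  nearest-neighbour), exhaustive cross-dimer screening with 3′-anchor
  detection, amplicon size spacing per separation platform (capillary
  20 bp / agarose 30 bp), the <300 bp degraded-DNA rule, and
  degeneracy-aware in-silico PCR (`predict_amplicon()`).
* **Balancing & sensitivity** — `propose_adjustment()` applies the stepwise
  ±0.1 µM concentration rule against the panel's median signal;
  `lod_from_grid()` derives each target's limit of detection (smallest copy
  level with all replicates ≥0.1 RFU and no failure above it) from a
  replicated sensitivity grid laid out by `design_sensitivity_grid()`.
* **Fixtures & CLI** — `generate_fixture()` writes a deterministic synthetic
  data set (panel, templates, measurements, RFU grid); `exec/plexcal` exposes
  everything as `plexcal quantify | dilute | panel-qc | balance | sensitivity
  | fixture`.

A seven-target example panel (COI markers for alpine ground beetles, wolf
spiders and a harvestman, plus an 18S Collembola pair; products 86–228 bp on
a capillary platform) ships with the package: `example_panel()`.

## Worked example

```r
library(plexcal)

# a 100-bp product at 50% GC, measured in triplicate
st <- quantify_stock("Collembola", strrep("ATGC", 25), c(9.8, 10.0, 10.2))
st
#> Template stock 'Collembola': 100 bp (50 AT / 50 GC), MW 61790.0 g/mol
#>   q = 10.000 ng/uL (n = 3) -> 9.746e+10 DS copies/uL

# bring it to 100 copies/uL for sensitivity testing
plan_serial_dilution(st$copies_per_ul, 100)
#> Dilution plan: 9.746e+10 -> 100 copies/uL (total factor 9.74614e+08, 9 steps, total CV 3.00%)
#>   aliquot_ul diluent_ul factor resulting_copies_per_ul step_cv
#> 1         10      90.00 10.000               9.746e+09    0.01
#> ...
#> 9         10      87.46  9.746               1.000e+02    0.01
#> Note: pre-wet the pipette tip before each transfer
```

The stock holds 9.746 × 10¹⁰ DS molecules per µL (10 ng/µL ÷ 61 790 g/mol ×
Avogadro, ×10⁻⁹ for the ng). Reaching 100 copies/µL needs a ×9.7 × 10⁸
dilution; the planner emits nine 1:10-scale steps at 10 µL aliquots, whose
independent 1% CVs combine to 3% total — far below the error of fewer, larger
steps.

```r
# QC the bundled panel and check its sensitivity grid
panel_qc(example_panel())            # flags the 129/144 bp gap (15 < 20 bp)
paths <- generate_fixture(tempfile(), seed = 1)
lod_from_grid(read_readings(paths[["readings"]]), "Collembola", "target_mix")
#> LOD for 'Collembola' (target_mix): 20 copies/reaction
#>   partial detection at: 7 copies
```

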