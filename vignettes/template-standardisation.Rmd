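---
title: "Standardised DNA templates for multiplex PCR: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardised DNA templates for multiplex PCR: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plexcal)
```

## The problem

A multiplex PCR amplifies several targets in one reaction, and the primer
pairs essentially never perform equally: better-performing pairs amplify
preferentially, biasing detection rates towards their targets. Balancing the
panel requires feeding every pair the *same number of template molecules* and
then adjusting primer concentrations until all targets give comparable signal.
Total-DNA extracts cannot deliver that equality when targets differ in genome
size or in the copy number of multiple-copy genes (mitochondrial COI versus
ribosomal 18S, say). The way out is to use quantified, cleaned PCR products as
templates: for a product of known sequence, a fluorometric mass concentration
converts exactly into molecules per microlitre.

plexcal implements that calibration arithmetic and the decision rules around
it. It deliberately contains no PCR chemistry: it quantifies, dilutes, checks
and decides.

## From mass concentration to copy number

For a double-stranded fragment whose strand sequence is known, the duplex
molecular weight is computed from its base-pair composition:

$$\mathrm{MW} = n_{AT}\, m_{AT} + n_{GC}\, m_{GC} + e,$$

where $n_{AT}$ and $n_{GC}$ count A–T and G–C pairs (each A or T character on
one strand is one A–T pair of the duplex, so the counts are strand-invariant)
and $m_{AT}$, $m_{GC}$ are per-pair masses. The defaults,
$m_{AT} = 617.4$ and $m_{GC} = 618.4$ g/mol with end term $e = 0$, are the
anhydrous average masses of the corresponding nucleotide-monophosphate pairs
(dAMP 313.21 + dTMP 304.2; dGMP 329.21 + dCMP 289.18). Published per-pair
coefficient sets differ slightly in end-group handling, so all four constants
are exposed through `mass_constants()`; any alternative convention is one
override away.

A measured concentration $q$ (ng/µL, the arithmetic mean of replicate
fluorometric readings — triplicates are standard practice) then gives

$$\mathrm{copies}/\mu L = \frac{q \times 10^{-9} \times N_A}{\mathrm{MW}}.$$

```{r}
quantify_stock("demo", strrep("ATGC", 25), c(9.8, 10.0, 10.2))
```

Degenerate IUPAC codes are rejected in quantified fragments: these are
sequenced products, and an ambiguity code there signals a data problem that
averaging would only hide. Replicate scatter above a 10% coefficient of
variation triggers a warning for the same reason — the whole scheme stands on
accurate pipetting and measurement.

## Dilution planning and pipetting error

Stocks are brought to a common working concentration (the classical series
spans 10 000 down to 5 copies/µL) by serial dilution. Several small steps are
more accurate than one large one, because small aliquots pipette badly. The
package makes this quantitative with a minimal error model: a table mapping
pipetted volume to coefficient of variation, linearly interpolated, never
extrapolated, with CV non-increasing in volume. The shipped default is
1 µL: 8%, 5 µL: 3%, 10 µL: 1%, 100 µL: 0.5% — a conservative reading of
typical air-displacement pipette specifications, and entirely user-replaceable
(`pipetting_error_model()`). Only the aliquot volume enters the lookup: the
diluent can be delivered in several accurate pushes, the aliquot cannot.

Steps are independent, so their CVs add in quadrature. That immediately
reproduces the bench rule of thumb:

```{r}
three <- plan_serial_dilution(1e6, 1e3)                # 3 x 1:10, 10 uL aliquots
one   <- plan_serial_dilution(1e6, 1e3,
                              max_step_factor = 1000, step_volume = 1)
compare_plans(three, one)[c("winner", "cv_a", "cv_b")]
```

`plan_serial_dilution()` uses the fewest steps whose factors stay at or below
`max_step_factor` (default 10): $\lceil \log R / \log F \rceil$ steps for
ratio $R$. Within that count the plan is full-factor steps followed by one
remainder step — for a ×2000 span, `10, 10, 10, 2`. The remainder is placed
last so the largest dilutions act on the most concentrated, least precious
material, and so the printed plan matches what a bench protocol would say. An
equal-factor decomposition ($R^{1/n}$ per step) would minimise the largest
factor, but produces awkward volumes for no CV benefit at a fixed aliquot
volume; the round-factor convention was chosen deliberately.

## Panel QC

`panel_qc()` bundles the checks that matter before any balancing starts.

**Melting temperatures.** Two estimators: the Wallace rule
$2(A{+}T) + 4(G{+}C)$ as the cheap, transparent default, and a
nearest-neighbour calculation (Allawi & SantaLucia 1997 unified parameters,
entropic salt correction $0.368\,(N{-}1)\ln[\mathrm{Na}^+]$, $C_T/4$ symmetry
factor; 50 mM Na⁺ and 500 nM total oligo by default). Degenerate primers are
expanded (cap 64 variants) and reported as min/mean/max rather than a single
falsely precise number. The panel check compares the spread (max − min across
all multiplex primers) to a tolerance, default 5 °C.

**Cross-dimers.** Primer pairs are screened in all combinations, self-pairs
included. The score is the longest ungapped run of complementary positions
over all antiparallel offsets, with base-set intersection semantics for
degenerate codes; a run covering either primer's 3′ terminus is flagged as
3′-anchored, since those duplexes are extensible. Thresholds default to 8
overall and 5 anchored. A run-length scan was chosen over thermodynamic
duplex energies because it is auditable and has an exact brute-force oracle —
the test suite verifies agreement with full enumeration on hundreds of random
primer pairs.

**Size spacing.** Adjacent product sizes must differ by at least the
platform's resolution: 20 bp for capillary electrophoresis, 30 bp on agarose
for fragments under 300 bp. Above 300 bp on agarose the requirement scales as
10% of the smaller fragment — resolution genuinely degrades with size, but
the 10% figure is a house rule and is labelled as such in reports. Notably,
the bundled example panel contains a 129/144 bp pair, 15 bp apart: capillary
systems evidently resolve it in practice, so the 20 bp default is
conservative. The check reports the conflict rather than resolving it.

**Degraded DNA.** When an assay targets degraded templates (gut contents,
faeces, museum material), products must be strictly shorter than 300 bp; a
300 bp product fails the boundary.

**In-silico PCR.** `predict_amplicon()` finds exact degeneracy-compatible
primer matches (intersection semantics, N matches everything) and reports
products inclusive of both primer footprints, with 0-based half-open
coordinates internally. Mismatch-tolerant binding is deliberately out of
scope: observed cross-reactions in this kind of assay tend to come from
specimen contamination, not near-match annealing, and a mismatch model would
suggest a precision the tool cannot honestly deliver.

## Balancing and sensitivity

With standardised templates in hand, balancing is a fixed-increment rule:
summarise per-target signal (median RFU over replicates; the median shrugs
off one failed lane) at a common template input, then decrease the
concentration of pairs above `median × (1 + tolerance)` and increase pairs
below `median × (1 − tolerance)` by one step — 0.1 µM — clamped to bounds
(0.1–1.0 µM, the range observed in practice for multiplex and singleplex
use), every move and clamp logged. The band is closed (a signal exactly at
the edge passes) and the tolerance defaults to ±25% of the median, a
conservative reading of "equal signal strength".

`balance_until_stable()` iterates the rule against a response function,
stopping on balance, on a revisited concentration vector (a limit cycle —
surfaced with a warning, never silent), or at the iteration bound
$(\max-\min)/\mathrm{step} \times n_\mathrm{targets}$. For testing the loop,
the fixture module ships a toy response, `rfu = efficiency × concentration`,
with efficiencies drawn from U(0.7, 1.3) and starting concentrations on the
0.1-µM grid in [0.2, 1.0]. Those ranges were picked so that one step changes
a signal by at most ~0.13 RFU while the tolerance band is ~0.5 × median wide
at the medians the loop actually visits — the rule is then contractive and
must converge, which is the property the tests exercise. The toy model is
not a PCR simulator and makes no chemical claim.

Detection uses the capillary electropherogram bound: a fragment is detected
when its peak reaches 0.1 RFU, inclusively. The limit of detection of a
target under a condition is the smallest tested copy level at which *every*
replicate is detected, with the stability requirement that no higher tested
level shows a failure; levels below the LOD with partial detection are
reported as the unstable range. Real grids can be non-monotone (a dropout
above a clean level); the rule then leaves the LOD undefined and reports the
conflict, rather than quietly picking a level a "stable reaction" standard
would reject.

## The fixture generator

`generate_fixture()` writes a complete synthetic data set so every code path
runs without external data: the bundled eight-pair panel (byte-identical
across runs), synthetic templates of exactly the panel's product sizes with
the concrete primer footprints at their ends and random filler between (so
in-silico PCR round-trips; the sequences are labelled non-biological — real
amplicon sequences live in public databases and are not shipped), triplicate
concentration measurements with 2% noise around per-fragment true values,
and a replicated sensitivity grid. The grid encodes the narrative the
sensitivity logic is designed for: copy levels 7, 20, 30, 100, 1000 and
10 000 per reaction across the four template conditions (single target,
target mix, each ± ~300 ng non-target background), fully detected from 20
copies upward with 0.3–1.5 RFU, and partial detection at 7 copies with one
replicate per triplet below 0.1 RFU. It is a grid *consistent with* reported
behaviour of a well-balanced assay, not a reproduction of any measured data
set — which is exactly what makes it a fair test of the LOD rule and no test
at all of PCR itself.

What passing tests show, therefore, is that the arithmetic, the planner, the
QC rules and the decision logic are correct on data with known structure.
They cannot show that a real panel will balance, or that a real LOD is 20
copies; those remain wet-lab facts.

## Numerical choices

* Copy-number arithmetic is double precision throughout; tests compare at
  stated relative tolerances (1e−9 for conservation and round-trips).
* Dilution plans treat a ratio within 1e−9 of 1 as "no dilution".
* Tolerance bands (balancing, detection) are closed intervals; boundary
  values pass.
* Degeneracy expansion is capped (default 64 variants) and refuses rather
  than samples beyond the cap.
* Test problem sizes: 1000 random sequences (50–500 bp) for the mass oracle,
  500 random primer pairs (≤12 nt) for the dimer oracle, 20 seeds for the
  balancing loop — sizes at which the brute-force oracles are exact and fast.

## Limitations

* No amplification kinetics, annealing-temperature effects or dye-channel
  modelling; gradient-PCR and cycle-number trade-offs are narrative
  knowledge, not computable here.
* The pipetting-error model is a volume-CV table, not a calibration of any
  specific instrument; replace the defaults with your pipettes' measured
  values.
* The dimer score ranks risk; it is not a free-energy prediction.
* Primer *design* is out of scope — plexcal checks panels, it does not
  propose them.
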