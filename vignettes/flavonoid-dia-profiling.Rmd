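---
title: "Glycosylated flavonoid profiling from DIA LC-MS data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glycosylated flavonoid profiling from DIA LC-MS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flavodia)
```

## The problem

Glycosylated flavonoids dominate the polyphenol profile of many plant
extracts, but they are hard to annotate automatically: dozens of
positional isomers share one molecular formula, and spectral-library
matching is sensitive to instrument type and collision energy. In
data-independent acquisition (DIA, the MS^E / all-ion-fragmentation family
of methods) the instrument alternates a low-energy scan of intact
precursors with a high-energy scan that fragments the entire mass range at
once. Nothing is isolated, so every fragment ion elutes as its own
chromatographic peak, in lockstep with its precursor.

`flavodia` turns that property into an annotation strategy. The fragment
channel is processed with exactly the same feature-detection machinery as
the precursor channel, producing an *MS2 feature table* of resolved
fragment peaks. Diagnostic aglycone fragments are recognised in that
table, linked back to co-eluting precursors by peak shape, and the
precursor-minus-fragment neutral loss identifies the sugar. The output is
a deliberately conservative call — aglycone, glycosidic bond type, sugar
class, e.g. `Kaempferol O-hexoside` — because gas-phase data alone cannot
fix the attachment position, and pretending otherwise produces
false precision.

## Fragmentation model

All m/z values are on the deprotonated ([M − H]⁻) basis; negative mode is
assumed throughout. For an aglycone of neutral monoisotopic mass $M$:

* **Heterolytic O-cleavage** releases the intact glycosyl residue and
  leaves the even-electron aglycone anion at $M - 1.007276$ (the proton
  mass).
* **Homolytic O-cleavage** transfers one hydrogen atom to the departing
  sugar, leaving the radical anion $[\mathrm{Agly} - 2\mathrm{H}]^{\cdot-}$
  exactly one hydrogen atom (1.007825 Da) below the heterolytic fragment.
  Correspondingly, when a loss is matched for a radical fragment the
  expected neutral is the glycosyl mass *plus* 1.007825 Da.
* **C-glycosides** never release the bare aglycone. Cross-ring cleavage of
  each C-bound sugar leaves a retained residue of 42.0106 Da (C₂H₂O,
  "etenol") or 72.0211 Da (C₃H₄O₂) on the fragment; the complementary
  neutral losses per sugar are 120.0423 / 90.0317 Da for a hexose and
  90.0317 / 60.0211 Da for a pentose.

The electron mass is ignored in all adduct arithmetic (deprotonation
subtracts the proton mass only). At m/z 300 the electron amounts to
1.8 ppm of a dalton, i.e. under 0.002 ppm of the m/z — far below both the
instrument accuracy this pipeline targets and the 0.2 ppm agreement we
verify against reference values. The "C₂H₃O residue" phrasing sometimes
used for C-glycoside fragments is implemented here on the deprotonated-ion
basis as a +42.0106 (C₂H₂O) gain; this reproduces the observed
etenol-series fragments (e.g. the apigenin di-etenol ion at 353.0667),
whereas a neutral-residue reading does not.

The fragment database generator (`build_fragment_db()`) enumerates, per
aglycone, the O-cleavage pair plus all distinct C-residue sums for one and
two sugars — seven records per aglycone. Two sugars is the cap because
di-C-glycosides (schaftoside-type) are the most complex species the
dictionary targets; deeper glycosylation is left to the O-loss entries
(disaccharide residues are in the sugar dictionary as single losses).

## Feature detection

Both DIA channels run through the identical stack, with one difference:
the fragment channel uses a lower minimum height (4 × 10³ vs 8 × 10³),
since fragment ions divide their precursor's current.

* **Mass detection**: centroids at or below the noise level (3 × 10²) are
  dropped.
* **EIC building**: deterministic, intensity-seeded greedy grouping.
  Seeds are taken in decreasing intensity order among centroids that reach
  the minimum height; each seed opens an m/z window — `max(0.005 Da,
  10 ppm)`, the "absolute or ppm" convention in which the wider component
  wins — and collects the most intense unassigned centroid per scan. An
  EIC must span ≥ 5 consecutive scans at ≥ 8 × 10² counts. This is a
  transparent approximation of wavelet-based builders; we validate it by
  ground-truth recovery on synthetic runs and by equivalence with
  exhaustive grouping on small instances, not by per-point equality with
  any particular implementation.
* **Peak resolving**: local-minimum search in RT. Points below the
  0.15 intensity quantile of the EIC (the complement of the 0.85
  "chromatographic threshold") are treated as baseline. Above-baseline
  segments split at local minima separated by ≥ 0.035 min; a candidate
  peak must reach the minimum height, have an apex/edge ratio ≥ 1.8, a
  duration within 0–2 min, and ≥ 5 points. A single missing scan inside a
  peak (a centroid lost to jitter or to a competing EIC) does not split
  it; only an RT gap wider than the local-minimum search range does.
  Areas are trapezoidal integrals over minutes.
* **Deisotoping**: features 1.00335/z Da apart (z ≤ 1 by default), within
  0.003 Da / 5 ppm and 0.05 min, with monotonically decreasing intensity,
  collapse onto their most intense member.
* **Join alignment**: master-list greedy matching with score
  $3\,(1 - |\Delta m/z|/\mathrm{tol}_{mz}) + 2\,(1 - |\Delta RT|/\mathrm{tol}_{RT})$
  at tolerances 0.007 Da / 12 ppm and 0.045 min; ties break on smaller
  |Δm/z|, then input order, so results are order-deterministic.
* **Gap filling**: empty cells are re-integrated from raw data within
  0.005 Da / 7 ppm and 0.04 min; a fill needs ≥ 4 contiguous scans forming
  a unimodal profile. The "intensity tolerance" of 0.2 is read as the
  maximum relative deviation from monotone along each flank — a rising
  flank may locally dip by at most 20%, mirrored on the falling side.

## Linking and sugar assignment

Peak-shape similarity is the Pearson correlation of the precursor and
fragment traces interpolated onto their shared RT grid, computed in the
shared sample where the precursor is most intense. The default threshold
of 0.8 and the default link RT tolerance (0.045 min, reusing the aligner
tolerance) are design choices: shape correlation for genuinely co-eluting
Gaussian peaks in the synthetic model sits above 0.95 even with noise, so
0.8 leaves headroom for asymmetric real peaks while rejecting neighbours
half a peak-width away. Pairs where the fragment exceeds its precursor are
flagged but kept — shared fragments and in-source effects make a hard cut
unsafe.

For O-cleavage fragments the loss is looked up in the sugar dictionary
(default tolerance 0.01 Da; observed-vs-theoretical deviations in
reference annotations reach ~0.003 Da, so 0.01 Da accepts them with
margin while keeping the dictionary entries unambiguous). All candidates
within tolerance are retained, ordered by |Δloss|, with the best marked.
For C-residue fragments the loss is decomposed into per-sugar partial
losses; the number of parts is fixed by the residues the fragment retains
(one sugar for 42/72 Da, two for 84–144 Da). Because a 90.0317 Da partial
loss can come from either a hexose or a pentose, the call lists all
alternatives joined by `" or "` — e.g.
`di-C-hexoside or C-hexoside-C-pentoside` for a 210.074 Da loss. This
ambiguity is intrinsic to the arithmetic, not a scoring failure, and the
reporting keeps it visible. MS2 aglycone features that find no precursor
partner remain in the MS2 annotation table as orphans with empty
precursor columns; they are informative (intense aglycones whose
precursor fell below the MS1 threshold) but never produce a glycoside
call.

Isobaric aglycone isomers (kaempferol / datiscetin / luteolin share
C₁₅H₁₀O₆) cannot be separated by exact mass; `jaccard_isomer_score()`
ranks candidates by fragment-set overlap, $|A \cap B| / |A \cup B|$ at a
m/z tolerance, which favours the isomer whose full predicted fragment
series is present.

## Summary analytics

The flavone:flavonol ratio is the plain quotient of backbone hit counts;
it is undefined (an error) when the flavonol count is zero. Sample
correlation uses Pearson on `log10(1 + intensity)` vectors over all
aligned rows (Spearman available); the log transform keeps a handful of
intense peaks from dominating the comparison, and constant-intensity
samples are excluded with a warning rather than returning NaN columns.
Database-overlap counts partition hit sets by consensus m/z rounded to 4
decimals — at that precision two genuinely different compounds virtually
never collide, while the same compound found via two databases always
does. Figures are ggplot2 objects (500 dpi PNG by default when written by
the pipeline).

## The synthetic-run generator

`simulate_run()` emulates what the pipeline consumes, not the full
physics of an LC-MS instrument. Each spiked glycoside contributes a
Gaussian elution profile (default sd 0.02 min, a plausible UPLC peak
width) to the MS1 channel at its computed [M − H]⁻ m/z, with an M+1
isotope satellite at +1.00335 Da and relative abundance 1.1% per carbon;
its diagnostic fragments trace the *identical* profile in the MS2
channel, scaled by per-fragment yields (defaults 0.6 / 0.35). Runs are 10
minutes at 10 Hz per channel, alternating scans; noise is uniform random
centroids around the floor intensity (default 200 counts, i.e. below the
3 × 10² mass-detection noise level — the detector's first filter is what
makes that floor invisible downstream); all m/z values carry Gaussian
jitter (3 ppm sd). Everything is reproducible under a fixed seed.

What the generator deliberately omits: chemical background and co-eluting
matrix, in-source fragmentation, detector saturation, RT drift between
samples, peak tailing, and shared fragments between co-eluting compounds.
Passing tests on synthetic cohorts therefore demonstrates that the
*algorithms* are correct and internally consistent — recovery of known
truth under clean, controlled conditions — not that real plant extracts
will annotate at the same rates. On real data the manual-inspection steps
(blank overview, chromatogram comparison) and the curated databases carry
correspondingly more weight.

The bundled demonstration cohort (`demo_cohort_spikes()`) holds twenty
distinct glycosides — O- and C-glycosides of six aglycones with mutually
distinct masses — across three samples, eluting between 1.5 and 6 min
with apex heights 2 × 10⁴ to 1 × 10⁵ (2.5–12× the MS1 height floor), the
regime of a small plant-extract batch. Validation runs the full pipeline
on this cohort and scores it against ground truth; the fragment database
for that check is generated for the six spiked aglycones, the analogue of
a study-specific curated database. With the isomer trio included instead,
every kaempferol call would be accompanied by datiscetin/luteolin
alternatives that exact mass cannot separate — the Jaccard score exists
for exactly that situation.

## Numerical choices and degenerate inputs

* Monoisotopic masses come from a fixed table of most-abundant-isotope
  masses (C, H, N, O, P, S, halogens, Na, K); formulas are parsed
  case-sensitively, and unknown symbols or zero counts are errors, never
  silently skipped.
* Problem sizes in the test-suite: toy single-trace runs of a few hundred
  scans for operation-level checks; the three-sample, twenty-spike cohort
  (6 000 scan cycles per run) for end-to-end validation.
* Tolerance semantics are uniform: every "x Da or y ppm" pair resolves to
  the wider window at the m/z in question.
* Ties in alignment break by score, then |Δm/z|, then input order;
  sugar-candidate ties break by |Δloss|. Both make outputs independent of
  database row order (verified by permutation tests).
* Degenerate inputs fail loudly: empty databases, inverted
  precursor/fragment pairs, non-positive masses and tolerances, missing
  MS levels, profile-mode spectra. Empty *results* (no features, no
  links) are valid empty tibbles, not errors.
* RT is minutes everywhere; mzML stores seconds and the I/O layer
  converts.

## Limitations

Positional isomers are out of scope by design — the pipeline reports
bond type and sugar class only. Positive-mode fragment rules, acylated
C-glycosides beyond the coumaroyl entries, tri-glycosylation via
C-residues, RT-drift warping beyond the join tolerance, and
spectral-library cosine matching are not implemented. The EIC builder is
a deterministic approximation validated against ground truth, not a
reimplementation of any specific wavelet algorithm; on very noisy real
data its greedy assignment may fragment low-intensity traces that a
smoothing builder would keep whole.
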