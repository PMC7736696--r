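---
title: "glycoflow: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{glycoflow: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoflow)
```

This vignette documents the models inside `glycoflow`, the parameters a user
may want to touch, the numerical choices that were genuinely open, and what
the synthetic-data tests do and do not demonstrate about real data.

## 1. Chemistry layer

All masses are monoisotopic and assembled from element-count formulas using
the IUPAC atomic masses and isotope abundances hard-coded in
`R/chem-core.R`. A glycopeptide's neutral mass is

$$ M = \sum_{\text{residues}} m_r + m_{\mathrm{H_2O}}
     + \sum_{b \in \{H,N,F,S\}} n_b\, m_b + \sum_{\text{mods}} \Delta m, $$

with glycan *residue* masses (monosaccharide − H₂O): Hex C₆H₁₀O₅
(162.0528 Da), HexNAc C₈H₁₃NO₅ (203.0794 Da), Fuc C₆H₁₀O₄ (146.0579 Da,
the deoxyhexose residue), NeuAc C₁₁H₁₇NO₈ (291.0954 Da). Ions are proton
adducts only: $m/z = (M + z \cdot 1.007276)/z$. Sodium and other adducts are
out of scope; the registered modifications are carbamidomethyl (C₂H₃NO),
Met/Cys oxidation (O) and formylation (CO).

**Isotope patterns** are computed by convolving per-element isotope
distributions, aggregated on the integer isotope-offset grid (0 =
monoisotopic). Fine structure within an offset is deliberately collapsed:
extraction later places isotope $k$ of a $z$+ ion at
$m/z_0 + k \cdot 1.00336/z$, the averagine mean spacing, and an m/z window of
0.025 around that centroid is far wider than the fine-structure spread for
peptide-sized molecules. Per element the $n$-atom distribution is obtained by
binary-exponentiation convolution with a $10^{-15}$ tail trim; the unit tests
check the result against an atom-by-atom polynomial-expansion oracle to
$10^{-9}$ on random formulas of up to 30 atoms, and that full patterns sum
to 1 within $10^{-6}$.

The pattern prefix used for extraction covers `min_covered_fraction` of the
distribution (default **0.95**). Which isotopes a targeted-integration tool
should include is a genuinely open choice; 0.95 keeps 4–7 isotopes for
tryptic glycopeptides, and since integrated areas are divided by the covered
fraction, the default only trades precision against interference
susceptibility. It is exposed in `quant_config()`.

## 2. Feature graph identification

Nodes are deconvoluted neutral-mass features (mass, RT, intensity) above an
intensity threshold (default **10⁶** counts). An edge is created whenever
both constraints hold for some building block $b$:

* $\bigl||\Delta M| - m_b\bigr| \le$ `mass_tol` (default **0.02 Da**), and
* $|\Delta RT| \le$ the block's RT window — **30 s** for Hex, HexNAc and the
  HexHexNAc composite, **20 s** for Fuc, **120 s** for NeuAc (sialic acids
  shift retention strongly; fucose barely).

The HexHexNAc composite block exists to bridge a missing intermediate
glycoform; its edge is created even when the two-step path is present.
With the default five blocks, no two block masses are within twice the mass
tolerance of each other, so a pair can match at most one block; with
user-extended registries all matches are emitted and flagged `ambiguous`.

Connected components are glycopeptide clusters (numbered by descending total
intensity). From each MS/MS-verified anchor — matched to a feature within
**10 ppm** and **30 s** — compositions propagate breadth-first, adding or
subtracting block counts per edge. Three things can go wrong, and each is
reported rather than hidden:

* a node reached with two different compositions (or from anchors of
  different peptides) is marked `conflicted` — kept and reported by default,
  dropped under `strict = TRUE`;
* a negative count (e.g. F = −1) marks the node `illogical`;
* `filter_illogical()` removes illogical nodes and then logical nodes whose
  *every* edge leads to a removed node, recording both reasons. Nodes with no
  edges at all (singleton clusters) are not touched by the second rule.

Propagation continues *through* illogical nodes: deltas are relative, so a
downstream node may still be logical; the oracle tests compare the whole
assignment against exhaustive path enumeration on small clusters.

Analytes detected at more than one RT (a known artifact of upstream feature
finding, and the signature of genuine isomers) are merged when their RTs are
within `rt_merge_window` (default **60 s** — the merge is meant to capture
split peaks and closely eluting isomers, a few peak widths wide) and flagged
`needs_review` when further apart, never silently summed.

One upstream convention deserves a note: the original graph tool's "maximum
subgroup degree = 1" setting has no published definition. `glycoflow`
propagates compositions over any number of edges (otherwise anchors could
not label a whole cluster) and treats degree limits as a reporting concern
only; this interpretation is documented here rather than asserted as the
original tool's behavior.

## 3. Preprocessing (deisotoping/decharging)

The pipeline accepts externally deconvoluted feature tables; the built-in
preprocessor exists so the whole chain runs from raw centroided scans. Per
scan, maximal runs of peaks spaced by $1.00336/z$ within `mz_tol` (default
**0.01 m/z**) are collected scanning $z$ from high to low (high-charge
envelopes are denser and must claim peaks first); an envelope needs at least
two isotopes. The monoisotopic member is the lowest-m/z candidate (among the
first three) whose leading intensities best match the averagine-predicted
pattern at the envelope mass, ties toward lower m/z. When the true
monoisotopic peak is below the noise floor this picks the next isotope and
the feature mass is high by $k \times 1.00336$ — the classic failure mode of
automated deconvolution. It cannot be fixed without raw profile data, so
every feature instead carries a `mono_confidence` score (margin between the
best and second-best candidate), making the error rate measurable.
Cross-scan linking is single-linkage with `mass_tol` 0.01 Da and an RT gap
tolerance of 10 s; feature RT is the intensity-weighted mean.

## 4. Curation and quantification

Per analyte (peptide, composition, RT center, width, charge list):

1. scans within `rt_center ± rt_width/2` are summed on a pooled m/z axis
   (peaks closer than 0.005 m/z merge). The default cluster width is
   **15 s**, narrowed to **7 s** per analyte where interferences elute
   closely — widths live in the analyte list, not in code;
2. per charge state, each theoretical isotope centroid is extracted as the
   most intense peak within ±**0.025 m/z**; missing isotopes contribute 0;
3. QC gates: |ppm| < **10**, IPQ < **0.2**, S/N > **9**;
4. passing charge states are integrated, divided by the covered isotopic
   fraction, summed, and total-area normalized per site.

Two estimators in step 3 have no published formula and are therefore our own
choices, stated prominently:

* **IPQ** $= \sum_i |o_i - t_i|$ over the included isotopes, with both the
  observed and theoretical intensities normalized to sum 1. It is
  dimensionless, 0 for a perfect match and 2 maximally, which makes the 0.2
  gate meaningful (one-tenth of the worst case). An all-zero envelope gets
  the sentinel IPQ 2, S/N 0, undefined ppm, and fails.
* **S/N** $= (\text{apex} - \text{background})/\text{noise}$ with background
  the median and noise the SD of peaks in a ±2.5 m/z window flanking the
  envelope, excluding peaks within the extraction window of any envelope
  isotope. Median/SD over a flanking window is robust to a single
  neighboring envelope; the estimator is exposed in `quant_config()` because
  the >9 gate makes results sensitive to it. With fewer than two flank peaks
  the noise is 0 and S/N degenerates to ∞ (apex above background) or 0.

RT alignment locates each calibrant's extracted-ion apex within **30 s** /
**0.1 m/z** of its expected position; the observed→reference *shift* is
interpolated piecewise-linearly between calibrants and held constant beyond
the outermost ones (interpolating the shift, not the mapped value, keeps the
mapping invertible outside the calibrated range). Fewer than three located
calibrants fall back to a single median shift; none, to the identity with a
warning. m/z recalibration fits a linear ppm error against m/z from at least
three located calibrant peaks, otherwise identity.

Isomeric compositions merged at identification time enter quantification
once, and relative abundances are not renormalized to any intersection of
analytes across runs.

## 5. The synthetic data generator

`make_default_truth()` builds six tryptic IgG/IgA *N*-glycopeptide site
profiles — IgG1 (EEQYNSTYR), IgG4 (EEQFNSTYR), IgG2/3 (EEQFNSTFR), IgA2 TPL
(TPLTANITK) and the joining-chain ENI/IIV peptides — each with 10–20
glycoforms grown as a *building-block-connected* subset of a packaged
composition menu. Connectedness is not a convenience: site
microheterogeneity is biosynthetically contiguous (glycoforms differ by
stepwise monosaccharide additions), and it is exactly this property that
makes anchor propagation able to label a whole cluster. Abundances decay
geometrically with a log-normal perturbation and sum to 1.

The RT model is linear: a large positive shift per NeuAc (**+60 s**, within
the 120 s search window), a small one per Fuc (**+5 s**), Gaussian jitter
(sd 2 s). The paper trail for these coefficients gives direction, not
magnitude; the defaults are documented here and configurable. Base RTs place
the six clusters 250 s apart in the experimentally observed elution order.
The spacing is a deliberate design choice: the IgG1 and IgG4 peptides differ
by exactly one oxygen, so a Fuc→Hex swap between their glycoforms reproduces
a NeuAc mass difference *exactly*, and clusters closer than the 120 s NeuAc
window would fuse through such coincidences. The default truth represents
distinct, baseline-resolved RT clusters; configuring closer base RTs
deliberately re-creates the cross-cluster ambiguity for study.

Confounders:

* **formylation** twins at +27.9949 Da, `rt_formyl_shift` (45 s) later,
  at a configurable fraction of the parent intensity (off by default);
* **Cys oxidation** twins at +15.9949 Da with near-identical RT for
  Cys-containing peptides, carrying `cys_ox_fraction` (default **0.7**,
  within the experimentally observed 65–77% range) of the species total.
  Because Hex − Fuc = 15.9949 Da exactly, these twins are isobaric with a
  Fuc→Hex swap — the generator reproduces the identification ambiguity this
  causes, and the test suite asserts it surfaces as flagged/removed
  assignments rather than silent calls. The optional HYT cluster
  (HYTNSSQDVTVPCR, carbamidomethyl-Cys) exercises this.

Scan simulation emits Gaussian elution profiles (sd 4 s) sampled every 1 s,
splits intensity over charge states 2–7 by configurable weights (defaults
0.55/0.35/0.10 on 2+/3+/4+; ions outside m/z 400–3,500 are dropped) and over
isotopes by the theoretical pattern. Noise has three dials, all 0 by default
(the default fixture is the noise-free reference): per-species log-normal
area noise between replicates (`noise_sigma`), per-peak log-normal noise
within a run (`scan_noise_sigma`), and Poisson-count exponential-intensity
baseline peaks. The quantification recovery tests use `noise_sigma = 0.04`,
`scan_noise_sigma = 0.05` and ~60 baseline peaks per scan — chosen to
emulate the few-percent technical variability of replicate nano-LC–MS runs.

**What passing tests do and do not show.** The synthetic data have exact
theoretical masses, Gaussian peaks, complete envelopes, and a closed
composition menu. Perfect recall on the noise-free fixture therefore
validates the *logic* (graph construction, propagation, filtering,
integration arithmetic), not performance on real chromatography: real data
add co-eluting background peptides, detector saturation, mass-calibration
drift, incomplete isotope envelopes and compositions outside any menu. The
quantification recovery bounds (median error < 2 percentage points, median
RSD < 5% across four replicates of a 15-glycoform site) are properties of
the simulated noise model, calibrated to be *qualitatively* comparable to
published replicate precision, not a claim about any instrument.

## 6. Problem sizes and determinism

All simulations used by the test-suite run at modest scale — six clusters of
10–20 glycoforms for identification (~80–100 features), one 15-glycoform
site × 4 replicates for quantification (~160 scans × ~250 peaks each) — the
sizes at which the brute-force oracles (polynomial expansion, exhaustive
path enumeration, pairwise edge checks) remain exact and fast. Every random
draw flows through a caller-supplied seed; identical seed and configuration
give byte-identical feature tables, scans and cluster tables (asserted in
the suite). RT is seconds everywhere internally; readers accept minutes via
an explicit argument.

## 7. Known limitations

* Proton adducts only; no sulfation/phosphorylation blocks (the block
  registry is user-extensible, the modification table is not yet).
* The preprocessor handles at most moderately overlapping envelopes; no
  profile-mode peak picking.
* Anchor generation from MS/MS spectra is out of scope: anchors are consumed
  as input, with only the oxonium/Y1/neutral-loss plausibility check in
  `check_anchor_msms()`.
* Protein-level inference (IgG2 vs IgG3, IgA1 vs IgA2) and O-glycan site
  localization are not addressed.
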