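---
title: "Methods: solution-NMR analysis of multi-domain proteins"
author: "DomainNMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: solution-NMR analysis of multi-domain proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DomainNMR)
```

This vignette documents the models, parameters and numerical choices
behind each analysis stage, what the synthetic-data generator does and
does not emulate, and the known limitations.

## Coordinates and geometry

`readStructure()` parses PDB files (via bio3d) and resolves alternate
locations by keeping the highest-occupancy conformer, with ties broken
alphabetically so conformer A wins — a deterministic rule matching
common practice. Residue numbering is the author numbering from the
file and is preserved through every downstream table; numbering
discontinuities become explicit `gaps`, because residues without
electron density are analytically meaningful (they correlate with
flexible, unprotected regions) and must not be silently renumbered
away.

`placeAmideHydrogens()` adds idealised amide protons where a structure
lacks them: H lies in the C(i−1)–N–CA plane on the external bisector of
the C–N–CA angle at 1.02 Å. This is the standard idealisation; a
force-field-specific placement would differ by hundredths of an
ångström, far below what an RDC fit can resolve. Prolines and residues
without a preceding carbonyl carbon (chain starts, post-gap residues)
are skipped. Placement commutes with global rigid motion to 1e-9 Å
(tested), so it can be applied before or after superposition.

`superpose()` implements the closed-form Kabsch least-squares overlay
on the intersection of (chain, residue, atom) keys. Hydrogens are
excluded by default so the matched-atom set is insensitive to whether
either model was protonated; the selection rule (`heavy`, `backbone`,
`CA`, `all`) is exposed because published "common atom" counts rarely
state their selection exactly. The reflection branch of the SVD is
always corrected, and selections with fewer than 3 pairs or collinear
geometry raise errors rather than returning a meaningless transform.

## Chemical shifts

**Completeness.** `assignmentCompleteness()` counts per-residue
chemistry honestly: prolines are excluded from amide H/N classes,
glycine from CB/HB, and glycine HA2/HA3 count as HA. The full construct
sequence (not just assigned residues) forms the denominator, and
percentages are rounded to one decimal, the conventional reporting
precision. The N-terminal residue is counted in the amide denominator:
its amide protons are usually unobservable in practice, but excluding
it would make the denominator disagree with the "non-proline residues"
convention used in assignment papers.

**Secondary shifts.** `secondaryShifts()` subtracts a bundled published
random-coil CA/CB scale (Wishart-type, DSS-referenced). The ΔCα−ΔCβ
difference cancels most referencing error, which is why the classifier
operates on the difference rather than on either shift alone. Glycine
contributes ΔCβ = 0.

**Classification.** `classifySecondaryStructure()` is a deliberately
simple run-length rule: ΔCα−ΔCβ above +0.7 ppm for ≥4 consecutive
assigned residues is helix, below −0.7 ppm for ≥3 residues is strand,
everything else coil; gaps in assignment break runs. The cuts are
literature-scale (secondary-shift offsets in regular structure are
several ppm, random-coil scatter a fraction of a ppm) and the minimum
run lengths reflect the shortest physically sensible elements. This is
not a TALOS-style predictor and is not meant to be: it has two
thresholds and two run lengths, all exposed as arguments.

**CSP.** `csp()` combines amide shifts as
`sqrt(dH² + (0.15 dN)²)`. The 0.15 nitrogen weight is the common
choice that maps the ~5-fold wider 15N dispersion onto the 1H scale; it
is an argument, not a constant. `identifyShifted()` applies a strict
`>` threshold (default 0.1 ppm), so a residue exactly at the threshold
is not reported — boundary behaviour is tested.

## Dynamics and exchange

**hetNOE.** `hetNoe()` computes the saturated/reference intensity
ratio and estimates its uncertainty by Monte Carlo: Gaussian baseline
noise is added independently to both intensities (both spectra carry
noise) over 500 draws by default, and the standard deviation of the
resampled ratio is reported. At noise-to-signal ≤ 2% the MC error
converges to the first-order propagation value
`ratio · sqrt((σ/I_sat)² + (σ/I_ref)²)` within 5% (tested at 10⁴
draws). Errors are reproducible for a fixed seed. `flagFlexible()`
uses the conventional 0.7 ratio cutoff, strict `<`.

**HDX.** `hdxClassify()` works on a three-timepoint grid (15 min, 24 h,
48 h by default). A peak is "detected" when intensity exceeds 3× the
baseline noise; the class is the length of the detected prefix:
unprotected, short, medium, persistent. The 3σ rule is an operational
substitute for visual peak inspection; it makes the classing monotone
in the exchange rate (tested over a rate ladder). `hdxExtent()` is the
clamped intensity deficit `1 − I/I_ref`.

## RDC analysis

The Saupe matrix carries Hz — the dipolar prefactor is folded in —
because couplings are measured and reported in Hz and the fit never
needs the prefactor separately. Two equivalent back-calculation routes
are implemented (`calcRdc()`, matrix contraction; `calcRdcAngles()`,
the (Da, R, θ, φ) polar form) and tested against each other to 1e-10;
keeping both guards the eigen-decomposition conventions.

**Conventions.** Eigenvalues are ordered |Azz| ≥ |Ayy| ≥ |Axx|;
Da = Azz/2; R = (2/3)(Axx − Ayy)/Azz with the x/y assignment chosen so
R ∈ [0, 2/3]; Euler angles are z-y-z in degrees; the principal frame is
made right-handed. The remaining 180° axis-flip ambiguity is inherent
to any order tensor and is folded out where it matters
(`interdomainAngle()` reports the angle between principal axes folded
to [0°, 90°]).

**Single-tensor fit.** The coupling is linear in the five independent
Saupe components, so `fitTensorSvd()` solves the 1/σ-weighted linear
problem by SVD of the design matrix. A singular-value ratio below
1e-10 raises a degeneracy error carrying the condition number — this
happens for near-parallel vector sets, where no tensor is identifiable.
χ² is the sum of squared σ-weighted residuals. Per-record σ should come
from repeat splitting measurements when available; `rdcDataset()`
applies a 0.5 Hz floor by default because triplicate-based σ estimates
are optimistically small, and falls back to a uniform 1 Hz in the
synthetic pipeline.

**Two-domain fit.** `fitTwoDomainShared()` implements the interdomain
orientation model: one shared Da and R, independent orientations per
domain (8 parameters). At fixed orientations the model is linear in
(Da, Da·R), so the magnitudes are profiled out exactly at each step and
Nelder-Mead only searches the 6 orientation angles. Starts are the two
per-domain SVD solutions and the pooled solution; starting from the
pooled solution guarantees the nested inequality χ²(pooled) ≥
χ²(two-orientation) by construction. The 180° flip ambiguity of each
per-domain start does not need extra restarts because the objective is
invariant under principal-axis flips. The iteration cap is 10⁴ with
Δχ² tolerance 1e-8; non-convergence is an error carrying the best χ².
The nested pooled fit is computed alongside for `fTestNested()`, which
uses the standard statistic
`F = ((χ²_red − χ²_full)/(p_full − p_red)) / (χ²_full/(N − p_full))`
and reports the F-CDF as the probability of significance. Under a true
common tensor the reported probabilities are uniform (KS-tested at 500
replicates in the acceptance run) — the test is calibrated, so a
reported 0.9999 means what it says.

**Q factor.** `qFactor()` defaults to the rms(d_exp) normalisation.
The literature also uses the tensor-magnitude normalisation
`sqrt(2 Da² (4 + 3R²)/5)`; it is available as an option because which
of the two a given paper used is often unstated — the rms form is the
more conservative default since it never rewards fitting small
couplings.

**NOE filtering.** Couplings from residues with hetNOE < 0.7 are
excluded before fitting (`filterByNoe()`): bond vectors averaging over
fast internal motion report a scaled, not a rigid-body, orientation.
Residues without an NOE value are retained with a warning rather than
dropped — dropping silently would bias fits on sparse NOE coverage.

## The synthetic-data generator

`makeTwoDomainStructure()` builds two poly-alanine domains with ideal
bond geometry by natural-extension placement: each domain is a helix
(φ = −57°, ψ = −47°; rise ≈ 1.5 Å per residue, tested) followed by an
extended segment, because a tensor fit against a single ideal helix is
poorly conditioned — its NH vectors lie on a cone — while the
helix-plus-strand mix is well conditioned. The domains are joined by a
3-residue linker with no coordinates, which exercises the gap
machinery exactly like a disordered loop. Domain B can be rigid-body
rotated (default axis: the tensor's y principal axis, so the principal
z-axis tilts by exactly the stated angle).

The generated ground truth fixes the study conditions used throughout
the tests and the acceptance run: alignment tensor Da = 15 Hz,
R = 0.3 (mid-range for a strongly aligned mid-size domain, giving
couplings within the ±40 Hz regime of dilute liquid-crystal
alignment); RDC noise 1 Hz (typical splitting-measurement
reproducibility); secondary-shift offsets +3.0/−0.5 ppm (helix) and
−1.5/+2.0 ppm (strand) with 0.2 ppm noise — round literature-scale
values; hetNOE ratios 0.85 (rigid) and 0.3 (flexible N-terminal tail);
HDX rates per structural class spaced ≥10× apart (1.0, 2×10⁻²,
1.8×10⁻³, 10⁻⁴ min⁻¹) so the three-timepoint classes are unambiguous
at 1% baseline noise; titration Kd = 5 mM with ligand points 0–50 mM
and 0.2 ppm saturation CSP on a 7-residue binding site, following the
one-site fast-exchange isotherm.

`simulateRdcs()` applies the single global tensor to the supplied
(solution-state) bond vectors; fitting those couplings against a
reference structure built without the rotation reproduces the
crystal-vs-solution comparison. Rotating a per-domain tensor together
with the domain's vectors would cancel identically and encode no
signal — the global-tensor formulation is the physically meaningful
one.

What the generator does *not* emulate: peak overlap and missing
assignments, heteroscedastic or correlated noise, cis/trans proline
heterogeneity, anisotropic internal motion (all couplings are
generated from rigid vectors), intrinsic-rate variation in HDX, and
ligand-induced intermediate exchange broadening. Passing tests on
synthetic data therefore demonstrate correctness of the estimators
under their stated noise model, not robustness to every pathology of
real spectra.

## Problem sizes and determinism

The test suite and acceptance script use 30–60 residues per domain
(50–120 bond vectors per fit), 100 seeds for single-tensor parameter
recovery, 50 seeds for interdomain-angle detection and 500 replicates
for the F-test null calibration — sizes chosen to estimate medians and
a KS statistic stably on a single core. Every stochastic function
takes an explicit seed and restores the caller's RNG state; the
pipeline (`runPipeline()`) reproduces all outputs byte-for-byte for a
fixed configuration and seed, and embeds the resolved configuration in
its manifest.

## Known limitations

- The two-domain model assumes both domains share the alignment
  magnitude; if interdomain flexibility partially averages one
  domain's alignment, the shared-Da assumption biases the recovered
  angle. Fitting more than two domains is out of scope.
- The secondary-structure classifier has no probabilistic output and
  ignores HN/N/C' shifts.
- The NMR-STAR reader covers the assigned-chemical-shift loop only.
- H placement is backbone-amide only; side-chain protons are not
  modelled.
- Exchange rates are classed, not fitted; protection factors against
  intrinsic rates are out of scope.
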