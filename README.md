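# DomainNMR

Solution-NMR analysis of multi-domain proteins: chemical-shift
assignment statistics, titration chemical-shift-perturbation (CSP)
mapping, CA/CB secondary-shift secondary-structure classification,
heteronuclear-NOE backbone dynamics, hydrogen–deuterium exchange (HDX)
protection classing, and residual-dipolar-coupling (RDC)
alignment-tensor analysis with a nested two-domain orientation model.

## The problem

Tandem-domain proteins (the motivating case is a tandem BRCT domain
from a kinetoplastid kinetochore protein) are routinely characterised
in solution by a battery of amide-resolved NMR experiments. Each
experiment yields a per-residue table — shifts, peak intensities,
couplings — and each has a small, well-defined analysis: combine,
threshold, fit, test. This package implements those analyses as
composable, tested functions behind S4 containers, so a complete study
can be reproduced from plain-text tables, and ships a synthetic-data
generator that emulates every input with known ground truth.

The centrepiece is the RDC analysis. Under weak alignment the residual
dipolar coupling of an NH bond reports its orientation through the
molecular alignment (Saupe) tensor *S*, a symmetric traceless 3×3
matrix:

    D = v' S v
      = Da [ (3 cos²θ − 1) + (3/2) R sin²θ cos 2φ ]

with (θ, φ) the bond's polar angles in the tensor principal frame,
axial magnitude Da and rhombicity R. Because D is linear in the five
independent components of *S*, a single-tensor fit is a weighted linear
least-squares problem solved by SVD (`fitTensorSvd()`). To ask whether
two domains are mutually oriented in solution as in a crystal model,
`fitTwoDomainShared()` fits one shared (Da, R) but independent tensor
orientations per domain (8 parameters) and compares it with the pooled
single-tensor fit (5 parameters) by an F-test on the χ² drop
(`fTestNested()`); `interdomainAngle()` reports the angle between the
two principal axes. Fit quality is summarised by the Cornilescu Q
factor, `Q = rms(D_exp − D_calc) / rms(D_exp)`.

## Worked example

```r
library(DomainNMR)

## synthetic two-domain construct: solution state carries a 7-degree
## interdomain rotation; the reference model does not
sol <- makeTwoDomainStructure(60, 60, rotation = 7, seed = 1)
ref <- makeTwoDomainStructure(60, 60, rotation = 0, seed = 1)

## simulate couplings in the solution state, 1 Hz noise
rdc <- simulateRdcs(sol$truth, nhBondVectors(sol$structure),
                    noiseSd = 1, seed = 1)

## exclude flexible residues, as a real analysis would
noe <- hetNoe(simulateHetNoe(sol$truth), nMc = 500, seed = 1)
rdc <- filterByNoe(rdc, noe, cutoff = 0.7)

## fit against the reference coordinates and test the orientation model
fit <- fitTwoDomainShared(rdc, nhBondVectors(ref$structure))
fit
#> RdcFit: 111 couplings, 8 parameters, chi2 = 86.23
#>   Q overall = 0.056; per domain: A = 0.042, B = 0.094
#>   [A] Da = 15.04 Hz, R = 0.288
#>   [B] Da = 15.04 Hz, R = 0.288
interdomainAngle(fit)
#> [1] 6.726219
fTestNested(fit@details$pooled, fit)$probability
#> [1] 1
```

The two-orientation model recovers the simulated 7° reorientation and
the F-test confirms the improvement over the pooled fit is significant.
The same functions accept real data: `readStructure()` (PDB),
`readShiftTable()` (NMR-STAR or TSV), `readRdcTable()` (TSV), and
`runPipeline()` orchestrates all stages with TSV/JSON reports and a
manifest.

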