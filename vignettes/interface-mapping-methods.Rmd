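---
title: "Methods: NMR titration mapping of a zinc-finger interaction interface"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NMR titration mapping of a zinc-finger interaction interface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fingermap)
```

## The scientific problem

The *Drosophila* dosage compensation complex is recruited to the male X
chromosome in part through a direct, highly specific contact between the
N-terminal C2H2 zinc finger of the ubiquitous DNA-binding protein CLAMP
and a short intrinsically disordered region of the male-specific organizer
MSL2. This package implements the quantitative analyses used to map such
an interface from solution NMR titrations: which residues of the labelled
partner respond to binding, how strong the interaction is, where the
responding residues sit relative to the finger's recognition helix, and
how the finger's DNA-reading positions compare with the C2H2 family norm.
A seeded synthetic-data generator provides every input with known ground
truth, so the whole pipeline is testable without deposited spectra.

## Fast exchange and the binding model

In an HSQC titration of a ^15^N-labelled protein P with unlabelled ligand
L under fast exchange ($k_\mathrm{off} \gg \Delta\omega$), each amide
shows a single population-averaged peak

$$\delta_\mathrm{obs} = (1 - f_b)\,\delta_\mathrm{free} + f_b\,\delta_\mathrm{bound},$$

with the bound fraction given by the single-site quadratic isotherm with
ligand depletion:

$$[PL] = \tfrac{1}{2}\left( P + L + K_d - \sqrt{(P+L+K_d)^2 - 4PL} \right),
\qquad f_b = [PL]/P.$$

`fraction_bound()` evaluates the smaller root in the cancellation-free
form $2PL / \big( (P+L+K_d) + \sqrt{\cdot}\,\big)$, which stays accurate
to ~1e-15 even when $K_d \ll P, L$; the test suite checks it against a
brute-force numeric root over six orders of magnitude.

### Global K~d~ fitting

`fit_kd()` shares one K~d~ across all fitted residues (a single binding
event) and gives each residue free bound-state offsets
$\Delta\delta_H, \Delta\delta_N$. Because the model is linear in these
offsets once $f_b$ is known, they are profiled out in closed form and the
fit reduces to a one-dimensional minimisation over $\log_{10} K_d$: a
25-point log-spaced grid on 1e-7 to 1e-1 M, golden-section refinement of
the best bracket, then a quasi-Newton polish. ^15^N residuals are scaled
by $\alpha_N$ (below). The fit is deterministic.

Two treatments of the free-state shifts are available:

* `fix_free_shifts = TRUE` (default): free-state positions are pinned to
  the measured apo peaks. Fewest parameters; appropriate when the apo
  spectrum is much better determined than the titration points.
* `fix_free_shifts = FALSE`: a free-state offset is fitted jointly per
  residue and dimension. When the apo spectrum carries the same
  peak-position noise as every other point — which is the case in a
  single titration session, and in the synthetic data — the apo-anchored
  model folds the apo noise coherently into every shift difference,
  biasing the fit and (worse) hiding that error from residual-based
  uncertainty estimates. The pipeline therefore fits with
  `fix_free_shifts = FALSE`.

When saturation never exceeds $f_b \approx 0.1$ at the final point the
data only bound K~d~ from below; the fit warns, and reports the upper
confidence limit as $+\infty$.

### Uncertainty

`bootstrap_kd_ci()` reports a percentile 2.5/97.5 interval over seeded
bootstrap refits. The default scheme is a semi-parametric residual
bootstrap: fitted peak trajectories plus residuals resampled from the
pooled per-dimension fit residuals, inflated by $\sqrt{n/(n-p)}$ to undo
the degrees-of-freedom deflation of raw residuals, with the apo point's
noise propagated under the jointly-fitted free-shift model. We chose this
default after measuring, in simulation at the package's own study
conditions (six interface residues, noise below), that case-resampling
whole residue trajectories — the other available scheme,
`method = "residue"` — delivers only ~86% empirical coverage for a
nominal 95% interval: with half a dozen exchangeable units the percentile
method is known to run narrow. The residual scheme measures ~92-93%
coverage under the same conditions. Residue-level resampling remains the
right choice when many residues report on binding and between-residue
heterogeneity (not peak noise) dominates; both are exposed.

## Chemical-shift perturbation and hotspots

`combined_csp()` uses the standard combined amide CSP

$$\Delta\delta_\mathrm{comb} = \sqrt{ \Delta\delta_H^2 +
(\alpha_N\,\Delta\delta_N)^2 },$$

with $\alpha_N = 0.14$ by default — the community-standard weighting that
makes the ~5x larger ^15^N ppm range commensurate with ^1^H. The value is
configurable because published analyses vary in the exact weight. The
endpoint is the highest-ratio titration point (closest to saturation);
profiles also carry `relative_csp` (CSP divided by the profile maximum)
for comparison with relative-perturbation bar plots.

`peak_trajectories()` checks the fast-exchange picture itself: each
residue's peak must move along a straight segment between free and bound
positions, so a total-least-squares line is fit through the
$(\delta_H, \alpha_N \delta_N)$ points and the maximum perpendicular
distance is reported; residues exceeding 3x a robust noise estimate (MAD
of all perpendicular residuals) are flagged as inconsistent with
two-state fast exchange.

`call_hotspots()` thresholds the CSP profile at mean + k·SD (default
k = 1) or at a quantile. Published interface mappings typically report a
ranked list without a stated cutoff, so the method and k are explicit
parameters and the full ranked profile is always retained alongside the
call.

## Zinc-finger numbering and DNA-binding-position typicality

`annotate_c2h2()` scans for the classical signature
`C-x(2,4)-C-x(3)-[FYLIVW]-x(5)-[hydrophobic]-x(2)-H-x(3,5)-H` and anchors
the recognition helix so that the first zinc-coordinating histidine sits
at position +7, i.e. helix position +1 is `his1 - 6`. Residues before the
helix count -1, -2, ... with no position 0 (zinc-finger community
convention). This anchoring was chosen because it reproduces, from the
motif alone, the full set of published position labels for the CLAMP
N-terminal finger (H138 at -1 through T150 at +12, with H149 as the
second coordinating histidine); a structure-derived helix start can be
substituted when available. The annotation span extends two residues
before the first cysteine and four past the last histidine — the
classical finger boundaries including the linker — clipped at sequence
ends and neighbouring fingers.

`clamp_zf_fragment()` ships a synthetic reconstruction of the CLAMP
finger span (127-153): every published residue identity is placed at its
published position, and the remaining positions are filler consistent
with the motif. It is a fixture for the numbering analysis, not the
native sequence.

`build_profile()` turns an aligned set of fingers into per-column residue
probabilities with pseudocounts,
$p_c(a) = (n_c(a) + \lambda q(a)) / (N_c + \lambda)$ (default
$\lambda = 1$, uniform background, gaps and X excluded from counts). This
replaces a profile-HMM treatment deliberately: all inputs here are
fixed-width finger alignments, so insert/delete states add nothing.
`information_content()` gives the per-column relative entropy in bits
(logo heights). `atypicality_score()` scores a query finger's residues at
the five canonical DNA-reading positions (-1, +1, +2, +3, +6) as
$\log_2 p_c(a)/q(a)$; negative totals mean the query uses residues rare
at those positions in the finger population. The total is also placed on
a seeded null of profile-sampled sequences; the percentile uses
randomised tie-breaking so it is exactly uniform under the null (verified
by a KS test in the suite).

## Disorder from chemical shifts

`secondary_shifts()` subtracts shipped random-coil reference values
(standard Wishart-school table; glycine has no CB, proline no amide H/N;
neighbour corrections omitted as negligible at helix/coil contrast
scale). `rci_s2()` computes a per-residue weighted mean absolute
secondary shift (weights CA/CB/C' 1, N 0.2, H/HA 2.5 — protons
up-weighted for their smaller ppm range, ^15^N down-weighted for its poor
coil reference), smooths with a centred 3-residue window, and maps it
through a random-coil-index style transform: `rci = 1/max(A, 0.05 ppm)`,
`s2 = clamp(1 - 0.15 * rci, 0, 1)`. The constants place
canonical-amplitude helix near s² ≈ 0.83 and pure coil at 0; only the
ordered/disordered contrast is meaningful, not the absolute s² values,
which is how shift-derived order is used in interface mapping.
`classify_regions()` segments at s² > 0.7 with a 3-residue minimum run,
merging shorter runs into their neighbours (shortest first, leftmost on
ties).

## The synthetic-data generator

`clamp_like_titration_spec()` encodes the study conditions the pipeline
is validated under: a 67-residue construct (87-153), 0.1 mM labelled
protein, ligand ratios 0, 0.25, 0.5, 1, 2, 4, 8 (the ligand-excess
regime; the original ladder is not published, so the fixture ladder is a
package choice), K~d~ = 0.2 mM, a six-residue interface on the helix
(142, 143, 144, 146, 147, 150) with bound-state offsets drawn once per
seed from 0.05-0.15 ppm (^1^H) and 0.3-1.0 ppm (^15^N) — at least 5x the
peak noise of 0.004/0.02 ppm (^1^H/^15^N). Noise is added to observed
peak positions, not to populations, matching how spectral uncertainty
manifests. All generators take mandatory seeds and restore the global RNG
state.

What the generator does *not* emulate: intermediate/slow exchange line
shapes, peak overlap and missing assignments (supported by the readers,
but not generated by default), multi-site binding, ^15^N reference
drift, and real between-residue correlations in coil shifts. Passing
tests therefore demonstrate correctness of the estimators under the
stated model, not robustness to every pathology of real spectra.

## Problem sizes and numerical choices

The validation suite uses: a 10^4^-point random grid for the isotherm
oracle; 20 seeds x 5 true K~d~ values (0.05-1 mM) with 200 bootstrap
replicates each for recovery and CI calibration; 20 seeds for hotspot
precision/recall and for disorder-boundary recovery; 2000 null draws for
percentile uniformity. These sizes give stable pass/fail behaviour at the
asserted thresholds while keeping the default suite around two minutes.
Ties in hotspot thresholds are broken strictly (> threshold); the
isotherm clamps its output to [0, 1] against rounding at the boundaries;
K~d~ optimisation is bracketed to 1e-7 to 1e-1 M, which spans any
NMR-titratable affinity.

## Known limitations

* One global K~d~; cooperative or multi-site binding is out of scope.
* The NMR-STAR reader covers only the `Atom_chem_shift` loop subset
  needed for BMRB chemical-shift depositions.
* The RCI-style s² is a qualitative order readout, not a substitute for
  relaxation-derived order parameters.
* Helix anchoring from the motif assumes a canonical finger; unusual
  spacer lengths shift the helix start, which can be overridden.
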