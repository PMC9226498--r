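# fingermap

Mapping a protein–peptide interaction interface from NMR titration data,
built around the interaction between the N-terminal C2H2 zinc finger of
the *Drosophila* CLAMP protein and the intrinsically disordered
CLAMP-binding region of MSL2 — the contact that helps recruit the dosage
compensation complex to the male X chromosome. The package is aimed at
structural biologists analysing HSQC titrations of a labelled domain with
an unlabelled partner.

## What it computes

* **Combined amide CSP**: for each residue observed in the apo and
  near-saturation spectra,
  `CSP = sqrt(Δδ_H² + (α·Δδ_N)²)` with α = 0.14, plus per-residue
  trajectory diagnostics (total-least-squares collinearity, the
  fingerprint of two-state fast exchange) and hotspot calling at
  mean + k·SD.
* **Global K_d under fast exchange**: observed peaks are population
  averages `δ_obs = (1−f_b)·δ_free + f_b·δ_bound` with the bound fraction
  from the ligand-depletion quadratic isotherm
  `[PL] = ((P+L+K_d) − sqrt((P+L+K_d)² − 4PL))/2`. One shared K_d, free
  per-residue bound-state offsets (profiled out in closed form), and a
  seeded bootstrap percentile confidence interval.
* **Zinc-finger numbering**: C2H2 motif scanning
  (`C-x(2,4)-C-x(3)-[FYLIVW]-x(5)-[hydrophobic]-x(2)-H-x(3,5)-H`),
  recognition-helix-relative positions (+1 = first helix residue, no 0),
  the five canonical DNA-reading positions (−1, +1, +2, +3, +6), and a
  log-odds atypicality score of a finger's DNA-binding residues against a
  position-probability profile of C2H2 fingers.
* **Disorder from shifts**: secondary shifts against a random-coil
  reference and an RCI-style order parameter s² ∈ [0, 1] with
  ordered/disordered segmentation.
* **Synthetic data with ground truth**: seeded generators for titration
  series, profile-sampled alignments and helix/coil shift tables, so
  every stage is testable end to end.

I/O covers a simple TSV dialect for shift tables, peak lists and
titration manifests, a minimal NMR-STAR v3 `Atom_chem_shift` subset (the
format of BMRB chemical-shift depositions), aligned FASTA, and B-factor
painting of PDB files for structure colouring.

## Worked example

The scripts under `analysis/` run the whole pipeline on a simulated
study-like titration (0.1 mM labelled 67-residue construct, ligand to 8×
excess, K_d = 0.2 mM, a six-residue helix interface, realistic peak
noise):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_csp_hotspots.R
Rscript analysis/03_fit_kd.R
Rscript analysis/04_zf_numbering.R
Rscript analysis/05_disorder.R
```

which prints, among other things:

```
CSP over 67 residues; max CSP 0.132 ppm at residue 146
Hotspots (mean + 1*SD, threshold 0.04315 ppm): 142, 143, 144, 146, 147, 150
hotspots match designed interface: TRUE

Global fast-exchange fit: Kd = 0.0001949 M (0.195 mM), rss = 0.0006693, 6 residues, 7 points
  bootstrap 95% CI: [0.0001649, 0.0002359] M
true Kd 0.2 mM; relative error 2.5%; CI covers truth: TRUE

C2H2 finger 127-153: C129/C132...H145/H149, helix 139-149 (+1 = 139)
total log-odds -20.250 (null percentile 0.000): atypical DNA-binding residue pattern

  start end      state
1    87 126 disordered
2   127 153    ordered
```

Reading the output: the six residues with CSP above mean + 1 SD are
exactly the designed interface — all on the recognition helix; the
global fit recovers the simulated 0.2 mM dissociation constant within
its bootstrap interval; the finger's DNA-reading positions score far
below the C2H2 profile norm (negative log-odds), i.e. an atypical
DNA-binding residue pattern; and the chain segments into a disordered
tail (87–126) and an ordered finger (127–153) at the designed boundary.

The same stages are available programmatically through `run_pipeline()`
with a single `run_config()`.

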