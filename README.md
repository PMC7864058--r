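# domcross

Quantifying coupled intra- and interdomain dynamics in flexibly linked
two-domain proteins, modelled on human Pin1 (WW domain, residues 1–39;
linker 40–52; PPIase domain 53–163).

Substrate binding at one end of the WW domain changes both the separation
between the two domains and the internal conformation of the WW domain.
`domcross` implements the full quantitative chain needed to detect that
cross-talk from NMR and MD data:

* **Relaxation fitting** — monoexponential decays I(t) = I₀e^(−Rt) with
  duplicate-delay noise estimation (σ = RMS(Δ)/√2) and Monte Carlo rate
  uncertainties; apo-vs-bound R₂−R₁/2 domain-mobility regression (the
  per-domain slope reads out relative rotational mobility); conversion to
  J_eff(0) = 2τ_c/5; combined amide CSPs
  Δδ_NH = √(Δδ_H² + (0.154·Δδ_N)²).
* **PRE analysis** — Γ₂(¹Hᴺ) = R₂,PARA − R₂,DIA with overflow
  ("disappeared peak") bookkeeping, the three-pass trimmed significance
  threshold M3 ± 2·STD3, apo-vs-bound ΔΓ₂ contrasts, and the
  Solomon–Bloembergen forward model
  Γ₂ ∝ S(S+1)(gμ_Bγ_I)²⟨r⁻⁶⟩[4τ_c + 3τ_c/(1+ω_H²τ_c²)]
  with ⟨r⁻⁶⟩ ensemble averaging.
* **Trajectory geometry** — per-frame site distances (atoms, Cα,
  mass-weighted domain centers of mass), radii of gyration, heavy-atom
  contact numbers (4.5 Å cutoff), fluctuating-pair selection, and
  hydrogen-bond occupancies (3.2 Å / 135°) with the residue-pair sum
  Π_XY = Σᵢ O_i,XY.
* **Correlation statistics** — Pearson r with SE_r = √((1−r²)/(N−2)) and
  the exact null probability P_N(|r| ≥ r₀) (adaptive quadrature of the
  null density, cross-checked against the t-transform tail on every
  call); |r| ≥ 0.05 significance rule; top-fraction selection.
* **Two-cluster model** — exact 1-D average-linkage partition of frames
  on an interdomain distance (sorted-run merging; no n×n matrix), with
  per-cluster contact and H-bond contrasts.
* **Synthetic data** — seeded generators for every input, with recorded
  ground truth: decay tables, correlated/discretized series, labelled
  bimodal mixtures, and a two-state two-domain toy ensemble that plants
  the separation/compactness anticorrelation by construction.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on
synthetic data and write their tables under `results/`. Running

```sh
Rscript analysis/01_simulate.R && Rscript analysis/05_correlations.R && Rscript analysis/06_clusters.R
```

prints (abridged):

```
planted: 5 fluctuating contact pairs, face residues 32, 34, 36, 38
pair   r        planted_r  significant
2-4    +0.985   +0.985     TRUE
5-7    +0.985   +0.985     TRUE
9-11   +0.985   +0.985     TRUE
12-14  +0.985   +0.985     TRUE
16-18  -0.985   -0.985     TRUE
null probability that |r| exceeds k x SE_r at n = 22,400:
    r0 p_pct
 0.007  29.5
 0.014   3.6
 0.021   0.2
 0.028   0.0
cluster means 32.7 / 50.1 A (design 32.7 / 50.1); sizes 998 / 1002
```

Reading: every designed contact pair correlates with interdomain
separation in its planted sense (four pairs close as the domains move
apart, one closes as they approach — the anticorrelation of interdomain
separation and intradomain compactness); a correlation of magnitude
0.028 would already arise by chance in 0.0% of uncorrelated
22,400-frame series; and average-linkage clustering of the interdomain
distance recovers the two design states at their design means. Step 03
additionally shows the PRE branch recovering the planted contact face
(residues 32/34/36/38) from the trimmed threshold, and step 02 recovers
a planted 0.80 mobility slope to ±0.02.

A one-call version of the same chain is available as
`run_pipeline(config)`, configurable from a YAML file.

## Layout

```
R/                  package code (all computation lives here)
analysis/01..06     numbered narrative drivers over the package
tests/testthat/     unit, property and acceptance tests
scripts/acceptance.R
vignettes/domain-coupling-methods.Rmd   the methods vignette
results/            small summary tables written by the analysis scripts
```
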