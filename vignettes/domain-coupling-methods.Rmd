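---
title: "Methods: quantifying coupled intra- and interdomain dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying coupled intra- and interdomain dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domcross)
```

## The scientific problem

Many signalling proteins are built from folded domains joined by flexible
linkers. Human Pin1 is the motivating case: a small WW domain (residues
1–39) that binds phosphorylated Ser/Thr–Pro motifs, a catalytic PPIase
domain (53–163), and a ~13-residue linker. Substrate binding at one end of
the WW domain changes both how far apart the two domains sit and how the
WW domain is folded internally — *domain cross-talk*. `domcross`
implements the quantitative machinery needed to detect and characterise
that coupling from two complementary data streams:

1. **NMR observables** — amide-proton paramagnetic relaxation enhancements
   (PREs) from a nitroxide spin label, and backbone ¹⁵N relaxation
   (R₂−R₁/2) as a per-residue rotational-mobility measure; and
2. **MD-trajectory statistics** — per-frame interdomain distances, domain
   radii of gyration, heavy-atom contact numbers, hydrogen-bond
   occupancies, and the correlation statistics that connect them.

Raw spectra and multi-microsecond trajectories are not redistributable at
package scale, so a first-class synthetic-data module generates every
input with recorded ground truth, and the test suite is largely a set of
parameter-recovery experiments against that truth.

## Relaxation-decay fitting

Peak intensities decay as $I(t) = I_0 e^{-Rt}$. `fit_monoexponential()`
seeds a Levenberg–Marquardt fit from a log-linear regression on the
positive intensities. The delay schedule carries duplicate points
(4 ms ×2, ..., 20 ms ×2); `estimate_noise()` turns the paired differences
at duplicated delays into a single-measurement noise,
$\sigma = \mathrm{RMS}(\Delta)/\sqrt{2}$, pooled over residues.
`monte_carlo_uncertainty()` then refits `n_draws = 500` noise-perturbed
copies of the fitted curve; the SD of the refit rates is the reported rate
uncertainty. The Monte Carlo default of 500 draws makes the SD estimate
itself good to ~3%, and the tests verify the result against the analytic
Cramér–Rao bound of the two-parameter model.

Rates that fail to converge or come out non-positive are carried as
`status = MISSING` rows, never dropped: downstream mergers must see the
full residue axis.

## Domain mobility and spectral densities

For a slowly tumbling protein, $R_2 - R_1/2 \propto J_{\mathrm{eff}}(0)
= 2\tau_c/5$, so plotting bound-state against apo-state values and
fitting a line per domain turns relative slope into relative rotational
mobility. `mobility_regression()` fits ordinary least squares per domain
(WW and PPIase by default; linker residues are reported but not fitted,
since a flexible tether has no single tumbling frame). Residues with
|studentized residual| > 2 are *flagged* but the line is not refit —
such outliers usually carry chemical-exchange contributions and are
interpreted against the global fit, not removed from it. An
intercept-free variant is available by flag.

`jeff0_tauc()` converts a rate to $J_{\mathrm{eff}}(0)$ and $\tau_c$
using one auditable constant bundle (`nmr_constants()`): ¹⁵N CSA
−170 ppm, N–H bond length 1.02 Å, CODATA gyromagnetic ratios, SI
prefactors, 700.13 MHz ¹H field. Because typeset unit conventions for
the CSA/dipolar prefactors vary across the literature, the package
treats the conversion as exact only up to its own forward model: the
tests enforce the algebraic round trip (rate → τ_c → rate, 1e-12
relative over 1–20 ns) and an order-of-magnitude check that a ~15 rad/s
rate maps to a ~10 ns tumbler at this field.

## PREs and the three-pass trimmed threshold

The transverse PRE of each amide proton is the PARA-minus-DIA rate
difference, with quadrature-combined uncertainty. Residues whose PARA
cross-peak broadens below detection while the DIA peak is visible are
`OVERFLOW`: a *qualitative* "very close to the label" datum that never
enters numerical statistics (it would dominate every mean) but is always
reported as significant.

Significance of the quantified values uses the three-pass trimmed
threshold: mean and sample SD of all values (M1, STD1), drop values
strictly outside M1 ± STD1; repeat (M2, STD2); then the core mean and SD
(M3, STD3) define the threshold M3 ± 2·STD3. Conventions pinned here,
with the rationale:

* sample SD (ddof = 1) in every pass;
* values exactly at a filter bound are **kept** (strict-outside
  exclusion), so a perfectly balanced two-level profile survives trimming;
* the final significance test is **strict** (`> upper`), since the rule is
  "more than 2 SD";
* a core that empties at any pass is an error naming the pass; a
  single-value core gets SD 0 with a warning.

One behavioural caveat is documented rather than hidden: because the
trimming shrinks the core SD, profiles whose non-contact background is a
single tight clump will always have a threshold close to that clump, and
~a quarter of pure-noise backgrounds will show one spurious exceedance
among ~30 residues. This is a property of the trimmed-2-SD rule itself.
The synthetic PRE fixture therefore gives the background a *designed*
two-level spread (below), which keeps the threshold above the whole
background; at very sparse compact populations (5%) the margin narrows
and the tests assert recovery of the planted set as a subset rather than
an exact equality.

Apo-versus-bound differences (ΔΓ₂) get their own trimmed threshold on the
difference profile (the bounds are generally asymmetric about zero), and
overflow transitions are tabulated qualitatively: a residue that is
overflow in the apo state but quantifiable after binding has "reappeared"
— direct evidence of contact loss.

## The Solomon–Bloembergen forward model

`sb_gamma2()` implements the point-dipole transverse enhancement
$$\Gamma_2 = K\,\frac{S(S+1)(g\mu_B\gamma_I)^2}{15}\,
\left\langle r^{-6}\right\rangle
\left(4\tau_c + \frac{3\tau_c}{1+\omega_H^2\tau_c^2}\right),$$
with $K = (\mu_0/4\pi)^2$ in the SI default (`prefactor = "plain"` drops
it for unit systems that absorb the factor). The effective correlation
time composes harmonically from tumbling and electron relaxation,
$1/\tau_c = 1/\tau_R + 1/\tau_{\mathrm{elec}}$. `ensemble_gamma2()`
substitutes the frame-weighted ensemble average $\langle r^{-6}\rangle$,
which is the quantity a mobile system actually reports; by convexity it
always exceeds the value at the mean distance, and the tests assert this
Jensen bound on random ensembles. τ_c for forward modelling is always an
explicit argument — the package never defaults it silently, because no
measured value exists for the effective electron-nuclear correlation
time of the system being emulated. The spin-label position is proxied by
a Cα site rather than an explicit nitroxide rotamer; rotamer libraries
are out of scope.

## Trajectory observables

All geometry runs on a frames × 3N coordinate matrix (Å) plus an atom
table carrying element, mass, residue and hydrogen-bond roles, read from
PDB/DCD via `bio3d` behind the package's own validation (atom-count
agreement, finite coordinates, element inference with a name-convention
fallback). Choices that the underlying data do not pin down:

* centers of mass and radii of gyration are **mass-weighted** by default
  (standard atomic masses), with a flag for geometric weighting;
* "heavy atom" means any non-hydrogen; the 4.5 Å contact cutoff and the
  3.2 Å / 135° hydrogen-bond cutoffs are **inclusive**;
* the D–H···A angle is measured at the hydrogen (180° = linear), and a
  bond's identity is the (donor hydrogen, acceptor atom) pair, so two
  distinct bonds between one residue pair accumulate into the pair sum
  $\Pi_{XY} = \sum_i O_{i,XY}$;
* fluctuating contact pairs are intradomain pairs with nonzero
  contact-number variance — any stricter variance floor would need a
  justification the data do not supply — with sequence-adjacent pairs
  retained and separation ≥ 3 flagged;
* frames are 0-based internally and 1-based in output tables.

## Correlation statistics

`pearson()` is the standard product-moment coefficient with degenerate
series rejected by name. Its sampling scale is
$\mathrm{SE}_r = \sqrt{(1-r^2)/(N-2)}$ — about 0.007 for $N = 22{,}400$
frames — and the null significance
$P_N(|r|\ge r_0)$ is evaluated two ways on every call: adaptive
quadrature of the null density $(1-r^2)^{(N-4)/2}$ (log-scale integrand,
normalised by the Γ-function prefactor) and the exact equivalent
two-sided t tail with $N-2$ degrees of freedom. The two must agree to
1e-6 or the call errors; the quadrature value is returned. At trajectory
scale the thresholds 1–4 × SE_r give null probabilities 29.5%, 3.6%,
0.2%, 0.0% — the package's standing analytic regression test. Note the
thresholds are the *rounded* SE multiples (0.007, 0.014, ...); using the
unrounded SE changes the first probability by two points, so the rounding
convention is part of the contract.

The significance cutoff for declaring a trajectory correlation
meaningful is $|r| \ge 0.05$ (inclusive), roughly 7 SE_r. Frames are
treated as independent samples; no autocorrelation or effective-sample-
size correction is applied (a stated non-goal), so P-values at trajectory
scale are optimistic in proportion to the frame-to-frame correlation
time of the observable.

`top_fraction()` keeps the largest-magnitude coefficients: the top
fraction/2 of the positive records and the top fraction/2 of the
negative ones, each side counting `ceiling(n_side * fraction/2)` of its
own records, ties broken by (|r| descending, labels) for determinism.
Selecting per side rather than per pooled magnitude preserves the sign
balance of the selection.

## The two-cluster model

`average_linkage_2cluster()` partitions frames on a scalar interdomain
distance. In one dimension, average-linkage clusters are contiguous
intervals of the sorted values and the average inter-cluster distance
between two disjoint intervals is simply the difference of their means,
so the exact dendrogram can be built by repeatedly merging the adjacent
run pair with the smallest mean difference — no n × n distance matrix.
The tests verify label-for-label agreement with naive matrix linkage on
hundreds of random instances. Ties merge lowest-frame-first; series
longer than 50,000 frames are stride-subsampled deterministically, with
the stride recorded. The lower-mean cluster is labelled `COMPACT`.
`cluster_contrast()` then recomputes per-cluster contact means and
hydrogen-bond occupancies over member frames and tabulates
extended-minus-compact differences.

## What the synthetic generators emulate

`gen_decay_tables()` reproduces the decay-series structure exactly
(monoexponential, I₀ = 100, Gaussian iid noise, duplicate delays).
Defaults are the study conditions: the 4–30 ms schedule with duplicates,
σ = 2 (2% of I₀).

`gen_two_state_ensemble()` is the core fixture: two rigid bead domains
(20-residue WW-like, 30-residue PPIase-like; N/H/Cα/O per residue plus
designed hinge beads), with a per-frame Bernoulli compact/extended state
that sets both the interdomain separation (means 32.7 / 50.1 Å — the
printed cluster means of the motivating study — with 1.5 Å Gaussian
jitter) and the WW-like hinge. Four designed contact pairs close when the
domains are *far apart*, one reversed pair closes when they are *close*,
and an N–H···O triad forms only in the extended state: the
anticorrelation between interdomain separation and intradomain geometry
is planted by construction, with integer per-state contact counts and a
closed-form planted correlation
$r = \pm\sqrt{pq\,\Delta\mu^2/(pq\,\Delta\mu^2+\sigma^2)}$ for the
binary mixture. Four "face" residues of the PPIase-like domain carry
their amides toward the spin-label site so the compact state produces
large PREs; the remaining amides sit in two equal-size distance clumps,
a deliberate background design that keeps the trimmed threshold above
the whole non-contact profile (see the PRE section). The reference
topology is written as a valid PDB and read back through the package's
own reader, so generated data exercise the real I/O path.

What the toy does **not** emulate: force-field energetics, side-chain
rotamers, solvent, autocorrelated frame-to-frame motion (states are iid
Bernoulli), or realistic PRE noise heteroscedasticity. Passing tests
demonstrate that the *statistical machinery* recovers planted structure;
they say nothing about force-field accuracy on real proteins.

`gen_correlated_series()` draws bivariate normals at a target r; the
discretized variant (contact-like small integers by quantile thresholds)
recomputes the post-discretization population correlation in closed form
— $\mathrm{corr}(x, \sum_k 1\{y>t_k\}) = \rho\sum_k\phi(t_k)/
\sqrt{\mathrm{Var}}$ — and stores it as the truth to recover.
`gen_bimodal_scalar()` provides the labelled Gaussian mixture for
clustering tests. Every generator is deterministic given (parameters,
seed) and restores the caller's RNG state.

## Numerical choices and degenerate inputs

* Rates are rad/s throughout; delays seconds internally (`delay_ms`
  accepted in files); coordinates Å.
* Readers reject malformed numerics, short delay schedules and
  atom-count mismatches rather than coercing; result tables round-trip
  through TSV at full precision (`%.17g`).
* `pearson` output is clipped to [−1, 1] against rounding; `pn` routes
  must agree to 1e-6; threshold passes error (with the pass index) if
  they empty.
* Problem sizes in the standing test suite were chosen so the whole
  suite exercises every property at convincing statistical power while
  staying quick to run routinely: 200-replicate recovery experiments,
  n = 22,400 for everything at trajectory scale, 2,000-frame ensembles,
  500 random threshold traces, 200 random linkage instances.

## Known limitations

* The τ_c conversion is internally consistent but pinned to one CSA /
  bond-length convention; absolute correlation times inherit that choice.
* No model-free analysis, anisotropic diffusion, or exchange-term
  fitting; no spin-label rotamer modelling; no autocorrelation correction
  of trajectory P-values; no k > 2 cluster-model selection.
* XTC trajectories are not read; convert to DCD or multi-model PDB.
* The trimmed-threshold false-positive behaviour discussed above is
  inherent to the rule and surfaces in any tight-background profile.
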