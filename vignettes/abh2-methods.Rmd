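---
title: "Models and methods: ABH2 binding, demethylation kinetics and active-site contacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ABH2kinetics)
```

## The scientific problem

Human ABH2 is a Fe(II)/α-ketoglutarate-dependent dioxygenase that directly
reverses cytotoxic alkyl lesions — chiefly N1-methyladenine (m1A) and
N3-methylcytosine (m3C) — by oxidative demethylation. Mutational analysis of
the active-site residues Tyr122, Ile168 and Asp173 asks a sharp quantitative
question: do these residues contribute to *binding* the damaged duplex, or
to *catalysis* once it is bound? Answering it requires two separable
measurements on each enzyme/lesion pair: an equilibrium dissociation
constant from a gel-shift titration, and an observed catalytic rate constant
from a demethylation time course, the latter normalized by how much
enzyme–substrate complex actually exists at the assay concentrations. This
package implements both estimators, the geometric analysis of the
lesion-binding pocket, and synthetic forward models of all the raw assays so
that each estimator can be validated by parameter recovery.

## Equilibrium binding

The titration measures the bound fraction of a 1.2 µM labeled 17-nt duplex
at enzyme concentrations 0–12.8 µM (nine points, triplicate). Band
intensities are quantified as `F = I_b / (I_b + I_u)` after background
subtraction (`boundFraction()`), and fitted to the Hill isotherm

$$F(E_0) = F_u + \frac{F_b - F_u}{1 + (K_d/E_0)^h}.$$

Assumptions worth keeping visible:

* $E_0$ is *total* enzyme, treated as free enzyme. This is the conventional
  EMSA analysis and is exact only when enzyme is in large excess over DNA;
  at the lowest titration points (0.4 µM enzyme against 1.2 µM DNA) it is an
  approximation. The package also ships the quadratic-depletion isotherm
  (`depletionModel()`) as a clearly separate alternative; the reported
  constants use the Hill form, which is the convention this analysis
  follows.
* $F_u$ and $F_b$ are the initial and final response levels, $h$ the
  empirical cooperativity exponent and $K_d$ the effective dissociation
  constant; with $h = 1$ the form reduces exactly to the hyperbolic
  isotherm (an identity the tests verify on a grid).
* Zero-enzyme lanes enter through the limit $F(0) = F_u$ rather than
  evaluating $(K_d/0)^h$.

Fitting is bounded Levenberg–Marquardt least squares over all replicate
points (`minpack.lm::nlsLM`, which unlike `stats::nls` also handles
zero-residual synthetic data). Initialization is data-driven: $K_d$ starts
at the concentration whose mean response is nearest half-maximal, $h$ at 1,
$F_u/F_b$ at the observed extremes; bounds are $K_d \in (0, 10\,\max E_0]$,
$h \in (0, 6]$, $0 \le F_u, F_b \le 1$. Inside the optimizer the two level
parameters are ordered by min/max rather than constrained jointly, so
derivative perturbations at the box bounds cannot abort the fit.
Non-convergence is reported as a flag on the result, not an exception.

Uncertainties: asymptotic SDs from the fit covariance are reported when the
residual is non-zero; `bootstrapHill()` provides case-resampling bootstrap
SDs (default 1000 refits, resampling replicates within each concentration),
since the published ± values do not state their method.

## Demethylation kinetics

Repair is read out by a methylation-sensitive restriction endonuclease that
recognizes the GATC site straddling the lesion: only demethylated product is
cleaved, releasing a short 5′-labeled fragment. The package models the
digestion as complete, with the cut placed after the first base of the GATC
site on the labeled strand (AGTTCAATG | ATCTTCAT), so the product band is
9 nt against the 17-nt substrate; only the fragment *lengths* matter to the
downstream quantification, so the exact cut-offset convention is
inconsequential, but it is stated here because restriction enzymes of this
family are often drawn cutting 5′ of the recognition tetramer.

The observed rate constant is defined as initial velocity over the
equilibrium concentration of the precatalytic complex:

$$k_{obs} = \frac{V_0}{[E{\cdot}S]}, \qquad
[E{\cdot}S] = \frac{(E_0+S_0+K_d) - \sqrt{(E_0+S_0+K_d)^2 - 4E_0S_0}}{2}.$$

Two numerical points:

* Of the two quadratic roots, only the minus root respects mass conservation
  ($[E{\cdot}S] \le \min(E_0, S_0)$); the plus root is unphysical. The
  implementation uses the cancellation-free form
  $2E_0S_0/(s + \sqrt{s^2-4E_0S_0})$, $s = E_0+S_0+K_d$, accurate also for
  $K_d \gg E_0, S_0$, and is tested against a brute-force root of
  $K_d = (E_0-x)(S_0-x)/x$ to $10^{-9}$ µM on 1000 random conditions.
* Since $[E{\cdot}S]$ decreases with $K_d$, $k_{obs}$ *increases* with $K_d$
  at fixed $V_0$: weaker binding means the same flux is carried by less
  complex, implying faster chemistry.

**Initial velocity.** "Initial slope of the kinetic curve" needs an
operational definition. The default fits the saturating progress model
$P(t) = A(1-e^{-\lambda t})$ and reports its exact $t=0$ slope in
concentration units, $V_0 = A\lambda S_0$. This is robust for fast
conditions where the earliest sampled point (30 s) is already well past
half-conversion — the estimator then flags `late_start` rather than
failing, because the study's own fastest condition (wild type on m1A,
$k_{obs} = 0.071$ s⁻¹) is in exactly that regime on the standard grid. A
linear fallback (`method = "linear"`) fits a line through the origin to the
early points with $P \le 0.15 \max P$. The method used is recorded in the
result. $A$ and $\lambda$ are individually poorly determined for slow
conditions far from plateau, but their product — the initial slope — is the
well-conditioned combination, which is why $V_0$ recovery stays accurate
across the full rate range.

**Uncertainty.** `propagateKobsSd()` propagates independent Gaussian errors
in $V_0$ and $K_d$ through the quotient by Monte Carlo (negative draws
rejected, seed-deterministic), since the published error bars do not state a
propagation method.

**Fold changes.** `foldChange()` reproduces the field's reporting style:
dissociation-constant ratios to one decimal, rate-constant ratios to the
nearest integer; the raw ratio is always attached as an attribute.

## The synthetic-data generator

The generator is the package's definition of the study conditions, and its
defaults are fixed accordingly: titration grid
{0, 0.4, 0.8, 1.2, 1.6, 3.2, 6.4, 9.6, 12.8} µM enzyme, 1.2 µM duplex,
triplicate; time grid {30, 60, 120, 300, 600, 900, 1800, 2700, 3600} s
covering 30 s to 1 h; $E_0 = S_0 = 1.0$ µM for kinetics; reference
(variant, lesion) parameters in `abh2RefParams()`.

* **Progress-curve form.** Reported demethylation time courses are data
  points without a stated functional form. The single-exponential saturation with
  $\lambda = V_0/(AS_0)$ is adopted because it has the correct initial slope
  by construction and a sub-unity plateau consistent with the reported
  incomplete conversion (enzyme/substrate/cofactor degradation over the long
  reaction). It is a phenomenological stand-in, not a mechanistic claim.
* **Plateaus.** Reported 30-min endpoint levels pin the wild-type (0.540 on
  m1A, 0.754 on m3C) and I168A (0.521, 0.50) plateaus. The Y122A and D173A
  endpoints are described only as "significantly lower"; the defaults use
  0.30 (m1A) and 0.25 (m3C). The choice is inert for rate recovery because
  $V_0 = A\lambda S_0$ is plateau-invariant.
* **Noise.** Additive Gaussian on the fraction scale, clipped to [0, 1] —
  the simplest model consistent with triplicate-SD error bars; the gel
  observation model (`simulateGel()`) adds multiplicative band scaling and
  additive background with per-band Gaussian noise and round-trips through
  `boundFraction()` exactly at zero noise.
* **Determinism.** Every generator takes a seed, runs in a private RNG
  state, and restores the caller's `.Random.seed`.

What the generator does *not* emulate — and hence what recovery tests do not
show about real data: gel-physics artifacts (smearing, lane-to-lane transfer
bias), correlated densitometry errors within a lane, partial restriction
digestion, cofactor-depletion kinetics beyond the phenomenological plateau,
and any deviation of real binding from the Hill form. Recovery results
validate the estimators, not the assay.

## Active-site contact classification

`contactTable()` classifies the eleven pocket residues (Val99, Val101,
Phe102, Arg110, Tyr122, Phe124, Ser125, Ile168, His171, Asp173, Glu175)
against the flipped-out base with the precedence hydrogen bond > stacking >
coordination (where a numeric distance is requested, e.g. Arg110) >
pocket wall > none; every record carries the minimum heavy-atom distance.

Default thresholds are standard structural-biology heuristics, stated
explicitly because no universal cutoffs exist for these categories: hydrogen bond
≤ 3.5 Å donor–acceptor (N/O/S vs N/O) with D–H⋯A ≥ 120° when hydrogens are
present (distance-only otherwise, as in typical crystal structures);
stacking ≤ 4.5 Å ring-centroid separation and ≤ 30° between least-squares
ring planes (angle folded to 0–90°); pocket wall ≤ 4.5 Å closest approach;
metal coordination ≤ 2.6 Å. The "coordination distance" is interpreted as
the minimum side-chain heavy-atom to base heavy-atom distance; the atom
scope is configurable (`scope = "all_heavy"`) because the original
convention is unstated, so published distances are verification targets
under a documented convention rather than guaranteed matches.
Intercalation (Val101/Phe102) is reported descriptively when the residue
approaches all lesion-flanking nucleotides within the wall cutoff — a
simplification of the qualitative statement that these residues occupy the
gap left by base eversion. Modified nucleotides are recognized via a
configurable het-code map (deposited codes for methylated/etheno bases vary
between entries); nothing is hard-coded.

`makeToyStructure()` writes idealized PDB fixtures (canonical H-bond pair,
parallel rings, probe at exact distance, metal triad) whose geometry
realizes the requested parameters exactly, so the classifier is tested
against constructed ground truth and against an independent all-pairs
distance oracle, including invariance under random rigid-body motions.

## Validation design and problem sizes

The test suite validates by parameter recovery at the study's own design
sizes: 27-point titrations and 9-point time courses. Noise-free round trips
pin $K_d$ within 1% and $k_{obs}$ within 2% for all eight reference
conditions; the endpoint chain reproduces the 54.0% / 75.4% 30-min
conversions through the full gel-quantification path. Stochastic behaviour
is characterized at noise SD 0.02 over 100 seeds: the estimators are nearly
unbiased (the signed median relative deviation of both $K_d$ and $k_{obs}$
is well under 5%), while the median *absolute* errors (≈4% for $K_d$, ≈7%
for $k_{obs}$) reflect the irreducible propagation of titration noise
through $K_d$ into $[E{\cdot}S]$. The activity ranking check requires
WT > I168A > each of {Y122A, D173A}; the relative order of the two slowest
mutants is deliberately not enforced, because their rate constants differ
within experimental error and no estimator can stably order them from data
at this noise level.

## Known limitations

* The Hill fit ignores DNA depletion (by convention); fitted $K_d$ values
  are *effective* constants tied to the 1.2 µM duplex design.
* Fitted Hill coefficients have no published counterpart to compare
  against; they are reported but unvalidated externally.
* The plateau mechanism is phenomenological; no cofactor-decay or
  product-inhibition model is attempted.
* The contact classifier assigns geometry, not energetics; protonation
  states, water-mediated bonds and MD-derived contact persistence are out of
  scope.
* Published text gives the m3C affinity range as 2.5–4.2 µM while the
  parameter table prints 2.49–4.1; the table values are used throughout and
  the discrepancy is noted here rather than resolved.
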