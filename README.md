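# ABH2kinetics

Quantitative analysis of alkylated-DNA repair by the human
Fe(II)/α-ketoglutarate-dependent dioxygenase ABH2 and its active-site mutants
(Y122A, I168A, D173A) acting on duplexes carrying N1-methyladenine (m1A) or
N3-methylcytosine (m3C). The package is aimed at enzymologists analysing
gel-based binding and activity assays: it turns densitometry readouts into
equilibrium dissociation constants and observed catalytic rate constants, and
maps the active-site contacts that rationalize them.

Three analysis stages, each with a synthetic forward model so every estimator
is testable by parameter recovery:

1. **Equilibrium binding (EMSA).** Bound fractions
   `F = I_bound / (I_bound + I_unbound)` from a titration of enzyme against
   1.2 µM labeled 17-nt duplex are fitted to the Hill isotherm

   ```
   F(E0) = Fu + (Fb − Fu) / (1 + (Kd / E0)^h)
   ```

   giving the effective dissociation constant `Kd`, the Hill coefficient `h`
   and the baseline/saturation levels, with asymptotic or case-resampling
   bootstrap uncertainties (`fitHill`, `bootstrapHill`).

2. **Demethylation kinetics.** A methylation-sensitive GATC restriction
   reporter converts repair into a 9-nt labeled fragment. From the product
   time course at `E0 = S0 = 1.0 µM`, the initial velocity `V0` is estimated
   as the exact `t = 0` slope of a saturating progress-curve fit, and the
   observed rate constant is

   ```
   kobs = V0 / [E·S],
   [E·S] = ((E0+S0+Kd) − sqrt((E0+S0+Kd)² − 4·E0·S0)) / 2
   ```

   — the exact ligand-depletion (quadratic) equilibrium concentration of the
   precatalytic complex, not the free-enzyme approximation
   (`initialVelocity`, `esEquilibrium`, `kObs`, `kineticSummary`).

3. **Active-site contacts.** A geometric classifier assigns
   hydrogen-bond / π-stacking / pocket-wall / coordination / intercalation
   categories to the eleven residues lining the damaged-base pocket against
   the flipped-out base in a PDB structure, plus a check of the
   His171/Asp173/His236 metal triad (`readStructure`, `contactTable`,
   `checkMetalSite`).

## Worked example

```r
library(ABH2kinetics)

## EMSA titration with 2% densitometry noise, generated from Kd = 2.45 uM
s   <- makeTitration(HillParams(Kd = 2.45), TitrationDesign(noiseSd = 0.02, seed = 42))
fit <- fitHill(s)
fit
#> Hill-equation fit (27 points, converged)
#>   Kd = 2.362 +/- 0.25 uM
#>   h  = 1.049 +/- 0.081
#>   Fu = 0.01422 +/- 0.014  Fb = 0.9795 +/- 0.042
#>   RSS = 0.0135

## demethylation time course at E0 = S0 = 1 uM, WT/m1A parameters
tc  <- makeTimeCourse(KineticTruth(0.071, 2.45, plateau = 0.54), noiseSd = 0.02, seed = 42)
kineticSummary(tc, AssayConditions(Kd = kd(fit)), KdSd = 0.07)
#> KineticResult (exponential): V0 = 0.01733 +/- 0.0013 uM/s; [E.S] = 0.2428 uM
#>   kobs = 0.07137 +/- 0.0055 1/s; 30-min endpoint = 57.0%
#>   flags: late_start
```

The fitted `Kd` (2.36 ± 0.25 µM) and `kobs` (0.0714 ± 0.0055 s⁻¹) recover the
generating truths (2.45 µM, 0.071 s⁻¹) within the noise; `[E·S]` = 0.24 µM
shows that at equimolar micromolar concentrations only ~24% of the enzyme is
in the precatalytic complex, which is exactly why the quadratic correction is
needed. The `late_start` flag records that the earliest sampled point is
already past half-conversion for this fast reaction.

The full simulate → fit → compare pipeline over all eight (variant, lesion)
reference conditions:

```r
runRecovery(noiseSd = 0)@folds
#>   lesion Kd_fold Kd_fold_raw kobs_WT_over_I168A kobs_fold_raw
#> 1    m1A     1.3    1.285714                  4         3.550
#> 2    m3C     1.6    1.646586                  6         5.625
```

i.e. the mutations barely move binding (1.3- and 1.6-fold spread in `Kd`) but
cut catalysis 4- and 6-fold — the separation of binding from catalysis that
the mutational analysis establishes.

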