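# fnirsdfc

Static and dynamic functional-connectivity analysis of task fNIRS
recordings, with a random-forest group classifier and a seeded synthetic
cohort generator.

## The problem

Functional near-infrared spectroscopy (fNIRS) measures cortical hemoglobin
changes through scalp source–detector channels while a participant performs
a cognitive task — here a 150-s verbal-fluency-style block (30 s pre-task /
60 s task / 60 s post-task) recorded at 10 Hz on a 52-channel frontotemporal
montage. Clinical studies of adolescent depression ask two questions of such
data: do patients and controls differ in the coupling between cortical
regions, and do those coupling features track symptom severity? A single
whole-period correlation per region pair ("static FC") compresses a dynamic
task into one number; this package additionally extracts *dynamic* FC —
correlations recomputed in 20-s sliding windows — and summarises each
participant's window-wise connectivity with principal components.

The analysis chain, in order:

1. **Quality control** — per-channel baseline SNR, `20·log10(μ/σ)` dB,
   retention at ≥ 40 dB in both wavelengths, cohort-wide exclusion.
2. **Preprocessing** — optical density → modified Beer–Lambert conversion
   to ΔHbO/ΔHbR, 0.01–0.2 Hz zero-phase Butterworth band-pass, Daubechies-5
   wavelet motion correction (tail-probability threshold 0.1), hemodynamic
   modality separation (functional ΔHbR = −0.6·ΔHbO), and aggregation to 6
   ROIs: DLPFC(R/L), mPFC(R/L), TL(R/L).
3. **Connectivity** — Fisher-z Pearson correlations: one 6×6 static matrix
   (15 pairs) over the full 150 s, and the K×M window-wise matrix **X**
   (K = 15 pairs, M = 131 windows of 20 s sliding by 1 s).
4. **PC features** — per-participant PCA of **X** over the window
   dimension; the component count N is the smallest whose cohort-mean
   cumulative contribution rate `CCR(N) = Σ₁ᴺκₙ / Σ₁ᴹκₙ · 100%` reaches
   90 %; scores **D** = X·U₁..ₙ (centered), shifted cohort-wide so the
   minimum is 0. Features: 15 static + 15·N dynamic per participant.
5. **Statistics** — KS-screened t/Wilcoxon group tests with
   Benjamini–Hochberg correction per feature family; Spearman
   feature–symptom correlations (depression/anxiety/anhedonia scores with a
   clinical-threshold inclusion screen); per-outcome regressions adjusted
   for age, sex, illness duration and antidepressant exposure in
   fluoxetine equivalents.
6. **Classification** — random forest (Gini) over a 10-fold stratified
   train/validation/test rotation with a grid search (trees 10–150, leaf
   1–11, bootstrap fraction 0.5–1.0; 990 configurations, reduced 3×3×2
   grid available), pooled test accuracy/F1/AUC with percentile-bootstrap
   CIs, and out-of-bag permutation importance.

Because cohorts of this kind are not publicly deposited, the package
includes a generator (`simulate_cohort()`) producing raw dual-wavelength
recordings plus clinical tables with *planted* group differences and
symptom links, so the whole chain is testable end to end. See the methods
vignette (`vignettes/fnirsdfc-methods.Rmd`) for the models, defaults and
limitations.

## Worked example

```r
library(fnirsdfc)

cohort <- simulate_cohort(simulation_config(n_per_group = c(MDD = 40L, HC = 40L),
                                            seed = 1))
res <- run_pipeline(cohort, grid = NULL,
                    config = data.frame(n_trees = 100L, min_leaf = 1L,
                                        bootstrap_fraction = 0.8))
print(res)
```

```
fNIRS connectivity pipeline result
Cohort feature table: 80 participants x 120 features (15 static + 15 x 7 dynamic)
  shift constant -6.9293, mean CCR(N) 91.6%
  2 feature(s) differ between groups at q < 0.05
Random-forest CV (trees = 100, min leaf = 1, bootstrap fraction = 0.8)
  pooled test accuracy 63.75% [52.50, 73.75]
  F1 0.623 [0.479, 0.737]; AUC 0.697 [0.563, 0.806]
  per-fold mean accuracy 63.75%; majority baseline 50.00%
```

The feature table kept 46 of 52 channels (six low-SNR channels excluded),
selected N = 7 components at a mean CCR of 91.6 %, and shifted the dynamic
scores by the cohort minimum (−6.93). Two window-wise PC features differ
between groups after FDR correction at this cohort size, and the classifier
separates the groups well above the 50 % majority baseline.

The symptom analyses recover the planted clinical links:

```r
subset(res$correlations, q < 0.05)
#>                  feature  score      r        p        q
#>  static|DLPFC(R)~mPFC(R) dass_d -0.629 1.37e-05 0.002465
#>  static|DLPFC(R)~mPFC(R) dass_a -0.677 1.60e-06 0.000575

res$regressions$dass_d
#> Regression of dass_d (n = 40): adj R^2 = 0.329, model p = 0.0019
#>                           Estimate Std. Error t value Pr(>|t|)
#> `static|DLPFC(R)~mPFC(R)`  -0.5570     0.1368 -4.0727   0.0003
#> ...
```

The depression score correlates negatively with right DLPFC–mPFC coupling
(Spearman r = −0.63; the generator planted −0.48) and remains a significant
standardized predictor (β = −0.56) after adjusting for age, sex, illness
duration and fluoxetine-equivalent dose.

A command-line front end wraps the same functions:

```sh
exec/fnirsdfc simulate --n-per-group 40 --seed 1 --out cohort_dir
exec/fnirsdfc run-all  --seed 1 --out results_dir
```

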