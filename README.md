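# tetherspan

Can a chromatin reader with two acetyl-lysine-binding bromodomains on one
flexible tether reach across a nucleosome and bridge two of them? BET
proteins (BRD2/3/4, BRDT) carry exactly that architecture — two folded
bromodomains (BD1, BD2) joined by a ~180-residue disordered linker — and
whether they can *span* the ~57 Å length of a nucleosome decides whether
they can scaffold acetylated chromatin internucleosomally. tetherspan
implements the full computational chain behind that question as a tested,
reusable R package:

- **SAXS analysis** — Guinier fits (`guinier_fit`), regularized
  pair-distance distributions P(r) with Dmax estimation (`compute_pr`),
  dimensionless Kratky curves (`dimensionless_kratky`), and Debye-equation
  forward models of bead ensembles (`debye_profile`,
  `ensemble_average_profile`).
- **Linker ensemble modeling** — a Cα-level dumbbell template of the BRD4
  tandem bromodomains (125 + 179 + 112 beads at 3.8 Å bonds;
  `build_dumbbell_template`), excluded-volume conformer sampling with a
  calibrated wormlike linker (`sample_conformers`), and filtering by the
  experimental size window Rg = 55.4 ± 5.5 Å, Dmax < 201 Å
  (`filter_by_constraints`).
- **Span statistics** — inter-binding-site distance distributions with KDE
  (`distance_distribution`) and the nucleosome-span fraction
  P(d > 57 Å) (`span_fraction`, `span_pipeline`).
- **Scaffolding equilibria** — mass-balance models that generate the
  bell-shaped "hook effect" titrations of bivalent-engagement (BRET) and
  bead-scaffolding (AlphaScreen) assays (`solve_bivalent_titration`,
  `solve_ternary_scaffold`), plus the assays' signal arithmetic
  (`corrected_bret_ratio`, `normalize_alpha`) and empirical hook-curve
  description (`fit_hook_curve`).
- **Compartmental-domain enrichment** — BED/bedGraph I/O, per-bp domain
  means, deepTools-style scale-regions matrices, k-means ACTIVE/INACTIVE
  classification, Welch enrichment tests and Spearman correlations at
  regulatory features (`scale_regions_matrix`, `kmeans_classify`,
  `enrichment_test`, `regulatory_correlation`).
- **Synthetic data** — generators for SAXS profiles, annotated genomes and
  titration plates with machine-readable ground-truth sidecars
  (`gen_saxs`, `gen_genome`, `gen_titration`), so every stage is testable
  offline.

The core statistic: sample conformers of the two-domain/flexible-linker
chain, keep those consistent with the measured SAXS size
(Rg ∈ [49.9, 60.9] Å, Dmax < 201 Å), measure the distance *d* between the
two acetyl-lysine binding sites (residues 140 and 433), and report

&nbsp;&nbsp;&nbsp;&nbsp;fraction_above = #{d > 57 Å} / n,&nbsp;&nbsp; plus min(d), median(d), max(d).

Fitted objects come with `tidy()`/`glance()` methods and `autoplot()`
visualisations; all user-facing functions take and return tibbles where the
data are tabular.

## Worked example

```r
library(tetherspan)

## --- SAXS: analyze a profile (here: a 30 Å uniform sphere) -------------
q <- seq(0.008, 0.35, by = 0.002)
x <- q * 30
profile <- saxs_profile(q, (3 * (sin(x) - x * cos(x)) / x^3)^2,
                        label = "sphere R = 30 A")
guinier_fit(profile)
#> <guinier_fit> Rg = 23.68 A, I(0) = 1.003, qRg in [0.189, 1.278], n = 24, R^2 = 0.9999
compute_pr(profile, dmax_trial = 90)
#> <pair_distribution> Dmax = 59.0 A, Rg(real) = 23.24 A, 201 r-points
```

The Guinier and real-space radii recover the closed form
√(3/5)·30 = 23.24 Å and the diameter 60 Å of the sphere.

```r
## --- Ensemble: can the tandem bromodomains span a nucleosome? ----------
run <- span_pipeline(n_models = 5000, seed = 1)
run$summary
#> # A tibble: 1 × 8
#>   min_d median_d max_d span_threshold fraction_above     n n_sampled n_retained
#>   <dbl>    <dbl> <dbl>          <dbl>          <dbl> <int>     <int>      <int>
#> 1  41.4     121.  174.             57          0.991  1364      5000       1364
autoplot(run$dist)   # KDE of the inter-site distances with the 57 Å line
```

Of 5000 excluded-volume conformers, 1364 pass the experimental size filter;
their binding-site separations range from ~41 to ~174 Å (median ~121 Å) and
99% exceed the 57 Å nucleosome span — the geometric prerequisite for
internucleosomal scaffolding.

```r
## --- Equilibrium: the hook effect of bivalent engagement ---------------
m <- bivalent_model(kd_a = 17, kd_b = 100, c_eff = 100, p_total = 0.1)
tit <- solve_bivalent_titration(m, 10^seq(-3, 3, length.out = 40))
fit_hook_curve(tit$conc, tit$signal)
#> # A tibble: 1 × 4
#>   ec50_rise peak_conc  hill at_boundary
#>       <dbl>     <dbl> <dbl> <lgl>
#> 1      5.43      41.2  1.12 FALSE
autoplot(tit)

kd_fold_change(76, 17)   #> 4.5
kd_fold_change(76, 24)   #> 3.2
```

The bivalent signal rises with an apparent EC50 of ~5.4 µM, peaks near
41 µM, and collapses at higher ligand — the hook shape that distinguishes
bridging from simple binding. The Kd ratios reproduce the 3.2–4.5-fold
avidity gain of tri- over di-acetylated histone tails.

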