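---
title: "Methods: tether-span analysis and nucleosome scaffolding models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tether-span analysis and nucleosome scaffolding models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

tetherspan asks a geometric question about chromatin readers: can the two
acetyl-lysine-binding bromodomains of a BET protein, joined by a long
disordered linker, reach across one nucleosome (about 57 Å) and therefore
bridge two? The package implements the complete computational chain behind
that question — SAXS profile analysis, coarse-grained ensemble modeling of
the tandem-bromodomain construct, inter-binding-site distance statistics,
equilibrium models of the proximity ("hook effect") assays used to test
scaffolding in vitro, and the ChIP-Seq compartmental-domain enrichment
procedure used to test its genomic correlates — together with synthetic-data
generators so that every stage can be exercised and tested without any
external download.

This vignette records the models, the tunable parameters, the numerical
choices, and the design decisions taken where the procedure was genuinely
open. It states no empirical number that the package's tests or acceptance
script do not themselves compute.

## 1. SAXS profile analysis

A `saxs_profile` is a tibble of momentum transfer $q$ (Å$^{-1}$, strictly
increasing), intensity (arbitrary units) and optional uncertainty. The
`.dat` reader tolerates comment lines, drops rows with $q \le 0$ or
non-finite intensity, and refuses profiles with fewer than 10 usable points
or non-monotone $q$.

**Guinier fit.** `guinier_fit()` fits $\ln I = \ln I_0 - q^2 R_g^2/3$ by
weighted linear regression over the widest low-$q$ window satisfying
$q R_g \le 1.3$ (the conventional validity cap for globular particles;
configurable). Because the window depends on the answer, the fit is
iterated — window recomputed from the current $R_g$ until the estimate
moves by less than 0.1%. For a uniform sphere the approximation itself is
biased upward by roughly 2% at a 1.3 cap; the tests assert recovery at that
tolerance, and a tighter cap can be passed where sub-percent accuracy
matters.

**Pair-distance distribution.** `compute_pr()` performs a regularized
indirect Fourier transform: $P(r)$ on a uniform grid over
$[0, D_\mathrm{max}^\mathrm{trial}]$, minimizing
$\lVert (I - A p)/\sigma \rVert^2 + \alpha\,\lVert D_2 p \rVert^2$ with the
Debye kernel $A_{ik} = \mathrm{sinc}(q_i r_k)\,\Delta r$, second-difference
penalty $D_2$, and $P(0) = P(D_\mathrm{max}^\mathrm{trial}) = 0$.
Non-negativity is enforced by iterated constrained least squares (negative
components clamped to zero and removed from the free set until none
remain). Numerical choices that matter:

- the penalty is rescaled by $\sum A_w^2 / \sum D_2^2$ so that the
  dimensionless default $\alpha = 0.05$ transfers across profiles;
- weights are relative ($\sigma = 0.01\,|I|$ when no uncertainty column is
  present) with a floor of $10^{-4}\max|I|$, so the near-zero high-$q$ tail
  of noise-free synthetic profiles cannot dominate the fit;
- a constant `background` can be subtracted before inversion; for profiles
  of discrete point scatterers this is the flat self-scattering term
  (the bead count, for unit form factors), which is not representable by a
  $P(r)$ vanishing at the origin;
- $D_\mathrm{max}$ is reported as the smallest grid point beyond which
  $P(r)$ stays below 1% of its maximum — a reproducible proxy for the
  manual truncation practised with interactive IFT tools;
- real-space $R_g$ comes from the second moment,
  $R_g^2 = \int r^2 P\,\mathrm{d}r / 2$ for unit-area $P$;
- a warning is issued when $D_\mathrm{max}^\mathrm{trial} > \pi/q_\min$,
  i.e. when the requested support exceeds what the lowest measured angle
  can constrain.

The real-space $R_g$ is robust (the tests recover closed forms and
ensemble ground truths to 1–5%). The $D_\mathrm{max}$ tail is the softest
quantity of the method: multiplicative noise lets the reconstruction park
small amounts of mass beyond the true support, extending the 1% criterion.
The synthetic-data tests therefore exercise $D_\mathrm{max}$ recovery at
the 0.2% relative-noise level typical of merged synchrotron profiles, where
recovery is within a few percent; noisier profiles deserve a trial-support
sweep and a sceptical eye on the reported tail.

**Kratky representation.** `dimensionless_kratky()` returns
$(qR_g, (qR_g)^2 I/I_0)$. A globular particle peaks at $x = \sqrt 3$ with
$y = 3/e$; a monotonic rise at large $x$ is the standard flexibility
signature, which the tests reproduce from sampled dumbbell ensembles.

**Forward model.** `debye_profile()` evaluates the Debye sum
$I(q) = \sum_{ij} f_i f_j \mathrm{sinc}(q r_{ij})$ with constant
dummy-residue form factors; only relative shape metrics are consumed
downstream, so no $q$-dependent form factor or hydration layer is modelled.
`ensemble_average_profile()` is the unweighted mean over conformers — the
forward model for a flexible molecule with equally populated states.

## 2. The dumbbell template and conformer sampling

`build_dumbbell_template()` assembles a Cα-level bead model: a rigid
125-bead N-terminal reader domain (residues 44–168 in BRD4 numbering), an
extended linker (default 179 beads, residues 169–347), and a rigid 112-bead
C-terminal domain (residues 348–459), all at 3.8 Å virtual bonds. The
published linker range "169 to 348" overlaps the second domain's first
residue; the package uses 169–347 to avoid duplicating residue 348 and
exposes the count as a parameter. Domains come either from crystal-structure
Cα coordinates (e.g. 4KV1/4KV4 chain A, with binding-site residues 140 and
433) or from an embedded surrogate: a compact self-avoiding chain grown
deterministically under a fixed internal seed, with radius of gyration
≈ 13 Å — the size of a folded bromodomain — and the binding-site bead placed
on the surface at maximal distance from the linker attachment point,
emulating the pocket-opposite-termini geometry of the real fold. At this
resolution the ≤ 4 Å offset between a Cα position and the Asn side-chain
amide the experiments reference is far below the width of the distance
distributions and is left uncorrected.

`sample_conformers()` regrows the linker independently per model, bead by
bead, and re-attaches the second domain as a rigid body in a uniformly
random orientation. Modes:

- **FJC** — independent random unit-vector bonds; the tests verify the
  freely-jointed closed form $\langle R^2 \rangle = N b^2$ to within three
  standard errors at 2000 models.
- **EXCLUDED_VOLUME** — the same proposal with rejection of any placement
  bringing a non-bonded bead pair closer than `clash_cutoff` (default
  4.0 Å, two Cα excluded-volume radii). Rejected beads are redrawn up to
  `max_retries` times; a stalled model restarts. Whole-chain
  accept/reject is not viable here: at Cα geometry a freely-jointed
  proposal clashes at next-nearest neighbours with probability ≈ 0.28 per
  step, so the chain-level acceptance for a 179-bond linker is ≈ $e^{-57}$.
  Bead-wise regrowth is the standard practical sampler for tethered
  self-avoiding chains; it carries a mild Rosenbluth-type bias toward
  compact states relative to the uniform self-avoiding ensemble, which is
  acceptable because the ensemble is subsequently conditioned on the
  experimental size window.

**Linker stiffness.** A pure freely-jointed chain at Cα scale is too
compact for this construct: its simulated ensemble (median $R_g$ ≈ 42 Å)
sits well below the measured ensemble average of 55.4 Å, so the
experimental $R_g$ window would select only the fully extended tail of the
distribution. The proposal therefore supports directional correlation:
each bond direction is $\mathrm{normalize}(\kappa\,\hat u_{k-1} + \hat g)$
with $\hat g$ a random unit vector, $\kappa = 0$ recovering the exact FJC.
The default pipeline uses `brd4_linker_stiffness()` = 0.97, calibrated once
so that the unfiltered simulated ensemble reproduces the measured mean
$R_g$ of 55.4 Å; at that value the upper range of per-model maximum
dimensions is also consistent with the measured 201 Å. An optional
`hinge_prob` introduces occasional isotropic bonds (flexible joints); along
the calibrated mean-$R_g$ contour it changes none of the downstream
statistics appreciably, so the minimal one-parameter model is the default.

Per-model $R_g$ (root-mean-square distance from the centroid),
$D_\mathrm{max}$ (exact maximum pairwise distance) and a clash score (count
of non-bonded pairs below a cutoff; identically zero in excluded-volume
mode) are computed in compiled code. The clash score is an explicitly
labelled steric surrogate: no attempt is made to reproduce an all-atom
energy, and no energy-weighted subsetting enters any reported statistic.

`filter_by_constraints()` applies the experimental window — by default
$49.9 \le R_g \le 60.9$ Å (55.4 ± 5.5) and $D_\mathrm{max} < 201$ Å — and
reports the retained fraction.

## 3. Span statistics

`distance_distribution()` measures the site-to-site distance per conformer
and a Gaussian KDE with Scott's-rule bandwidth (with a small fallback
bandwidth for degenerate, zero-variance samples). `span_fraction()` reports
the fraction of distances *strictly greater* than the threshold (default
57 Å, the nucleosome span), plus raw-sample extrema and median — extrema
always from the raw distances, never the KDE.

`span_pipeline()` chains template → sampling (5000 excluded-volume models
by default, calibrated stiffness) → experimental filter → distance
distribution. On this sampler the constraint-passing ensemble spans a broad
distance range whose extremes bracket the experimentally derived 15–157 Å,
but nearly all retained conformers (≈ 99%) exceed the 57 Å threshold,
compared with 83% reported for the energy-guided Rosetta ensemble the
experiments used. The gap is informative rather than numerical noise: a
clash-only sampler contains no attractive energetics, so the subpopulation
of conformers with the two domains docked against each other at high
overall $R_g$ — which an all-atom score function rewards — is essentially
absent here. Reproducing that subpopulation would require exactly the
energy model this package deliberately excludes. The package therefore
supports the qualitative claim (the overwhelming majority of
size-consistent conformers span a nucleosome) while the 83% figure itself
is a property of the original modelling protocol's energetics.

## 4. Equilibrium models of the proximity assays

Both assays produce bell-shaped ("hook effect") titrations: signal requires
a bridging species, which is destroyed at high titrant when every site is
occupied monovalently. The models are ideal-solution mass-balance systems,
in micromolar units throughout.

**Bivalent engagement** (`solve_bivalent_titration()`): protein P with
sites A and B titrated with a two-epitope ligand L. Species: free P,
singly bound P·L (via A or via B), the cyclic P·L with both sites engaged
by one ligand, and the doubly occupied P·L·L′. Ring closure is modelled
with an effective concentration: the second, intramolecular association is
scaled by $c_\mathrm{eff}$, the standard avidity formalism —
$[\mathrm{P\!\cdot\!L}]_\mathrm{cyc} = [P][L]\,c_\mathrm{eff}/(K_A K_B)$.
The free-ligand concentration solves the ligand balance by bisection on a
provably monotone residual to $10^{-10}$ relative; all other species follow
in closed form. The signal is the cyclically engaged fraction, the BRET
observable's proxy. The alternative topology the assay cannot exclude (two
proteins bridged by one peptide) is deliberately not modelled.

**Ternary scaffolding** (`solve_ternary_scaffold()`): a bivalent scaffold P
bridging donor- and acceptor-bead epitopes D and A, species
{P, P·D, P·A, D·P·A}, signal $[\mathrm{D\!\cdot\!P\!\cdot\!A}]$. The many
nucleosomes on a real bead are collapsed to single-epitope species — this
reproduces the curve shape, not absolute counts. For each total-P grid
point the free-D/free-A balances are solved by damped fixed-point iteration
(half-step damping, $10^{-12}$ relative) inside a bracketed monotone root
on free P. The tests verify every species against an independent
closed-form oracle (the inner balance collapses to a quadratic in free A)
and mass conservation to $10^{-6}$ relative everywhere.

**Assay arithmetic.** `corrected_bret_ratio()` is
$1000\,(E_{610}/E_{450} - C_{610}/C_{450})$ (milli-BRET units);
`normalize_alpha()` averages technical replicates, subtracts the mean
negative control and rescales the maximum to 1, erroring when no corrected
value is positive.

**Empirical curve description.** `fit_hook_curve()` reports the grid argmax
as the peak and a rising-limb EC50 from a four-parameter log-logistic fit
restricted to concentrations at or below the peak. The truncation point is
located on a three-point running mean of the signal so that a single noisy
point cannot clip the fit window; with that guard the tests recover the
noise-free EC50 within 15% in at least 90% of 2%-noise simulations.
Published EC50 values for the real assays derive from unpublished raw
curves and are treated as plausibility anchors only, never as test targets.

## 5. Compartmental-domain enrichment

Coordinates are 0-based half-open BED/bedGraph semantics throughout;
domains and tracks are unstranded. Parsing goes through rtracklayer behind
tibble surfaces; overlapping bedGraph intervals are rejected.

- `domain_mean_signal()` is the mean signal per base pair with uncovered
  bases counting as zero (a documented, reproducible default; a flag
  restricts to covered bases instead).
- `scale_regions_matrix()` reproduces deepTools-style scale-regions
  binning: 0.5 Mb flanks at native scale, domain bodies linearly rescaled
  to 1 Mb, every bin the mean per-bp signal of its source span. The default
  bin size is 10 kb — not the upstream tool's default — so that synthetic
  genomes run in seconds; it is configurable, and the tests verify exact
  body-mean preservation on bin-aligned inputs. Flanks running off a
  chromosome edge are truncated and flagged.
- `kmeans_classify()` z-scores each track's columns, stacks tracks, and
  runs k-means with 10 random restarts under a fixed seed (base R provides
  no k-means++ initializer; multiple restarts serve the same
  stabilisation). The cluster with the higher grand mean of the
  first-listed, activating track is named ACTIVE — the naming convention
  the upstream procedure leaves implicit.
- `enrichment_test()` is the two-sided Welch t statistic with
  Welch–Satterthwaite degrees of freedom on per-domain means (zero-variance
  equal-mean groups yield $t = 0$, $p = 1$). Raw statistics are reported;
  a Benjamini–Hochberg adjustment can be applied by the caller via
  `p.adjust` but is deliberately not the default.
- `regulatory_correlation()` assigns a feature to a domain when its
  midpoint falls inside (unambiguous for edge-straddling features),
  computes per-feature mean signal for both tracks, and reports Spearman
  correlations (average-rank ties) per feature class with at least three
  usable features. Per-feature means — rather than per-bp values within
  features — are the implemented reading.

## 6. Synthetic data: what it emulates and what it does not

`gen_saxs()` produces either the analytic uniform-sphere profile or the
ensemble-averaged Debye profile of a sampled dumbbell ensemble (calibrated
stiffness by default), with multiplicative Gaussian noise and a
$\sigma = \mathrm{noise} \times I$ column, plus a sidecar recording the
ensemble's coordinate-space $R_g$, maximum dimension, and the
1%-tail $D_\mathrm{max}$ of the exact pair-distance histogram (the proper
oracle for the IFT's criterion). Real scattering noise is
count-based and correlated across $q$ after merging; independent
multiplicative noise is a reasonable desk-scale approximation at these
noise levels, nothing more.

`gen_genome()` plants non-overlapping domains of two classes on one
synthetic chromosome, with per-run Gaussian signal (run length
`resolution_bp`, default 1 kb — run-length emission is what bedGraph
encodes; per-base draws over ~100 Mb would add nothing testable),
regulatory features placed uniformly within domains, and truth labels in a
sidecar. It deliberately omits read-level artefacts — mappability, GC bias,
fragment-length effects, input normalization — so passing tests demonstrate
the correctness of the binning/classification/statistics chain, not
robustness to sequencing artefacts.

`gen_titration()` writes replicate plates from either solver with
multiplicative noise and records the noise-free curve's fitted EC50 and
peak as the sidecar truth.

Every generator requires a seed, and identical seeds reproduce output files
byte for byte.

## 7. Problem sizes and determinism

The test suite runs entirely on synthetic data built at test time: 5000
excluded-volume conformers per seed for three seeds in the end-to-end span
checks (the study-scale ensemble; about 10 s of compiled sampling in
total), 2000-model chains for the FJC closed form, 100-seed null
calibration for the enrichment statistic on 20-domain genomes, and 20-seed
EC50 recovery. All randomness flows through R's RNG — compiled code draws
via R's generators — so `set.seed()` reproduces every ensemble,
genome and plate exactly.

## 8. Known limitations

- The conformer sampler is a steric, energy-free model. It is calibrated to
  the measured ensemble $R_g$ and brackets the measured distance range, but
  it cannot reproduce statistics that depend on attractive interdomain
  energetics (notably the exact below-57 Å weight of the distance
  distribution), and its clash score is not comparable to any all-atom
  energy, so energy-subset analyses are exposed only as an option.
- Unweighted bead-wise regrowth is Rosenbluth-biased relative to the
  uniform self-avoiding ensemble; the bias is small at these chain lengths
  and is absorbed by the size-window conditioning.
- IFT $D_\mathrm{max}$ inflates with profile noise (see §1); treat
  reported tails from noisy profiles as upper estimates.
- The equilibrium models are ideal-solution, single-epitope abstractions;
  they reproduce hook-curve shapes and peak positions, not absolute signal
  magnitudes of bead assays.
- No multi-concentration merging, hydration-layer modelling, read-level
  genomics, peak calling or liftover: inputs are assumed to be processed
  profiles, tracks and annotations.
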