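---
title: "Two-deme demographic inference with peripagen: models, statistics, and design choices"
author: "peripagen maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-deme demographic inference with peripagen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The inference problem

`peripagen` implements a multi-locus analysis for a pair of diverging
populations — typically a widespread "ancestral-range" variety and a
narrow, possibly peripherally derived one — sampled at a dozen or so
phased nuclear loci and an organellar sequence. The pipeline answers two
linked questions:

1. **Is the polymorphism at each locus compatible with neutral,
   equilibrium evolution?** (per-locus diversity summaries, Tajima's D,
   Fu and Li's D\*/F\*, Fu's F~S~, Fay and Wu's H, the multilocus HKA
   test, AMOVA-based Φ~ST~)
2. **Which two-deme demographic history explains the joint data, and at
   what parameter values?** (coalescent simulation of a 20-scenario
   family, ABC scenario choice, composite-likelihood fitting of the
   joint site frequency spectrum)

The scenario family is designed to discriminate *peripatric* origins
(the small variety founded by colonization from the large one, scenario
families A/B) from *vicariant* ones (both splitting from an ancestor,
with a later bottleneck in one, families C/D), each with five migration
regimes (suffix 1: none; 2: only early after divergence; 3: only
recently, during the large deme's expansion; 4: both windows; 5:
ongoing).

# The demographic model

Backward in time, with all times in generations before present:

* two demes with current diploid effective sizes $N_1$ (ancestral-range
  deme) and $N_2$ (derived deme);
* at $t_1$ (looking backward) deme 2 drops to the founder/bottleneck
  size $N_{2f}$; in the A/B families this size persists until the
  divergence time $t_3$ (a founder event), in C/D only until $t_2$
  (a transient bottleneck, $t_1 \le t_2 < t_3$);
* in the B/D families deme 1 changes from $N_1$ to the pre-expansion
  size $N_{1b}$ at $t_0$ (a recent expansion, forward in time);
* at $t_3$ deme 2 merges into deme 1, whose size from there on is the
  ancestral $N_A$ (for A/B the ancestor *is* deme 1, so the template
  ties $N_A = N_1$);
* per-lineage backward migration at rates $m_{12}, m_{21}$, active only
  inside the suffix-defined epochs.

The coalescent engine is a standard structured coalescent with
piecewise-constant rates: within a deme of size $N$ the pair-coalescence
rate is $k(k-1)/(4N\,p)$ per generation, with ploidy factor $p = 1$ for
nuclear diploid loci and $p = 0.5$ (configurable) for the uniparental
organellar locus. Size changes are instantaneous steps; exponential
growth is deliberately not modelled, as the scenario family is defined
by epochs, not growth curves. Mutations follow the infinite-sites model
at a per-site per-generation rate $\mu$; loci are non-recombining blocks
that assort freely. The engine is compiled (Rcpp) with a self-contained,
seed-deterministic RNG, so per-locus substreams reproduce independently
of execution order.

**Migration-window defaults.** The verbal definitions of the migration
regimes ("initial", "recent", "ongoing") are mapped to concrete windows
as: initial $[t_1, t_3]$, recent $[0, t_0]$, ongoing $[0, t_3]$. These
are the package defaults and can be reconfigured by editing a scenario's
`migrationWindows`.

# Per-locus statistics

All statistics are computed from per-column allele counts, so FASTA
alignments (A/C/G/T with `N` and `-`) and simulated 0/1 matrices share
one code path:

* columns containing gaps are removed before nucleotide analyses
  (`maskIndelColumns`); a contiguous gap run can optionally be re-coded
  as one binary character so an indel counts as a single event in
  haplotype analyses;
* `N` is treated as missing pairwise — a site still counts in the locus
  length $L$ (a complete-deletion alternative is just masking those
  columns too);
* π is the mean pairwise difference per site; θ~w~ is $S/(a_1 L)$;
  haplotype diversity uses the $n/(n-1)$ small-sample correction;
* Tajima's D uses the 1989 variance constants; Fu and Li's starred
  statistics use the corrected constants of the DnaSP/libsequence
  lineage; Fu's F~S~ evaluates the Ewens distribution of the haplotype
  count with log-space Stirling numbers (stable to n of several
  hundred); Fay and Wu's H is the *unnormalized* 2000 definition,
  computed through the unfolded SFS so that the π and θ~H~ terms always
  refer to the same polarizable sites;
* polarization uses the majority outgroup residue; sites where the
  outgroup is missing, tied, or carries an allele absent from the
  ingroup are skipped, as are ingroup tri-allelic sites (they still
  count in S);
* R~m~ is the Hudson–Kaplan four-gamete lower bound with the standard
  interval reduction;
* Φ~ST~ is the AMOVA (Excoffier) variance-component ratio on
  pairwise-difference distances between haplotypes — the convention of
  sequence-data AMOVA — with significance from permuting haplotypes
  across populations, $p = (\#\{perm \ge obs\} + 1)/(B + 1)$. Hudson's
  $1 - H_w/H_b$ is reported alongside as a cross-check. Permuting
  haplotypes (not diploid individuals) matches the fact that all
  statistics operate on phased haplotypes.

Multi-locus summaries are unweighted arithmetic means across loci of the
per-site statistics; the per-locus table is always available
(`locusStatsTable`), so a length-weighted alternative is one
`weighted.mean` away.

# The multilocus HKA test

The one-taxon configuration contrasts within-taxon polymorphism $S_i$
with mean divergence $D_i$ to a single outgroup across $L$ loci, under
locus θ's and one shared scaled divergence time $T$ (units of $2N$
generations; the ancestor is assumed at the ingroup size). We use the
moment system

$$E[S_i] = \theta_i a_1(n_i), \qquad E[D_i] = \theta_i (T + 1),$$

with variances $\theta_i a_1 + \theta_i^2 a_2$ and
$\theta_i(T+1) + \theta_i^2$ (the latter includes the ancestral
coalescent term). Rather than iterating a multivariate Newton scheme,
the package exploits the fact that the full system reduces in closed
form to a single monotone equation in $T$ — solved with Brent's method
to relative tolerance 1e-10 — after which
$\hat\theta_i = (S_i + D_i)/(a_1(n_i) + \hat T + 1)$. This conserves
$\sum_i (\hat E S_i + \hat E D_i) = \sum_i (S_i + D_i)$ identically and
cannot diverge, which is why it replaces the damped-Newton design that a
general moment system would need. $D_i$ is the mean pairwise
ingroup–outgroup difference count; a net-of-within correction can be
applied upstream by subtracting π~L~/2 from `D` in the input table if
desired.

Degrees of freedom are $L - 1$ ($2L$ observations, $L + 1$ parameters),
and the statistic is referred to the upper tail of χ².

# ABC scenario choice

The reference table simulates study-shaped datasets per scenario from
the priors and records a **fixed, versioned statistic set** (26 values):
per population — haplotype count, S, π, Tajima's D, private S — and
between populations — per-locus Φ~ST~, mean between-population pairwise
difference per site, shared S — each as the mean and variance across
loci. Undefined per-locus values (monomorphic loci) enter as 0 so the
vector has no missing entries. Rejection standardizes by median/MAD
(robust to the long-tailed prior predictive), retains the closest
fraction (default the classic 1%), and the "direct" posterior is the
retained scenario frequencies. The "logistic" posterior is a
ridge-regularized multinomial regression (weight decay 1e-6) of the
scenario label on the statistic offsets, evaluated at zero offset, with
delta-method intervals on the intercepts; the ridge keeps complete
separation from destroying the fit, a documented deviation from the
unregularized textbook regression. Parameter posteriors use the
local-linear (Beaumont) adjustment with Epanechnikov weights, clipped to
the prior box.

**Priors.** Desk-scale defaults (`defaultPriors`) are uniform in times
and log-uniform in sizes and migration rates, with the *definitional*
constraints of the grammar: $t_0 < t_3$, $t_1 \le t_2 < t_3$,
$N_{1b} < N_1$ (an expansion is an expansion), $N_{2f} < N_2$ and
$N_{2f} < N_A$ (a founder event/bottleneck is a contraction). Bounds
(sizes $10^2$–$10^6$ by role; times $10^3$–$4\times10^5$ generations,
i.e. up to 10 Ma at 25 y/generation; $m$ in $10^{-8}$–$10^{-5}$) were
chosen once as the realistic range for long-lived conifer varieties
diverging in the Pliocene–Pleistocene, and are declared in one place so
a study can replace them wholesale.

Confidence evaluation draws pseudo-observed datasets from each
scenario's prior, classifies them against the table, and reports the
confusion matrix with per-scenario type-I error (true scenario not
chosen) and type-II error (scenario chosen when false).

# Composite-likelihood fitting of the joint SFS

The expected joint SFS under a parameter vector is estimated by Monte
Carlo as branch-length measure: every genealogy contributes
$\mu L \times$ (branch length) to the cell of its subtended
(deme-1, deme-2) descendant pair. This is the Rao–Blackwellized version
of dropping mutations and is considerably less noisy per simulation.
The composite likelihood of the observed spectrum is
$\sum_e m_e \log_{10} \hat p_e$ over polymorphic entries, with $\hat p$
renormalized over those entries and zeros floored at $1/(10Z)$ ($Z$ the
simulated expected-SNP total) before renormalization.

**Identifiability.** The normalized spectrum is invariant to rescaling
all sizes and times by a common factor, so a fit on shape alone cannot
recover absolute times. `fitScenario` therefore adds (by default) a
Poisson log-likelihood on the observed number of polymorphic sites —
exactly the role the monomorphic cell plays in SFS likelihoods when the
sequenced length is known. With it, divergence-time recovery at desk
scale is accurate to a few tens of percent; without it, only ratios are
meaningful.

Optimization is Nelder–Mead over box-transformed (logistic) parameters,
log-scaled where the prior is log-uniform; each "loop" fixes the
simulation seed (common random numbers) so the optimizer sees a smooth
surface, and loops refresh the seed to avoid over-fitting one noise
realization. Restarts draw fresh starting points from the prior. Model
comparison uses $\mathrm{AIC} = 2k - 2\ln(10)\,\mathrm{maxlog_{10}CL}$;
parametric-bootstrap intervals refit spectra simulated at the MLE.

# The synthetic-data generator

`studyTemplate()` fixes the study conditions the package is exercised
under: 14 nuclear loci totalling 6,077 bp (433 bp × 13 + 448 bp; the
true per-locus lengths can be substituted in the locus table), 112 + 63
diploid individuals (224 + 126 phased haplotypes), one haploid
organellar locus of 1,589 bp (two regions of 901 and 688 bp
concatenated) carried by every individual, generating scenario B3 at the
point estimates $N_1 = 5.17\times10^5$, $N_2 = 3.63\times10^4$,
$t_3 = 3.65$ Ma, $t_0 = 0.61$ Ma, $t_1 = 0.65$ Ma,
$m_{12} = 1.91\times10^{-7}$, $m_{21} = 8.37\times10^{-7}$,
$\mu = 5.58\times10^{-9}$ per site per generation, generation time 25
years. Quantities the point estimates do not pin down are set once:
$N_{1b} = N_1/10$, $N_{2f} = N_2/10$ (an order-of-magnitude expansion
and founder event, the canonical "strong but not extreme" choice),
$N_A = N_1$, and an outgroup calibration depth of 16.7 Ma (668,000
generations), consistent with a silent-site divergence near 0.0075 at
the default rate.

What the generator deliberately does **not** emulate: within-variety
population substructure (the study design pools populations into two
varieties for inference; simulating 10 + 6 demes would change the
question), sequencing error, indel evolution, phasing uncertainty, and
intralocus recombination. Tests passing on these data therefore validate
the *inference machinery* under the stated model — they do not certify
robustness to substructure or data-cleaning artifacts in real
alignments.

Outgroup sequences are generated by placing
$\mathrm{Poisson}(2\mu L t_{out})$ substitutions at fresh sites, which
reproduces the expected ingroup–outgroup divergence without simulating
the outgroup coalescent; this is adequate for exercising polarization
and HKA, and is the reason simulated H values center on zero.

# Numerical choices and degenerate inputs

* Undefined statistics are `NA`, never silently 0 ($S=0$ ⟹ D
  undefined; a single haplotype ⟹ F~S~ undefined; no polarizable site
  ⟹ H undefined). The ABC statistic vector is the one place where
  per-locus `NA`s become 0, because rejection distances cannot carry
  missing entries; this is stated on `datasetStats`.
* Stirling rows and their log-space recurrences are cached per n;
  log-sum-exp guards all Ewens tail sums.
* The mutation dropper errors (rather than silently saturating) if the
  infinite-sites assignment would need more sites than the locus has.
* Ties in ABC rejection are broken by row index; retained-set size is
  exactly `ceiling(tolerance * rows)`.
* Zero-MAD statistics are dropped from the rejection distance with a
  warning rather than dividing by zero.
* `phiSt` returns 0 (not negative ratios) when total variance is
  non-positive; negative variance-component estimates otherwise pass
  through, as in AMOVA practice.

# Problem sizes used by the test suite

The distributional checks run at sizes chosen to make Monte-Carlo error
bars meaningful on a single CPU: $10^4$ replicates for the single-deme
closed-form calibrations; 5,000 simulations per scenario and 50
pseudo-observed datasets for scenario recovery at the full study shape;
divergence-time recovery on 14 loci × (20 + 20) haplotypes with 2,000
simulations per likelihood evaluation, 10 loops, 5 restarts; model
ranking over 20 replicates at 800 simulations per evaluation. The
paper-scale settings (millions of simulations, 100 restarts, 100
bootstrap spectra) are reachable through the same arguments.

# Known limitations

* The HKA variance model assumes the ancestor at the ingroup size and a
  single outgroup sequence; with several outgroup haplotypes the mean
  divergence slightly underestimates the single-pair variance.
* The logistic posterior's intervals are intercept-only delta-method
  approximations; they say nothing about reference-table Monte-Carlo
  error.
* Composite likelihoods treat sites as independent; AIC differences
  between scenarios are therefore indicative rankings, not calibrated
  evidence ratios.
* Φ~ST~ permutation p-values are conservative on very short loci, where
  the permutation distribution is coarse.
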