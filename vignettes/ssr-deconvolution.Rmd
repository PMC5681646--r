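---
title: "Deconvolving mixed yeast populations from SSR meta-profiles"
author: "ssrdeconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving mixed yeast populations from SSR meta-profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrdeconv)
```

## The problem

Wine fermentations, like many other environments colonized by
*Saccharomyces cerevisiae*, are usually driven by several strains at
once. Amplicon metagenomics resolves such communities to the species
level at best, while classical strain typing (microsatellite profiling
of isolated colonies) sees one individual at a time. When a panel of
microsatellite (SSR) loci is amplified directly from the mixed sample,
each locus shows the **union** of the alleles of every strain present —
a *meta-profile*. The question this package answers is: *which
combination of strains from a reference collection best explains an
observed meta-profile?*

## The model

Let $U$ be the set of distinct alleles (locus, fragment length pairs)
seen in the reference collection and the query sample, of size $m$. The
reference collection of $p$ strains becomes a binary design matrix
$X \in \{0,1\}^{m \times p}$, with $x_{ij} = 1$ iff strain $j$ carries
allele $i$; the query becomes a response $y \in \{0,1\}^m$. We fit a
binomial GLM of $y$ on $X$ with three structural constraints that
encode the pooling physics:

* **no intercept** — an allele absent from every present strain should
  have probability near zero, not near the sample base rate;
* **non-negative coefficients** ($\beta_j \ge 0$) — a strain can only
  *add* alleles to a pool, never subtract them;
* **L1 (lasso) penalty** — most reference strains are absent, so the
  coefficient vector must be sparse.

The solver minimizes the penalized objective
$$\frac{1}{m}\sum_{i=1}^m \left[\log(1 + e^{x_i^\top\beta}) -
y_i\, x_i^\top\beta\right] + \lambda \sum_j \beta_j,
\qquad \beta_j \ge 0,$$
over a log-spaced path of 100 penalty values starting at the smallest
$\lambda$ for which $\beta = 0$. The penalty is chosen by 10-fold
cross-validation over the universe rows, minimizing by default the mean
squared error between held-out responses and predicted probabilities.
Strains with coefficients above `coef_epsilon` ($10^{-8}$) are called
**present**. Coefficient magnitudes are selection scores only; they are
not strain abundances.

The fit is scored by combining the called strains' profiles into a
predicted meta-profile and comparing it with the query:
$$\mathrm{GLMerror} = 100 \cdot
\frac{|\,\mathrm{predicted} \,\triangle\, \mathrm{query}\,|}
     {|\,\mathrm{predicted}\,|},$$
the percent of alleles differing (symmetric difference) relative to the
predicted profile size. We read "alleles differing" as the symmetric
difference because it penalizes both missed and spurious alleles and is
zero exactly on a perfect reconstruction. When no strain is called the
ratio is undefined; we report 100 with a `degenerate` flag rather than
fail, so batch benchmarks stay total.

Pool-level evaluation uses three further statistics. For a pool of
$S_p$ strains, the **discrimination ability** of a locus is
$D_a = S_{sa}/S_p$, where $S_{sa}$ counts pooled strains carrying at
least one allele found in no other pooled strain *and* present in the
observed pool profile. The **average locus error** over $N$ pools is
$E_a = 100 \cdot \frac{1}{N}\sum_{\text{pools}} d_a/e_{pa}$, the mean
fraction of a locus's expected alleles differing between observed and
expected pooled profiles. Recovery of a known pool is summarized by the
**true-positive rate** $100 \cdot P_p/Q_p$ (parental strains recovered
over parental strains pooled) and the count of false-positive calls.

### Numerical choices

* Allele identity is exact (locus, integer length): fragment sizing is
  assumed already binned upstream; no tolerance window is applied.
* The allele universe is sorted by locus name then length, making
  encodings — and therefore fits — bit-reproducible.
* Cross-validation folds are assigned to universe rows by a seeded RNG,
  unstratified; the same seed gives bit-identical results.
* The solver is glmnet's coordinate descent with a convergence
  threshold of $10^{-7}$; predictors are standardized internally and
  coefficients reported on the 0/1 scale.
* A binomial fit needs both response classes at least twice. Rows of
  zeros appended to $X$ have linear predictor 0 for every $\beta$ (no
  intercept), so padding an almost-all-ones response changes nothing
  in the optimum while keeping the solver applicable; if
  cross-validation is still infeasible, the penalty minimizing the
  full-path deviance is used, with a warning.
* Queries for loci that failed amplification contribute zero rows, not
  missing-data codes: an absent allele is evidence of absence here,
  a deliberate reading documented rather than hidden.

## Reference collections: typing and pruning

Strain relatedness is summarized by the Cavalli-Sforza–Edwards chord
distance. A single strain's "allele frequencies" at a locus are taken
uniform over its scored alleles (1 for a homozygous call, 0.5/0.5 for a
heterozygous one) — the convention that fixes the distance scale, so it
is stated prominently. Per locus typed in both strains,
$$d_\ell = \frac{2}{\pi}\sqrt{2\Big(1 -
\sum_a \sqrt{f_p(a) f_q(a)}\Big)},$$
and the distance is the *mean* of $d_\ell$ over shared loci (summing
instead would only rescale it); loci untyped in either strain are
dropped pairwise. The upper bound is $2\sqrt{2}/\pi \approx 0.9003$.
Trees are built by neighbor joining (`njTree()`) and midpoint-rooted;
negative NJ branch estimates on non-additive matrices are clamped to
zero with a warning.

Deconvolution presumes each reference strain can be recognized as
itself. Collections violate this in two ways: exact clones, and haploid
strains whose alleles are a subset of a diploid's, which the model can
freely substitute. `pruneReference()` deconvolves every strain's own
profile against the collection and removes redundancy until a full pass
is clean. Two call signatures trigger a removal: more than one strain
called (keep the query strain if called, else the largest-coefficient
call, ties by input order), and a single call that is *not* the query
strain — the solver collapses exactly collinear profiles onto one
column, so an unrecognized self-query is the fingerprint of a clone.
Passes re-evaluate against the shrunken collection and the procedure is
idempotent by construction; a guard errors after 100 rounds.

## What the simulator emulates — and what it does not

`simulateReference()` generates a typing study: a panel of 12 SSR loci
(the standard *S. cerevisiae* panel names), 8 ladder alleles per locus
spaced by a 3 bp repeat unit from a base length of 100 bp, and
heterozygosity probability 0.5 per locus. By default half the strains
share a clonal founder (clone groups of two on average), with each
clone stepping one repeat unit away from its founder per locus with
probability 0.05. The clonal default matters: environmental collections
contain groups of near-identical strains expanded from a common source,
and it is exactly these near-clones that make pooled identification
hard — an unstructured collection of ladder-random strains is
unrealistically easy (recovery stays at 100% for every pool size). The
defaults aim at a realistic *difficulty regime*, not at any particular
collection's allele frequencies, which are not public.

`simulateExperiment()` pools $k$ strains without replacement, sets the
observed profile to the union of the parental profiles, and optionally
corrupts it with amplification noise: independent per-allele dropout at
locus-specific rates (presets of 9% and 4.6% mimic the two error-prone
panel loci C6 and C8) and optional stutter (a spurious allele one
repeat unit below a true one). Per-pool seeds derive from the master
seed by a counter, so any pool regenerates in isolation.

The simulator does **not** model PCR kinetics, peak heights, allele
size calibration, stutter ladders of more than one step, or linkage
between loci. Passing benchmarks on synthetic pools therefore
demonstrate the statistical machinery — encoding, selection, scoring,
pruning — under a realistic difficulty regime; they do not certify
performance on any particular wet-lab electropherogram pipeline.

## Benchmark design and expected regime

The benchmark harness mirrors the method's validation design: simulate
a collection, prune it, generate pools of $k = 2..6$ strains, and
deconvolve each pool against the pruned reference with the full
12-locus panel and with a reduced 10-locus panel excluding C6/C8. On a
50-strain clonal collection with the defaults (200 pools per $k$ in the
test suite, 100 in the acceptance script), all-parental recovery starts
at or near 100% for two-strain pools and declines with pool size while
the fraction of pools with at least one false-positive call rises —
the false positives being, overwhelmingly, near-clones of true
parentals. The full panel recovers at least as well as the reduced one:
even error-prone loci contribute discriminating alleles to the joint
model. These trends, not any fixed percentage, are the contract the
acceptance tests assert; the problem sizes above were chosen so the
whole suite runs in minutes on one CPU.

## Known limitations

* Coefficients are not abundances; a strain present at low template
  share can carry the same coefficient as a dominant one.
* A query strain missing from the reference cannot be identified, only
  flagged through a non-zero GLMerror (unexplained query alleles).
* Allele identity is exact; miscalibrated fragment sizes upstream
  translate directly into spurious or missed alleles.
* $D_a$ is a property of a *known* pool (it needs the parental
  profiles) and is reported per locus for study design, not inference.
* The pruning representative rule (query strain first, then largest
  coefficient, then input order) is a reproducibility convention; the
  removed/kept partition of a clone group is otherwise arbitrary.
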