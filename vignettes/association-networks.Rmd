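---
title: "Methods: microbe-metabolite association networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microbe-metabolite association networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assocnet)
```

## The model

assocnet links two feature tables collected on the same set of microbiome
samples: a microbial table (OTU counts from 16S amplicon data, or a
presence table of biosynthetic gene cluster families from shotgun
assemblies) and a molecular table (LC-MS or LC-MS/MS feature intensities,
each feature carrying an m/z value). The working object for every feature
$X$ is its *presence set*

$$\mathrm{Samples}_X = \{\, S : \mathrm{abundance}(X, S) > t \,\},$$

with a strict threshold $t$ (`MinCount` for counts, `MinIntensity` for
intensities). A molecule and a microbe are *associated* when their presence
sets co-occur across samples far more (or less) often than independence
predicts. The null model is Fisher's exact test on the $2 \times 2$ table
$(a, b, c, d)$ = (both present, molecule only, microbe only, neither): the
hypergeometric distribution of $a$ given the margins. Sampling units are
whole microbiome samples, assumed independent — natural for cohorts of
distinct subjects, optimistic within repeated-measure designs.

Because the pipeline must see both directions — a microbe that *produces* a
molecule co-occurs with it, a microbe that *consumes or transforms* a
precursor excludes it — the test is two-sided, and each retained edge is
labelled `positive` or `negative` by comparing observed co-occurrence with
its expectation: positive iff $a\,n > (a+b)(a+c)$, with exact equality
called positive and flagged. This observed-versus-expected rule stays
defined when a table cell is zero, where the odds-ratio estimate does not.

### Tunable parameters that matter

| parameter | default | meaning |
|---|---|---|
| `MinCount` | 0 | counts strictly above it are "present" (0 means any nonzero count) |
| `MinIntensity` | 1000 (LC-MS practice) | same rule for intensities |
| molecular prevalence filter | 2 samples | features seen once are untestable |
| BGC-family prevalence filter | 10 samples | rare families are uninformative |
| `p_threshold` (scan) | $10^{-10}$ | edge retention cutoff, strict `<` |
| dedup `mz_tol` | 0.01 Th | absolute, not ppm |
| dedup `p_threshold` | $10^{-5}$ | fixed gate, not multiplicity-corrected |
| clade `percent` | 80 | coverage a clade must reach |

## Numerical notes on the exact test

The all-pairs scan can evaluate $10^6$–$10^8$ tables, so P values are
computed in batches grouped by the margin pair $(|S_X|, |S_A|)$: each group
shares one hypergeometric support, enumerated once. Two regimes:

* $n \le 55$: every numerator $\binom{k_x}{a}\binom{n-k_x}{k_y-a}$ and the
  denominator $\binom{n}{k_y}$ are integers below $2^{53}$, so the
  two-sided mass (all tables whose point probability does not exceed the
  observed one) is accumulated by exact integer comparison — exact rational
  arithmetic carried in doubles, with no tie tolerance at all.
* $n > 55$: log-space `dhyper` with the conventional $1 + 10^{-7}$
  relative tie tolerance, the same convention `stats::fisher.test` uses.

Degenerate margins (a single feasible table) give $P = 1$. The test suite
checks the engine against an independent by-definition enumeration for
every table with $n \le 30$ and against `stats::fisher.test` on random
tables up to $n = 500$.

## Deduplication

LC-MS feature extractors report one molecule as several features at nearly
identical m/z. Two molecular features are putative duplicates when (i)
$|\Delta m/z| \le$ `mz_tol`, (ii) their presence sets co-occur with Fisher
$P \le 10^{-5}$, and (iii) the co-occurrence is *positive*. The third
condition is an interpretation this package makes explicit: duplicates are
one molecule observed twice, so they must co-occur; a significant two-sided
P can also come from near-perfect mutual exclusion, which must not merge
features. Groups are connected components of the duplicate graph, so
transitive chains can merge features whose pairwise $\Delta m/z$ exceeds
the tolerance — accepted as part of the component definition. Each group
becomes one consensus feature: unweighted mean m/z, union presence set, id
`dedup:` + the lexicographically smallest member (singletons pass through
unchanged). Candidates are generated with an m/z-sorted sliding window, so
only the m/z-compatible pairs are tested; both gates are conjunctive, so
the output is unaffected. Retention time is deliberately not used.

## False discovery rates

Two estimators are provided.

**Target-decoy (TDA).** For every molecular feature a decoy is drawn: a
uniformly random subset of the sample universe of the same size (for
continuous scans, the feature's intensity vector randomly permuted across
samples, the natural continuous analogue). Decoys are scanned against the
same microbes with the same test, and

$$\widehat{\mathrm{FDR}}(t) = \frac{|\mathrm{DecoyAssociations}(t)|}
  {d \cdot |\mathrm{RealAssociations}(t)|},$$

capped at 1 and defined as 1 when no real association passes, where $d$ is
the number of decoys per target.

Two conventions matter in practice and are fixed here after a variance
analysis (not after observing test outcomes):

* *Threshold selection runs on a fixed grid* (`10^-30 ... 10^-2` by
  decades, the same grid the CLI exposes), choosing the most permissive
  grid point whose estimate is $\le q$. Selecting on the continuum of
  observed P values instead would let the estimate hit zero at
  `n_real = 1, n_decoy = 0` — a guaranteed false selection on null data.
* *Calibration-grade analyses use $d = 10$ decoys per target.* With a
  single decoy the estimate's resolution near zero is $1/n_\mathrm{real}$,
  far too coarse to certify a 1% FDR on a 20-discovery problem. One decoy
  per target remains the default of `tda_fdr()` itself.

**Benjamini-Hochberg.** `bh_adjust()` is the standard step-up procedure
(via `stats::p.adjust`), applied over the full molecule-by-microbe family
actually searched — `adjust_edges()` carries the family size from the scan,
so q values of a pre-filtered edge list still refer to all tested pairs
(exact for the retained smallest P values, conservative otherwise). BH
assumes valid P values, so the mutual-information criterion — thresholded
on the statistic itself, with no null distribution — is FDR-controlled by
TDA only.

## Alternative association tests

Pearson and Spearman run on the continuous intensity matrices (raw by
default; a log10 option exists because no transform is canonical), with
two-sided P values from the $t_{n-2}$ reference; constant vectors are
skipped with a message rather than an error. Mutual information is the
plug-in estimate on presence indicators, in bits, with $0\log 0 = 0$; in
continuous mode features are binarized first (default two levels), since
no binning scheme is canonical for intensities.

## Clade assignment

Given a rooted phylogeny over the microbial features, each molecule's
positively associated microbes are marked and the molecule is assigned to
the *minimal clade containing at least `percent`% of all marked leaves*
(the coverage reading). The alternative reading — at least P% of the
clade's own leaves marked — would make any single marked leaf trivially
optimal and is rejected. Further choices, all deterministic:

* candidate clades are internal nodes only (one leaf is a species, not a
  clade), so single-leaf evidence maps to the leaf's parent;
* "minimal" = fewest leaves; ties broken by greater depth, then postorder
  position (with coverage above 50% qualifying clades are nested, so ties
  cannot actually arise there);
* the root never qualifies: an assignment must be a proper subtree;
* marked counting is one postorder pass, $O(\text{tree size})$, verified
  against brute-force enumeration of all subtrees;
* unrooted Newick input is midpoint-rooted with a warning.

Pruning to the associated microbes precedes assignment; suppressed unary
nodes have their branch lengths summed.

## The synthetic generator

`simulate_dataset()` emulates exactly the structure the test assumes:
independent samples; independent Bernoulli background features; planted
(molecule, microbe) pairs where the molecule's presence is conditioned on
the microbe's; duplicate clusters sharing a latent presence set thinned by
independent dropout, with m/z jittered inside the dedup tolerance.
Defaults — 200 samples, 100 molecules, 50 microbes, background presence
probability 0.3, planted conditionals 0.95/0.02, dropout 0.1, m/z jitter
0.004 Th around centers uniform in 100–1500 Th — describe a mid-size cohort
with moderately prevalent features and near-deterministic planted signals,
and are the fixed study conditions of the calibration and recovery tests.
Continuous mode draws log-normal intensity (meanlog $\log 5\times 10^4$,
sdlog 1) where present and 0 where absent, mimicking LC-MS zero inflation.

What the generator does *not* emulate: compositional coupling between
features, batch and confounder structure, repeated measures, intensity
censoring near the detection limit, isotopes and adducts. Passing the
calibration tests therefore certifies the machinery under the test's own
assumptions; on real cohorts, shared confounders (the paper-facing caveat
for any co-occurrence method) can inflate the effective FDR, and the
`correlated_background` switch exists precisely to watch the TDA estimate
degrade under a shared latent factor.

## Problem sizes used by the test suite

The suite and the acceptance script run entirely on synthetic data at the
default study conditions: 20 simulation seeds for null calibration, 5–10
seeds for recovery and benchmarking, exhaustive Fisher verification over
all 46,376 tables with $n \le 30$, 1000 random BH vectors, and 200 random
trees of up to 12 leaves for the clade oracle. These sizes make every
statistical check reproducible in well under a minute each on one core
while keeping Monte-Carlo error well below the asserted margins.

## Known limitations

* Associations are marginal pairwise co-occurrences: no confounder
  adjustment, no compositionality correction, no multi-step pathways.
* The TDA estimate assumes decoys mimic null targets; strong dependence
  among molecular features (beyond what deduplication removes) makes it
  optimistic.
* MI has no significance calibration by construction here.
* Clade assignment depends on the tree being correct and rooted
  meaningfully; midpoint rooting is a fallback, not a recommendation.
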