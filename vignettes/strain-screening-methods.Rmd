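---
title: "Methods: screening and prioritizing diazotrophic plant growth-promoting bacteria"
author: "diazoScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening and prioritizing diazotrophic plant growth-promoting bacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diazoScreen)
```

# The analysis problem

Culture-based strain screening asks a chain of questions about a
collection of bacterial isolates — here, diazotrophs and nitrogen
scavengers recovered on semisolid N-free media from soils and from
*Solanum* (tomato and lulo) rhizospheres:

1. **How dense are the source populations?** Serial-dilution
   presence/absence outcomes give most-probable-number (MPN) estimates
   of viable cells per gram.
2. **How genotypically diverse is the collection?** rep-PCR (BOX-PCR)
   band profiles are compared with a proportional size tolerance,
   clustered by UPGMA on Jaccard similarity, and counted as distinct
   profiles at a high similarity threshold.
3. **How does it relate phylogenetically?** Kimura two-parameter
   distances on aligned 16S rRNA fragments, neighbor-joining trees and
   bootstrap support.
4. **Which strains help plants?** Greenhouse dry-weight responses are
   analysed per species and response by one-way ANOVA with Scott-Knott
   clustering of treatment means.
5. **Which strains should go forward?** A bonitur (arbitrary-point)
   scale converts four in vitro traits (0–3 each) and four biometric
   responses (0–2 each) into a 0–20 total with dense ranks.

`diazoScreen` implements this chain as testable, reusable components
around a single validated container, `StrainCollection`. A synthetic
collection generator with known ground truth makes every stage testable
without access to the original raw data.

# MPN estimation and the summary arithmetic

For a vial inoculated with $m$ grams of original material from a
suspension of density $\lambda$ cells g$^{-1}$, the probability of
growth is $1 - e^{-\lambda m}$ under Poisson sampling. With $g_i$
positive vials of $n_i$ at amounts $m_i$, `estimateMPN()` solves the
maximum-likelihood score equation

$$\sum_i \frac{g_i m_i e^{-\lambda m_i}}{1 - e^{-\lambda m_i}}
  = \sum_i (n_i - g_i)\, m_i$$

by bracketed root finding (initial bracket $[10^{-3}, 10^{12}]$
cells g$^{-1}$, expanded geometrically when needed; relative tolerance
$10^{-8}$). The 95% interval comes from the observed information of
$\log\lambda$, which at the MLE is
$\lambda^2 \sum_i g_i m_i^2 e^{-\lambda m_i}/(1-e^{-\lambda m_i})^2$;
intervals are therefore log-normal and always positive. Two edge cases
follow the likelihood rather than a formula: an all-negative series has
$\hat\lambda = 0$, and an all-positive series has an unbounded MLE and
is flagged, reporting only the 95% likelihood lower bound (the density
at which the all-positive outcome has probability 0.05). On the classic
three-tube pattern 3-2-0 at inocula 0.1/0.01/0.001 g the estimator
returns 93.28 cells g$^{-1}$, matching the published three-tube MPN
table entry of 93.

Display values divide by $10^4$ and round to two decimals, the
reporting scale of the summary tables. Aggregation rules in
`totalMPN()` / `summarizeMPN()` are deliberate:

* a sample's total is the **sum over media of the display values**,
  including media from which no isolate was recovered;
* per-medium and per-soil means divide by the number of samples (nine),
  **counting absent media as zero**, not by the count of non-zero
  cells;
* everything is computed at full precision and rounded only at display.
  Comparisons against 2-decimal published values use a 0.015 tolerance,
  which absorbs per-cell rounding (a total printed as 18.67 can arise
  from cells that sum to 18.66).

The reference table shipped in `inst/extdata` reproduces the published
per-sample totals and the JNFb per-medium mean ($44.32/9 = 4.92$)
exactly under these rules. The published JMV and LGI per-medium means
do **not** follow from the table's cells under any divisor we tried
(they were presumably computed from unpublished replicate-level data);
the package does not assert them anywhere.

# Fingerprint similarity and clustering

Band matching is the one genuinely bespoke primitive. Two fragments
$x$ and $y$ (bp) are matchable iff

$$|x - y| \le \mathrm{tol} \cdot \frac{x + y}{2},$$

with tol = 0.02 by default — a 2% tolerance expressed symmetrically in
the two sizes, the usual convention of gel-analysis software. Matching
is one-to-one; the default greedy pass consumes matchable pairs in
order of increasing size difference, which is deterministic and
identical to the optimal assignment on well-separated gels. For
pathological profiles an exact maximum bipartite matching
(`method = "optimal"`, augmenting paths) is available; the two methods
agree everywhere except chains of ambiguously close bands.

Jaccard similarity is $m/(|a| + |b| - m)$ with $m$ matched pairs (two
empty profiles are defined as identical, and tol = 0 degenerates to the
exact multiset Jaccard). UPGMA operates on distance $1 - s$ through
average linkage (`stats::hclust(method = "average")`, the size-weighted
recurrence), so merge heights are monotone; similarity groups at a
cutoff $c$ (default 0.70) are the maximal subtrees whose merges all
stay at similarity $\ge c$ — exactly a tree cut at height $1 - c$.
Profile counting (default threshold 0.95) reports groups of size two or
more as near-clonal sets.

# 16S distances, NJ trees and bootstrap

K2P distances count transitions ($P$) and transversions ($Q$) over
usable sites and evaluate
$d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q)$. Sites with a
gap or N in **either** sequence are excluded pair by pair (pairwise
deletion) — this maximizes usable sites per pair; complete deletion
would discard whole columns. Saturated pairs ($1-2P-Q \le 0$ or
$1-2Q \le 0$) raise an error rather than returning NaN. Our
implementation is cross-checked in the tests against the reference
distance implementation in `ape` and against hand-derived closed forms.

Trees come from Saitou–Nei neighbor joining (`ape::nj`). Small-sample
NJ can estimate negative branch lengths; these are clamped to zero for
display with the raw values retained in the `raw_edge_length`
attribute. Bootstrap support resamples alignment columns with
replacement, rebuilds the NJ tree per replicate, and scores each
internal edge of the reference tree by the fraction of replicates
containing the same unrooted bipartition; replicates made undefined by
saturation are skipped and counted, and more than 10% skipped is an
error. The conventional 1000 replicates is the default; tests use fewer
on small alignments, which is enough because support there is driven by
tens of fixed differences.

# ANOVA, Scott-Knott and correlation

One-way ANOVA per species and response uses the standard decomposition
(`stats::aov`). A collection screened on two plant species with two
responses yields four independent analyses — matching how such trials
are reported — and no multiple-testing correction is applied across
them, mirroring standard practice for this design. Unbalanced designs
replace $r$ by the harmonic mean of group sizes and are flagged.
Constant data (a degenerate but legal input) yields $F = 0$ by
definition rather than 0/0.

Scott-Knott follows the original 1974 procedure. With sorted means, the
candidate split maximizes
$B_0 = T_1^2/k_1 + T_2^2/k_2 - (T_1+T_2)^2/(k_1+k_2)$; the statistic

$$\lambda = \frac{\pi}{2(\pi - 2)} \frac{B_0}{\hat\sigma_0^2},\qquad
\hat\sigma_0^2 = \frac{\sum_i (\bar y_i - \bar y)^2 + \nu s^2_{\bar y}}
                      {k + \nu},\quad s^2_{\bar y} = \mathrm{MSE}/r$$

is compared with the $\chi^2$ quantile at $1-\alpha$ with $k/(\pi-2)$
(non-integer) degrees of freedom; accepted splits recurse on both
halves. Groups are therefore always contiguous intervals in mean order,
labels run `a`, `b`, ... from the highest mean down, and decreasing
$\alpha$ can only coarsen the partition. The implementation is verified
against an independently coded exhaustive split search for $k \le 6$,
and its null behavior (all true means equal) splits at close to the
nominal rate — measured 0.048 over 400 simulations at $\alpha = 0.05$
with $k = 5$, $r = 5$.

One interpretive point: with two well-separated tiers of several
treatments each, the procedure separates the tiers essentially always,
but *within*-tier subdivision still occurs at rate $\approx \alpha$ per
tier — that is the designed type-I behavior, not a defect. The
recovery tests therefore assert exact two-group recovery for
single-treatment tiers, and tier purity (no group mixes tiers) for
multi-treatment tiers.

# Bonitur scoring

Trait scores bin each strain's value against the mean of the
**positive strains only** for that trait. The package's default
(`mode = "band"`) places the bin edges at $0.65\,\bar t$ and
$1.35\,\bar t$ — a symmetric 35% band around the mean. We chose this
over the alternative verbal reading of "35% / 70% of the mean"
(`mode = "literal"`, retained behind the flag) because only the band
interpretation reproduces the published AlPO$_4$ cutoffs: with mean
3.85, $0.65 \times 3.85 = 2.50$ and $1.35 \times 3.85 = 5.20$ at one
decimal, exactly the printed bounds (and the FePO$_4$ bound 4.1 follows
from mean 6.36 within rounding). Non-detections and detected zeros both
score 0; boundary values take the higher bin, as the published bound
listing implies ($\le$ lower $\to$ 1, $\ge$ lower and $\le$ upper
$\to$ 2, $\ge$ upper $\to$ 3, the shared bounds resolving upward).

Biometric scores default to the Scott-Knott-relative rule — 0/1/2 for a
cluster below / sharing / above the control's cluster — which is the
operational definition of "significantly lower / similar / higher than
uninoculated plants". `cutoffScore()` replays fixed published bounds
(e.g. tomato RDW 0.23/0.27 g) for auditing published score tables
without the underlying replicate data.

Totals are sums of the eight components, bounded by
$4 \times 3 + 4 \times 2 = 20$; ranks are dense (tied totals share a
rank, the next distinct total takes the next integer), display ties are
broken by strain id, and the biotechnological-potential flag marks
totals $\ge 10$.

# The synthetic collection generator

`simulateCollection()` emulates the statistical structure of the
101-strain study so that every stage has a ground truth:

* **Provenance**: 101 strains; source, soil, medium and genus drawn
  from the study's marginal frequencies (isolation sources 26/42/33
  across BS/TR/LR, media 49/6/31/13/2, one dominant genus at share
  0.58).
* **Traits**: detection is Bernoulli per trait with probabilities
  0.485 (IAA), 0.713 (FePO$_4$), 0.435 (AlPO$_4$), 0.435
  (siderophores). Positive values are log-normal with means anchored on
  the reported positive-strain means (33.1, 6.36, 3.85; siderophore
  index $1 +$ log-normal with mean 0.7) and log-scale SDs of about 1,
  chosen so that roughly 50–100 draws span the reported
  order-of-magnitude ranges (e.g. 2.96–193.97 for IAA). Log-normality
  reflects the strong right skew of the printed ranges.
* **Fingerprints**: 20 latent profile prototypes of 12 bands drawn
  log-uniform on 200–5000 bp with a guaranteed 5% relative spacing
  (bands closer than the matching tolerance are unresolvable on a gel);
  strains inherit their prototype with 95% band retention, occasional
  private bands (also spacing-filtered) and 0.2% multiplicative jitter
  — an order of magnitude below the 2% matching tolerance. Five
  planted clone pairs copy a partner's profile up to jitter.
* **Biomass**: five replicates per treatment and species; control
  means sit at the centre of the published control score bands (tomato
  0.25/0.83, lulo 0.12/0.315 g per plant); per-strain effects are
  normal with SD 0.15 of the control mean and residual CV 0.08.
* **Dilutions**: nine samples at true densities log-uniform on
  $10^4$–$3\times10^5$ cells g$^{-1}$, three dilutions
  ($10^{-4}$–$10^{-6}$ g) with three vials each. The vials-per-dilution
  choice is a convention — the original study does not state its MPN
  replication design.

Each component draws from its own RNG stream derived from the master
seed, so changing one component's design does not disturb another —
that keeps regression tests stable. With the default within-cluster
variation, occasional *accidental* near-clonal pairs arise beyond the
planted ones (as they do in real collections); tests that need exact
clone bookkeeping use one prototype per strain so the planted pairs are
the only high-similarity pairs.

What the generator does **not** emulate: 16S sequence evolution
(phylogeny tests build alignments and additive matrices directly),
spatial or temporal structure, trait correlations between assays, and
genus-trait associations. Passing recovery tests therefore demonstrate
correctness of the estimators under the stated sampling models, not
robustness to real-data violations of them.

# Numerical and design choices

* MPN root finding is bracketed and monotone (the score is decreasing
  in $\lambda$), so convergence is guaranteed; the bracket expands
  geometrically for extreme series.
* UPGMA ties (two pairs at the same minimal distance) follow the
  deterministic order of the underlying implementation; cluster numbers
  are renumbered by first appearance in input order so outputs are
  stable across platforms.
* Strain ids are compared after stripping leading zeros ("04T" and
  "4T" are one strain, as published tables use both forms); stored
  labels are never rewritten.
* Trait tables encode "not detected" as an empty cell or `ND`; a
  numeric 0 is a detected zero. Both score 0, but the distinction is
  preserved in storage because a non-detection is not a measured zero.
* The P-solubilization unit is carried as a label without conversion:
  the source material reports mg l$^{-1}$ in one place and mg g$^{-1}$
  in another, and the package records values on the printed numeric
  scale rather than resolving the inconsistency.
* Negative NJ branch lengths are clamped at 0 for display (the
  convention of common tree software) with raw values retained.
* Scott-Knott uses the continuous $\chi^2$ quantile for its
  non-integer degrees of freedom $k/(\pi-2)$.

# Problem sizes used in tests

The shipped tests run the full chain at the study scale (101 strains)
once, use 60–300 Monte-Carlo replicates for coverage/rate checks, 2000
cheap trait-only replicates for the detection-frequency check, and
$n \le 12$ taxa for exact NJ recovery — sizes at which each property is
sharply testable in seconds.

# Known limitations

* The MPN interval is the log-normal observed-information
  approximation; no exact or Cornish-Fisher-corrected variants.
* Greedy band matching is documented and deterministic but not always
  maximal on ambiguous profiles (use `method = "optimal"` there).
* No mixed models or repeated-measures structure in the biomass
  analysis; no multiple-testing correction across species/responses.
* Taxonomic classification (RDP/BLAST/SILVA) is out of scope: genus
  labels are inputs.
* The dendrogram-based profile count at 95% is one of two defensible
  definitions (the other being pairwise thresholding); counts from
  commercial gel software need not match exactly.
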