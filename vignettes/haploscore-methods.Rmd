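---
title: "Scoring candidate IBD segments with HaploScore: model, estimators and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring candidate IBD segments with HaploScore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haploscore)
```

## The problem

Fast identity-by-descent (IBD) detectors of the hash-and-extend family
(GERMLINE and its relatives) find candidate shared segments between pairs of
individuals by seeding on short exact haplotype matches and extending them at
the *diplotype* level: extension continues through any site at which the two
genotypes are compatible with sharing, i.e. through every site that is not an
opposite homozygote. Diplotype extension is what makes long segments
recoverable from statistically phased data, where haplotype switch errors
are inevitable — but it is also overly permissive: a segment can be reported
although no consistent pair of haplotypes carries it, because the putatively
shared allele hops between the two haplotypes of an individual. Segments
reported on that basis are false IBD, and in trio-validated array data they
dominate the short-segment range.

Trios expose the problem: if a child truly shares a segment with an unrelated
individual, the transmitting parent must share an encompassing segment with
that individual. A child-other segment with no or truncated parent-other
support is, with high probability, a false positive — the truncation points
are almost always confidently genotyped opposite homozygotes, which exclude
IBD at the site unless the call is wrong.

## The HaploScore metric

For a candidate segment $S$ between individuals $a$ and $b$, with per-site
genotyping error rate $\varepsilon$ and per-site switch error rate $\sigma$,

$$\mathrm{HaploScore}(S) \;=\; \frac{1}{|S|}\left(\frac{n_g}{\varepsilon} +
\frac{n_s}{\sigma}\right),$$

where $|S|$ is the number of genotyped sites in the segment and $(n_g, n_s)$
are the numbers of genotyping and switch errors that jointly minimise the
expression while reconciling the segment as a match on a single haplotype in
each individual. The score is a per-site count of observed errors weighted by
how surprising each error type is; true segments need roughly the expected
number of errors and score low, diplotype-only segments need many and score
high.

The minimisation is a shortest path in a layered DAG with one level per site
and four nodes per level — the haplotype configurations $(i, j)$, haplotype
$i$ of $a$ matched against haplotype $j$ of $b$. A node costs $0$ if the two
configured alleles agree and $1/\varepsilon$ if they disagree; an edge
between consecutive levels costs $1/\sigma$ per configuration coordinate that
changes ($0$, $1/\sigma$ or $2/\sigma$); edges from the source into level 1
and from level $|S|$ into the sink are free, so the initial configuration is
unconstrained. The dynamic program relaxes each of the four nodes of a level
over its four predecessors — exactly 16 predecessor comparisons per site
(`haploscore()` exposes the instrumented counter) — so the cost is
$O(|S|)$ per segment. `haploscore_batch()` additionally supports early
termination: node and edge weights are non-negative, so the best running
level cost is a lower bound on the final cost, and a segment can be declared
"above threshold" as soon as that bound exceeds `max_score * |S|` without
ever misclassifying it relative to the threshold.

Properties worth noting (all verified by the test suite):

* only the ratio $\sigma/\varepsilon$ matters for ranking: replacing
  $(\varepsilon, \sigma)$ by $(c\varepsilon, c\sigma)$ divides every score by
  $c$;
* the score is symmetric in the two individuals and invariant to relabelling
  either individual's haplotypes, because the initial configuration is free;
* `haploscore_bruteforce()` enumerates all $4^{|S|}$ configuration paths with
  an independent code path and is used as the oracle for the dynamic program
  on short segments.

### Numerical choices

Costs are carried through the DP as integer pairs $(n_g, n_s)$ per cell, not
floating sums; the real-valued score is formed once at the end. Cell
comparisons use the scaled cost $n_g\sigma + n_s\varepsilon$ (the path cost
multiplied by $\varepsilon\sigma > 0$), and exact ties are broken toward the
smaller switch count, which makes the reported $(n_g, n_s)$ deterministic.
A missing allele can never witness a mismatch, so any configuration touching
one has node cost 0; segment site counts $|S|$ are not reduced for missing
data, keeping $|S|$ equal to the number of genotyped sites of the segment
record. Edge weights depend only on the number of changed coordinates, with
no discount at sites whose node costs vanish.

## Error-rate estimators

The switch error rate is estimated by comparing statistically phased
haplotypes against trio-phased truth (`switch_error_rate()`): at each
phase-informative site (heterozygous, same genotype in both versions, not
excluded as ambiguous) the alignment of the statistical to the true
haplotypes is either direct or flipped, and each flip between consecutive
informative sites counts as one switch error. The reported rate divides the
total switch count by (individuals × all sites), the arithmetic that yields
0.003 per site from 3,629 switches over 52 children × 23,142 sites
(`switch_rate_from_counts()`). Two caveats are inherent to the counting
estimator: a pair of switches with no informative site between them is
invisible, which biases the estimate down by a factor of roughly
$1 - 2\sigma(1-p)/p$ where $p$ is the heterozygote fraction (negligible at
$\sigma \approx 0.003$ on common variants, noticeable at $\sigma = 0.01$);
and a flip of a single site counts as two switches. The estimator-recovery
tests therefore use fully heterozygous haplotypes, where every site is
informative and the estimator is exactly unbiased.

The genotyping error rate comes from replicate genotyping
(`genotyping_error_rate()`): discordant non-missing genotype pairs over
comparable pairs, halved to express it per allele. Without replicate data
the shipped default is $\varepsilon = 0.0075$; the shipped switch default is
$\sigma = 0.003$. These defaults parameterise `error_rates()`.

`trio_phase()` resolves the child's allele origins wherever Mendelian laws
determine them — any member homozygous, given consistency. All-heterozygous
sites are flagged ambiguous and Mendelian violations inconsistent; both are
excluded from switch counting and passed through unchanged, never repaired.

## Threshold matrices and filtering

`build_threshold_matrix()` reproduces the score-threshold construction:
validated segments are binned by genetic length (0.1 cM bins over 2–10 cM)
and, within each length bin, by parent-overlap fraction into 100 equal bins
of (0, 1]; each cell's threshold starts as the mean HaploScore of its
segments and is then replaced by the maximum over all cells of equal or
higher overlap in the same row. The running maximum enforces the operational
guarantee of `filter_segments()`: raising the target overlap never loosens
the score cut, so filtered sets are nested. Cells above a row's highest
populated overlap bin, and empty rows, stay `NA` — thresholds are never
interpolated into regions with no data, and segments whose row is missing are
dropped with a warning rather than silently kept. At filtering time, segments
outside the binned length range use the nearest bin: sub-2 cM segments are
rare when the detector already enforces a 2 cM minimum, and segments beyond
10 cM are almost always true, so the lenient longest bin is safe.

`site_density_filter()` removes segments from sparsely genotyped regions
(assembly gaps, platform artifacts): the chromosome is tiled with 1 cM
windows, and a segment is dropped when its own site density (sites/cM) falls
below the 10th percentile of window densities. The comparison is strict
(`<`), so a chromosome of uniform density filters nothing; an `inclusive`
switch and a `"window"` mode (drop segments overlapping a sparse window) are
available because the boundary convention and the unit of comparison are
both defensible either way.

## The synthetic trio cohort

Individual-level genotype data of the kind this method was developed on
cannot be redistributed, so the package carries a simulator
(`simulate_truth()`, `degrade()`, `detect_candidates()`) that makes every
stage testable with known ground truth. The default configuration
(`sim_config()`) is a desk-scale, array-like chromosome: 20,000 common
biallelic sites (allele frequencies uniform on 0.05–0.5, drawn
independently per site) over 60 cM / 60 Mb at uniform recombination rate,
200 individuals of whom 20 are father–mother–child trios, error rates at the
shipped defaults $\varepsilon = 0.0075$, $\sigma = 0.003$, and planted
intervals with lengths uniform on 2–8 cM.

Two kinds of ground truth are planted before children are generated:

* **True IBD** (150 by default): a contiguous haplotype stretch copied
  between two founders, at most one of whom is a trio parent. Children then
  inherit recombinant parental haplotypes (crossovers as a Poisson process on
  the cM axis), and every transmitted portion of a planted segment is
  recorded as an exact child-other truth segment.
* **Diplotype lures** (150 by default): intervals between a donor and a
  receiver made free of opposite homozygotes (the minimal change: where the
  two are opposite homozygous, one receiver allele is set to the donor's),
  with the receiver's phase otherwise uninformative, plus one genuinely
  shared 250-site haplotype block per ~2 cM. Lures are the synthetic
  counterpart of what linkage disequilibrium produces in real panels: long
  diplotype-compatible stretches seeded by short chance haplotype matches.
  With independently drawn sites, the per-site opposite-homozygote
  probability between unrelated individuals is ~0.07, so no multi-cM
  diplotype-compatible run — and hence no false candidate — can arise by
  chance alone; planting the lures explicitly puts the false-positive
  mechanism under direct control instead of tuning an LD model until it
  emerges. The block length guarantees that each block spans at least one
  full 100-site seed window wherever it falls, so lure detectability is
  governed by the seed criterion and not by window alignment luck, while the
  shared fraction stays small enough (≤ ~38% for the shortest lures) that
  lures still require many reconciliation errors and score high.

`degrade()` then emulates observation: per individual and site, a genotyping
error flips one uniformly chosen allele with probability $\varepsilon$, and
a switch error swaps the two haplotypes from that site onward with
probability $\sigma$ (suffix swap, matching the estimator's definition of a
switch between consecutive sites). Genotype errors are applied before
switches — chip first, phasing after. Every injected event is logged, so
tests can compare optimal reconciliations against the actual injections.

`detect_candidates()` is the deliberately permissive matcher: exact
haplotype-pair matches over consecutive non-overlapping 100-site windows
seed candidates; seeds extend site-by-site in both directions through any
non-opposite-homozygote site with a total budget of 2 opposite homozygotes
per match (the `-err_hom 2` allowance, read as a per-match total);
overlapping matches merge, ends never rest on an opposite homozygote, and
candidates shorter than 2 cM are discarded. Extension alternates one site
right, one site left, so the shared budget is spent evenly. In experiments,
within-trio parent–child pairs are excluded from the scan (`scan_pairs()`):
a parent and child genuinely share a haplotype chromosome-wide, which is
exactly the relationship the candidate analysis conditions away.

### What the simulator does and does not emulate

It emulates: Mendelian trio structure with map-driven recombination, planted
true sharing and its transmission, switch and genotyping noise at realistic
array rates, and the diplotype-compatible false-positive mechanism. It does
not emulate: linkage disequilibrium or any demographic/coalescent structure
(founder sites are independent), allele-frequency spectra of real chips
beyond a uniform common-variant band, batch effects, or missingness (the
data model supports missing alleles; the generator does not inject them).
Consequently, passing tests show that the scorer, estimators and filters
behave correctly on data whose error structure is known exactly — they do
not certify recall or precision values on any real cohort, where LD makes
false candidates more abundant and more heterogeneous than planted lures.

## Evaluation machinery and the robustness experiment

`roc_curve()` sweeps a score threshold over all distinct values (a segment is
called true when its score is strictly below the threshold; lower scores mean
more credible IBD throughout, and every function takes the orientation
explicitly) and `auc_mann_whitney()` computes the area as the tie-corrected
probability that a random true segment scores below a random false one —
identical to the trapezoid area under the full sweep. `precision_recall()`
reports per-length-bin curves with within-bin recall denominators, plus a
pooled mode. `binned_mean_overlap()` produces the length-by-score overlap
heat-map summaries.

`robustness_grid()` re-scores candidates over a logarithmic grid of switch
rates spanning $\varepsilon/100$ to $10\varepsilon$ with $\varepsilon$ fixed
(25 points by default) and reports the AUC per grid point and the worst
relative drop versus the grid optimum; it can simultaneously vary the
overlap threshold defining truth. Because the worst-case drop is a maximum
of a sampled statistic, and a single default-size cohort yields only a few
dozen false candidates above 3 cM, the single-cohort drop estimate carries
Monte Carlo noise of a few tenths of a percent concentrated at the grid
endpoints. `robustness_study()` therefore pools candidates from replicate
cohorts (30 by default, consecutive seeds, identical generator settings)
before computing the grid AUCs, which reports the same estimand at the
precision the comparison needs. The problem sizes used by the shipped
experiments are the `sim_config()` defaults throughout; the estimator
recovery checks use 50 individuals × 100,000 fully heterozygous sites.

## Known limitations

* The switch-error estimator undercounts tightly spaced switch pairs on
  common-variant data (see above); rates estimated on sparse or
  low-heterozygosity panels should be treated as lower bounds.
* The candidate detector is an emulation of seed-and-extend matching, not a
  reimplementation of any specific tool's heuristics; its per-match total
  opposite-homozygote budget is stricter than per-window allowances, which
  erodes candidate ends by up to a window when flank seeds are lost to
  noise.
* Lures control the abundance and structure of false candidates explicitly;
  conclusions about absolute false-positive *rates* on real data are out of
  reach of this simulation by design.
* All coordinates are 1-based closed site intervals against a single
  chromosome's site map; multi-chromosome analyses run the pipeline per
  chromosome.
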