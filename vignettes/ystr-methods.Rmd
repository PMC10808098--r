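---
title: "Y-STR haplotype diversity, distance, network and TMRCA methods"
author: "ystrtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Y-STR haplotype diversity, distance, network and TMRCA methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ystrtrace)
```

## The problem this package addresses

Surveys of a Y-chromosome haplogroup — a paternal lineage defined by a
single SNP such as P164 — commonly genotype carrier males at a panel of
Y-chromosomal short tandem repeats (Y-STRs). Each locus's allele is an
integer repeat count, and the joint vector across loci is the
individual's haplotype. From tables of such haplotypes, population
geneticists ask four questions that `ystrtrace` answers with one
consistent toolset:

1. How diverse is the haplogroup within each population (gene diversity,
   microsatellite variance)?
2. How differentiated are populations from one another (pairwise Rst with
   permutation significance, summarized by multidimensional scaling)?
3. How do the individual haplotypes relate mutationally (median-joining
   networks)?
4. How old is the haplogroup in each population (founder-based TMRCA
   estimation)?

The motivating use case is tracing a dispersal: under a serial-founder
colonization process, diversity and estimated ages should decay along the
route, population differentiation should track isolation, and networks
should show star-like clusters around founder haplotypes.

## Panel conventions

The 17-locus Yfiler panel is normalized to 15 loci before any statistic
is computed:

* **DYS389II** is typed as a compound amplicon that contains the DYS389I
  repeat stretch; the repeat count of its own stretch is obtained by
  subtracting DYS389I. `normalize_panel()` performs the subtraction once
  and flags the table so it cannot be applied twice; a DYS389II count not
  exceeding DYS389I is rejected as biologically impossible.
* **DYS385a/b** are two copies of a multicopy locus whose a/b assignment
  the kit cannot resolve, so both columns are excluded from haplotype
  statistics.

Missing calls are an explicit `NA` — never 0, which is not a possible
repeat count. Intermediate (non-integer) alleles such as 13.2 are rejected
by default because every downstream statistic is defined on integer repeat
scores; `read_haplotype_table(intermediate = "drop")` discards such
records instead when a survey contains occasional microvariants.

## Diversity statistics

**Nei average gene diversity.** Per locus $l$ with allele frequencies
$p_i$ over $n$ non-missing calls, the unbiased gene diversity is
$h_l = \frac{n}{n-1}\bigl(1-\sum_i p_i^2\bigr)$; `nei_average_gene_diversity()`
reports the mean of $h_l$ across the 15 loci with its SD across loci.
"Gene diversity based on Y-STR loci" admits a second reading — the
diversity of whole haplotypes treated as single alleles — so that variant
is provided separately as `nei_haplotype_diversity()`; the per-locus mean
is the default reading because it is the quantity that varies smoothly in
sparse surveys where nearly all haplotypes are distinct.

**Vp** is the mean across loci of the variance of repeat counts, on
complete haplotypes only (a record missing any locus is excluded rather
than zero-filled, which would deflate the variance). The unbiased
$(n-1)$ denominator is used: the choice matters for estimator-recovery
tests, where the sample variance of repeat counts must estimate
$\mu T$ without a systematic $1/n$ deficit. Units are squared repeat
units.

Both statistics are invariant under record order and under adding a
constant to all repeat counts at a locus, which the test suite checks
directly, and both are validated against brute-force pair-counting
oracles (gene diversity equals the fraction of differing pairs; the
unbiased variance equals half the mean squared pairwise difference).

## Rst distances and permutation testing

Rst is the microsatellite analog of Fst: repeat scores carry mutational
distance, so variance in repeat counts is partitioned within versus
among populations. `rst_pair()` computes, per locus, the one-level AMOVA
variance components from mean squared deviations
($\sigma^2_w$ = within-group mean square; $\sigma^2_a$ = (among-group
mean square − within-group mean square)/$n_c$ with the standard
unequal-sample-size coefficient $n_c$), sums both components across the
15 loci, and forms

$$R_{ST} = \frac{\sum_l \sigma^2_{a,l}}{\sum_l (\sigma^2_{a,l} + \sigma^2_{w,l})}.$$

Summing components before the ratio (rather than averaging per-locus
ratios) keeps loci with little variance from dominating through unstable
ratios. Because the among-group component is a difference of mean
squares, sampling noise can make Rst slightly negative when the groups
are effectively one population; negative values are reported as computed
in distance matrices and floored at zero only for MDS embedding.

Significance comes from reassigning individuals to the two groups with
group sizes preserved. The p-value uses the add-one correction
$p = (1+b)/(1+B)$, where $b$ counts permuted Rst values at least as
large as the observed one, so that a reported p is never exactly zero —
necessary when p-values are compared against a Bonferroni threshold
$\alpha/m$ ($m = k(k-1)/2$ pairs for $k$ populations;
`bonferroni_threshold()` also carries the conventional 4-decimal display
form). For small groups `permutation_test(method = "exhaustive")`
enumerates all $\binom{n_A+n_B}{n_A}$ assignments instead. Calibration:
under the null (both groups drawn from one simulated population) the
empirical type-I rate at nominal 0.05 sits within [0.03, 0.08] over 500
simulated pairs, and sampled p-values agree with exhaustive enumeration
within binomial error.

## Multidimensional scaling

`classical_mds()` is metric (Torgerson) MDS: double-center the squared
distance matrix, eigendecompose, and keep the top-$k$ positive-eigenvalue
axes. Fit is reported as Kruskal stress-1,
$\sqrt{\sum(d-\hat d)^2/\sum d^2}$, and as the squared correlation
between input and embedded distances. Exact Euclidean inputs embed with
stress 0 and $R^2 = 1$ (a test invariant). Statistical packages with
GUI MDS procedures typically run iterative (often non-metric) scaling
whose stress values depend on the variant, initialization and stopping
rule; printed stress values from such programs are therefore not
reproducible by any principled reimplementation, and no attempt is made
to match them. The classical solution is deterministic, which we value
more in a pipeline than a marginally lower stress.

## Median-joining networks

`median_joining()` implements the median-joining algorithm on weighted
single-step distances $d(a,b) = \sum_l w_l\,|a_l-b_l|$:

1. Build the $\varepsilon$-relaxed minimum spanning network over the
   current sequence set: link $\{u,v\}$ iff
   $d(u,v) \le m(u,v) + \varepsilon$, where $m(u,v)$ is the minimax path
   distance (the largest step on the path connecting $u$ and $v$ in a
   minimum spanning tree). With $\varepsilon = 0$ this is the union of
   all minimum spanning trees.
2. For each linked pair $(u,v)$ and each third sequence $t$, form the
   componentwise median (equivalently, $t$ clamped into
   $[\min(u,v), \max(u,v)]$ per locus — the unique middle value of
   three). New medians are added in batches of minimal connection cost
   $(d(u,v)+d(u,t)+d(v,t))/2$.
3. Repeat to convergence, then prune obsolete median vectors:
   iteratively remove inferred nodes with degree < 2 in the spanning
   network or lying on no shortest observed-to-observed connection.

Choices a user should know:

* **Epsilon defaults to 0**, the common software default; larger values
  admit more parallel connections (and more median vectors).
* **Weights** default to `locus_weights_inverse_variance()`: weight
  proportional to 1/variance, rescaled so the most variable locus has
  weight 1, rounded to an integer scale and capped (default 10);
  monomorphic loci receive the cap. Fast, volatile loci thereby
  contribute less to the topology.
* **Determinism.** All processing follows lexicographic haplotype order,
  so results are independent of record order — unlike interactive
  network programs, reruns are byte-identical.
* **Edge lengths.** Weighted distances drive construction; reported edge
  `steps` are always unweighted mutational steps
  $\sum_l |\Delta_l|$, which is what figure captions mean by "number of
  differences".
* **A structural caveat.** The emitted graph is exactly the
  $\varepsilon$-MSN of its final node set (checked in tests against an
  independent minimax oracle). It is *not* the quasi-median closure:
  shortest network paths between non-linked haplotypes can exceed their
  direct mutational distance, because with $\varepsilon = 0$ the
  algorithm does not insert every geodesic intermediate. Group
  separations from `group_separation()` (minimum network path between
  population groups, in steps) are therefore upper bounds on the direct
  single-step distance between their closest haplotypes.

## Founder-based TMRCA estimation

All three estimators date the time since a founder haplotype by the
mutational scatter of its descendants, assuming the symmetric single-step
mutation model (every mutation changes a repeat count by ±1 with equal
probability) and a star genealogy. The founder defaults to
`modal_founder()`: the per-locus modal repeat, ties broken toward the
value minimizing total distance to the sample, then toward the smaller
repeat. The field's literature rarely states its root choice, so
published point estimates are reproducible only conditional on this rule.

**Rho.** $\rho = \frac1n \sum_i \sum_l |x_{il} - r_l|$, with SD
$\sqrt{\rho/n}$ under the star approximation; age in generations is
$\rho / \sum_l \mu_l$. Two biases are inherent and documented rather than
hidden: on correlated (coalescent) genealogies $\rho$ is downwardly
biased relative to the true TMRCA; and even on a star, $\rho$ measures
*net* displacement, whose per-locus expectation is
$E\,|W(\mathrm{Poisson}(\mu T))| < \mu T$ once back mutations occur. The
test suite checks recovery against the exact random-walk expectation
(and shows the $\mu T$ first-order target is missed by more than Monte
Carlo error already at $T\mu \approx 0.1$ per locus).

**Weighted rho.** A mutation observed at a slow locus represents more
elapsed time than one at a fast locus. Each locus yields its own age
$t_l = \bar d_l/\mu_l$ (mean absolute founder distance over rate), and
the combined age is the unweighted mean of the per-locus ages
$T = \frac1L \sum_l t_l$ — equivalently, steps are weighted by
$\bar\mu/\mu_l$. The statistic is reported on the rho scale as
$\rho_w = T L \bar\mu$, so with equal rates $\rho_w \equiv \rho$
exactly (a tested algebraic identity). An inverse-variance combination
with weights $\propto \mu_l$ was considered and rejected: it collapses
algebraically to the unweighted rho age and thus cannot express the
slow-locus emphasis that motivates the method.

**ASD ("quadratic") dating.** The average squared distance
$ASD_l = \frac1n\sum_i (x_{il}-r_l)^2$ has expectation $\mu_l T$ under
the symmetric single-step walk *regardless of back mutations* — the
second moment is linear in time, which is the defining property of
discrete-random-walk ("quadratic") calculators. The age is
$T = \sum_l ASD_l / \sum_l \mu_l$. In simulations at $T\mu > 0.5$ per
locus the ASD age's bias is markedly smaller in magnitude than rho's
(tested).

**Uncertainty and reporting.** The rho age SD is analytic
($\sqrt{\rho/n}/\sum\mu$); weighted-rho and ASD age SDs come from a
seeded nonparametric bootstrap over individuals (default 1,000
resamples), since no closed form is standard. `date_population()` and
`tmrca_report()` emit all three estimators at 25 and 30 years per
generation (the two generation-time conventions used for Y-chromosome
dating), with years rounded to integers for display.

Mutation rates are supplied per locus as a provenance-labelled
`mutation_rate_table`; the package bundles a clearly-labelled synthetic
15-locus table (rates 0.0004–0.0063 per generation, the right order of
magnitude for Yfiler loci) for simulation and examples only — real
dating should use rates retrieved from a mutation-rate database, with
the retrieval date recorded in `source_label`.

## The simulator: what it emulates and what it does not

`simulate_star()` and `simulate_kingman()` generate haplotype tables on
the two genealogy regimes that matter for founder dating: independent
lineages (where rho-type estimators are calibrated) and Kingman
coalescent trees rescaled to a fixed depth (where shared internal
branches induce the correlation that biases rho downward). Mutations are
Poisson per branch and locus, each ±1 with probability ½.
`simulate_split()` lets a common founder drift along two independent
ancestral branches for `split_time` generations before within-population
evolution, the minimal model that moves expected Rst from ~0 (zero split)
toward 1 (deep split, shallow populations). All simulators are
bit-reproducible under a seed and emit tables that pass the package's
own validation.

Deliberate omissions: no multi-step mutations, no allele-range
constraints, no migration, no selection, no population growth models.
Passing calibration tests on these simulations therefore demonstrates
estimator correctness under the stated model, not robustness to the
messier mutation processes of real Y-STRs (microvariants, locus-specific
directionality), which is why intermediate alleles are surfaced loudly
at the I/O boundary rather than silently coerced.

Default study conditions used by the test suite and the acceptance
script — chosen once as representative of desk-scale calibration and
not tuned afterwards — are: 15 loci at $\mu = 0.002$/generation, founder
at 20 repeats, $n = 50$ lineages, depths of 50–300 generations, 200
replicates per condition, 500 null pairs at 399 permutations for the
type-I check, and a five-population serial-founder chain (n = 102,
depths 160→50 generations, 40-generation founder gaps) for the worked
analysis under `analysis/`.

## Numerical and degenerate-input policy

* Zero total repeat variance makes Rst undefined (error), as does any
  group with fewer than two complete haplotypes.
* A single-individual population dates to $\rho = 0$ with a warning that
  a TMRCA of one lineage is undefined.
* Monomorphic loci get the weight cap in network weighting; an all-zero
  distance matrix embeds at the origin with stress 0.
* Ties are broken deterministically everywhere (lexicographic haplotype
  order; smaller repeat value for founder modes).
* The add-one permutation p-value is bounded below by $1/(1+B)$, never 0.

## Known limitations

* Rho-based dating inherits the star-genealogy assumption; on strongly
  correlated genealogies all founder-based ages are relative measures,
  not calendar dates.
* The median-joining network is reconstructed from the final relaxed
  spanning network; alternative equally-parsimonious connections outside
  the MSN are not represented, and the quasi-median closure is not
  computed (see the structural caveat above).
* Classical MDS of Rst matrices treats them as dissimilarities; strongly
  non-Euclidean matrices lose the variance carried by negative
  eigenvalues, which the reported eigenvalue vector makes visible.
* Frequencies of a haplogroup in a population require survey totals that
  a carriers-only haplotype table cannot supply; `diversity_summary()`
  accepts them as side information.
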