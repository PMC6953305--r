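---
title: "Mapping combining-ability loci with multi-allelic LD-block markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping combining-ability loci with multi-allelic LD-block markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcaldb)
```

## The problem

Hybrid rice is bred from cytoplasmic male-sterile (CMS) females crossed to
restorer males. What a parent transmits to its hybrids is summarized by its
*general combining ability* (GCA): the average deviation of its crosses from
the overall cross mean. Improving the GCA of a parent for grain-quality
traits by phenotypic selection alone is slow — each candidate parent must be
crossed, grown, and its hybrids' grain assayed. If genomic loci associated
with GCA can be found, marker-assisted selection can pyramid favorable
alleles into a maintainer or restorer line directly.

`gcaldb` implements that analysis end to end for North Carolina design II
(NCII) experiments: every female crossed with every male, phenotypes
measured on replicated F2 bulks, parents genotyped once.

## Models

**GCA estimation.** Per trait, replicate values of the crosses of parent
$i$ follow

$$ v_{ik} = \mu + g_i + \varepsilon_{ik}, $$

so on a balanced complete factorial the estimator of $g_i$ is the mean of
all replicate values of parent $i$'s crosses minus the grand mean of its
NCII set. Effects are computed independently per set (e.g. one *indica* and
one *japonica* factorial) and sum to zero within each (set, parent class).
Replicate-level values feed a two-way ANOVA (female, male, interaction,
error, via `stats::aov`); the error mean square drives least-significant-
difference letter displays at $\alpha = 0.01$ (shared letters = not
significantly different). Averaging replicates within cross before effect
computation would give identical effects on balanced data; the replicate-
level form is kept because the ANOVA needs it. Missing crosses are an error
naming the cross: the estimator is only unbiased on the complete factorial.

**SNPLDB markers.** Nearby SNPs travel in linkage-disequilibrium blocks.
Rather than testing each SNP, SNPs of one block are collapsed into a single
multi-allelic marker whose alleles are the observed haplotypes — fewer,
better-populated tests. Blocks are found by the confidence-interval
(Gabriel) method on pairwise $D' = |D|/D_{max}$: a pair is in *strong LD*
when the likelihood-based 90% CI of $D'$ has lower bound $\ge 0.70$ and
upper bound $\ge 0.98$, and shows *strong recombination* when the upper
bound is $< 0.90$; an interval of SNPs is a block when its outermost pair is
in strong LD, at least 95% of its informative pairs (strong LD or strong
recombination) are in strong LD, and its span is at most 200 kb. SNPs
outside every block become singleton markers. Markers carry minor-allele
frequency ($1 - \max_i p_i$), gene diversity ($1 - \sum p_i^2$), and
polymorphism information content
($1 - \sum p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$).

**Association.** Per trait and marker, a single-factor ANOVA of the pooled
per-parent GCA effects across allele classes,

$$ y_{ij} = \mu + a_i + \varepsilon_{ij}, $$

reporting $F$, $P$ and $R^2 = SS_{between}/SS_{total}$. Significance uses a
fixed per-trait $\alpha$: 0.001 by default, 0.01 for chalky area size and
amylose content. There is deliberately **no** multiple-testing correction
and no kinship/structure correction — the model is the plain single-factor
test; both omissions are stated limitations (below).

**Superior alleles.** Each of the nine grain-quality traits has a polarity:
brown/milled/head rice rate and gel consistency are higher-better; chalky
grain percentage, chalky area size, chalkiness degree, gelatinization
temperature (measured as alkali spreading) and amylose content are
lower-better. At a significant locus the superior allele is the class with
the most favorable mean GCA under that polarity. Per-parent tallies of
superior alleles, homozygous-versus-carrier group-mean increments
($({\bar x}_2 - {\bar x}_1)/{\bar x}_1 \times 100$), and cross rankings by
the union of two parents' superior loci support pyramiding decisions.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_maf` | 0.01 | minimum minor-allele frequency per SNP |
| `max_distance_bp` | 200 000 | maximum block span (bp) |
| `ci_strong_low`, `ci_strong_high` | 0.70, 0.98 | strong-LD CI bounds |
| `ci_recomb` | 0.90 | strong-recombination CI bound |
| `min_strong_frac` | 0.95 | strong-LD fraction among informative pairs |
| `rare_count_threshold` | 2 | block haplotypes seen in fewer parents merge into `"other"` |
| `alpha_policy()` | 0.001; CAS, AC 0.01 | per-trait significance |
| `lsd_alpha` | 0.01 | LSD letter grouping level |
| `min_group_size` | 2 | smallest allele class tested |

The MAF threshold is applied as a **minor**-allele frequency. The upstream
description of the genotype filter reads "minimum major allele frequency";
a major-allele threshold of 0.01 would be vacuous, so minor-allele
frequency is taken as the intended meaning, and the threshold is
configurable.

## Numerical choices

* **$D'$ CI.** The multinomial likelihood of the estimated haplotype counts
  is evaluated on a fixed 101-point grid over $[0,1]$ (resolution is a
  config knob); the bounds are the grid points one step outside the 5% and
  95% cumulative-probability crossings, the convention of the standard
  block-partitioning software. With the CI used only against the 0.70 /
  0.90 / 0.98 thresholds, grid resolution 0.01 is immaterial.
* **Phase ambiguity.** Double heterozygotes are resolved by a two-haplotype
  EM (initialized at linkage equilibrium, tolerance $10^{-6}$, at most 100
  iterations). Near-inbred panels contain almost none, so this is nearly
  moot but keeps the estimator well defined.
* **Overlapping candidate blocks** are resolved greedily, largest bp span
  first, ties to the leftmost start — deterministic and matched exactly by
  the brute-force oracle used in the tests.
* **Imputation** is per-SNP modal genotype, ties toward homozygous
  reference then heterozygous. It is deterministic and idempotent; a
  haplotype-HMM imputer would be better on low-coverage data but no worked
  example here depends on the imputation choice.
* **Ties** elsewhere: superior-allele ties break to the lexicographically
  smallest allele id; within-block heterozygotes are assigned the pure
  haplotype matching the majority of member-SNP calls, ties to `"other"`.
* **Degenerate association inputs** are flagged, not thrown: one usable
  allele class marks the result untestable; zero within-class variance with
  distinct means reports the smallest representable positive P with a flag.
* **Boundary rule** in quality scoring: a value on a level boundary takes
  the better level.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are the study
conditions the analysis assumes.

* **Parents** are near-inbred: each parent draws one haplotype per block
  and is homozygous for it, with residual heterozygosity 0.02 and missing
  calls 0.05 per call — plausible rates for genotyping-by-sequencing of
  inbred rice; the source data report neither, so these are stated
  defaults, exposed in the config, chosen once.
* **Haplotype patterns** tile the binary representation of the haplotype
  index across member SNPs, so 2–3-haplotype blocks are in complete
  pairwise LD (at most three gametes present) — the structure the block
  finder is meant to detect.
* **Phenotypes** compose $\mu + g_{female} + g_{male} + s_{fm} + e$ with
  i.i.d. normal SCA deviations and replicate errors; true GCA effects are
  the sum of the parent's QTL allele effects, centered within (set, class).
  SCA is included although the downstream model never estimates it: GCA
  estimation should be tested under that contamination.
* **QTL effects derive from the drawn (true) haplotypes**, recorded by the
  generator alongside the noisy calls: heterozygosity and missingness are
  call-level measurement artifacts and must not alter the simulated
  biology. The association stage still sees the noisy calls.
* **Not emulated:** coalescent recombination gradients, selection,
  population structure beyond the two-set partition, linked QTLs, or
  trait-trait correlations. Passing tests therefore demonstrate correctness
  of the estimators and the block/association machinery under the stated
  model, not robustness to confounded real-panel structure.

## Experiment sizes

The packaged experiments use sizes chosen to make Monte Carlo noise small
relative to the bands they are checked against: the planted-QTL recovery
experiment runs 200 replicates of a 14-parent, 8 × 6 NCII with a
3-trait-unit QTL against a replicate error SD of 1 (recovery ≈ 0.96); the
null type-I experiment pools 10 independent 33-parent simulations of 1000
singleton markers each (10 000 tests). The oracle-equivalence property runs
100 random panels of at most 12 SNPs against brute-force interval
enumeration.

## Quality scoring

`score_trait()`/`comprehensive_score()` grade trait values into five levels
(level 1 best) with per-level scores; nine traits at level 1 total the full
90 points. The packaged YAML table is **synthetic**: the real five-level
cut-offs live in supplementary material not distributed with the source
text, so the shipped thresholds are plausible placeholders in the style of
the NY/T 593-2002 standard and nothing downstream depends on them. Replace
`inst/extdata/level_table_synthetic.yaml` with real thresholds for
production use.

## Known limitations

* The single-factor association model ignores kinship and population
  structure; with two subspecies pooled, alleles private to one subspecies
  can associate with any trait differing between subspecies. `per_group =
  TRUE` scans sets separately as a check.
* Fixed per-trait $\alpha$ with no multiple-testing correction inflates the
  family-wise error over thousands of markers; significant sets should be
  read as candidate lists.
* The published raw sequencing panel is not redistributable, so the
  published per-locus $P$/$R^2$ values cannot be recomputed from scratch;
  the packaged transcriptions of the published tables are verified by
  internal arithmetic (row counts, column sums, increment recomputation)
  instead.
* Mode imputation underestimates rare-allele carriers relative to a
  haplotype-aware imputer when missingness is high.

## A worked run

```{r, eval = FALSE}
parents <- simulate_parents(example_blocks(), 14, seed = 7)
qtl <- qtl_spec("BRR", 1:3, c("222" = 3))
sim <- simulate_ncii(parents, list(qtl), sim_config(8, 6, seed = 7))
res <- run_pipeline(parents, sim$traits, sim$design,
                    cfg = run_config(seed = 7), out_dir = "results")
res$scan$significant
res$tally
head(res$cross_ranking)
```
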