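---
title: "Family-based exome variant prioritization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based exome variant prioritization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FamVarPrio)
```

## The analysis model

FamVarPrio implements the post-sequencing half of a family-based exome
study of a common, genetically heterogeneous condition such as adolescent
idiopathic scoliosis: multiplex multigeneration families, each with a few
(3--5) affected members exome-sequenced, under the hypothesis that
low-frequency, functionally damaging variants co-occur in distantly
related affected relatives.  The pipeline has four analytic stages:

1. **Per-family filter cascade.**  Within each family, a variant is
   retained iff it (i) belongs to a protein-altering consequence class
   (nonsynonymous SNV, coding indel, stop gain, splice site), (ii) is not
   a known artifact, (iii) has a reference-population minor allele
   frequency strictly below 0.05 or is absent from the frequency database
   ("novel"), (iv) is scored damaging by at least one of SIFT, Polyphen2,
   LRT and MutationTaster *if* the site is annotated in the prediction
   database, and (v) is carried by **every** sequenced member of the
   family.

2. **Cross-family aggregation.**  Retained sets are combined into a
   gene-sharing table (gene, number of distinct carrying families, an
   identical-variant flag for exact `chrom:pos:ref:alt` recurrence), a
   census of genes shared by at least *t* families, and summary tables
   (consequence and frequency-bin breakdowns, per-chromosome and
   per-family counts, private-gene share).

3. **Gene-set overrepresentation.**  For a term with $K$ members in a
   background universe of $N$ genes, $k$ of which occur in a mappable
   gene list of size $n$, the raw p-value is the hypergeometric right
   tail
   $$p = \sum_{i=k}^{\min(n,K)} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}},$$
   i.e. the one-sided Fisher exact test of the 2x2 enrichment table,
   or its conservative EASE variant (below).  Reported per term: count
   $k$, $100\,k/n$, fold enrichment $(k/n)/(K/N)$, raw and adjusted p.

4. **Co-segregation classification.**  For candidate variants genotyped
   in additional family members, carriers are tallied among affected and
   unaffected members and the pattern is called `full` (all affected
   carry, no unaffected does), `none` (both an affected non-carrier and
   an unaffected carrier exist) or `partial` (exactly one violation).

## Filtering rules and their edge cases

**Frequency boundary.**  The cutoff is exclusive: a variant at exactly
the threshold is dropped; retention requires MAF $< 0.05$ or a novel
site.  The 0.05 default is deliberately more permissive than typical
rare-variant thresholds (often 0.01), because a condition affecting 2--3%
of the population can plausibly be driven by alleles in the 1--5% range.

**Carrier definition.**  "Shared" means allele presence (het or hom_alt),
not identical zygosity; requiring identical genotypes would spuriously
drop hom/het mixtures arising in inbred loops or from hemizygous calls.
Hemizygous single-allele genotypes (relevant for X-linked genes in males)
are accepted as written and count as carrying.

**Missing genotypes.**  A missing genotype in any sequenced member fails
the sharing test.  This is the conservative choice: no imputation is
attempted, and a variant unverifiable in one discovery member is not a
family-shared candidate.  A variant with *no* genotyped sequenced member
is an error, not a silent drop.

**Damaging rule conditionality.**  The prediction rule applies only to
variants present in the prediction database; unannotated variants pass by
default (`retain_if_unannotated = TRUE`).  Coding indels are largely
absent from SNV-oriented prediction databases, so dropping unannotated
sites would silently remove most frameshifts.

**Artifact strip.**  Recurring platform artifacts are supplied as a
caller-side blacklist of exact variant keys (default empty), plus a
per-variant flag; keying on position-and-alleles rather than gene is the
narrowest rule that removes a known bad call without touching real
variation nearby.

**Stage order.**  All five predicates are row-wise, so the retained set
equals the intersection of the per-predicate pass sets; the documented
order (consequence, artifact, frequency, damaging, sharing) affects only
the funnel counts used for auditing.

**Genotype handling.**  Genotypes are treated as unphased throughout;
compound-heterozygote phasing is out of scope.  Multiallelic records are
decomposed into one entry per alt allele, and a sample called `1/2` is a
het carrier of both entries.

## Enrichment statistics

`hypergeomRightTail()` evaluates each tail term in log space
(`lchoose` + log-sum-exp), so p-values far below double underflow in the
individual binomials remain accurate.  `easeScore()` is the jackknifed
variant popularized by annotation servers: one annotated gene is removed
from the list before testing, giving the tail at $(k-1)$ hits in a list
of $(n-1)$ with the background unchanged.  A singleton hit therefore
scores exactly 1, and the EASE score is everywhere at least the plain
tail (verified as a property over exhaustive grids in the tests).

**Background choice.**  The default background universe is the set of
genes covered by the supplied term collection.  Annotation services use
proprietary internal universes; because fold enrichment and p-values
depend on $K/N$, results from such services are comparable only in their
$100\,k/n$ column, which depends solely on the submitted list.  The
package therefore treats the percentage column as the reproducible
reporting surface and documents fold/p as background-relative.  An
explicit `background` argument supports a custom universe.

**Multiplicity.**  Benjamini--Hochberg step-up adjustment is the default
(`stats::p.adjust` underneath); Bonferroni and no adjustment are
available.  Terms with fewer than 2 list hits are suppressed, matching
common annotation-server defaults.

**Rounding.**  All reported percentages are computed on unrounded ratios
and then rounded half-up (`roundHalfUp()`), the convention of printed
tables, rather than R's round-half-even: integer percent for consequence
and frequency-bin tables, two decimals for the enrichment percentage
column, one decimal for the private-gene share.

## The segregation rule is a convention

Published family studies typically report co-segregation qualitatively
("segregated", "partial", "no segregation") without a quantitative
definition.  The three-way rule implemented here (two possible
violations: an affected non-carrier, an unaffected carrier; `full` = no
violation, `none` = both, `partial` = exactly one) is a declared
operationalization, not an inference of any particular study's intent.
Reduced penetrance and phenocopies are not modeled in the call;
`confirmed_negative` members (examined and found unaffected) pool with
unaffected, and `unknown`-status members are excluded from the tallies.
Calls with no additional affected or no additional unaffected member
beyond the discovery set are flagged `low_information` rather than
suppressed.

## What the synthetic cohort emulates

`simulateCohort()` generates the full input of the pipeline under one
seed.  Defaults encode the cohort structure the pipeline is designed
for:

| parameter | default | rationale |
|---|---|---|
| `n_families` | 23 | multiplex-cohort scale |
| `sequenced_range` | 3--5 | affected members sequenced per family |
| `depth` | 3 generations | multigeneration pedigrees |
| `variants_median`, `variants_range` | 51, 11--128 | per-family retained-variant counts (lognormal, log-sd 0.61 spans the range at ~2 sd) |
| `maf_mixture` | 12/18/22/48% | novel, <0.001, 0.001--0.01, 0.01--0.05 frequency shares |
| `n_background_genes` | 12,000 | exome-scale gene universe |
| `n_term_sets`, `genes_per_term` | 60, 120 | 1% per-term coverage, annotation-collection scale |
| `planted_term_fold` | 2.5 | the magnitude of the strongest cellular-component enrichments such cohorts show (~2--2.6) |
| `prediction_sensitivity` | 1.0 | P(damaging call | planted, annotated) |
| `decoy_rates` | 0.3/0.3/0.2/0.2 | unshared / high-frequency / all-benign / non-whitelisted decoys per planted variant |
| `recurrent_variant_prob` | 0.03 | identical-key recurrence across families |
| `penetrance`, `phenocopy_rate` | 1, 0 | affection equals carrier status by default |

Each family receives a carrier lineage rooted in one founder; planted
variants are forced heterozygous along that lineage (Mendelian-consistent
by construction: every carrier non-founder has a carrier parent) and are
therefore carried by all sequenced members.  Decoy classes each violate
exactly one cascade stage, in known counts recorded in the truth table,
so cascade recall and per-stage false retention are exactly measurable.
Affection status is assigned deterministically from carrier status at
the defaults; the `penetrance`/`phenocopy_rate` knobs de-idealize this
for stress-testing segregation calls.

**Planted-term calibration.**  The probability that a planted variant's
gene is drawn from the planted term is calibrated by fixed-point
iteration so the *realized* fold enrichment in the distinct retained
gene list matches `planted_term_fold`.  Naive proportional excess
undershoots for two reasons: repeated draws collapse to fewer distinct
genes (term saturation), and the default testing background is the
term-covered universe, not all genes.

**What is deliberately not emulated.**  No linkage disequilibrium, no
sequencing-error or genotype-missingness model, no human exome geometry
(positions are uniform over toy contigs; per-chromosome counts are
format-level only), and no background carriers of a family's variants in
*other* families — the sharing rule's null behavior is exercised by the
unshared decoy class and by the binomial founder-draw mode of
`transmitGenotypes()` instead.  Passing tests therefore demonstrate the
pipeline's correctness on idealized inputs, not robustness to genotyping
error or population structure in real exomes.

## Numerical choices and test problem sizes

- The hypergeometric implementation is validated against two independent
  oracles: exact summation with `choose()` exhaustively for $N \le 48$
  (where every binomial coefficient is exactly representable in a
  double, $\binom{48}{24} < 2^{53}$), and `stats::phyper` on randomized
  configurations up to $N = 200$, both at $10^{-12}$ relative error.
  Exact rational arithmetic beyond $N \approx 50$ would require big
  integers, which the implementation avoids by working in log space.
- EASE conservativeness is asserted with an absolute slack of $10^{-12}$
  to absorb machine-epsilon noise where the two tails coincide at 1.
- Cascade recall/decoy suites run 100 seeds on reduced cohorts (3
  families, median 18 planted variants) — the recovery properties are
  size-invariant — while the planted-term power experiment runs 100
  replicates at the full default conditions (23 families, median 51).
- Retained variants are ordered by (chrom, pos, alt) with plain
  lexicographic chromosome order; ties beyond that cannot occur because
  variant keys are unique.

## Known limitations

- Gene assignment is one symbol per variant entry; overlapping-gene
  loci rely on a primary-gene annotation key or fall back to the first
  listed symbol (warned and counted).
- The enrichment module tests terms flat: no ontology-graph propagation
  and no similarity clustering of related terms.
- The segregation call is qualitative; no LOD-score linkage support is
  computed.
- Left-alignment/normalization of indels is trusted to the upstream
  caller; identical-variant recurrence is exact key equality, so the
  same indel represented two ways would not be flagged.
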