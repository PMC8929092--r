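---
title: "Homozygosity haplotype mapping: model, algorithms and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homozygosity haplotype mapping: model, algorithms and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hhscan)
```

## The model

In a founder population, affected relatives who inherit a disease
variant from a common ancestor also inherit the surrounding
chromosomal segment identical by descent (IBD). Inside such a segment
two carriers can never be homozygous for *opposite* alleles: at least
one of them carries the shared ancestral allele at every marker. The
homozygosity haplotype (HH) method exploits this negative signature.
Each individual's genotypes are reduced to the homozygous calls (the
*homozygosity haplotype*); a *dhSNP* is a marker where two individuals
are homozygous for opposite alleles; a *Region with Conserved
Homozygosity Haplotype* (RCHH) is a maximal dhSNP-free interval,
bounded by dhSNPs or chromosome ends, whose genetic length reaches a
cutoff. No phasing or haplotype reconstruction is needed — zygosity
and allele identity suffice — which is why the method scales to
hundreds of thousands of SNPs and tolerates both dominant and
recessive inheritance (one shared copy is enough to forbid discordant
homozygosity).

Because homozygous runs also arise by chance, the cutoff and the
marker density govern specificity: short dhSNP-free stretches are
ubiquitous, long ones are not. The expected genetic length of the
ancestral segment for two affected relatives separated by m and n
meioses from the ancestor is `rca_expected_length(m, n)` (in Morgans):
2^(−m+1) when n = 0, 3/4 when m = n = 1, and 2^(−m−n+2) otherwise —
close relatives share long segments, distant ones short segments, so
sparse panels and distant relationships both argue for adjusting the
cutoff.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `cutoff_cm` | 7 | cM | minimum RCHH genetic length; 7 cM suits a sparse, unevenly spaced panel where chance homozygosity runs are long; dense arrays or distant relatives justify ~3 cM |
| `window_cm` | 1 | cM | granularity of representative selection; smaller windows find more local optima at linear cost |
| `neg_log10_threshold` | 1.2 | −log₁₀(p) | first-stage screen, p ≤ 0.06; deliberately liberal because stage two (variant filtering) does the final pruning |
| `epsilon` | 0.001 | per call | assumed genotyping error rate for the reliability check, typical for array data after QC |
| `reliability_reps` | 10⁵ | replicates | Monte Carlo resolution ~3·10⁻³ at the 0.001 decision bound |
| MAF cutoff | 0.001 | frequency | rare-variant inclusion bound; unknown frequency counts as potentially rare |

## Representative regions: the design choice

The published method divides each autosome into small windows and
selects per window the representative RCHH shared by the largest
number of patients, but does not define multi-subject sharing. We
define: a set S shares interval I exactly when **every pair** within S
is dhSNP-free inside I. This pairwise-consistency closure keeps
sharing monotone under subsetting and reduces to the pairwise
definition at |S| = 2.

Finding the largest S for an interval is a maximum-clique problem, so
the scan is greedy — and the interval must *shrink* as the set grows.
An earlier design that grew S over a fixed generating-pair interval
was implemented and rejected: the region over which k patients all
share is the intersection of their pairwise segments and is in general
far shorter than any single pair's segment, so sharing counts
saturated at 2–3 and truly shared segments were never ranked first.
The shipped algorithm, per window: start from each patient pair whose
dhSNP-free segment overlapping the window is at least `cutoff_cm`
long; repeatedly add the patient whose addition leaves the longest
dhSNP-free segment (over all pairs in the enlarged set) that still
overlaps the window and still meets the cutoff, breaking ties by
sample id; stop when no addition survives. The window's representative
maximizes the sharing-set size, then genetic length, then leftmost
position; windows represented by the same candidate collapse into one
row. Controls share a representative when they have no dhSNP against
*any* member of its patient set inside it — sharing is judged against
the established ancestral haplotype, mirroring the patient definition.

Two related choices: representative intervals are dhSNP-bounded but
**not** trimmed to markers homozygous in all members (for |S| = 6 such
markers occur at rate ≈ 0.5⁶ and trimming would destroy real regions;
pairwise RCHHs from `pairwise_rchh()` do keep the classical trim to
the outermost pair-homozygous markers), and intervals may extend
beyond their window (the window anchors the search; the region is
whatever the data support there).

## The pool-comparison statistic

Patient and control sharing proportions are compared with the pooled
two-proportion z statistic and a one-sided upper-tail normal p-value
(the alternative of interest is patients sharing *more*). When the
pooled proportion is 0 or 1 there is no information either way and the
test returns z = 0, p = 0.5 rather than dividing by zero. No
multiple-testing adjustment is applied at this stage, by design. The
printed p-values of the original study's region list are *not*
reproduced by this statistic in either one- or two-sided form (e.g.
11/11 vs 17/26 yields 1.91 one-sided against a printed 1.63); the
original program's exact formula is not recoverable, so the packaged
region list is treated as a fixture, not as a recomputation target.
Families with no genotyped controls get representatives with n₂ = 0
and an undefined p-value; `significant_rchhs(keep_na = TRUE)` lets
them through to the variant stage, since excluding a family for
lacking controls would discard exactly the families the second stage
can still serve.

## Genotyping-error reliability

A single miscalled genotype can convert a concordant marker into a
dhSNP and truncate a true RCHH below the cutoff. The check perturbs
every non-missing call of the pooled individuals inside a region —
each call is replaced, with probability ε, by one of the other two
genotype states chosen uniformly — and estimates the probability that
at least one dhSNP appears in a pair that had none before. On a single
concordant homozygous marker and two individuals this probability is
exactly ε(1−ε) (one member must flip to the opposite homozygote, the
other must stay), which the test suite verifies against the Monte
Carlo estimate at 10⁵ replicates. The published reliability bound
(probability < 0.001) is kept as the `reliable` flag, but note its
stringency: over a ~10 cM region with 15 patient pairs at ε = 0.001
the event probability is naturally of order 0.1, so long regions
rarely clear it — the estimate itself, not the flag, is the useful
quantity for comparing regions. The simulation is seeded and chunked;
"Monte Carlo" here is plain independent-replicate simulation (no
chain), as nothing in the error model requires one.

## The synthetic cohort

The generator emulates the statistical structure the method assumes,
at desk scale:

* a three-generation pedigree: a founder couple, four married-in
  children, six grandchildren per couple (34 individuals);
* a panel of four chromosomes (120/100/90/80 cM) at 5 markers/cM with
  founder allele frequencies uniform on [0.05, 0.5]; bp positions are
  synthesized as round(cM·10⁶) so both coordinates stay monotone;
* gene dropping with crossovers as a Poisson process of rate 1 per
  Morgan (Haldane, no interference — the simplest process consistent
  with a cM map);
* a 10 cM tagged founder segment (chr 1, 50–60 cM) that co-segregates
  with affection: the six designated affected grandchildren are
  conditioned to inherit it, unaffected descendants are conditioned
  not to. Transmitting parents are obligate carriers (incomplete
  penetrance) and are ranked last for control genotyping, so the
  default control pool is 18 unaffected grandchildren plus two
  married-in spouses;
* per-call genotyping error 0.001 and missingness 0.01;
* an annotated variant table with one causal record inside the
  implant (unknown frequencies, non-synonymous, carried exactly by
  the founder-segment carriers) plus 30 noise records of which a
  configured 30% are constructed to pass the rare-variant filter.

The co-segregation conditioning deserves a note: conditioning *only*
the affected (forcing the tagged haplotype down their lineages) leaves
every middle-generation parent an obligate carrier and roughly half
the other grandchildren carriers, so the implanted region is shared by
much of the control pool and is not differentially shared at all —
parameter recovery then fails for structural reasons, not statistical
ones. A segment that causes (with incomplete penetrance) the affection
is the world the method actually assumes. Marker density matters the
same way: at 2 markers/cM, chance 7 cM dhSNP-free runs among a handful
of patients are common and outrank the true region; 5 markers/cM is
still ~7× sparser than the emulated array but dense enough that chance
runs are rare.

What a green recovery test establishes: under this generative model,
the scan ranks a region overlapping the implant first and the causal
variant survives filtering, in at least 45 of 50 seeds. What it does
not establish: performance under linkage disequilibrium, uneven marker
spacing, population substructure, phenocopies, or real array error
profiles — none of which the generator models.

## Numerical and degenerate-input choices

* Coordinates are 1-based, fully closed intervals throughout; variant
  vs region overlap is any-base overlap of closed intervals.
* Genome builds are opaque tags; interval containment across differing
  tags warns and proceeds (no liftover). The packaged variant table
  carries an explicitly ambiguous tag because its header and its
  generating methods disagree; 4 of its 15 rows fall outside their
  stated region as printed and are flagged, never silently corrected.
* Chromosomes with fewer than two markers yield no regions (not an
  error); a marker-count mismatch between PED and MAP is an error
  naming the row.
* PLINK MAP files carry no allele labels, so ref/alt cannot be
  recovered from PED/MAP alone (monomorphic markers are ambiguous).
  The writer emits a `.alleles` sidecar; the reader falls back to
  major-allele-as-reference with alphabetic tie-break.
* "Unknown" population frequency means an absent value; a recorded
  0.0 is a known frequency below any threshold and passes. Both
  frequency sources must individually be unknown or below the cutoff.
  "Benign" matches exactly (case-insensitive) — "likely benign" is
  retained, as no finer scheme is defined.
* Missing genotype calls never create nor break a dhSNP; they are
  absent from the homozygosity haplotype by construction.
* All simulations (cohort, variant table, reliability) save and
  restore the caller's RNG state and are reproducible from their seed
  arguments alone.

## Known limitations

* The sharing-set search is greedy, not exact maximum-clique; on
  adversarial instances it can under-count the sharing set (the test
  suite exercises separable and simulated instances, where it is
  exact in practice).
* One-sided testing means regions shared predominantly by controls
  are never flagged; that is the intended direction of the screen.
* X-chromosome handling, LOD-score linkage, phasing, imputation and
  liftover are out of scope; annotation is consumed, never computed.
* The published region list's p-values are fixtures (see above), so
  cross-checks against them are structural (row counts, thresholds,
  extrema), not statistical.
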