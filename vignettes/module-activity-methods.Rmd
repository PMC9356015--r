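---
title: "Methods: cross-species DEG overlap and functional-module activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species DEG overlap and functional-module activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degmods)
```

# The scientific problem

Contiguous gene-dosage lesions such as heterozygous microdeletions
rarely act through a single critical gene. A recurring analysis
pattern for such lesions combines (i) differential expression in an
accessible tissue of a small patient cohort, (ii) a cross-species
replication in a syntenic animal model, (iii) network context — which
biological processes are perturbed when the dysregulated genes are
viewed together with their protein-interaction partners — and (iv)
developmental context — whether genes silenced in the adult tissue
were active during early brain development. `degmods` implements this
pattern as a reusable, fully testable pipeline, together with a
synthetic-study generator that plants known truth into every input so
each stage's behaviour can be verified offline.

# Differential expression

Counts are filtered by total abundance: a gene is kept only when its
summed count over *all* samples is at least 10 (the exclusion rule is
"less than 10", so a total of exactly 10 survives). The bundled test
is deliberately simple and is **not** a negative-binomial
shrinkage model: counts are scaled to counts-per-million by
total-count normalisation, transformed to `log2(CPM + 1)`, and each
gene is tested with a Welch unequal-variance t-test. Fold change is
`log2(mean case CPM + 1) − log2(mean control CPM + 1)`; the
pseudocount of 1 on the CPM scale avoids division by zero and is
configurable. Raw p-values are adjusted by Benjamini–Hochberg
step-up (`stats::p.adjust`), and DEGs are selected by strict
inequality under one of two regimes: `adjusted` (`p_adj < 0.05`) or
`raw` (`p_raw < 0.05`), the latter intended for cohorts too small or
too variable for genome-wide correction. Externally produced DEG
tables (for example real DESeq2 output) can be substituted for the
bundled test through `read_deg_table()`; every downstream stage
consumes only the table.

Two consequences of the simple test are worth stating plainly. First,
total-count normalisation is compositional: if a large fraction of
the transcriptome shifts in one direction, fold-change estimates of
unchanged genes acquire a small opposite bias. Second, with a
3-vs-4-sample cohort the Welch test has useful power at uncorrected
thresholds but essentially no genes survive BH correction at a
20,000-gene scale; the worked demonstrations therefore analyse the
small pseudo-human cohort at the uncorrected threshold and rely on
the cross-species intersection to control false positives, which is
exactly the rationale such designs use in practice. The adjusted
regime remains the primary selection rule and is exercised by the
test suite (boundary behaviour, null calibration, and realized-FDP
control at better-powered sample sizes).

# Cross-species overlap and its permutation null

DEG sets are mapped across species through a two-column orthology
table; source ids that are ambiguous (more than one distinct target)
or unmapped are dropped and logged, so only 1:1 relations are used.
The observed k-way intersection is compared to a Monte-Carlo null:
in each of `n_samplings` (default 100,000) rounds, independent
uniform subsets of the observed set sizes are drawn from a fixed
universe (default 20,000 genes — configurable, since the appropriate
universe depends on the annotation used) and the intersection size
recorded. The empirical p-value uses the add-one convention
`(count_ge + 1) / (n_samplings + 1)`, so a reported value is never
exactly zero; the smallest reportable value at the default sampling
count is just below `1e-5`. The null fixes set *sizes*, not
identities, which is the natural formalisation of "random samplings
from the universe".

For two sets the intersection of two uniform subsets is exactly
hypergeometric, so `hypergeometric_overlap_p()` provides an
independent analytic oracle; the test suite verifies the Monte-Carlo
p against it within three Monte-Carlo standard errors (plus the 1/B
bias of the add-one estimator) across a parameter grid, including a
fully enumerable case (universe 10, sizes 5/5, observed 5, exact
probability 1/252).

Two design variants mirror the analysis the pipeline is built for:
`exclude_region_genes()` removes the deletion-region genes from the
shared set before re-testing (shared dysregulation should not be
carried by the deleted genes alone), and `control_split_overlap()`
is a negative control that splits the control samples into two
seeded halves, "discovers" DEGs between them at the raw threshold,
and verifies that their overlap with the other species' DEG set is
chance-level. If the split carries no variation at all (degenerate
input, e.g. duplicated samples), the control DEG set is empty and a
warning is raised.

# DEG-interacted functional modules

The protein-interaction network is an undirected simple graph
(self-loops removed, reversed duplicates collapsed). The
DEG-interacted network is the subgraph spanned by the DEGs present
in the network plus their first interaction neighbours, with all
edges induced on that node set; DEGs with no interactions remain as
isolated nodes and can never satisfy the module edge rule on their
own. Note that when a network is read from an edge-list file,
isolated nodes are not representable, so DEGs without any edge are
reported as absent at that point.

A functional module is the DEG-interacted subnetwork restricted to
the genes annotated to one GO biological-process term. Annotations
are first filtered to experimentally supported rows — evidence codes
`EXP, IDA, IPI, IMP, IGI, IEP` by default (the GO consortium's
experimental branch; configurable) — and to the biological-process
aspect. Annotations are used exactly as given: a gene annotated to a
child term is *not* propagated to ancestor terms, because the module
definition is per annotated process. A module is retained when it
contains at least one DEG and at least one edge; it is *not*
required to be connected ("one interaction" is read literally as at
least one edge anywhere in the module).

# Module activity: running-sum enrichment and permutation z

The activity statistic asks whether a module's genes concentrate at
the top of the full fold-change-ranked gene list. For a ranking of
all `N` tested genes (not only network genes), walking down the list
accumulates

$$S_i = S_{i-1} + \begin{cases} 1/N_f & \text{gene } i \in f \\
-1/(N-N_f) & \text{otherwise,} \end{cases} \qquad
ES_f = \max_{i \in \{1..N\}} S_i ,$$

where $N_f$ is the number of module genes present in the ranking.
Because the total rise equals the total fall, $S_N = 0$ exactly, so
$ES_f \in [0, 1]$, with 1 attained precisely when the module genes
fill a prefix of the list. *Activity* uses the descending ranking
(up-regulated genes first); *inactivity* the ascending one. Ranking
uses the table's log2 fold changes (monotone-equivalent to raw fold
change, so the choice is inert) and breaks ties by gene id so runs
are deterministic.

Significance is a permutation z: the null is the score of the same
module on uniformly permuted gene lists (default 1000), and
$z = (ES_f - \mu)/\sigma$ with $\mu, \sigma$ the null mean and
sample standard deviation (the $n-1$ denominator; the choice is
configurable and immaterial at 1000 draws). Since the score depends
on the ranking only through the member positions, each null draw
samples $N_f$ positions without replacement instead of permuting
$N$ genes — distributionally identical and much faster; the running
sum between members decays linearly, so the maximum is attained at a
member position and the score can be evaluated from the sorted
positions directly. Both equivalences are asserted against a naive
loop implementation in the test suite. Each (module, direction) pair
draws its permutations from an independent seeded substream, so
single modules can be re-scored reproducibly.

A module is **activated** when its activity z exceeds 2 while its
inactivity z is negative, **inactivated** under the mirrored rule,
and **neither** otherwise; the two sign gates make the classes
mutually exclusive. A null standard deviation of zero (possible only
in degenerate configurations) yields status `degenerate` and the
module is excluded from both classes.

# Dosage, developmental stages, and NDD enrichment

`dosage_check()` partitions the deletion-region genes by tissue into
expressed (TPM strictly above 1.5) and low; region genes missing
from the expression table are reported, never silently dropped.
`select_brain_silent_degs()` keeps DEGs with adult-brain-cortex TPM
strictly below 1.5, tallying DEGs without expression data
separately. For that group, `stage_profile_test()` runs a one-way
layout across developmental stages (default `prenatal, infant,
child, adolescent, adult`) with genes as observations and applies
Tukey's HSD via the studentized range distribution
(`stats::TukeyHSD`). The layout treats stages as independent groups
although each gene contributes one value per stage — a deliberate
simplification matching common usage; a paired analysis is out of
scope. `select_prenatal_max()` then keeps genes whose prenatal RPKM
exceeds 1.5 *and* is a strict maximum over all stages; ties are
logged and excluded. Thresholds keep their native units (TPM for
adult tissue, RPKM for stages); no cross-unit conversion is
attempted.

NDD enrichment is a one-sided exact binomial test: with `k` of `n`
DEGs in the disease list and background proportion
`p0 = |list ∩ universe| / |universe|`, it reports
`P(X ≥ k), X ~ Binomial(n, p0)`. The universe is the set of genes
actually tested for differential expression after the low-count
filter — a choice the pipeline records in its output, since the test
is sensitive to it.

# The synthetic-study generator

`simulate_study()` produces every pipeline input with coordinated
planted truth:

* **Counts** are negative-binomial with lognormal per-gene baseline
  means (`meanlog = 4`, `sdlog = 1`, so a median baseline of ~55
  counts) and dispersion 0.1 shared between groups — typical bulk
  RNA-seq orders of magnitude. Cohort sizes default to 3 cases vs 4
  controls for the "human" pseudo-species and 10 vs 10 for the
  "mouse" one. Planted DEGs (5% of the 20,000-gene universe) have
  case means multiplied by `2^±2`; half of them are shared between
  the species through a constructed 1:1 orthology table. Eight
  deletion-region genes have case means halved, emulating
  uncompensated heterozygous dosage.
* **Network and annotations**: background edges are uniform random
  pairs (Erdős–Rényi by edge count, default 30,000); each planted
  module (default four of 30 genes — the first half planted
  activated, i.e. members up-shifted, the rest inactivated) is made
  internally connected by a random path plus extra internal edges,
  and becomes one GO term annotating exactly its genes with
  experimental evidence. Background terms carry a configurable
  fraction of non-experimental (IEA) and molecular-function rows so
  the filters are exercised.
* **Tissue and stage tables**: planted prenatal-maximum genes (30,
  all of them planted DEGs) get cortex TPM below 1.5 and a strict
  prenatal-maximum stage profile above 1.5 RPKM; an equally sized
  decoy set is brain-silent but adult-peaked; all other genes get
  strictly increasing (adult-peaked) profiles, so the planted truth
  is exactly recoverable by the developmental chain.
* **NDD list**: 500 genes, 20% drawn from the planted DEGs, planting
  a genuine enrichment.

The generator is deterministic: one integer seed fixes every output
byte. What it does *not* emulate — batch effects, covariate and sex
structure, many-to-many orthology, scale-free network topology,
correlated genes, count outliers — bounds what green tests mean:
they demonstrate the statistical machinery is correct under its own
assumptions, not that the bundled DE test matches a dedicated
negative-binomial model on real data.

# Numerical and testing choices

* Strict inequalities everywhere a threshold is printed as strict
  (`< 0.05`, `> 1.5`, "less than 10"); boundary cases are tested on
  the excluded side.
* The running sum's terminal zero is structural; the implementation
  clamps the score at 0 against ~1e-16 rounding, and oracle
  agreement is asserted at 1e-12 (accumulation order differs between
  the fast and naive paths, so bitwise identity is not meaningful).
* Empirical p-values use add-one smoothing and are compared to
  analytic oracles within three Monte-Carlo standard errors plus the
  estimator's 1/B bias.
* Deterministic tie-breaks: ranking ties by gene id; the control
  split is a seeded sample; module substream seeds are drawn once
  from the batch seed.
* Test problem sizes are chosen so that stated tolerances sit at
  comfortable analytic margins: e.g. fold-change recovery at
  n = 50/50 uses a uniform baseline (`sdlog = 0`, dispersion 0.05)
  where the analytic sampling sd of the estimate (~0.075) puts the
  ±0.2 tolerance at ~2.7σ; module-recovery replicates use
  5,000-gene rankings with a +1 shift over a 0.5-sd fold-change
  background; null-calibration replicates use 2,000-gene universes
  at the study's cohort sizes.
* Realized false-discovery proportion is averaged with the standard
  convention FDP = 0 when nothing is selected.

# Known limitations

The bundled DE test trades power and compositional robustness for
self-containedness; real analyses should feed DESeq2/edgeR/limma
tables in through `read_deg_table()`. The overlap null ignores gene
correlation. GO ancestor propagation is off by default and no
semantic summarisation of classified modules is provided. The Tukey
stage test ignores the repeated-measures structure. Edge-list files
cannot represent isolated network nodes.
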