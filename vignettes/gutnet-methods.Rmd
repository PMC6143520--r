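---
title: "Methods and design notes for gutnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for gutnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutnet)
```

`gutnet` implements a case-control analysis chain for 16S taxon count
tables and a signed microbe-based disease network. This vignette records
the statistical models, the tunable parameters and their defaults, the
numerical conventions, and the design decisions taken where more than one
reasonable choice existed. Every empirical statement here is one the
package's test suite or `scripts/acceptance.R` computes itself.

## Differential abundance

Per-taxon testing uses the unpaired two-sided Wilcoxon rank-sum test on
relative abundances. Two details matter for small unbalanced designs such
as 35 cases vs 6 controls:

* **Exactness under ties.** Microbiome tables are zero-inflated, so ties
  are the norm, and the standard exact distribution (which assumes no ties)
  does not apply. When `choose(n1 + n2, n1) <= 2e5` the test enumerates
  every assignment of group labels, scores each by the midrank sum of the
  first group, and doubles the smaller tail (capped at 1). An alternative
  two-sided rule — the probability of a rank sum at least as far from its
  mean as observed — is available via `method = "abs_dev"`; tail doubling
  is the default because it matches the convention of `wilcox.test` and is
  directly checked against a brute-force enumeration oracle in the tests.
  Above the cutoff the normal approximation with tie-corrected variance
  and continuity correction is used; on tie-free exact cases and on the
  approximate branch the implementation agrees with `stats::wilcox.test`
  to 1e-10.
* **Testing proportions, not counts.** Group means are reported as
  relative abundances. Because the test is rank-based, normalization
  affects only the tie structure, not the ranks of non-tied values.

Benjamini–Hochberg correction is applied within each taxonomic rank
separately (phylum-level and genus-level tables are separate families),
with the family size `m` defaulting to the number of taxa actually tested
at that rank and overridable for users who want a larger family. The
implementation delegates to `stats::p.adjust(method = "BH", n = m)` and is
tested against the literal step-up definition.

A prevalence filter (default: a taxon must be non-zero in at least 10% of
samples) removes all-zero and near-all-zero taxa whose tests are
degenerate. The threshold is configurable; 10% is a common amplicon
default and is logged in results by construction (filtered taxa simply do
not appear).

## Taxon tables

The TSV dialect is the legacy QIIME export: `#OTU ID` header, taxa as
rows, samples as columns, final `taxonomy` column with a `"; "`-separated
Greengenes-prefixed lineage. A transposed samples-as-rows dialect is
available behind a flag. Reading a written table reproduces it exactly
(counts are stored as integers; relative tables are serialized with 17
significant digits so doubles round-trip losslessly).

Rank collapsing sums taxa sharing a label at the requested rank. Taxa with
an empty slot are pooled per deepest named ancestor as
`<ancestor>_unclass` — e.g. a genus-less Clostridiaceae member becomes
`Clostridiaceae_unclass`, a taxon unclassified below kingdom becomes
`Bacteria_unclass` — reproducing the labels such tables conventionally
carry. Collapsing conserves per-sample mass exactly and is idempotent at
its own rank.

The Bacteroidetes/Firmicutes ratio is computed **per sample** and the
groups are then compared by the rank-sum test; a group-mean ratio would
admit no rank test at all. Samples whose Firmicutes proportion falls below
`eps = 1e-6` are flagged and excluded rather than pseudocounted, because a
pseudocount would silently distort the ranks the test consumes.

## Diversity and ordination

Shannon diversity is computed in bits (base 2, the common amplicon
convention) with any base available; it renormalizes its input, so counts
and proportions are equivalent. Bray–Curtis dissimilarity is delegated to
`vegan::vegdist`. PCoA is classical scaling: double-centre `-d^2/2`,
eigendecompose, scale eigenvectors by the square roots of positive
eigenvalues. Negative eigenvalues (Bray–Curtis matrices are generally
non-Euclidean) are reported but not corrected — no Lingoes or Cailliez
constant — to keep coordinates interpretable against the raw
dissimilarities; variance proportions are taken over positive eigenvalues
only. Degenerate all-zero matrices return all-zero coordinates with a
warning rather than erroring, and requesting more axes than positive
eigenvalues truncates with a warning.

Group separation uses the PERMANOVA pseudo-F computed directly from the
distance matrix (among-group vs within-group sums of squared
dissimilarities), with labels permuted at fixed group sizes and the
add-one estimate `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`, so the
smallest attainable p is `1/(n_perm + 1)` and p = 0 is impossible. When
within-group distances are all zero the statistic is infinite and only
permutations reproducing the partition can match it, which the comparison
handles explicitly. The statistic equals `vegan::adonis2`'s pseudo-F (the
test suite checks agreement to 1e-10); the in-package permutation loop
exists so that seeding, smoothing and the degenerate case are fully
specified. Under exchangeable null data the rejection rate at
`alpha = 0.05` falls in [0.03, 0.07] over 1000 simulated datasets
(`n_perm = 199`), as the acceptance suite verifies.

## SCFA functional groups

The genus-to-group map covers butyrate producers (Fusobacterium,
Eubacterium, Anaerostipes, Subdoligranulum, Faecalibacterium, Roseburia),
lactate producers (Lactobacillus, Bifidobacterium, Streptococcus,
Lactococcus) and mucin degraders (Prevotella, Akkermansia). The
`other_scfa` group (propionate, succinate, acetate producers) ships empty:
its genus-level membership is not standardized, and inventing members
would fabricate biology; users extend the map explicitly. Matching is
exact string match on genus labels after normalization — no fuzzy
matching. Group proportions are computed per sample and then averaged per
group (the only order compatible with a per-sample rank test), and group
comparisons reuse `rank_sum_test()` verbatim so its exactness guarantees
carry over.

## The disease network

Association records (disease, microbe, direction, evidence) are reduced to
per-disease signed profiles by majority vote; exact ties drop the microbe
from that disease's profile with a warning, since no direction is
defensible. Microbe keys are normalized — whitespace trimmed, rank prefix
stripped, genus token extracted from binomials, lowercased — so profiles
extracted from taxon tables and profiles parsed from association TSVs
interoperate.

The similarity score is a signed cosine over {−1, 0, +1} microbe vectors,
normalized by the geometric mean of the two support sizes:
`S(a,b) = sum_{m in Ma∩Mb} sign_a(m)·sign_b(m) / sqrt(|Ma|·|Mb|)`. It is
symmetric, bounded in [−1, 1] (Cauchy–Schwarz), zero for disjoint
profiles, and ±1 exactly for identical/fully-reversed profiles — the
simplest score matching the intended semantics of "consistent" and
"reversed" microbiome changes. This is a deliberate reimplementation
choice: curated association databases pair naturally with many similarity
definitions, and this one is fully specified here so results are
reproducible from this package alone.

Edge significance is assessed by a support-preserving permutation null:
each profile's microbe set is redrawn uniformly from the universe (the
union of all profile supports) at its observed size, with its sign
multiset shuffled independently, and the two-sided add-one p-value counts
`|S_perm| >= |S_obs|`. Pairs are canonically ordered by disease name and
each pair derives its own deterministic sub-seed, so p(a,b) = p(b,a) and
whole networks are seed-reproducible. The default inclusion rule is
`p < 0.05` uncorrected with `min_shared = 1` shared microbe, with optional
BH adjustment across all tested pairs — curated association lists are
small and sparse, and the uncorrected default favours sensitivity; users
wanting strict error control should set `adjust = "BH"`.

Like any finite permutation test with add-one smoothing and a discrete
statistic, the edge test is mildly conservative: with sparse profiles
(supports of ~5–10 microbes) the attainable p-values are coarse and the
null edge rate at `alpha = 0.05` sits visibly below 0.05, while with
larger supports (tens of microbes) the statistic is fine-grained and the
empirical edge rate is statistically compatible with the nominal level.
The acceptance suite therefore measures planted-pair recovery on a sparse,
curated-database-like design (density 0.1 over 60 microbes) and null
calibration on a dense design (density 0.4 over 120 microbes); the test is
conservative, never anti-conservative, in both regimes.

## The synthetic-data generators

The community generator draws each sample Dirichlet-multinomial: the
group's expected composition scaled by a total concentration (dispersion),
a Gamma-based Dirichlet draw, then a multinomial at a lognormal library
size (rounded, floored at 1000 reads so no sample is empty). Case-group
compositions are the control baseline with multiplicative fold changes,
renormalized — `p_case = f·p / sum(f·p)` — which gives closed-form
expected proportions for oracle tests. One scenario seed drives
everything; each sample uses a deterministically derived sub-seed, so
adding samples never perturbs earlier ones and identical scenarios produce
byte-identical tables.

The default ASD-vs-TD scenario emulates an unbalanced 35-case/6-control
gut study: control baselines put Bacteroidetes near 0.31 with a
substantial kingdom-only unclassified fraction (0.145), Firmicutes
absorbing most of the remainder; the case group plants 4-fold increases on
the major Bacteroidetes genera and 4-fold decreases on eight genera
commonly depleted in ASD guts plus the `Bacteria_unclass` bucket. Three
further genera reported as ASD-increased in some studies but without a
clear significance level (Sutterella, Odoribacter, Butyricimonas) are
exposed behind `include_abstract_trio = FALSE` rather than planted by
default. Two emulation choices deserve emphasis:

* Genus baselines are *plausible values*, not estimates: published
  group-mean tables are means of proportions and are mutually inconsistent
  as a composition (they need not sum to 1), and genera reported at
  ~1e-5 mean abundance are undetectable at realistic library sizes by any
  method, so planted genera are given baselines in the 0.004–0.05 range
  where a 4-fold shift is in principle recoverable.
* `dispersion = 200` (total Dirichlet concentration) gives moderate
  between-subject overdispersion — realistic 16S tables are overdispersed
  relative to multinomial sampling, and at 200 a taxon at proportion p has
  between-sample standard deviation `sqrt(p(1-p)/201)`, i.e. a ~45%
  coefficient of variation at p = 0.025. Library sizes are lognormal with
  arithmetic mean 30,000 reads and shape 0.5.

What the generator does **not** emulate: read-level error, chimeras, PCR
bias, taxonomic misassignment, phylogenetic structure, or the extreme
zero-inflation of very rare taxa. Passing tests on synthetic data
therefore demonstrate the statistical machinery is correct under the
stated model, not that any particular biological dataset will behave this
way.

The association generator samples background (disease, microbe)
associations independently at a configurable density with random signs,
then plants disease pairs sharing exactly `n_shared` microbes at a chosen
sign-consistency fraction; chance co-occurrences outside the planted set
are removed from the second disease so "exactly `n_shared`" holds by
construction and the ground truth is unambiguous.

## Problem sizes used by the tests

The suite runs its statistical checks at fixed, documented sizes chosen to
give stable verdicts at interactive runtimes: 1000 random datasets for the
exact-test and BH oracles; 1000 exchangeable-null datasets of 16 samples
(`n_perm = 199`) for permutation-test calibration; 20 seeds of the default
35-vs-6 scenario for planted-effect recovery and the
Bacteroidetes/Firmicutes comparison, and 50 no-effect seeds for the null
false-discovery check; 50 seeds for planted disease-pair recovery
(`n_perm = 999`) and 50 dense-design seeds for network null calibration;
and two full pipeline runs for byte-identity. The whole suite completes in
a few minutes on one CPU.

## Known limitations

* No phylogeny: UniFrac metrics and double principal-coordinates analysis
  are out of scope.
* No compositional (log-ratio) differential methods and no covariate
  adjustment; the design is strictly two-group unpaired.
* No metagenome function prediction; the functional-group step is a fixed
  genus-level lookup.
* The network's similarity and inclusion rules are fully specified here
  but are one defensible choice among several; counts of links obtained
  with other scores or other association-database snapshots are not
  comparable.
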