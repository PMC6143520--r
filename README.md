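# gutnet

Two-group analysis of 16S rRNA gut-microbiome count tables, and signed
microbe-based disease networks.

Case-control amplicon studies routinely ask three questions: which taxa
differ between groups, whether whole communities separate, and what the
shifts imply downstream. `gutnet` packages that workflow for unbalanced
designs (e.g. 35 cases vs 6 controls), and adds a fourth step: projecting a
disease's signed microbiome signature against curated microbe-disease
association tables (HMDAD-style: disease, microbe, direction of change) to
find diseases whose microbiota shift the same way or the opposite way.
It is aimed at microbiome analysts who have a QIIME-style taxon table, or
who want a fully synthetic, ground-truth-bearing testbed for such analyses.

## What it computes

* **Differential abundance.** Per-taxon two-sided Wilcoxon rank-sum tests on
  relative abundances, exact by full enumeration (midranks for ties) when
  `choose(n1 + n2, n1) <= 2e5`, otherwise a tie-corrected normal
  approximation with continuity correction. Benjamini–Hochberg step-up
  correction `q_(i) = min_{j>=i} p_(j) m / j` is applied within each
  taxonomic rank.
* **Taxon tables.** Legacy QIIME TSV I/O with Greengenes lineages
  (`k__; p__; ...`), rank collapsing with `<ancestor>_unclass` pooling of
  unclassified taxa, and the per-sample Bacteroidetes/Firmicutes ratio.
* **Diversity.** Shannon entropy `H = -sum p_i log2 p_i`; Bray–Curtis
  dissimilarity `BC(a,b) = sum|a_i - b_i| / sum(a_i + b_i)`; classical-scaling
  PCoA; and a PERMANOVA-style pseudo-F permutation test for group
  separation with add-one p smoothing.
* **SCFA functional groups.** Genus-level butyrate producers, lactate
  producers and mucin degraders, summed per sample.
* **Disease network.** Per-disease signed microbe profiles (majority vote
  over association records), signed-cosine similarity
  `S(a,b) = sum_{m in Ma∩Mb} sign_a(m) sign_b(m) / sqrt(|Ma||Mb|)`,
  support-preserving permutation p-values, and export of the resulting
  signed network as edge-list TSV or GraphML.
* **Synthetic data.** A Dirichlet-multinomial community simulator with
  planted fold changes (closed-form expected compositions) and a signed
  association-list simulator with planted disease pairs, both fully seeded,
  so every stage can be validated against known ground truth.

## Worked example

```r
library(gutnet)

scenario <- default_asd_scenario(seed = 42)   # 35 cases vs 6 controls
sim <- simulate_counts(scenario)
rel <- to_relative(sim$table)

res <- differential_abundance(rel, sim$design, rank = "genus")
head(res, 5)
#>                    taxon mean_case mean_control  p_value  q_value direction
#> 1       Bacteria_unclass    0.0242       0.1684 0.000116 0.000728        -1
#> 2            Bacteroides    0.4899       0.1824 0.000116 0.000728         1
#> 3        Parabacteroides    0.0779       0.0293 0.000116 0.000728         1
#> 4             Prevotella    0.1361       0.0612 0.000116 0.000728         1
#> 5 Clostridiaceae_unclass    0.0093       0.0473 0.000135 0.000728        -1

bf <- bf_ratio(collapse_rank(rel, "phylum"))
grp <- sim$design$group
median(bf$ratio[grp == "case"])     #> 3.22
median(bf$ratio[grp == "control"])  #> 0.69
rank_sum_test(bf$ratio[grp == "case"], bf$ratio[grp == "control"])
#> 0.000116

pt <- permutation_group_test(bray_curtis_matrix(rel), sim$design,
                             n_perm = 999, seed = 1)
pt$statistic; pt$p_value
#> 102.5
#> 0.001

extract_signed_profile(res, alpha = 0.05, disease = "ASD")
#> signed profile 'ASD': 21 microbe(s) (3 up, 18 down)
```

The planted case-group enrichment of Bacteroidetes genera and depletion of
eight Firmicutes/Proteobacteria/Actinobacteria genera are recovered at
`q < 0.05` with the correct signs; the per-sample Bacteroidetes/Firmicutes
ratio is significantly higher in the case group; and the communities
separate at the smallest attainable permutation p. The signed profile can
then be combined with association records (`read_associations()`,
`build_profiles()`) and fed to `build_network()` to obtain positively and
negatively linked diseases, ranked by `disease_neighbors()`.

`run_pipeline(pipeline_config(out_dir = "run1"))` executes the whole chain
(simulate → differential abundance → diversity → functional groups →
profile → network) and writes a manifest with per-file MD5 hashes; fixed
seeds give byte-identical reruns.

## Limitations

The simulator emulates compositional overdispersed counts, not read-level
artifacts; no phylogeny is modelled, so UniFrac-family metrics and
phylogenetic ordinations are out of scope, as are metagenome function
prediction and compositional (log-ratio) differential methods. Details and
rationale are in `vignettes/gutnet-methods.Rmd`.
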