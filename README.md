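# targetfuse

Integration of transcription-factor ChIP-Seq binding dynamics with RNA-Seq
differential expression to call **direct target genes** of a
stress-activated factor. The motivating setting is the p53 response of
hematopoietic stem and progenitor cells to irradiation: expression changes
alone mix direct and downstream effects, and binding sites alone are
regulatory potential, not regulation. A direct target is a gene that (i) is
dysregulated in a factor-*dependent* way and (ii) carries a binding peak
near its transcription start site.

## What it computes

For counts `y` with genotype x treatment x replicate design and a set of
peaks with pre/post-stimulus binding signal:

1. **Differential expression** (per contrast vs untreated wild type):
   CPM filter (>= 5 CPM in >= 3 samples), TMM normalization, common NB
   dispersion phi (variance = mu + phi mu^2) by conditional maximum
   likelihood, exact conditional two-sided test of group sums, BH
   adjustment; a gene is dysregulated when max(FC, 1/FC) >= 2 and
   FDR <= 0.05 (inclusive).
2. **Response programs**: hierarchical clustering (distance = 1 − Pearson
   r, complete linkage, k = 3) of relative expression, labelled
   A (factor-dependent up), B (factor-independent up),
   C (factor-dependent down).
3. **Peak groups**: binding fold change (IR + ½)/(UT + ½); Group I
   (>= 1.5-fold gain), II (minimal change), III (>= 1.5-fold loss);
   proximal/distal at 1 kb from the nearest TSS.
4. **Association**: per (program, peak-group) cell, fold enrichment

   `FE = f_obs / f_rand`

   where `f_obs` is the fraction of program genes with a peak center
   within 10 kb of the TSS and `f_rand` the mean fraction over 10 random
   sets of 200 expressed genes; significance by two-tailed Fisher exact
   test against the pooled random draws.
5. **Direct targets**: program A/C genes with a peak within 10 kb; then an
   offline novelty/druggability triage against known-target lists, a
   bundled literature co-mention index, and a druggable-gene list.

A seeded synthetic-data generator (`generate_scenario()`) plants all of
this structure — programs, effect sizes, peak groups, peak–gene links —
and writes a truth manifest, so the whole pipeline is testable offline.

## Worked example

```r
library(targetfuse)

sc  <- generate_scenario(scenario_config(seed = 1))   # synthetic study
res <- integrate_targets(sc$genes, sc$counts, sc$design, sc$peaks,
                         pipeline_config(seed = 1))
res
#> <targetfuse result>
#>   expressed genes:   2000
#>   dysregulated:      276
#>   peaks:             750
#>   direct targets:    129
#>   min association p: 1.18e-39

glance(res$de_wtir)        # irradiated wild type vs untreated wild type
#>   n_genes n_called dispersion contrast reference
#> 1    2000      273     0.0999 WT-IR    WT-UT

dplyr::filter(tidy(res$association), peak_group == "I")
#>   cluster_label peak_group n_cluster_genes n_associated f_obs f_rand
#> 1 A             I                      144          110 0.764  0.222
#> 2 B             I                       48           10 0.208  0.222
#> 3 C             I                       83           14 0.169  0.222
```

Reading: of the 144 program-A genes (factor-dependent induction), 76% have
a binding-gain (Group I) peak within 10 kb versus 22% of random expressed
genes — a 3.4-fold enrichment and the grid's smallest Fisher p — while the
factor-independent program B sits at background. `res$targets` lists each
direct-target gene with its supporting peaks and distances:

```r
head(dplyr::filter(tidy(res$targets), is_direct_target), 3)
#>   gene_id   cluster_label peak_id    distance peak_group
#> 1 gene_0033 A             peak_00001     9422 I
#> 2 gene_0058 C             peak_00507     1857 I
#> 3 gene_0077 A             peak_00002     7043 I
```

`autoplot(res$association)` draws the bubble grid (size = fold
enrichment, colour = −log10 p); `plot_volcano()`, `plot_clusters()` and
`plot_signal_matrix()` cover the other result types.

A file-based run with the same stages, plus triage and TSV outputs:

```sh
exec/targetfuse synthesize --out fixture --seed 1
exec/targetfuse run --config config.yaml     # paths + thresholds in YAML
exec/targetfuse summarize --dir output_dir
```

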