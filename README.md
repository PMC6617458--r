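# metapept

Shotgun-metagenome community profiling from protein 9-mers, gene-family
profiling with RPKG normalization, and count-based differential-abundance
statistics — with a deterministic two-treatment community simulator for
end-to-end validation.

## The problem

Rhizosphere (and other soil) microbiome studies increasingly use whole-genome
shotgun sequencing rather than amplicons, and need to answer two questions per
treatment contrast:

1. **Who is there, and who shifted?** Every merged read is translated in all
   six reading frames; each amino-acid 9-mer of those peptides is looked up in
   an index mapping peptides to the lowest common ancestor (LCA) of all
   reference proteins containing them, and the per-read hits are aggregated
   into a single **consensus taxon** by a top-down descent of the taxonomy
   (move into a child only while it holds at least a fraction *f* = 0.8 of the
   current hit weight; root-level hits are discarded; with *f* = 1 this is
   exactly the LCA). Reads are rolled up to genus count tables.
2. **Which functions shifted?** Reads (or their ORFs) are matched against
   profile models of chitin-cycle glycoside-hydrolase families (GH18, GH19,
   GH20, CE4, GH5, GH7, GH8, GH46, GH75, GH80) and nitrogen-cycle genes
   (amoA AOA/AOB, amoB, napA, nrfA, narG, nirS, nirK, norB, nosZ + two
   atypical clades, nifH, ureC). Matches are kept at e-value <= 1e-10 and
   model coverage >= 60%, counted per family (one count per read and family),
   and normalized to **RPKG**:

   RPKG = count / (model length in kb) / genome equivalents,

   where genome equivalents = total bases / average genome size (AGS), AGS
   estimated from universal single-copy marker hit rates.

Treatment effects are tested with the field's count statistics, implemented
here from first principles:

* abundance filter (CPM >= 4 in >= 4 samples), TMM normalization factors;
* negative-binomial dispersion by quantile-adjusted conditional maximum
  likelihood (qCML) and a conditional two-sided **exact test** on group sums;
* **quasi-Poisson GLMs** with a log-exposure offset for gene-family counts;
* Benjamini-Hochberg FDR;
* Bray-Curtis distances with **PERMANOVA** (exhaustively enumerated for small
  designs such as 4 + 4, where all C(8,4) = 70 relabelings are evaluated) and
  a multivariate dispersion-homogeneity test (PCoA distances to group
  centroids).

The built-in simulator generates the statistical structure this analysis
assumes — a ranked taxonomy, genus-disjoint proteomes, genomes, two-treatment
read sets with Dirichlet replicate noise and known fold changes, and
domtblout-style match tables — so every stage is testable with exact ground
truth and no downloads.

## Worked example

```r
library(metapept)

cfg <- pipeline_config(seed = 1)     # simulate the default 2 x 4 study
out <- run_taxonomic_analysis(cfg)
#> [simulate] 8 samples x 10000 reads, 10 genera
#> [classify] mean fraction assigned 1.000
#> [permanova] pseudo-F 8.798 p 0.0286 (exhaustive)
#> [cpm_filter] 10 features kept, 0 removed
#> [diffstats] 2/10 features significant at FDR 0.05

out$permanova
#> PERMANOVA: pseudo-F = 8.798, p = 0.02857 (exhaustive, 70 relabelings)

dplyr::select(out$diff, name, log2_fold_change, p_value, fdr, significant)
#>        name log2_fold_change  p_value      fdr significant
#> 1  genus_01         -0.02981 7.66e-01 8.51e-01       FALSE
#> ...
#> 9  genus_09          2.61117 1.00e-94 1.00e-93        TRUE
#> 10 genus_10          1.52211 5.08e-27 2.54e-26        TRUE
```

The two flagged genera are the simulator's spiked ones: `genus_09` (7.6x,
log2 = 2.93) and `genus_10` (3.4x, log2 = 1.77); the estimated log2 fold
changes (2.61, 1.52) sit slightly below the spikes because relative
abundances are compositional — raising two genera necessarily lowers the
rest. The exhaustive PERMANOVA p of 0.0286 = 2/70 is the smallest value a
4 + 4 design can attain.

The functional arm mirrors this for gene families:

```r
fun <- run_functional_analysis(pipeline_config(seed = 1))
fun$rpkg          # families x samples RPKG table
fun$diff          # quasi-Poisson tests, BH-corrected
```

Plot helpers: `plot_relative_abundance()`, `plot_volcano()`, `plot_pcoa()`;
`tidy()`/`glance()` methods summarize `permanova` and
`dispersion_homogeneity` objects.

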