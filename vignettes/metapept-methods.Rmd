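---
title: "Methods: protein 9-mer classification, RPKG profiling and count statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: protein 9-mer classification, RPKG profiling and count statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in
**metapept**, the assumptions behind them, the tunable parameters, the
design choices that were genuinely open, and what the simulation-based
validation does and does not establish about real data.

# Taxonomic classification

## Model

A merged shotgun read is translated in all six reading frames (standard
genetic code; stops rendered `*`, ambiguous codons `X`, trailing partial
codons dropped; frames ordered `+1, +2, +3` then `-1, -2, -3` on the
reverse complement). Every 9-residue window of those peptides that consists
solely of the 20 standard amino acids is looked up in a pre-built index
mapping each 9-mer to the **lowest common ancestor (LCA)** of all reference
proteins containing it. Windows containing stops or non-standard residues
(B, J, O, U, X, Z) break rather than match — a window is either fully
informative or not queried at all. I and L are kept distinct; equating them
(as some peptide-centric tools do for mass-spectrometry data) would only
coarsen assignments and is not needed for nucleotide-derived peptides.

The per-read hit multiset is reduced to one **consensus taxon**:

1. hits at the taxonomy root are discarded (they carry no information);
2. if nothing remains the read is *unclassified*;
3. otherwise, starting at the root, the search repeatedly descends into the
   child whose subtree carries at least a fraction `f` of the current
   node's hit weight (hits at internal nodes count toward their own
   subtree), stopping when no child qualifies.

`f` defaults to 0.8. Values at or below 0.5 are rejected: with `f > 0.5`
at most one child can qualify, so the descent is unambiguous and
deterministic. At `f = 1` the procedure returns exactly the LCA of the
surviving hits — this equivalence is verified against an independent
root-path-intersection oracle in the test suite. The published pipelines
this stage emulates do not document their aggregation rule precisely; the
threshold descent above is this package's concrete, documented choice, and
`f` is exposed so users can span the spectrum from permissive plurality
(`f` slightly above 0.5) to strict LCA (`f = 1`).

Hits are pooled across all six frames before aggregation rather than voted
per frame: a read has one true source, and the wrong-frame translations of
a real coding region essentially never produce indexed 9-mers (a random
9-mer has probability $20^{-9} \approx 2\times10^{-12}$ of matching any
given indexed peptide).

## Parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 9 residues | peptide window length; the index stores one LCA taxid per k-mer |
| `f` | 0.8 | consensus descent threshold, in (0.5, 1] |
| rank | genus | reporting rank for count tables |

Upstream read QC (trimming/merging: minimum length 100, maximum 500,
minimum overlap 100, quality 30) is *not* re-implemented; the pipeline
consumes merged reads and records those settings in its config provenance
block only.

# Functional profiling

`find_orfs()` reports all maximal stop-free stretches of at least
30 residues across the six frames — a transparent stop-to-stop finder, not
a gene caller; externally produced ORFs and HMMER match tables
(domtblout dialect) can be supplied instead at the module boundary.

Matches are filtered at e-value <= 1e-10 and model coverage >= 60%, both
boundaries inclusive. **Coverage is defined on the profile model**
(`(hmm_to - hmm_from + 1) / model_length_aa`), the convention of the
functional-gene repositories this emulates; the read-side alternative
would pass nearly every long alignment and is not what "60% coverage" of a
protein family means in that ecosystem. Counting is per read and family: a
read's duplicate domains collapse to its best e-value record, while one
read may legitimately count toward several families.

**RPKG** (reads per kilobase of model per genome equivalent) is

$$\mathrm{RPKG} = \frac{\text{count}}{L_{aa} \cdot 3/1000} \cdot
\frac{1}{\mathrm{GE}},$$

with the model length converted from residues to kilobases of equivalent
nucleotide (×3/1000) because the counted reads are nucleotide sequences; a
`unit = "aa"` switch provides the kilo-amino-acid alternative since the
convention is not universal. RPKG is invariant under uniform depth scaling
(counts and GE scale together), which the tests assert to 1e-12.

**Genome equivalents.** GE = total bases / AGS. The average genome size is
estimated from universal single-copy marker hit rates: a marker of
amino-acid length $L$ hit by $h$ of $R$ reads implies
$\mathrm{AGS}_j = 3LR/h$ bp, and the community AGS is the geometric mean
over markers with hits. This is a transparent rate estimator honoring the
same contract as dedicated AGS tools (GE = bp / AGS), not a port of any of
them; a known AGS can be supplied directly. With read-share-weighted
communities the estimator targets the harmonic mean genome size, which is
the quantity that makes GE equal the number of sequenced genome copies.

The built-in registry carries the 10 chitin-cycle families and 14 N-cycle
gene models (bacterial and archaeal ammonia-monooxygenase amoA clades kept
separate; nitrous-oxide reductase nosZ split into the typical clade and two
atypical clades). Model lengths are configurable defaults chosen for this
artifact — public profile lengths for these families are not fixed by any
single authority — and hao, nor, nasA and nir are excluded because no
usable public profile exists for them.

# Differential abundance

All statistics are implemented from first principles in this package;
edgeR, vegan and `stats::glm` appear only in the test suite as independent
cross-checks (TMM factors and the exact test reproduce edgeR to machine
precision at equal library sizes).

## Filtering and normalization

Features are kept if their counts-per-million reach 4 in at least
4 samples — the replicate count of the emulated design — which strips
sequencing errors and singleton artefacts before testing. TMM factors are
computed exactly in the standard way: reference sample = the one whose
75th-percentile CPM is closest to the mean; pairwise M-values doubly
trimmed (30% on M, 5% on A) after excluding zero counts; precision-weighted
(inverse asymptotic binomial variance) mean; factors rescaled to geometric
mean 1.

## Negative-binomial exact testing with qCML dispersion

Counts $y_{ij} \sim \mathrm{NB}(\mu_{ij}, \phi)$ with
$\mathrm{Var} = \mu + \phi\mu^2$. Libraries are first equalized to the
geometric-mean effective size (library size × TMM factor). The quantile
adjustment here is a moment-matching map
$y^* = \mu_{out} + (y - \mu_{in})\sqrt{v_{out}/v_{in}}$ applied per feature
and sample, iterated once with the re-estimated dispersion; it is exactly
the identity when effective sizes are equal, the only regime in which any
quantile adjustment is exact. The common dispersion maximizes the summed
conditional log-likelihood given group totals (which is free of the group
means) over a log-spaced grid on $[10^{-6}, 10]$ refined by golden-section
search; optional tagwise dispersions maximize the per-feature conditional
likelihood plus a shared-likelihood penalty weighted by
`prior_df / residual df` (`prior_df = 10`), shrinking them toward the
common value.

The two-sided exact p-value conditions on the total of the two group sums:
all splits of the total with probability no larger than the observed
split's probability (under the NB convolution with the estimated
dispersion) are summed. Perfectly balanced splits give p = 1 by symmetry;
the implementation agrees with a full enumeration oracle to < 1e-9 for all
totals up to 30, and its type-I error on null simulations
(1,000 features, 4 + 4, true dispersion 0.1) sits at the nominal 5% level.
The log2 fold change uses normalized group means with a 0.125 pseudo-count,
treatment (second group in sample order, not alphabetical order) versus
control.

## Quasi-Poisson GLMs for gene families

Family counts are modeled with a log-link quasi-Poisson GLM (IRLS, 50
iterations; non-convergence is flagged and yields an NA p-value) with the
main effect of treatment and a per-sample offset `log(GE)`, so the
treatment coefficient acts on the RPKG scale — a per-family constant such
as the model length only shifts the intercept. This deliberately models
*raw counts with an exposure offset* rather than precomputed RPKG values:
the expectation model is identical, but count-scale fitting keeps the
mean-variance relationship the quasi-likelihood needs. The dispersion is
the Pearson statistic over $n - 2$ degrees of freedom and the treatment
test is a t-test on the coefficient with $n - 2$ df. A perfect fit
(Pearson statistic numerically zero) has no noise to test against and
returns p = 1.

BH FDR is applied within each analysis family (the genus table, each
function table) separately, mirroring per-table testing; the significance
threshold is 0.05 throughout.

## Community-level tests

Bray-Curtis dissimilarity on per-sample relative abundances was chosen as
the default distance — the standard choice for abundance data in this
workflow, with the metric swappable by passing any `dist`. PERMANOVA
partitions the squared distances; for two groups with
$\binom{n}{n_1} \le$ `exhaustive_limit` (default 10,000) all relabelings
are enumerated and the p-value is exact — a 4 + 4 design has 70, so its
smallest attainable p is 2/70 = 1/35 (the observed labeling and its group
swap). Otherwise `n_perm` random permutations are drawn with
$p = (\#\{F^* \ge F\} + 1)/(n_{perm} + 1)$. Dispersion homogeneity embeds
the samples by PCoA (negative eigenvalues truncated at zero), computes each
sample's distance to its own group centroid, and permutes group labels in
an F-test on those distances; when all distances are numerically equal
there is nothing to test and F = 0, p = 1.

# The simulator

`simulate_reference()` builds a ranked taxonomy (each genus under its own
phylum), genus-specific random proteomes, and genomes that concatenate each
protein's CDS (random synonymous codons, ATG/TAA bounded) separated by
50 nt neutral spacers. Genera are rejection-resampled until **no 9-mer is
shared between genera**, so classifier recovery is exact by construction
rather than probabilistic; an `overlap` mode shares proteins between two
species per genus to exercise LCA/consensus behavior within genera. The
first five protein slots of every genus are universal single-copy markers
of common length (300 aa) for AGS estimation.

`simulate_community_reads()` emulates the two-treatment, four-replicate
design: per replicate, genus proportions are the base abundances (fold
changes applied in the treatment group, then renormalized) with Dirichlet
replicate noise; reads of 200 nt are drawn uniformly from the source
genome on either strand. The defaults are the emulated study conditions:
10 genera, 8 × 10,000 reads, error rate 0 (substitution errors are
available via `error_rate`), and two spiked genera at 7.6× (base 0.8%) and
3.4× (base 0.6%) — the magnitudes reported for the strongest bacterial
responders in the emulated experiment.

**Dirichlet concentration.** The replicate standard errors reported for
genus relative abundances in the emulated study imply replicate CVs from
roughly 10% (abundant genera) to 40% (a 0.6% genus at 0.59 ± 0.12,
n = 4). A single Dirichlet concentration ties CV to abundance as
$CV \approx 1/\sqrt{c\,p}$; matching the low-abundance end alone would give
$c \approx 1000$ and the mid-range $c \approx 5000$–20,000. The default is
**c = 2000**, the mid-range of that implied scale, corresponding to an NB
dispersion of about 0.08 for a 0.6% genus. This was fixed from that
arithmetic, not adjusted afterward.

`simulate_gene_matches()` draws true filtered counts per family as
Poisson(base rate × depth factor × fold change) and emits domtblout
records containing exactly those passing records plus failing decoys
(10% of records by default), so applying the study filters to the emitted
table recovers the truth counts *exactly* — a construction oracle used
throughout the tests. Default family effects mirror the reported shifts
(bacterial amoA up ~3×, the three nosZ clades down ~0.75×, GH46/GH75 up).

## What passing tests do and do not show

The simulator produces the *statistical structure* the analysis assumes:
known taxonomy, disjoint proteomes, uniform read sampling, substitution
errors only, Dirichlet-multinomial replicate noise, Poisson family counts.
Passing its tests demonstrates that the algorithms are implemented
correctly and that the statistical stack is calibrated under its own
model. It does **not** show that real rhizosphere data satisfy these
assumptions: real reference databases have shared and missing peptides
across taxa (so real assignment fractions are far below the simulator's
~100% — the emulated study assigned ~15% of reads), real genomes share
k-mers, indels and quality decay exist, and real replicate noise is not
exactly Dirichlet. Conclusions about real data rest on the method, not on
these recoveries.

# Numerical choices and degenerate inputs

* Exact-test split probabilities are computed in log space and normalized;
  ties at the observed probability are included with a 1 + 1e-10 relative
  guard. Dispersions below 1e-10 use the Poisson limit.
* Group sums of (possibly fractional) pseudo-counts are rounded to
  integers for the exact enumeration.
* The common-dispersion search brackets the grid maximum and refines by
  `optimize()`; a maximum at the lower boundary returns 1e-6 (effectively
  Poisson).
* TMM of a single sample, or of a pair with all-zero overlap, returns 1.
* `permanova` requires >= 2 samples per group; ties in the permutation
  distribution are counted with a 1e-12 slack toward the observed value.
* Empty read streams give fraction assigned 0 (0/0 → 0 by convention);
  unreadable records are skipped with a warning but counted in the total.
* Simulated corpora are fully determined by `(config, seed)`; pipeline
  reruns are byte-identical.

# Problem sizes used in validation

The packaged validation uses the default corpus (8 samples × 10,000 ×
200 nt reads, 10 genera × 20 proteins), 20 independent seeds for the
spike-in power study, 1,000-feature null tables for type-I calibration,
and exhaustive (70-relabeling) PERMANOVA — sizes at which every check runs
in seconds to a few minutes on a single CPU while keeping Monte-Carlo
standard errors well inside the asserted margins.

# Known limitations

* The k-mer index is an in-memory hash; it targets reference sets up to a
  few million distinct 9-mers, not a full UniProt-scale index.
* `find_orfs` is stop-to-stop, frame-based; it does not model start-codon
  usage or gene boundaries.
* The AGS estimator assumes markers are universal and single-copy with
  known lengths; violations bias GE, as they do for all such estimators.
* The quantile adjustment is moment-based; at strongly unequal library
  sizes the NB exact test is approximate (as is any count-equalization
  scheme), and its p-values drift slightly from implementations using
  other adjustment approximations.
* Streaming is chunked in memory, not constant-memory, at the scales this
  package targets.
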