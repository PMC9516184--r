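---
title: "Identifying direct, condition-dependent transcription-factor targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying direct, condition-dependent transcription-factor targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ChIPdirect)
```

## The problem

A transcription factor (TF) regulates a gene *directly* when it both binds
near that gene and is required for the gene's normal expression. Neither
data type alone settles the question: ChIP-seq finds thousands of bound
segments, most of them without a transcriptional consequence, and a
genotype contrast (wild type versus a TF null mutant) finds thousands of
differentially expressed genes, most of them downstream of indirect
cascades. ChIPdirect implements the intersection-based workflow used to
resolve this for condition-dependent regulators — the motivating case being
a copper-deficiency response factor assayed under low-copper and
copper-replete conditions — taking per-replicate peak calls, a gene
annotation, a genome sequence, and a differential-expression (DE) table as
inputs, and producing candidate sets for direct activation and direct
repression per condition.

The pipeline deliberately begins *after* read processing: trimming,
alignment, peak calling and DE model fitting are established upstream steps
with their own tools, and their products (narrowPeak/BED files and a DE
table) are the interfaces.

## Consensus peaks across replicates

Replicate ChIP-seq experiments call overlapping but not identical segments.
Two replicate peaks are treated as the same binding event when at least
80% of the length of the shorter segment is covered by their overlap:

$$\mathrm{overlap}(a, b) \ge f_\mathrm{merge} \cdot \min(|a|, |b|),
\qquad f_\mathrm{merge} = 0.8 .$$

The criterion is evaluated pairwise on the *original* replicate peaks; the
merge graph's connected components (single linkage) each become one
consensus peak spanning the union of their members. Two consequences
follow and are asserted in the test suite: a consensus segment is at least
as long as the broadest member it absorbs, and the result is independent
of input order. Support is the number of distinct *replicates* (not peaks)
in a component; components below `min_support = 2` of 4 replicates are
dropped. We deliberately do not re-test the union segment against its
members: iterated re-merging is not part of the stated rule, and single
linkage on originals is deterministic and order-free. Both the fraction
and the support threshold are configurable.

## Condition-specific versus shared binding

Whether a binding event is present under both conditions is decided on
*peak centers*, which are robust to the exact extents called in different
condition backgrounds. Each consensus peak of extent $[s, e)$ defines a
window $c \pm 0.3\,L$ with $c = (s+e)/2$ and $L = e - s$; a peak is
`shared` when its window intersects the window of any peak from the other
condition. Centers of odd-length segments are half-integers and are kept
as exact reals — windows are compared with strict half-open inequalities,
never rounded, so classification cannot depend on platform rounding
behavior.

Mock immunoprecipitations from an untagged line flag antibody
cross-reaction artifacts. A consensus peak is flagged when it shares at
least 1 bp with a mock segment (plain intersection — a different, looser
question than center matching). Flagged peaks are reported but kept by
default, because presence of a mock peak does not prove the tagged-line
signal is artifactual; `exclude_control_flagged = TRUE` removes them
before annotation for users who prefer the conservative set.

## Peak-to-gene annotation

A peak links to every gene whose body it overlaps and every gene whose
promoter window (default 2,000 bp upstream of the transcription start
site, TSS) it touches; one peak can link several genes and vice versa.
Each link carries one localization code:

* `S` — the peak contains the TSS base;
* `P` — the peak lies entirely upstream (5′) of the TSS;
* `G` — the peak lies entirely 3′ of the TSS, including peaks running
  past the termination site (TTS), since `S` is reserved for the start.

Signed distances run from the TSS to the peak center in gene orientation
(negative upstream). Per-gene codes condense to the compact reporting
form `"<support><code>"`, e.g. `"4G"` for a gene-body peak seen in all
four replicates, or `"4P, 2P"` for two distinct promoter peaks. The
2,000-bp promoter default reflects the compact promoter architecture of
*Arabidopsis*-sized genomes and the observation that binding concentrates
within a couple hundred bp upstream of the TSS; it is a parameter, not a
constant.

## Integration with differential expression

The DE table is oriented as log2(WT/mutant): positive values mean the TF
is required for full expression. Genes are classed per contrast as
`activated` (log2FC above `min_abs_log2fc`, adjusted $p \le$ `padj_max`),
`repressed` (mirror image), or `unchanged` (including genes whose
adjusted $p$ is missing — missingness from independent filtering is never
coerced to significance or to 1). A gene becomes a
`direct_activation_candidate` under a condition when it has at least one
linked consensus peak there *and* is classed `activated` there; repression
analogously. The defaults `padj_max = 0.05`, `min_abs_log2fc = 0` are
reported in the run manifest; both are exposed because candidate-set
sizes are sensitive to them and no single choice suits all designs.

Overlap between gene sets (e.g. candidates versus an in-vitro binding
list) is tested with the upper-tail hypergeometric probability
$P(X \ge k)$ for overlap $k$ between sets of sizes $K$ and $n$ drawn from
a universe of $N$ genes, computed in log space via `phyper()`; the
universe defaults to the annotated gene count of the supplied GFF3, a
Benjamini–Hochberg helper covers many-list testing.

## Motif positional statistics

Binding-site motifs are supplied as IUPAC-degenerate patterns (presets:
`GTACTRC`, `TCTTCTST`, the `GTAC` core, and the extended `AGTACA`
variant) and matched exactly over their character classes on both strands;
an `N` in the sequence is an unknown base and never satisfies a non-N
motif position. Three statistics describe where motifs sit:

1. **Copies per peak** — all matches (overlapping ones included, so tandem
   arrangements count every copy) whose midpoint falls inside the peak.
2. **Distance to peak center** — site midpoint minus peak center, binned
   in 75-bp bins centered on zero. Midpoints, not starts, keep distances
   symmetric for even- and odd-length motifs; signed distances are the
   default, absolute available by flag.
3. **Normalized positional profile** — upstream sites map to real bp
   before the TSS, intra-genic sites to (fraction of gene length) × 2,000
   so every gene body spans the same axis segment, and downstream sites to
   real bp past the normalized TTS; binned at 200 bp. For profile
   assignment each peak contributes its closest-TSS linked gene ("primary
   gene"), avoiding double-counting of sites whose peak links several
   genes.

## The synthetic dataset

Because real direct-target analyses start from deposited sequencing runs,
the package ships a generator that emulates their *downstream products*
with known ground truth: a random two-chromosome, 1-Mb-per-chromosome
genome with 250 non-overlapping stranded genes; 200 true binding sites
centered 150 bp upstream of distinct TSSs, each carrying two planted motif
instances; four replicate peak files per condition in which each site
appears with Normal(0, 20 bp) center jitter, Normal(400, 25 bp) widths and
20% dropout, plus 100 irreproducible background peaks per replicate placed
clear of true sites; one mock peak file per condition (a quarter of mock
peaks sit on true sites to emulate cross-reaction); and a DE table in which
20 bound genes are activated and 20 repressed at |log2FC| = 4 under the
low-copper contrast (30% of sites are low-copper-only, the rest shared;
the control contrast is null). Expression counts are negative-binomial
(dispersion 0.05, 3 replicates per genotype); p-values come from a Wald z
statistic on log2 counts with a delta-method model variance, adjusted per
contrast by Benjamini–Hochberg — a deliberate simplification, since the
pipeline consumes only (log2FC, padj) and the DE model itself is not under
test. All draws come from one stream seeded once, so a seed reproduces
every file byte for byte.

What passing on this dataset shows — and what it does not: the generator
produces clean Gaussian jitter, uniform background, and independent
replicates. Real ChIP-seq adds correlated artifacts (blacklist regions,
copy-number bias, antibody batch effects) and real DE adds correlated
dispersion; recovering planted truth here validates the *logic* of every
stage, not performance on any particular organism's data.

One property of the generator is worth stating explicitly: with
Benjamini–Hochberg control at FDR 0.05 and ~40 true effects, one or two
null genes are *expected* to pass the significance threshold. The
end-to-end check of the calling logic therefore compares calls against
the intersection of truly-bound genes with *observed* expression classes
(which the conjunction must reproduce exactly when dropout is zero),
while precision/recall against the *planted* classes are reported by
`score_against_truth()` as performance numbers.

## Numerical and edge-case choices

* Ranges are held as standard 1-based closed `GRanges`; BED/narrowPeak
  files are converted at the boundary. Center and window arithmetic uses
  the continuous extent $[start-1, end]$, so all worked examples in BED
  coordinates hold exactly.
* Chromosome names match by exact string equality; `"Chr1"` and `"1"` are
  different sequences, and mismatches surface as empty overlaps rather
  than being silently aliased.
* Degenerate inputs are contracts, not crashes: empty peak files warn and
  return empty sets; an unattainable `min_support` produces empty but
  well-formed outputs at every later stage; empty motif-site sets give
  zero-row histograms, never `NaN` densities.
* Duplicate identical peaks within a replicate are deduplicated with a
  warning; support counts distinct replicates, so duplicates cannot
  inflate it.
* `merge_criterion` uses `>=`, so an overlap of exactly 80% of the
  shortest segment merges; `windows_overlap` uses strict inequalities on
  half-open windows, so windows that merely touch do not match.

## Scales used in validation

The shipped tests run the full pipeline on the reference simulation
(200 sites, two conditions, four replicates, ~2 Mb genome; about a minute
per run), brute-force oracle comparisons on 200 random instances of up to
50 peaks, scanner-versus-regex equivalence on 1,000 random 500-bp
sequences, and exhaustive hypergeometric enumeration for all universes up
to $N = 12$. These sizes exercise every code path while keeping a full
check fast enough to run routinely; they are choices of the package, and
all of them scale up by changing the corresponding configuration values.

## Limitations

* Presence/absence condition comparison only — no read-count differential
  binding (a complementary analysis with different input requirements).
* Exact degenerate matching, not position-weight-matrix scoring; de novo
  motif discovery is out of scope by design (discovery needs the real
  peak sequences; scanning reproduces all positional analytics).
* Transcript-isoform-level annotation (alternative TSSs) is not modeled;
  gene models are single-interval.
* The peak-to-gene association window is a default, not an inference;
  candidate counts depend on it and on the DE thresholds, which is why
  both are recorded in the manifest of every run.

## A minimal run

```{r, eval = FALSE}
library(ChIPdirect)
res <- run_all(run_config(out_dir = "chipdirect_run", seed = 1))
res$scores$site_recovery
res$targets$set_sizes
```
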