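---
title: "Methods: TE landscapes, piRNA signatures and silencing-pathway ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TE landscapes, piRNA signatures and silencing-pathway ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tescape)
library(dplyr)
```

`tescape` implements a desk-scale version of the analysis stack used to
characterize transposable-element (TE) communities and their germline
silencing in species without reference genomes: repeat-library hygiene and
redundancy clustering, shotgun-read masking and genome-proportion
estimation, TE community diversity, divergence ("amplification") landscapes,
small-RNA preprocessing, putative piRNA selection, the ping-pong signature,
superfamily-level expression aggregation, and cross-species
silencing-pathway expression ratios. This vignette documents the models,
parameter choices and numerical conventions; the README shows the worked
example.

## Coordinates, alphabet and formats

All coordinates are 0-based half-open internally. RepeatMasker tables
(1-based inclusive, with the "C" column-order quirk for minus-strand hits)
are converted on read and restored on write; minus-strand hits always store
forward-strand consensus coordinates plus a strand flag. Small-RNA input may
be RNA (U); it is normalized to the DNA alphabet on ingest and the original
alphabet is restored on write. Records with symbols outside `A,C,G,T,U,N`
are rejected with a report rather than silently altered. Unparseable
RepeatMasker lines (headers, alignment bodies) are skipped and counted, not
fatal, because real `.out`/`.align` files always contain them.

## The mismatch-bounded ungapped mapper

Small-RNA work needs full-length, ungapped, bounded-mismatch matching
(Bowtie-v semantics). `map_with_mismatches()` finds *every* placement of a
query on a target with at most *k* substitutions. It splits each query into
`k + 1` disjoint exact seed blocks; by the pigeonhole principle any
placement with at most `k` mismatches matches at least one block exactly.
Seed hits (a `Biostrings` `PDict` scan over the concatenated targets) are
verified by Hamming count, so the result is provably identical to a
brute-force sliding window, which the test suite asserts on a thousand
random instances. Problems too small to amortize the seed index are scanned
directly; the two paths return identical hit sets. Queries containing
ambiguous symbols take the scan path.

Orientation policy: antisense queries are reverse-complemented before
matching and all offsets are reported on the target's forward strand, so
the 5' end of an antisense read sits at `offset + width - 1`.

## Repeat landscape estimation

`mask_reads()` is a deliberately small stand-in for a full repeat masker:
exact 11-mer seeds (stride 4) on both strands, ungapped extension along the
seed diagonal, per-read greedy attribution by score (`aligned length - 2 x
mismatches`; ties break to the lower consensus id, then lower coordinate)
so each read position is masked at most once. Divergence is the raw Hamming
mismatch fraction — no Kimura-style multiple-hit correction — both because
the synthetic ground truth is substitution-only (making the raw fraction
exact) and because parsed RepeatMasker divergences are passed through
verbatim, whichever correction the producing tool applied. Alignments more
diverged than `max_div` (default 40%) are dropped as chance-level.
Percent-of-genome figures divide merged masked base pairs by the total
sequencing effort; running once with and once without unclassified repeats
in the library brackets the contribution of degraded TE copies.

`cluster_contigs()` approximates CD-HIT-est's greedy incremental
clustering: entries sorted by decreasing length, each joining the first
cluster whose representative matches at or above the identity threshold,
with identity defined as matches over the shorter sequence under the best
ungapped offset (forward strands only). Exact CD-HIT replication (banded
gapped alignment, word filters, both-strand comparison) is out of scope;
at the thresholds used (1.0, 0.95, 0.80) the greedy structure is the
scientifically relevant behaviour.

## Diversity indices

TE superfamilies are treated as species and masked base pairs as
individuals. Simpson's index uses the finite-sample form
`D = sum n_i(n_i - 1) / (N(N - 1))`, Shannon's `H = -sum p_i ln p_i` with
`0 ln 0 = 0`. Unclassified repeats and categories identifiable only to
class level are excluded before the calculation. On the bundled landscape
table the 17 named superfamilies with numeric percent-of-genome values
(library excluding unknowns) give `H = 1.92` (2 dp), which the acceptance
suite pins. The community's published Gini-Simpson value (0.83) is
reproduced from the printed columns only if the percentage values are fed
to the finite-sample formula as though they were individual counts (an
`N` of about 39 "individuals"), which inflates `1 - D` relative to its
proportion-based value of about 0.81; the base-pair counts the index is
actually defined over are not printed. Because that reconstruction rests
on treating percentages as counts, the package does not pin the published
Simpson number and validates the implementation against closed forms and
limits instead.

## Divergence landscapes and activity calls

Each read contributes once per superfamily via its least-divergent hit,
binned at 1%. "Ongoing activity" is the presence of reads in the `[0, 1)`
bin. Shape labels are assigned after 3-bin moving-average smoothing
(partial windows at the edges): a smoothed maximum in bin 0 is
`recent-peak-decreasing`; otherwise one smoothed local maximum is
`past-peak-unimodal`, more are `past-peak-multimodal`. The smoothing rule
exists because published classifications of these histograms are visual;
3 bins is the narrowest window that stops single-bin noise from splitting
peaks, and the tests pin its behaviour on hand-worked cases.

## Small-RNA processing and the ping-pong signature

Filtering order is length (18-40 nt), N-content, then contaminant removal
by exact full-length matching (both strands) against mitochondrial/rRNA
references — exact matching is conservative and deterministic where the
original tooling used aligner defaults. Putative piRNAs are the 25-30 nt
subset; both total and unique counts are reported since both denominators
are in common use. miRNA annotation is exact-match against a reference
catalogue over 21-24 nt reads.

Sense piRNA mapping allows 0 mismatches (a primary piRNA processed from a
transcript should match it exactly); antisense mapping allows 3 (slicer
cleavage tolerates imperfect pairing). Transcripts lacking hits in either
orientation are excluded before signature computation. For sense 5' at `s`
and antisense 5' at `a` (transcript coordinates), the overlap is
`a - s + 1`; every (sense, antisense) placement pair on the same
transcript with overlap 1-25 is counted once, read-level (duplicate
sequences count per read, multi-mapping pairs per transcript), because the
upstream definition is transcript-centric and read-abundance collapsing is
not specified anywhere authoritative. The Z-score at the focal length
(10 nt) standardizes the focal fraction against the sample mean and
standard deviation (n-1) of all other overlap fractions in 1-25; it is
undefined (NA) when the background is degenerate. This background
construction is stated explicitly so results are reproducible — published
ping-pong pipelines delegate it to scripts without printing the formula.

## Expression aggregation and tests

TPM uses the transcript length as effective length — no fragment-length
correction — keeping the synthetic oracle closed-form; every nonzero
sample column sums to 1e6. Superfamily expression averages each
transcript's TPM across same-sex replicates and sums within superfamily.
Sex-bias testing is Welch's t on `log10(TPM + 1)` per superfamily (the
pseudocount handles zeros, which log-transforming pipelines rarely state),
skipping superfamilies under 10 transcripts. Full differential-expression
machinery is intentionally out of scope; where a transcript shortlist from
such an analysis exists it can be applied as a pre-filter. Abundance-
expression association is OLS on log10-log10 with non-positive values
excluded.

On the bundled landscape table, the published abundance-expression
correlations were computed over superfamilies "detected in both the
genomic and transcriptomic datasets", a set whose membership is not
enumerated; with percent-of-genome as the abundance measure the testis
correlation over superfamilies with printed percentages falls below the
published magnitude (0.66), while genomic contig counts — also a Table
column, and defined for all shared superfamilies including those whose
percent column is blank — give 19 shared superfamilies for testes and
r of about 0.90 in both sexes. The package therefore checks the
correlation as a direction-and-magnitude property on contig counts.

## Pathway ratios across species

The gene sets (21 piRNA-processing genes, 14 NuRD-and-associated
repressive genes, TRIM28, 14 miRNA-processing genes) ship as a YAML
resource. Per individual, each silencing set's summed TPM is divided by
the miRNA set's summed TPM; the miRNA pathway is the normalizer because
its expression is not expected to scale with genome size. In full mode
genes missing from a species' table contribute zero (emulating missing
annotations); conservative mode first intersects all sets with the genes
present in every species — the published conservative subsets are not
enumerated, so intersection is the stated assumption. The genome-size test
is OLS of the per-species mean ratio on log10(genome size) with a 95% CI
on the slope; constant ratios give slope 0 and r = 0 by convention.

## The synthetic-data generators

The generators exist so every stage has planted ground truth:

* `simulate_repeat_genome()` plants per-superfamily genome proportions
  (deterministic read counts, `round(p * n_reads)`, so the planted
  landscape is exactly the configured one), random consensus sequences,
  and per-read divergence drawn from point/exponential/normal/mixture
  models, realized as `Binomial(read length, d/100)` substitutions at
  distinct positions. Substitution-only mutation keeps Hamming divergence
  an exact oracle; indels and rearrangements are deliberately absent.
* `simulate_transcriptome()` draws per-replicate counts multinomially with
  probability proportional to expression times length, so TPM recovery is
  closed-form.
* `simulate_small_rna()` plants a piRNA pool (lengths
  `round(N(29, 1))` clamped to 25-30), an exact first-nucleotide-U
  probability `u`, and ping-pong sense partners at probability `rho` whose
  5' ends sit exactly 10 nt into their antisense trigger. miRNA reads (the
  22-nt secondary peak) and contaminant fragments come from bundled
  synthetic references — 50 random 22-mers and random rRNA/mito stand-ins,
  exact-match annotatable, no external catalogue required.
* `simulate_species_panel()` draws per-individual TPM log-normally around
  species means; a zero noise setting reproduces configured ratios
  exactly.

What passing recovery tests does and does not show: the generators share
the pipeline's coordinate conventions and mutation model, so they validate
bookkeeping, estimator arithmetic and statistical calibration — not
robustness to indels, chimeric contigs, sequencing-error profiles, or
annotation ambiguity in real libraries.

## Problem sizes and calibration checks

The shipped tests run the landscape recovery at 20,000 reads of 150 bp
over two planted superfamilies (50%/30%, exponential divergence with mean
4%), tolerance two percentage points; ping-pong power and null calibration
at 100 seeds per arm with 20,000 piRNAs over 20 transcripts of 1.5 kb
(planted pair fraction 0.3 versus 0); mapper-versus-oracle equivalence on
1,000 random instances with k up to 3; and the pathway-ratio null on the
15-species panel at log-scale noise 0.2 with 100 seeds, requiring the
slope CI to cover zero at least 90 times. These sizes were chosen as the
smallest at which the binomial/OLS error bands in the assertions are
comfortably narrower than the tolerances they check.

## Known limitations

* The masker is seed-and-extend and ungapped; heavily indel-diverged
  copies would be fragmented or missed (real repeat maskers align with
  gaps). Divergences are uncorrected mismatch fractions.
* Clustering identity ignores the reverse strand and gaps.
* Ping-pong pair counting weights placements, not collapsed unique
  sequences; pools dominated by a few hyper-amplified sequences will show
  correspondingly amplified pair counts.
* TPM has no fragment-length or GC correction.
* The conservative pathway-ratio mode depends on which genes the input
  tables contain, not on an external orthology assessment.
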