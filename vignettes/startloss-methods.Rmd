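---
title: "Methods: start-loss candidate discovery, isoform usage, and founder-haplotype dating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: start-loss candidate discovery, isoform usage, and founder-haplotype dating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The disease mechanism this package models

Some essential genes encode two protein isoforms that differ only at the
N-terminus: the shorter isoform is translated from an internal, in-frame
ATG of the longer isoform's coding sequence, typically from an alternative
first exon under a different promoter. When the two isoforms are expressed
at very different ratios across tissues, a single point mutation in the
short isoform's start codon can deplete the protein specifically in the
tissues that rely on that isoform — a tissue-restricted loss of an
otherwise essential gene, compatible with life but severely pathogenic.
`startloss` implements the computational side of hunting for such loci and
for the population history of a recurrent start-loss allele:

1. **Containment scan** — find genes whose shortest protein isoform is an
   exact, in-frame N-terminal truncation of the longest isoform.
2. **Isoform-usage ratio** — quantify, per tissue, the fraction of
   expression attributable to the short isoform, from reads over
   isoform-unique exonic regions.
3. **Dual-isoform variant consequences** — annotate how one genomic
   variant hits each isoform (missense vs start-loss, frameshift
   termination scanning).
4. **ROH and founder-age estimation** — call runs of homozygosity around
   the focal variant, intersect them across carriers, and convert the
   shared genetic length into an age in generations.

## Containment scan

For each gene with at least two coding transcripts, the longest and the
shortest transcript by spliced CDS length are compared (ties broken by
lexicographic transcript id so runs are deterministic; intermediate
isoforms are ignored, which follows the longest-vs-shortest framing of the
original screen). The gene is a candidate iff

* the short isoform's start ATG lies inside the long isoform's CDS at
  frame offset 0 (at CDS position $3k+1$ for some $k \ge 0$), and
* the short protein equals the long protein's suffix from residue $k+1$,
  with no gaps or mismatches; $k$ is the N-terminal truncation in amino
  acids.

Because the criterion demands complete identity without gaps, anchored
string equality is mathematically equivalent to an ungapped zero-mismatch
protein alignment, so no external aligner is needed; a diagnostic
`all_offsets` mode reports matches at non-anchored offsets. The filter
cascade then intersects candidates with an essential-gene list, removes
disease-annotated genes, and keeps truncations strictly below 50 aa
(strict, so a gene at exactly 50 is excluded). The 50-aa bound reflects
that isoform pairs differing by large N-terminal extensions may be
functionally distinct proteins rather than redundant isoforms. Essential
and disease lists are plain one-column files supplied by the user; nothing
is fetched.

Transcripts whose CDS fails translation — no in-frame stop, an internal
stop, or an ambiguity base (N) inside the CDS — are skipped with a
warning, mirroring how tolerant genome-wide scans treat malformed
annotations; they are never fatal. Annotated CDSs without a stop codon are
therefore effectively excluded from the scan.

## Isoform-usage ratio

The discriminating signal between two isoforms is read coverage over the
exonic territory unique to each (interval set difference of the exon
unions). Counting follows the per-region convention of `bedtools
multicov`: a read contributes to every unique region it overlaps by at
least one base, so a read spanning unique regions of both isoforms
increments both counts. An `assign-to-larger-overlap` mode exists but is
off by default; the default is kept for fidelity to the per-unique-exon
counting procedure the statistic comes from.

Counts are averaged across the samples of a tissue *first*, then the
ratio
$$r_t = \frac{\bar c_{\text{short},t}}{\bar c_{\text{short},t} + \bar c_{\text{long},t}}$$
is formed (not a mean of per-sample ratios). A tissue whose mean total
count is below `min_count = 10` is left undefined: with a handful of reads
the ratio degenerates to 0 or 1 and would dominate the variability
statistic. The source procedure is silent on a minimum-evidence rule; 10
mean reads is this package's choice and is exposed in the configuration.
A gene's cross-tissue variability is the range (max − min) of its defined
tissue ratios, needs at least two defined tissues, and a gene is flagged
iff variability is strictly greater than 0.5.

## Variant consequences on both isoforms

SNVs are mapped to HGVS-style c. positions (c.1 = the A of the start
ATG), the affected codon is retranslated, and the effect is classified as
start-loss (codon 1's ATG disrupted), stop-gain, missense or synonymous.
Start-loss is reported as protein effect `p.?` — the convention for "the
downstream protein effect is not predicted" — rather than guessing rescue
from a downstream ATG; `downstream_inframe_atgs()` lists candidate
re-initiation codons for diagnostics, which matters here because the
disease mechanism is precisely isoform-specific ATG loss. Positions
upstream of the ATG are rejected rather than given negative c. numbers:
only coding effects are in scope.

Insertions arrive VCF-style (left-anchored) and are re-expressed as
"between c.$i$ and c.$i{+}1$" in coding orientation. A length not
divisible by 3 shifts the frame: the mutant coding sequence — including
the 3' UTR, since the new stop can lie past the annotated one — is
rebuilt and translated from the first affected codon ($\lfloor i/3\rfloor
+ 1$) to the first stop, yielding `X{n}Yfs*{m}` with the stop at residue
$n+m-1$; a frame that reaches the transcript end without a stop is
flagged `fs*?`. The insertion position is read CDS-relative (consistent
with the c. arithmetic of the locus it models); a transcript-relative
reading would shift the codon numbers and is not used. A 50-nt-rule flag
annotates premature stops more than 50 nt upstream of the last exon-exon
junction as predicted nonsense-mediated-decay substrates; this is an
annotation, not a decay model.

## ROH calling and founder-haplotype dating

Genotypes are kept when depth ≥ 10 and genotype quality ≥ 50 (inclusive
thresholds), on biallelic sites only. Runs of homozygosity are called
with the four classical parameters: at least 5 SNPs, span at least
100 kb, inter-SNP gaps at most 10,000 kb, zero tolerated heterozygous
calls. With zero tolerated hets, every het terminates a run, so a direct
maximal-run caller over the filtered genotype vector is
behavior-equivalent to a windowed scanner for the runs that survive the
thresholds; the windowing machinery (window size, window-proportion
thresholds) is deliberately not reproduced. The caller refuses unsorted
input rather than silently sorting.

The ROH segments containing the focal variant are intersected across
carriers (max of starts, min of ends); a carrier without a focal ROH is
an error, because it falsifies the shared-founder hypothesis rather than
shrinking the interval. The physical interval is converted to
centiMorgans by piecewise-linear interpolation on a cumulative
recombination map (flat extrapolation beyond the anchors, flagged).

**Age model.** Each of $n$ independent meiotic transmission paths from
the founder retains, on each side of the focal variant, an exponentially
distributed segment with mean $100/g$ cM after $g$ generations. The
shared segment is the per-side minimum over paths, so its total genetic
length $L$ is Gamma(2, rate $ng/100$) with expectation $200/(ng)$, and
the method-of-moments / profile-likelihood estimate is
$$\hat g = \frac{200}{n \cdot L_{\text{cM}}}.$$
$n$ is a required input: the mapping from carriers to independent
transmission paths depends on the pedigree structure and is not guessed
(a proband autozygous through both parental lineages contributes two
paths). Because $L \sim$ Gamma(2), $\hat g = 2g/S$ with $S \sim$
Gamma(2,1): the estimator is mean-unbiased but *median*-biased upward by
$2/q_{0.5}(\Gamma_2) \approx 1.19$. The default keeps the plain formula
(its arithmetic is the documented contract, e.g. 4 cM over 10 paths
$\to$ 5.0 generations); `median_debias = TRUE` multiplies the correction
out and makes the estimator median-unbiased under the model, which is
what the recovery properties in the test suite assert at the 10% level.
Confidence intervals are central quantiles of a seeded parametric
bootstrap under the fitted erosion model. Single-cohort estimates are
heavy-tailed by construction ($1/\Gamma_2$ has infinite variance);
consumers should prefer interval estimates or medians over replicated
designs, which is what the acceptance script reports.

The genomic inbreeding coefficient `inbreeding_from_roh()` is the ROH
fraction of the genome considered ($F_{\mathrm{ROH}}$): 50 Mb of ROH over
a ~3.2 Gb autosomal genome gives 1/64, the classical second-cousin-level
coefficient.

## What the simulators emulate — and what they do not

The generators produce every input the pipeline consumes, with recorded
ground truth, deterministic to the byte given (seed, config):

* **Annotation/genome**: candidate loci are built with the
  alternative-first-exon topology (long isoform's private first exon
  carrying codons 1..k; short isoform's first exon extending the shared
  exon upstream, so its ATG is exonic in both). Negatives include
  internal-mismatch pairs, out-of-frame-ATG pairs, disjoint isoform
  pairs and single-transcript genes, on both strands. Truncation depths
  default to 3–60 aa so the 50-aa filter stage is exercised.
* **Expression**: short counts are Binomial(depth, usage) per sample and
  gene. Binomial, not negative-binomial: the downstream statistic is a
  tissue-averaged ratio, and overdispersion moves its variance but not
  its target. Real RNA-seq adds mappability, positional and library-size
  effects that are *not* modeled, so passing recovery tests demonstrates
  the statistic's correctness, not robustness to alignment artifacts.
* **Probands**: haplotype erosion around the focal allele (per-side
  minimum of exponential path retentions), consanguineous closure
  (homozygous across the retained interval), background heterozygosity
  at density 0.3 outside it, Poisson(40) depths, and a configurable
  QC-failing fraction. There is no coalescent, no phasing ambiguity and
  no capture-density structure; real exome data has uneven SNP density,
  so a real shared ROH may be larger or smaller than marker resolution
  suggests. Marker density (default 2,000 markers over 30 Mb, ~15 kb
  spacing) bounds how precisely called boundaries can track the planted
  truth; tests assert agreement within a generous multiple of the
  spacing.

## Numerical and design choices

* Internal coordinates are 0-based half-open everywhere; GTF and VCF
  convert at the I/O boundary. This keeps interval arithmetic free of
  off-by-one adjustments.
* Ties in isoform selection are broken lexicographically; with several
  equally-longest transcripts only the id-first one is compared (an
  any-longest containment mode is available through `check_containment`
  applied to each).
* Degenerate inputs: depth-0 expression yields all-undefined ratios;
  genes whose two transcripts have identical exon structure are flagged
  indistinguishable; an eroded founder interval narrower than the marker
  spacing triggers regeneration (capped) in the simulator, and an
  interval below the ROH caller's minimum span is simply not callable —
  downstream code treats that as "no shared segment".
* All stochastic routines take explicit seeds; bootstrap CIs use 95%
  central quantiles.
* Problem sizes in the test suite and acceptance script (20-gene
  annotations, 30-gene usage panels at depth 1000, 2,000-marker cohorts,
  500–2000 estimator replicates) were chosen as the smallest designs at
  which the binomial/Gamma sampling noise is far from the asserted
  tolerances.

## Known limitations

* Only SNVs and insertions are annotated (no deletions, MNVs or
  splice-site effects); consequences are reported per isoform, not
  aggregated to a single "worst" call.
* The ROH caller assumes het-free runs (the zero-tolerated-het setting);
  a study design requiring tolerated hets inside runs would need the full
  windowed scanner.
* The age estimator is a single-parameter erosion model: it ignores
  haplotype-sharing correlation between related carriers beyond the path
  count, mutation/genotyping error at segment edges, and map uncertainty.
  It deliberately does not claim to reproduce any particular published
  generation count from a physical interval alone — the cM length of a
  published interval depends on the map used.
* Selenocysteine recoding, ribosomal slippage, CDS phase attributes and
  GFF3 input are out of scope.
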