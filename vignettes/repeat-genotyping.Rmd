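---
title: "Genotyping the FGF14 intron-1 GAA repeat from long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping the FGF14 intron-1 GAA repeat from long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgf14gaa)
library(dplyr)
```

## The problem

Spinocerebellar ataxia type 27B (SCA27B) is a late-onset dominant ataxia
caused by expansion of a pure GAA trinucleotide repeat in intron 1 of
*FGF14*. Alleles of at least 250 repeat units are considered pathogenic
(incomplete penetrance), and alleles of at least 300 units fully penetrant.
Screening a cohort for this expansion typically proceeds by long-range PCR
(LR-PCR) across the repeat, gel selection of enlarged products, long-read
(HiFi) sequencing of the selected products, and repeat-primed PCR (RP-PCR)
as an orthogonal wet-lab readout.

Two complications make naive sizing unreliable. First, long reads carry
errors concentrated in low-complexity sequence, so base-level alignment
through the tract is fragile. Second, not every enlarged allele is a pure
GAA expansion: *complex configurations* interleave GAA runs with
GCA-containing motifs (GCAGAA and its extensions), can produce LR-PCR
products and RP-PCR signals that mimic a pathogenic expansion, and are not
considered pathogenic unless an embedded pure run is itself long. A correct
caller must therefore size the tract robustly *and* decompose its motif
structure.

This package implements that analysis as a deterministic pipeline, together
with a synthetic-read generator that reproduces the study design well enough
to test every stage without access to patient data (none are deposited for
this locus study).

## Locus model

All stages share a `locus_template()`: three upstream and three downstream
anchor sequences used to recognise locus-spanning reads, two junction
20-mers spanning the flank/repeat boundaries, the flanks themselves, the
position of an upstream T>A SNP (modelled on rs534066520), and the
six-motif lexicon GCA(GAA)~4~, GCA(GAA)~3~, (GCA)~2~GAA, GCA(GAA)~2~,
GCAGAA, GAA.

The flanks are a *model*, not a copy of GRCh38: they are built so that (i)
each anchor occurs exactly once on its own side and never on the other,
(ii) the junction 20-mers arise verbatim exactly when a tract starts with
one GAA unit (upstream) or ends with two (downstream), and (iii) the flanks
total 150 nt, preserving the product-size identity *200 units + flanks =
750 bp* on which gel selection rests. The repeat's true phase against the
genomic flank is not resolvable from the printed anchor set alone; the
template's phase convention is internal and is calibrated by round-trip
tests (error-free reads of an *N*-unit allele must size to exactly *N* for
all *N* from 3 to 500). One consequence of the construction is that the
upstream flank necessarily ends in `...GAA`, so a degenerate single-unit
tract creates the *downstream* junction upstream of the upstream one;
sizing detects and refuses this (`inverted_junctions`) rather than
reporting a negative span.

## Pipeline stages

**Read extraction.** A read spans the locus if at least one upstream and
one downstream anchor match, with every upstream match ending before every
downstream match begins (this order check rejects chimeras). Both
orientations are searched and the read is normalised to locus-forward;
reads valid in both orientations are rejected as ambiguous rather than
guessed. Matching is exact by default — error tolerance comes from having
three alternative anchors per side — but a per-anchor Hamming tolerance
(`max_mismatches`) is available. `N` never matches. Every input read is
accounted for exactly once, either accepted or in one rejection category.

**Junction sizing.** The repeat is sized from the distance between exact
matches of the two junction 20-mers: `unit_count = round(gap / 3) + 3`,
where the `+3` restores the one GAA unit inside the upstream junction and
the two inside the downstream junction. On multiple matches the last
upstream and first downstream are taken, maximising the enclosed tract
against spurious matches arising under sequencing error. Rounding is
nearest-integer (an integer gap is never half-way, so ties cannot occur);
substitution errors inside the tract leave the gap untouched, and indels
move the estimate by a third of a unit each, which the rounding absorbs.

**Motif decomposition.** The junction-inclusive tract (from 3 nt before the
upstream junction end to 6 nt after the downstream junction start, i.e.
exactly 3 × `unit_count` nt for an error-free pure read) is tokenized by
greedy left-to-right longest-match over the lexicon, with the two 9-nt
motifs tried in the order (GCA)~2~GAA before GCA(GAA)~2~. Unmatched
positions become 1-nt NOISE tokens; token spans always tile the tract.
Greedy was chosen over full dynamic programming for speed; on error-free
motif concatenations it provably attains the minimal-NOISE tiling, and the
test suite enforces equality with a DP oracle on thousands of random
concatenations. One boundary effect is worth knowing: greedy extends a
trailing GCAGAA-family interrupt into GCA(GAA)~4~ when at least three GAA
units follow, so the measured downstream run of a tract written
"...GCAGAA + (GAA)~d~" is d − 3. Where block-exact decomposition matters
(e.g. constructing ground-truth complex alleles), ending the interrupt
region with (GCA)~2~GAA avoids the absorption.

**Terminal runs.** A pure-GAA run is a maximal stretch of GAA tokens in
which isolated noise of at most two consecutive nucleotides is transparent
(mismatched bases are common inside genuinely pure expanded tracts); any
other motif, or three or more consecutive noise nucleotides, ends the run.
The profiler reports the run anchored at the tract start, the run anchored
at the end, and the longest anywhere — complex configurations carry their
long pure runs at the tract ends, and the downstream run is the clinically
scrutinised one.

**Uniform-length selection and allele clustering.** Amplicon read sets can
include shattered or artifactual reads with outlying tract lengths. Sorted
tract lengths are split into candidate populations at gaps of at least 30
nt (10 units); within each population a window of width max(12 nt, 1% of
the median length) slides over the lengths, and the window holding the most
reads wins (ties broken by lower variance, then shorter median, then lower
edge — all order-free, so selection is invariant to input order).
Populations whose best window holds fewer than `min_reads` (default 3)
reads are discarded. The published procedure identifies this dense region
visually on a waterfall plot and gives no numbers; the window rule is this
package's construction and every constant is exposed in
`pipeline_config()`. Selected reads are then clustered into at most two
alleles by splitting at the largest inter-read unit-count gap when it
reaches 10 units (supporting compound heterozygotes); allele summaries are
medians across reads.

**Classification.** An allele is PURE when its consensus purity (GAA
nucleotides over all motif nucleotides) reaches 0.95 — the published
classification is made visually from waterfall plots, so a numeric
threshold is unavoidable and configurable; otherwise it is a complex
configuration split at an embedded run of 100 units. Penetrance bands are
inclusive integer intervals: ≥ 300 FULL, 250–299 INCOMPLETE, 200–249
UNCERTAIN, below 200 BELOW.

**RP-PCR prediction.** The wet assay's ladder tracks the longest contiguous
GAA stretch, so the in-silico rule scores each allele by its longest run
(or its whole size when PURE) and maps scores ≥ 191 to *positive*, ≥ 100 to
*inconclusive*, and the rest to *negative*, taking the strongest allele per
individual. These thresholds are bracketed by the observed categories — the
largest negative-run was 83 units, inconclusive runs were 134–167 units,
and the smallest positive pure allele 191 units — and are an inference
from those observations, not an assay specification; whether a smaller
pure allele would still test positive cannot be decided from those data,
so the boundaries are configurable.

**SNP genotyping.** The base at the template SNP position is read per read
at an offset from the nearest upstream anchor match (anchor-relative, no
global alignment, so flank indels cost little); a per-allele call needs at
least 3 informative reads and an 80% majority. The T allele tracks
wild-type and pure expanded alleles, A tracks complex configurations;
`snp_association()` tabulates called alleles by class against base and
counts discordances.

## The synthetic cohort generator

`simulate_cohort()` emulates the study design: diploid individuals with two
alleles drawn from named configurations, per-allele read depths, full-length
reads with independent per-base substitution/insertion/deletion errors
(uniform rates, no homopolymer weighting — adequate at HiFi-like rates
below 1%), random strand per read, and — in amplicon mode — gel selection
that silently removes products of at most 750 bp, exactly as preparative
electrophoresis removes wild-type alleles from sequencing. All randomness
flows from the single spec seed; with `exact_counts = TRUE` genotypes are
assigned by quota rather than sampled, so truth tables hit specified counts
exactly. Read ids carry allele and strand after a `|` separator for truth
tracking only; a test scrambles all ids and requires identical output.

`reference_cohort_spec()` mirrors, individual for individual, the published
three-group screen (476 undiagnosed ataxia, 548 MSA, 455 healthy): per
group the published numbers of carriers of pure expansions ≥ 250, 200–249
and < 200 units, complex configurations with embedded runs ≥ 100 units
(with the published terminal-run pairs 34/167, 27/134, 27/160, 31/140), and
complex configurations with runs < 100 units spanning the published ranges;
everyone else is a (GAA)~16~/(GAA)~16~ wild-type homozygote and every
carrier is heterozygous with that wild-type allele. Where a published
per-individual value exists (269, 254, 245, 212, 240, 191 units) it is used
verbatim; where only a range is printed, values span the range
deterministically (for the six ataxia alleles ≥ 250: 251, 300, 305, 312,
330, 361 — five in the full-penetrance band, as published). Two judgement
calls deserve note:

* the 191-unit pure product is 723 bp and fails a literal > 750 bp gel
  rule, yet it was among the gel-selected samples — gel mobility near the
  cutoff is approximate. The generator therefore supports a per-allele
  `gel_override` flag, used for exactly that allele, while `gel_select()`
  itself stays exact;
* complex tracts end their interrupt region with one (GCA)~2~GAA so that
  greedy tokenization reproduces the intended terminal runs block-exactly
  (see the boundary effect above).

Default per-allele depth is drawn from 20–200 reads, a desk-scale reduction
of the per-individual read counts of amplicon HiFi runs (published median
1,644, range 22–17,480); the cohort-scale tests fix depth at 20, which
keeps the full three-group simulation (1,479 individuals, ~1,800 reads) at
about a minute on one CPU.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: PCR stutter and chimeric molecules, somatic
mosaicism of repeat length, the systematic shortening of LR-PCR products
relative to the germline allele (the pipeline's `sizing_bias()` quantifies
that shortening when both amplicon and PCR-free sizings are supplied, e.g.
the published medians 269 vs 283 and 307 vs 318 give differences of 14 and
11 units), quality-score structure, and reads that only partially span the
locus. Cohort-level reproduction of the published frequency table is a
consistency check of the pipeline's bookkeeping under the study's
conditions, not a validation against raw patient reads.

## Statistics

`frequency_table()` counts each individual once under its highest-priority
category (pure ≥ 250 > pure 200–249 > pure < 200 > complex run ≥ 100 >
complex run < 100), reports the allele size for pure categories and the
longest embedded run for complex ones, and rounds percentages half-up to
one decimal, matching the published table's formatting (that table's
"5.3%" for 24/455 is the half-up rounding; the accompanying text's "5.2%"
is a truncation and the table is taken as authoritative).

`fisher_exact()` conditions on both margins and computes the two-sided p
as the sum of hypergeometric probabilities of tables no more probable than
the observed one (the "small-p" convention, stated explicitly because
two-sided conventions differ and the source names none), in log space, with
the sample odds ratio ad/bc. The test suite proves equality with full
enumeration on every 2×2 table with margins up to 40. On the cohort
contrast of 6/476 ataxia versus 1/455 healthy carriers this gives p ≈ 0.12;
the figure printed alongside that contrast in the source study (0.18) does
not correspond to any standard two-sided convention on that table, so the
package reports its own exactly-defined value rather than hard-coding a
number it cannot derive.

`spearman_exact()` correlates midranks and, for n ≤ 8, computes the
two-sided p by full enumeration of all n! permutations (the published
onset-versus-size correlation has n = 6, so it is exact there); larger n
uses the z = ρ√(n−1) normal approximation.

## Worked example

```{r example}
tpl <- locus_template()

# an MSA-like carrier: wild-type allele fails the gel, the 269-unit pure
# expansion amplifies
reads <- simulate_reads(
  build_allele_sequence(tpl, allele_config(list(c("GAA", 269)))),
  depth = 20, error_model(sub_rate = 0.002, seed = 42)
)
call_individual(reads, "patient1", "msa") |>
  dplyr::select(sample, allele1_units, allele1_class, allele1_band,
    rp_prediction, snp_genotype)
```

```{r waterfall, fig.width = 6, fig.height = 3}
cx <- allele_config(
  list(c("GAA", 34), c("GCAGAA", 40), c("GCAGCAGAA", 1), c("GAA", 167)), "A"
)
cx_reads <- simulate_reads(
  build_allele_sequence(tpl, cx), 12, error_model(sub_rate = 0.003, seed = 7)
)
prof <- profile_reads(extract_repeat_reads(cx_reads, tpl), tpl)
plot_waterfall(prof)
```

## Numerical choices, degenerate inputs, limitations

* Coordinates are 0-based half-open throughout; `junction_up_end` is
  exclusive.
* `count_units()` errors on a negative junction gap; `locate_junctions()`
  reports which junction is missing, or `inverted_junctions`.
* An empty FASTQ yields an empty extraction with a zeroed summary; an
  individual with no locus-spanning reads is called with empty alleles and
  flagged `no_locus_reads` (in amplicon mode this is the expected call for
  wild-type homozygotes).
* Purity is undefined (NA) when a tract contains no motif tokens at all.
* Clusters below `min_reads` are dropped with a warning count rather than
  reported; two reads are never enough for an allele call.
* The pipeline does not polish consensus sequences, does not phase beyond
  the single template SNP, and does not align to a reference genome;
  WGS-derived reads are expected pre-extracted (or are found by the same
  anchor scan). The 5′ flanking 17-bp deletion–insertion variant sometimes
  discussed at this locus is out of scope (its sequence is not modelled).
* With a single allele call the SNP genotype is reported as homozygous for
  the observed base; in amplicon mode the gel-excluded wild-type partner is
  invisible, so a heterozygous carrier's genotype reflects only the
  expanded allele. Allele-level association (`snp_association()`) is
  unaffected.

## Problem sizes used by the tests

The acceptance-style tests run the full truth-mirrored cohort (1,479
individuals at depth 20, error-free), the exhaustive Fisher enumeration
(margins ≤ 40, >50,000 distinct tables), 1,000 random tokenizer
concatenations against the DP oracle, and exact sizing round-trips for
every allele size from 3 to 500 units — together a few minutes on one CPU.
These sizes were chosen to exercise every code path at full published
cohort scale while keeping the suite fast enough to run on every change.
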