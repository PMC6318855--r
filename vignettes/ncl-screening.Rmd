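---
title: "Post-screening non-co-linear transcript events: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-screening non-co-linear transcript events: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Non-co-linear (NCL) transcripts carry exon junctions whose order or
orientation contradicts the reference genome: back-splice junctions of
circular RNAs, intragenic trans-spliced junctions, and intergenic fusion
junctions. Many RNA-seq detectors call such events, and their call sets
disagree substantially — both in which events they report and in how many
junction-spanning reads (`N_NCL`) they attribute to each. A large share of
the disagreement comes from false positives, especially alignment
ambiguity: short reads from repetitive or paralogous sequence can fake an
NCL junction.

`nclscreen` is a post-processor. It does not detect events; it takes the
tables the detectors already produced, puts them on a common footing,
removes events whose junction-flanking sequence has an ambiguous alignment,
and attaches per-event reliability and expression-context metrics so that a
user can rank events before committing to validation experiments.

## Pipeline stages

### Harmonization

Detector coordinates wobble by a few bases around splice sites. Each
reported donor position is snapped to the nearest annotated donor boundary
(transcript-direction exon end) and each acceptor to the nearest annotated
acceptor boundary (transcript-direction exon start), provided the distance
is at most `snap_dist = 5` bp. Events where either side has no annotated
boundary within range are set aside in an audit table rather than
silently dropped: restricting to annotated junctions is deliberate, since
junctions at known exon boundaries are the reliably comparable subset and
several detectors only ever report them.

Numerical choices here:

* donor and acceptor snapping use separate boundary indexes, so the two
  roles can never swap;
* a tie at equal distance resolves to the smaller genomic coordinate
  (deterministic and documented, nothing deeper);
* the two sides snap independently — we do not require that one
  transcript own both boundaries, because fusion junctions never satisfy
  that and intragenic events may span isoforms;
* if one tool reports the same harmonized junction twice, the counts are
  summed and a warning logged.

After snapping, the per-tool reports are unioned by junction key. An event
is `intragenic` exactly when the donor's and acceptor's owning gene-id
sets intersect, otherwise `intergenic`.

### Ambiguity screening

For each event we rebuild the sequence a junction-spanning read would
traverse: the last `flank = 100` nt of spliced transcript sequence ending
at the donor, concatenated with the first 100 nt starting at the acceptor.
Flanks walk the *spliced* transcript, not the genome, because the flanking
sequence of an NCL junction is exonic. When several transcripts own a
boundary, the one giving the longest flank is used (ties by transcript
id). For an intragenic event whose exonic circle — the acceptor-to-donor
exonic span — is shorter than 200 nt, the circle sequence is used exactly
once and split evenly between the two flanks; duplicating circle sequence
would manufacture artificial self-similarity, and an even split keeps the
junction centered for the alignment check. Minus-strand sequence is
reverse-complemented. The junction offset within the query (equal to the
donor flank length) is carried along.

The concatenated sequences are written as FASTA and aligned externally
(BLAT against the genome and the annotated transcripts); the pipeline
consumes the resulting PSL files. Two failure modes are flagged:

* **Alternative co-linear explanation** — a single alignment crosses the
  junction offset with at least `side_margin = 10` query bases on each
  side and query-wide identity above `identity_threshold = 0.80`. Such an
  alignment explains the reads in normal exon order (typically via
  another isoform), so no NCL junction is needed. The margin guards
  against trivially clipped hits; the identity is measured against the
  whole query, so partial hits are penalized proportionally.
* **Multi-hit** — among genome alignments covering at least
  `min_coverage = 0.5` of the query, two or more distinct target loci
  score within `score_gap = 3` of the best. The score is the web-BLAT
  convention `matches + repMatches − misMatches − qNumInsert −
  tNumInsert`. The event's own donor/acceptor split pair counts as one
  locus, as do duplicate hits at an identical interval.

An event satisfying both is reported once as `alt_colinear` (the more
specific diagnosis); both raw flags are retained in the evidence columns.
A query with no hits at all is reported `ok` with zero scores and a
warning, since absence of alignment is not evidence of ambiguity.

### Evidence counting

Around each harmonized junction we count, from the splice-junction table
of the aligner (unique reads only — multi-mappers are excluded
throughout):

* `N_D`: unique reads over all annotated introns whose donor-side exonic
  boundary equals the event's donor position (several across isoforms;
  deduplicated by genomic interval), and `N_A` symmetrically;
* per-gene totals over every annotated intron, the denominators of
  junction usage;
* for intragenic events, the number of read pairs with one read on the
  NCL junction and the mate aligned *entirely* outside the closed circle
  interval (or on another chromosome). Mates straddling a circle edge do
  not count — a strict rule is the conservative reading, since a
  straddling mate is consistent with the circular isoform. A positive
  count argues for an intragenic trans-spliced isoform rather than a
  circRNA.

### Metrics

With `N_i` the count reported by tool `i` (zero for tools that did not
detect the event) over the `n` compared tools:

$$\tau = \frac{\sum_{i=1}^{n} \left(1 - \frac{\log(N_i + 1)}{\log(\max(N) + 1)}\right)}{n - 1}$$

ranges from 0 (all tools agree on one positive count) to 1 (a single
tool). The log base cancels. The reliability score is

$$\mathrm{score} = \log_{10}\frac{\mathrm{Median}(N)^2 + \kappa}{\tau + \kappa},
\qquad \kappa = 0.01,$$

with the median over the full `n`-vector, zeros included. Including
non-detectors as zeros is what makes the score separate tool-specific
events: a junction seen by one tool out of six has median 0 and tau 1,
scoring near −2, regardless of how many reads that one tool claims.
`n` is fixed per locus class by the configured tool panel (each tool's
`scope` declares whether it reports intragenic, intergenic or both), not
recomputed per event. Medians of even-length vectors are the mean of the
two central values.

Abundance relative to co-linear splicing at the same boundaries:

$$R = \frac{2N_{NCL}}{2N_{NCL} + N_D + N_A}, \qquad
CF = \frac{N_{NCL}}{N_{NCL} + N_D + N_A + 1}.$$

`R > 0.5` (equivalently `CF` above roughly 1/3) means the NCL isoform
out-expresses its co-linear counterpart. For these and for RPM we need a
single representative `N_NCL`; we use the median over the tools that
*did* detect the event. A tool that missed an event contributes no count
measurement, and a zero-inflated median would zero the abundance of every
minority event — so reliability metrics use the zero-filled vector while
abundance metrics use the detected-only median. Both medians are reported.

Junction usage within the host gene: `P_D = N_D /` (sum of unique reads
over all the gene's annotated junctions), `P_A` likewise, and `P_median`
the median per-junction usage of the gene, the baseline the NCL
boundaries are compared against. For intergenic events the two sides have
different host genes, so the per-side medians are both reported (the
natural resolution when one gene cannot be singled out). When a boundary
is owned by several genes, the host is the intersection gene for
intragenic events and the lexicographically first owner otherwise.

`RPM_raw` and `RPM_mapped` divide the representative count by the library
sizes (raw reads; uniquely mapped reads), which come from the
sequencing/alignment logs via the run configuration — they are inputs,
never recomputed. TPM/FPKM are joined from an external quantification
table per host gene, never computed here. SCE (synonymous constraint
element) overlap flags are positional lookups; when no SCE annotation is
supplied they render as `NA`, never as false or zero.

### Reports

Results are split into intragenic and intergenic tab-delimited tables; in
the default `drop_ambiguous` mode flagged events move to a side table, so
the accounting identity *before = alt_colinear + multi_hit + after* holds
per locus class on every run. A tool-membership matrix, per-tool
summaries (detections, tool-specific events, ambiguous fractions), the
supporting-tool histogram, and empirical cumulative distributions of tau
and the score per stratum (locus class × ambiguous/non-ambiguous) are
exported for external plotting or Kolmogorov–Smirnov testing. Output is
deterministic: fixed sort (chrom, donor, acceptor), floats at six
decimals, `NA` for missing optional annotations.

## The synthetic fixture generator

Real inputs require a sequencing library, a panel of third-party
detectors, BLAT and a spliced aligner. To keep the package fully testable
without any of that, `simulate_ncl_fixture()` builds the entire input
universe with planted ground truth:

* a random genome with non-overlapping multi-exon genes on both strands
  (defaults: 36 genes, 4–8 exons of 100–300 bp, introns 100–400 bp, two
  chromosomes); a fraction of genes get a second exon-skipping isoform —
  the structure behind genuine alternative co-linear explanations — and a
  200 bp exonic segment is copied twice into a gene-free tail so decoy
  loci carry truly aliasing sequence;
* planted events: 30 circRNA, 10 intragenic trans-spliced (with 1–5
  planted out-of-circle mate pairs each), 10 fusions, all at annotated
  boundaries, each claiming boundaries and adjacent introns no other
  event touches so planted counts are recoverable without interference;
  10 events receive alternative-co-linear evidence and 10 multi-hit
  evidence;
* per-tool tables from a six-tool panel: detection probability 0.8 per
  tool (every event keeps at least one detector), reported counts under
  multiplicative log-normal noise (sdlog 0.25, floored at 1), and 30% of
  records jittered by up to 3 bp to exercise snapping;
* directly-authored PSL, splice-junction and chimeric files realizing the
  planted classes: every event gets its genuine split self-pair; multi-hit
  events add two decoy-locus hits with scores 2 apart at 60% query
  coverage (inside the score gap, below the identity threshold); planted
  alternative-co-linear events add a transcript hit crossing the junction
  at 85% identity.

The defaults were set once to resemble a small multi-detector study — the
six-tool panel matches a typical fusion-detector comparison, and the
detection/dispersion levels produce the visible between-tool disagreement
the method exists to quantify. Everything derives from a single seed
(each stage uses `seed` plus a fixed offset), and fixture trees are
byte-identical across runs.

What the generator does *not* emulate: read-level sequencing error,
fragment-length distributions, RT template-switching artifacts,
expression-dependent detection bias, and real repeat families (alignment
files are authored directly rather than produced by an aligner over
simulated reads). Passing tests therefore demonstrate that the
harmonization, classification rules and metric arithmetic are implemented
correctly and recover planted structure — not that the thresholds are
optimal for any particular real library. An integration with real data
replaces the authored files with BLAT PSL output over the exported
junction FASTA and the aligner's SJ/chimeric tables, leaving the
configuration otherwise unchanged.

## Problem sizes and runtime choices

The shipped tests run the generator at its default 50-event size for
end-to-end checks and at a 10-event size for determinism checks; the
property tests sweep 10,000 random count vectors for tau and the full
0–20 count grid for the ratio identity. These sizes were chosen to give
the invariants room to fail while keeping a full suite run around a
minute on one CPU.

## Known limitations

* Whether "80% identical" in the ambiguity rule should compare against
  the query length or against the event's own best split alignment is a
  judgment call; this package fixes query-wide identity, configurable via
  `identity_threshold`.
* Chimeric records are matched to events by coordinate proximity (the
  snap radius); read-level re-alignment is out of scope, so a mate pair
  supporting two nearby events would be credited to both.
* Strand agreement between the junction-supporting read and its outside
  mate is not enforced when counting out-of-circle pairs.
* TPM/FPKM and library sizes are consumed, not estimated; garbage in,
  garbage out.

## A minimal session

```{r}
library(nclscreen)

## self-contained demonstration inputs
fx <- simulate_ncl_fixture(sim_config(seed = 1), "fixture")

## the full screen, reports written as TSV
res <- ncl_screen(fx$run_config, out_dir = "fixture/out")

## reliability metrics of surviving intragenic events
res$results$intragenic[, .(key, tau_ncl, ncl_score, r_ncl, cf)]
```
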