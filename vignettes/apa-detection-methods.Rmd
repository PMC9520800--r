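---
title: "Detecting 3'-UTR alternative polyadenylation from coverage: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting 3'-UTR alternative polyadenylation from coverage: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apadetect)
```

## The problem and the model

A gene with two polyadenylation sites in its 3'-UTR produces a short
isoform (cleaved at the proximal site) and a long one (cleaved at the
annotated distal end). In RNA-seq coverage this leaves a step: upstream of
the proximal site every transcript contributes depth, downstream only the
long isoforms do. A change in proximal-site usage between two conditions
changes the *ratio* of upstream to downstream mean coverage, and that ratio
change — not absolute expression — is what the detector tests.

Concretely, for a candidate cleavage site inside a gene's search region the
package computes, per condition, the summed depth `r` and length `l` of the
upstream and downstream parts, the mean coverages `n = r_u/l_u` and
`N = r_d/l_d`, and the ratio difference `n1/N1 - n2/N2`. If the short-isoform
proportion is `p`, the expected ratio is `1/(1 - p)`, so the ratio
difference is a monotone image of the usage shift. Sites with
`|ratio difference| <= 0.1` are discarded as candidates; the rest are tested
with a Pearson 2x2 chi-square (1 df) on `[[r_u1, r_d1], [r_u2, r_d2]]`.
Significance means both `|ratio difference| > 0.1` and `p < 0.05`.

Two details deserve emphasis:

* **The table holds depth sums, not means.** The chi-square needs
  count-scale input; per-bp means would deflate the statistic by the region
  length. The alternative is available (`table_scale = "means"`), and a unit
  test documents the exact factor between the two. Consequently the
  statistic scales linearly with coverage depth (scaling both conditions by
  `k` multiplies chi-square by `k`); the ratio difference is scale-free and
  the 0.1 filter is what keeps deep libraries from flagging trivial shifts.
* **Filtered is not untestable.** Sites failing the ratio filter carry
  `p = 1` and rank below every tested site; sites with a zero downstream
  mean or a zero chi-square marginal are flagged `untestable` and carried
  through, never silently dropped. In benchmark scoring an untestable true
  event counts as a miss.

## Coordinates, frames and candidate sites

All internal coordinates are 0-based half-open (BED convention); refFlat is
read natively and GTF converted on load. One frame per gene is built from
the coding transcript whose annotated end is 3'-most: the frame runs from
its stop-codon boundary to the gene's 3'-most transcript end. In extended
mode the searched region continues 10,000 bp downstream (clipped at
position 0), deliberately *not* trimmed when it runs into a neighbouring
gene — the overlap is flagged instead, since trimming would silently change
the downstream mean. Genes with a UTR under 50 bp are skipped: there is no
room for an informative split. "3'-most end" rather than "longest
transcript" is the operative reading because the distal boundary is what
bounds the search for distal sites; a transcript of greater total length
with an interior 3' end would not.

Candidates come from one of two sources, resolved automatically: with any
3'-end-seq input, peaks; otherwise PAS hexamers (`AATAAA`, `ATTAAA` by
default; any motif list, e.g. the twelve common variants, is accepted). The
hexamer match places the candidate at the motif's 3' boundary in transcript
orientation with no extra offset — the true cleavage site lies some bases
downstream, but the test splits whole regions and is insensitive at that
scale, and any fixed offset would be a guess. Candidates closer than 50 bp
to either frame boundary are dropped so both flanks of every tested split
are non-degenerate. `N` bases never match. The peak caller defines a hill
as a maximal run of strictly positive pooled coverage; the cleavage
position is the depth argmax within the hill, ties resolved to the 3'-most
position. The reading in which the hill's 3' boundary, not the argmax, is
the site is genuinely open; it is implemented behind `cleavage =
"hill_end"` with argmax as default, since peak height is what quantifies
cleavage at the site.

Replicates within a condition are pooled by position-wise sum before
testing. Pooling is stated behaviour for 3'-end-seq; for RNA-seq replicates
it is a choice, made because the 2x2 test needs one table per site and the
sums are the sufficient statistic under the model above.

## The simulator

The simulator generates the study that the benchmark and the acceptance
script run: `n_genes` genes, each on its own contig with a 100 bp CDS stub,
a UTR drawn uniformly from 800–2000 bp, one proximal site at 25–60% of the
UTR length (at least 50 bp from both boundaries, and far enough from the
distal end that the two 3'-end-seq hills stay separate), and a random
strand so the strand-mirroring code paths are exercised end to end. Per
gene, replicate and condition a transcript count `T ~ Poisson(50)` is
drawn; a fraction `p_short` of it ends at the proximal site, and per-base
depth is drawn independently as `Poisson(depth_scale * copies)` — full
copies upstream of the proximal site, long-isoform copies downstream. Event
genes (`is_event`) differ in `p_short` by an amount uniform on (0.10, 0.5];
null genes by at most `null_jitter`.

Design choices that were genuinely open:

* **Depth-level rather than read-level simulation.** The test consumes only
  regional depth sums, which this model controls exactly; read-level
  simulation would add machinery without changing what is being tested.
  Nothing here models sequencing error, GC bias, fragment-length effects,
  spliced alignment or mappability — passing benchmarks say the statistic
  behaves as designed on its own model, not that real libraries are this
  clean.
* **Proportional isoform split.** `T` is split as `p_short * T` rather than
  binomially. The per-replicate expression draw then cancels from the
  pooled coverage ratio, so estimator noise shrinks with sequencing depth —
  the regime the method actually shows, with accuracy saturating at high
  depth and degrading below it. A binomial split would add a
  depth-independent noise floor that dominates everything and would make
  depth irrelevant.
* **Null jitter of 0.025.** Null genes get a small proportion difference
  rather than exactly equal proportions, so specificity is estimated
  against a realistic null. The default bound is 0.025 (configurable up to
  0.05): the ratio `1/(1 - p)` has slope `1/(1 - p)^2`, up to 4 on the
  simulated `p` range [0.1, 0.5], so 0.025 maps to at most 0.1 on the
  ratio-difference scale — the null class stays identifiable under the
  detector's own filter. A null bound of 0.05 would push a sizeable
  fraction of null genes past the 0.1 filter by construction and measure
  the generator, not the detector.
* **Baseline `p_short` on [0.10, 0.50].** Keeps the ratio transform's slope
  bounded and both isoforms present, so downstream regions are rarely
  empty.
* **Depth presets.** `depth_preset()` maps a library-size label to
  `depth_scale = M/150` per transcript copy: an M-million-pair library of
  2x76 bp reads over a ~100 Mbp expressed transcriptome leaves roughly
  `M/3` per-base depth on a typical UTR per replicate, i.e. ~2x pooled
  coverage at "2M" and ~30x at "30M". On this map detection accuracy
  saturates from "10M" upward and is measurably lower at "2M", matching the
  depth behaviour the detector is known for.

Determinism is contractual: the seed is a mandatory argument, the global
RNG state is saved and restored, and the same (parameters, seed) pair
regenerates the dataset bit-identically. The synthetic 3'-end-seq generator
places a triangular hill (default width 50 bp) at each used site with
height proportional to that site's total usage, jittering the centre by up
to 2 bp; the optional synthetic genome plants the canonical hexamer just
upstream of each proximal site so the PAS path rediscovers the truth from
sequence alone.

## Evaluation

ROC curves sweep a threshold over distinct score values (ties grouped into
one step) with trapezoidal AUC; the implementation is checked against
pairwise concordance (Mann–Whitney) to 1e-9 and against pROC. The ranking
score is `1 - p`, with filtered and untestable sites forced to 0 — the
filter is part of the decision rule, and ranking filtered sites by their
p-value would overstate separation. Sensitivity and specificity use the
fixed `p < 0.05` and `|ratio difference| > 0.1` rule, with genes the
detector could not test counted as negative calls. Validation against
3'-end-seq accepts an event when a peak lies within 50 bp (inclusive) of
the site.

The benchmark sizes are chosen for desk-scale runs: 1000 genes (500 events)
for the headline numbers, 600 genes per seed for the depth comparison;
both complete in seconds to a couple of minutes on one CPU.

## Numerical and degenerate-input notes

* The chi-square is computed from the closed form
  `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` in double precision (entries are
  coerced to double first; the marginal product overflows 32-bit integers
  easily). Non-integer entries are accepted; a Yates-corrected variant is
  exposed but off by default ("canonical" 2x2 test read as plain Pearson).
* Zero marginals, zero downstream means, empty regions, all-zero tracks,
  empty candidate lists and single-class truth vectors all have defined
  behaviour (untestable / empty / error with a named reason) and tests.
* Default-report tie-breaks are total: smallest p, then largest absolute
  ratio difference, then the 5'-most position (strand-aware), so reports
  are byte-reproducible.
* bedGraph input must be position-sorted (checked, error otherwise);
  positions absent from the file are depth 0. BAM depth counting skips
  unmapped, secondary, supplementary and duplicate records, with an
  optional mapping-quality floor (off by default).

## Known limitations

Only 3'-UTR APA is in scope: no intronic or internal-exon events, no
isoform-level quantification, no between-library normalisation beyond the
ratio construction itself, and no PAS-strength model — motif matching is
verbatim. The chi-square inherits coverage-scale sensitivity (documented
above); on very deep real libraries the q-value column and a stricter
ratio threshold are the intended levers. Real-data event counts depend on
annotation completeness and library quality and are outside what the
simulator can certify.
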