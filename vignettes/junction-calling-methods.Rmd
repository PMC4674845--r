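---
title: "Classification-based splice junction calling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classification-based splice junction calling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

When paired-end RNA-seq reads are aligned to a reference *genome* with a
DNA aligner such as BWA, reads that span an exon–exon boundary cannot be
mapped end to end: the aligner places the longer exonic segment and reports
the remainder as a soft or hard clip. Introns also inflate the observed
template length of read pairs that *encompass* a junction, turning them
discordant. `clipjunc` turns these side effects into signal: it detects
candidate donor/acceptor sites, describes each site with a small feature
vector, classifies sites with an SVM trained on labeled data, re-aligns
clipped segments in focal, mate-bounded regions, and assembles junctions
under explicit evidence conditions.

Coordinates are 0-based, half-open throughout. A **donor** position is the
first intronic base (the boundary after the last exonic base); an
**acceptor** position is the first exonic base after the intron. Both
coincide with the clip positions of suffix- and prefix-clipped reads in
reference-forward orientation, which keeps all boundary arithmetic uniform.

## The pipeline

1. **Load and classify records.** Primary records only. A record is `FULL`
   (no clip operations), `SOFT_CLIP`/`HARD_CLIP`, or `DISCARD` (unmapped or
   `mapq < 20`; the threshold is configurable — the method's sources
   discard "low quality" without naming a value). Coverage counts only
   reference-consuming bases of non-discarded reads.
2. **Insert-size model.** Discordance is defined against the closed range
   `[m − 3v, m + 3v]`. Estimating `m, v` from genome-space template lengths
   of transcriptome reads is nontrivial: in gene-dense data a *majority* of
   templates is intron-inflated, so a central trim (e.g. keeping the middle
   99%) does not remove the contamination. The estimator therefore anchors
   on the histogram mode (10 bp bins) of the absolute template lengths and
   iteratively keeps values in `[m − 3v, m + 3v]` (three passes). On clean
   draws it recovers the configured mean/sd within sampling error; under
   >50% one-sided contamination it stays within a few bp. Pairs on
   different contigs or in the same orientation are discordant regardless
   of insert size; boundary values are concordant.
3. **Candidate sites** come from (a) clip positions — one raw site per
   distinct position, direction by majority clip side (suffix→donor,
   prefix→acceptor, ties to donor) — and (b) coverage zero-crossings,
   which recover sites in thinly covered regions (a single fully mapped
   read inside an exon flanks itself with an acceptor and a donor site).
   Sites within `s = 10` bp merge greedily left-to-right, per direction
   (donors and acceptors can legitimately abut, so they never merge); the
   cluster representative is the member with the most clip events, ties to
   the leftmost. Coverage-change sites within `s` of a same-direction clip
   site are suppressed — clip evidence is strictly stronger.
4. **Focal re-alignment.** A suffix clip at `b0` searches candidate
   acceptor sites downstream; a prefix clip searches donors upstream. If
   the mate maps on the search side, its far end bounds the region,
   otherwise the bound is `b0 ± 1,500,000` bp (the maximum junction size).
   Sites are tried nearest-first; the segment is placed flush with the
   boundary and accepted at up to `ceiling(0.04 × clip_len)` mismatches
   (4% tracks typical simulated error rates; the sources are silent).
   A placement that would make the read's own pair discordant is rejected —
   this is what disambiguates repeats within the focal window. If no site
   accepts, an ungapped sliding scan over the whole window may propose a
   `NEW_SITE` (added to the candidate list with origin `REALIGN`); more
   than 5 equally acceptable hits is ambiguous → `UNALIGNED`. Both ends of
   a doubly clipped read are processed independently.
5. **Features and normalization.** Per site: `f_clip` (reads clipped
   there), `f_seg` (clipped segments re-aligned there), `f_disc`
   (discordant pairs whose mates lie entirely on opposite sides — the
   "encompassing" rule is taken literally: neither mate may overlap the
   site), and `f_cov` (mean depth of the left flank minus the right flank
   for donors, mirrored for acceptors; flanks are `l = 25` bp, clamped at
   contig ends with the true clamped length as denominator). All four are
   divided by the mean coverage of the site's *anchor* flank (left for
   donors, right for acceptors) so that expression level cancels. A zero
   anchor yields an all-zero vector rather than a pseudo-count ratio: such
   a site has no local expression and should look weak to the classifier.
6. **Classification.** Features are additionally min–max scaled to [0, 1]
   (stored in the model — this is distinct from the coverage
   normalization). The SVM is this package's own SMO implementation
   (maximal-violating-pair working-set selection on a precomputed kernel
   matrix; validated against libsvm via scikit-learn to ~1e-3 in decision
   values) because no SVM library is part of the supported dependency set.
   Training uses stratified, seeded 10-fold CV with a grid search over
   `C ∈ 2^{-3..7}`, `γ ∈ 2^{-7..3}` (step 2²); the final model refits on
   all examples. Labels: in simulation mode a candidate within 10 bp (the
   merge distance) of a truth boundary of matching direction is positive;
   in annotation mode positives are annotated sites with nonzero local
   coverage (an annotated but silent site is *not* expressed in the sample
   and must not be a positive), negatives an equal-sized seeded sample of
   covered, non-annotated candidates.
7. **Junction calling.** Sites become nodes; a re-aligned clipped segment
   connects the site its read is clipped at to the site it re-aligned at
   (donor→acceptor). A junction is called iff (1) both endpoint sites are
   classified true, (2) an edge exists, and (3) the insert-size conflict
   check passes: for each supporting read the implied *transcript-space*
   insert (reference outer span minus the junction's intron length) is
   tested for discordance; mate-less supports abstain, and the junction is
   discarded only when **all** voting supports conflict — one clean
   placement is positive evidence, which minimizes false negatives from
   occasional mate mis-mapping. Filtered junctions are retained with
   status `CONFLICT_FILTERED` for transparency.

## Benchmarking utilities

Called junctions match a benchmark junction when both boundary distances
are within a slack value; matching is greedy nearest-first (donor +
acceptor distance) and one-to-one, so clustered calls cannot double-count.
`precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`, `F = 2PR/(P+R)`, with 0/0
defined as 0. True positives are non-decreasing in slack by construction.
Call-set overlap between two tools is the TP of the same matcher. The
mapped-base ratio is placed bases over total read bases; with simulator
truth, a base counts only when placed at its true genomic coordinate.

## What the simulator emulates — and what it does not

The generator states a world once: two contigs (`train`/`test`, mirroring
a train-on-one-chromosome, test-on-another design), ~10 transcripts per
contig with 4–6 exons (internal exons 120–300 bp, the last exon 500–900 bp
— long 3'-UTR-like exons are what gives a genome-space library its
population of within-exon pairs, without which no insert model is
estimable), introns from three regimes: 60–85 bp (below `3v`, invisible to
the discordance feature by design), 150–600 bp, 800–1,500 bp, plus one
guaranteed 2,447 bp intron per contig to exercise long-jump focal search
with short clips. Reads are 100 bp, inserts Normal(300, 30), coverage 20×,
substitution errors 0 by default (0.01 in the noisy acceptance world), and
20% of clipped alignments are emitted as hard clips so FASTQ recovery is
always exercised. Expression weights are uniform on [0.5, 1.5] (mean 1, so
realized depth tracks the configured coverage).

The emulated aligner is deterministic and honest about exactly the
behaviors the caller consumes: full-match CIGAR for within-exon reads, the
longest exonic block mapped and the rest clipped for junction-spanning
reads, mate fields and TLEN from true placements. It does **not** model
ambiguous repeat placement, indels, quality-dependent errors, strand
randomness (transcripts are forward-strand), intron retention, or
expression-level biology. A green end-to-end test therefore establishes
the correctness of the post-alignment machinery under clean upstream
behavior — not robustness to a real aligner's pathologies.

## Numerical choices and degenerate inputs

- Mismatch budget `ceiling(0.04 × clip_len)`, minimum 0; 8 bp minimum clip
  length (shorter segments are too ambiguous to place).
- Greedy merge ties: most clip events, then leftmost. Representative
  positions, not cluster means, keep sites on observed boundaries.
- Zero-coverage anchors give all-zero normalized features (see above).
- Empty BAM → zero junctions, clean exit. Mate-less reads abstain from
  conflict votes; an all-abstain edge passes.
- All randomness (weights, fragments, errors, hard-clip draws, folds,
  negative sampling) derives from explicit seeds; simulator outputs,
  training sets and junction files are byte-identical across reruns.

## Known limitations

- Reverse-strand transcripts are not simulated by default; orientation
  handling is exercised only through mate-2 reverse-complement reads.
- The conflict check subtracts only the junction under test from the
  implied insert; a fragment spanning two long introns can still look
  discordant and (if it is the only support) filter a true junction.
- Annotation-mode training requires enough covered, non-annotated
  candidate sites to balance the classes; gene-dense toy regions can make
  this infeasible, which raises an explicit error rather than silently
  unbalancing.
- The published external benchmarks (real mouse/human datasets) are not
  reproducible offline; the acceptance suite substitutes the simulated
  world for the end-to-end claims and reproduces the published metric
  arithmetic exactly.
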