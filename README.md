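# clipjunc

Splice-junction calling from clip-reporting DNA alignments of paired-end
RNA-seq reads.

## The problem

Aligning RNA-seq reads to a reference *genome* with a DNA aligner (BWA and
friends) leaves characteristic scars at exon–exon boundaries: reads that
span a junction are soft/hard-clipped at the boundary, read pairs that
encompass a long intron become discordant (observed template length outside
`[m − 3v, m + 3v]` for insert mean `m` and standard deviation `v`), and
coverage collapses on the intronic side of every boundary. `clipjunc` is
for anyone who has such alignments and wants accurate junction calls
without re-aligning with a dedicated spliced aligner: it treats each
candidate donor/acceptor site as a point in a four-dimensional feature
space and lets a trained classifier — not user-set thresholds — decide
which sites are real.

Per candidate site the features are (i) reads clipped at the site,
(ii) clipped segments re-aligned at the site by focal, mate-bounded search,
(iii) discordant encompassing pairs, and (iv) the flanking coverage
difference; all four are normalized by the site's anchor-flank coverage.
Junctions are then assembled from classified sites under three conditions:
both endpoints true, at least one split-mapped read connecting them, and an
insert-size conflict check on the implied transcript-space insert
(`precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`, `F = 2PR/(P+R)` against a
slack-matched benchmark).

A fully deterministic simulator (toy genome, transcript models, paired
reads, emulated clip-reporting aligner, truth sets) makes every stage
testable offline.

## Worked example

```r
library(clipjunc)
library(data.table)

# simulate a small two-contig world with known junctions
cfg  <- sim_config(seed = 11, n_transcripts = 3)
sim  <- simulate_dataset(cfg, file.path(tempdir(), "demo"))

# run the pipeline up to the feature matrix
pcfg <- pipeline_config(bam = sim$bam, ref = sim$ref,
                        fastq1 = sim$fastq1, fastq2 = sim$fastq2)
run  <- run_pipeline(pcfg, model = NULL)
run$insert_model
#> insert-size model: m = 297.48, v = 42.19 (n = 454)

# train on contig "train", call junctions on contig "test"
examples <- build_training_set(run$features, truth = sim$models$truth)
model    <- train_model(examples[contig == "train"])
model
#> site classifier: rbf SVM, C = 32, gamma = 0.0078125, CV accuracy = 1.0000

pred  <- predict_sites(model, run$features)
edges <- build_connection_graph(run$sites, run$results, run$events)
juncs <- call_junctions(edges, run$sites, pred, run$events, run$pairs,
                        run$insert_model)
head(juncs[contig == "test"], 5)
#>    contig donor_pos acceptor_pos n_clip n_seg n_disc status
#> 1:   test       482          545     20    17      1 CALLED
#> 2:   test       755         1247     28    15     36 CALLED
#> 3:   test      1399         2738     35    17     38 CALLED
#> 4:   test      3026         5473     23    23     29 CALLED
#> 5:   test      6948         7213     13    11      9 CALLED

# slack-matched accuracy against the simulator's truth
bench <- covered_truth(sim$models, sim$reads)
compute_metrics(match_with_slack(juncs[contig == "test"],
                                 bench[contig == "test"], 8))
#> precision = 1.0000  recall = 1.0000  F-value = 1.0000
```

`donor_pos` is the first intronic base, `acceptor_pos` the first exonic
base after the intron (0-based, half-open). `n_clip`/`n_seg`/`n_disc` are
the supporting clipped reads, re-aligned clipped segments, and discordant
encompassing pairs; junctions failing the insert-size conflict check are
retained with `status = CONFLICT_FILTERED`.

A command-line interface wraps the same steps:

```sh
Rscript inst/cli/clipjunc.R simulate --out simdir --seed 11
Rscript inst/cli/clipjunc.R train --bam simdir/aln.bam --ref simdir/ref.fa \
    --fastq1 simdir/reads_1.fastq --fastq2 simdir/reads_2.fastq \
    --truth simdir/truth_junctions.tsv --model-out model.rds
Rscript inst/cli/clipjunc.R call --bam simdir/aln.bam --ref simdir/ref.fa \
    --fastq1 simdir/reads_1.fastq --fastq2 simdir/reads_2.fastq \
    --model model.rds --out calls
Rscript inst/cli/clipjunc.R evaluate --called calls/junctions.tsv \
    --truth simdir/truth_junctions.tsv
```

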