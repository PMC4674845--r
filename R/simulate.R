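# Self-contained fixture generator: toy genome with transcript models,
# paired-end spliced reads, an emulated clip-reporting aligner (BWA-like),
# FASTQ/BAM/FASTA writers and the truth set. Everything is deterministic per
# seed; all outputs are rebuilt from code at run time.

#' Simulation configuration
#'
#' Defaults state the simulated world: two contigs (`train`, `test`)
#' mirroring a train-on-one-chromosome / test-on-another design; ~10
#' transcripts per contig with 4-6 exons of 120-300 bp; intron lengths drawn
#' from three regimes — shorter than `3v` (60-85 bp, too short to make
#' encompassing pairs discordant), intermediate (150-600 bp) and long
#' (800-1500 bp) — plus one 2,447 bp intron per contig so that long-jump
#' focal re-alignment with short clips is always exercised; 100 bp reads,
#' insert size Normal(300, 30), 20x target coverage, substitution error rate
#' 0 and a 0.2 hard-clip emission fraction so the FASTQ recovery path always
#' runs.
#'
#' @param seed Master seed (all stage seeds derive from it).
#' @param contigs Contig names.
#' @param n_transcripts Transcripts per contig.
#' @param exons_per_transcript Integer range of exon counts.
#' @param exon_len Min/max internal exon length (bp).
#' @param terminal_exon_len Min/max length of each transcript's last exon
#'   (bp); long 3'-UTR-like exons give the library a population of
#'   within-exon pairs, without which no insert-size model is estimable from
#'   genome-space alignments.
#' @param intron_short,intron_mid,intron_long Min/max intron lengths of the
#'   three regimes.
#' @param long_intron One guaranteed long intron length per contig (bp).
#' @param read_len Read length (bp).
#' @param insert_mean,insert_sd Fragment-length distribution (bp).
#' @param coverage Target mean exonic depth (reads).
#' @param error_rate Per-base substitution error rate.
#' @param hard_clip_frac Fraction of clipped alignments emitted as hard clips.
#' @param weight_range Transcript expression-weight range (mean 1).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, contigs = c("train", "test"),
                       n_transcripts = 10L, exons_per_transcript = 4:6,
                       exon_len = c(120L, 300L),
                       terminal_exon_len = c(500L, 900L),
                       intron_short = c(60L, 85L),
                       intron_mid = c(150L, 600L),
                       intron_long = c(800L, 1500L),
                       long_intron = 2447L,
                       read_len = 100L, insert_mean = 300, insert_sd = 30,
                       coverage = 20, error_rate = 0,
                       hard_clip_frac = 0.2,
                       weight_range = c(0.5, 1.5)) {
  structure(as.list(environment()), class = "sim_config")
}

#' Generate the reference genome and transcript models
#'
#' Transcripts are laid out left-to-right without overlap, separated by
#' intergenic gaps; the truth set records every (donor, acceptor) junction
#' (donor = first intronic base, acceptor = first exonic base after the
#' intron, 0-based).
#'
#' @param cfg A `sim_config`.
#' @return List: `genome` (named character), `exons` (`data.table` of exon
#'   intervals per transcript), `weights`, `truth` (junction table).
#' @export
generate_reference_and_transcripts <- function(cfg) {
  set.seed(cfg$seed)
  exon_rows <- list(); truth_rows <- list(); weights <- list()
  genome <- character(0)
  for (ct in cfg$contigs) {
    cursor <- 200L
    for (t in seq_len(cfg$n_transcripts)) {
      n_ex <- if (length(cfg$exons_per_transcript) == 1L)
        cfg$exons_per_transcript else sample(cfg$exons_per_transcript, 1L)
      elens <- sample(cfg$exon_len[1]:cfg$exon_len[2], n_ex, replace = TRUE)
      elens[n_ex] <- sample(cfg$terminal_exon_len[1]:cfg$terminal_exon_len[2], 1L)
      regimes <- sample(c("short", "mid", "long"), n_ex - 1L, replace = TRUE,
                        prob = c(0.25, 0.45, 0.3))
      ilens <- vapply(regimes, function(r) {
        rng <- switch(r, short = cfg$intron_short, mid = cfg$intron_mid,
                      long = cfg$intron_long)
        sample(rng[1]:rng[2], 1L)
      }, integer(1))
      if (t == 1L) ilens[length(ilens)] <- cfg$long_intron
      starts <- integer(n_ex); ends <- integer(n_ex)
      p <- cursor
      for (e in seq_len(n_ex)) {
        starts[e] <- p; ends[e] <- p + elens[e]
        p <- ends[e] + if (e < n_ex) ilens[e] else 0L
      }
      tx <- sprintf("%s_tx%02d", ct, t)
      exon_rows[[length(exon_rows) + 1L]] <-
        data.table(contig = ct, tx = tx, exon = seq_len(n_ex),
                   start = starts, end = ends)
      truth_rows[[length(truth_rows) + 1L]] <-
        data.table(contig = ct, donor_pos = ends[-n_ex],
                   acceptor_pos = starts[-1L], tx = tx)
      weights[[tx]] <- runif(1, cfg$weight_range[1], cfg$weight_range[2])
      cursor <- p + sample(300:600, 1L)
    }
    glen <- cursor + 200L
    genome[[ct]] <- paste(sample(c("A", "C", "G", "T"), glen, replace = TRUE),
                          collapse = "")
  }
  list(genome = genome, exons = rbindlist(exon_rows),
       weights = unlist(weights), truth = rbindlist(truth_rows))
}

tx_sequence <- function(genome, ex) {
  paste(vapply(seq_len(nrow(ex)), function(i)
    substr(genome[[ex$contig[i]]], ex$start[i] + 1L, ex$end[i]),
    character(1)), collapse = "")
}

# genomic blocks (0-based start:len) of transcript-space interval [a, b)
tx_interval_blocks <- function(ex, a, b) {
  out <- character(0)
  off <- 0L
  for (i in seq_len(nrow(ex))) {
    elen <- ex$end[i] - ex$start[i]
    lo <- max(a, off); hi <- min(b, off + elen)
    if (hi > lo)
      out <- c(out, sprintf("%d:%d", ex$start[i] + (lo - off), hi - lo))
    off <- off + elen
    if (off >= b) break
  }
  paste(out, collapse = ",")
}

#' Simulate paired-end spliced reads
#'
#' Fragments are drawn in transcript space with Normal(insert mean, sd)
#' lengths (resampled when longer than the transcript); mate 1 is the
#' fragment's left end on the forward strand, mate 2 the right end on the
#' reverse strand. Substitution errors are applied at the configured rate.
#' The truth records every read's genomic blocks (per-base true placement).
#'
#' @param models Output of [generate_reference_and_transcripts()].
#' @param cfg A `sim_config`.
#' @return `data.table` of reads: `qname`, `mate`, `contig`, `is_reverse`,
#'   `oriented_seq` (forward-genome orientation), `sequenced_seq`, `blocks`
#'   (encoded truth placement), `tstart` (transcript offset).
#' @export
simulate_paired_reads <- function(models, cfg) {
  set.seed(cfg$seed + 1L)
  rl <- cfg$read_len
  rows <- list()
  for (txid in unique(models$exons$tx)) {
    ex <- models$exons[models$exons$tx == txid][order(start)]
    ct <- ex$contig[1]
    tseq <- tx_sequence(models$genome, ex)
    tlen <- nchar(tseq)
    w <- models$weights[[txid]]
    n_pairs <- max(1L, round(cfg$coverage * w * tlen / (2 * rl)))
    for (i in seq_len(n_pairs)) {
      ins <- 0L
      repeat {
        ins <- as.integer(round(rnorm(1, cfg$insert_mean, cfg$insert_sd)))
        if (ins >= rl && ins <= tlen) break
        if (tlen < rl) ins <- tlen  # degenerate tiny transcript
        if (ins > tlen && cfg$insert_mean > tlen) { ins <- tlen; break }
      }
      start <- sample.int(tlen - ins + 1L, 1L) - 1L
      qname <- sprintf("%s_r%05d", txid, i)
      s1 <- substr(tseq, start + 1L, start + rl)
      a2 <- start + ins - rl
      s2 <- substr(tseq, a2 + 1L, a2 + rl)
      rows[[length(rows) + 1L]] <- data.table(
        qname = qname, mate = 1:2, contig = ct, is_reverse = c(FALSE, TRUE),
        oriented_seq = c(apply_errors(s1, cfg$error_rate),
                         apply_errors(s2, cfg$error_rate)),
        blocks = c(tx_interval_blocks(ex, start, start + rl),
                   tx_interval_blocks(ex, a2, a2 + rl)),
        tstart = c(start, a2), tx = txid)
    }
  }
  reads <- rbindlist(rows)
  reads[, sequenced_seq := ifelse(is_reverse, revcomp(oriented_seq),
                                  oriented_seq)]
  reads[]
}

apply_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  hit <- which(runif(n) < rate)
  if (!length(hit)) return(seq)
  ch <- strsplit(seq, "")[[1]]
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  paste(ch, collapse = "")
}

#' Emulate a clip-reporting DNA aligner on simulated reads
#'
#' Deterministically reproduces the upstream behavior the junction caller
#' consumes: a read fully inside one exon gets a full-match CIGAR at its
#' true locus; a read crossing one or more junctions has its longest
#' exonic block mapped and the remainder soft-clipped (a seeded fraction of
#' clipped alignments is emitted as hard clips, dropping the clipped bases
#' from SEQ). Mate fields and TLEN come from the true placements, so
#' encompassing pairs over long introns become discordant. No ambiguous
#' repeat placement is modeled.
#'
#' @param reads Read table from [simulate_paired_reads()].
#' @param cfg A `sim_config`.
#' @return `data.table` of SAM-like records (0-based `pos`).
#' @export
emulate_aligner <- function(reads, cfg) {
  set.seed(cfg$seed + 2L)
  n <- nrow(reads)
  pos <- integer(n); cig <- character(n); seqout <- character(n)
  end <- integer(n)
  hard_draw <- runif(n) < cfg$hard_clip_frac
  for (i in seq_len(n)) {
    bl <- strsplit(reads$blocks[i], ",", fixed = TRUE)[[1]]
    parts <- do.call(rbind, strsplit(bl, ":", fixed = TRUE))
    gstart <- as.integer(parts[, 1]); glen <- as.integer(parts[, 2])
    k <- which.max(glen)
    pre <- if (k > 1L) sum(glen[seq_len(k - 1L)]) else 0L
    suf <- sum(glen) - pre - glen[k]
    pos[i] <- gstart[k]
    end[i] <- gstart[k] + glen[k]
    op <- if (hard_draw[i] && (pre > 0L || suf > 0L)) "H" else "S"
    cig[i] <- paste0(if (pre > 0L) paste0(pre, op) else "",
                     glen[k], "M",
                     if (suf > 0L) paste0(suf, op) else "")
    sq <- reads$oriented_seq[i]
    seqout[i] <- if (op == "H")
      substr(sq, pre + 1L, pre + glen[k]) else sq
  }
  rec <- data.table(qname = reads$qname, mate = reads$mate,
                    contig = reads$contig, pos = pos, cigar = cig,
                    seq = seqout, is_reverse = reads$is_reverse, end = end)
  # mate fields and signed TLEN from the two records of each pair
  m1 <- rec[mate == 1L, .(qname, p1 = pos, e1 = end)]
  m2 <- rec[mate == 2L, .(qname, p2 = pos, e2 = end)]
  mm <- merge(m1, m2, by = "qname")
  rec <- merge(rec, mm, by = "qname", sort = FALSE)
  rec[, mate_pos := ifelse(mate == 1L, p2, p1)]
  outer <- pmax(rec$e1, rec$e2) - pmin(rec$p1, rec$p2)
  left <- ifelse(rec$mate == 1L, rec$p1 <= rec$p2, rec$p2 < rec$p1)
  rec[, isize := ifelse(left, outer, -outer)]
  rec[, `:=`(p1 = NULL, p2 = NULL, e1 = NULL, e2 = NULL, end = NULL)]
  setorder(rec, contig, pos, qname, mate)
  rec[]
}

#' Write simulated records as a sorted, indexed BAM
#'
#' @param rec Record table from [emulate_aligner()].
#' @param genome Named character vector of contig sequences.
#' @param bam_path Destination BAM path (a `.bai` is created alongside).
#' @return The BAM path.
#' @export
write_sim_bam <- function(rec, genome, bam_path) {
  sam <- sub("\\.bam$", ".sam", bam_path)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome), nchar(genome)))
  flag <- 1L + 64L * (rec$mate == 1L) + 128L * (rec$mate == 2L) +
    16L * rec$is_reverse + 32L * !rec$is_reverse
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                  rec$qname, flag, rec$contig, rec$pos + 1L, 60L, rec$cigar,
                  "=", rec$mate_pos + 1L, rec$isize, rec$seq,
                  strrep("I", nchar(rec$seq)))
  writeLines(c(hdr, body), sam)
  dest <- sub("\\.bam$", "", bam_path)
  Rsamtools::asBam(sam, dest, overwrite = TRUE, indexDestination = TRUE)
  unlink(sam)
  bam_path
}

#' Write simulated reads as a FASTQ pair
#'
#' @param reads Read table from [simulate_paired_reads()].
#' @param fq1,fq2 Output paths.
#' @export
write_sim_fastq <- function(reads, fq1, fq2) {
  for (m in 1:2) {
    r <- reads[mate == m]
    lines <- as.vector(rbind(paste0("@", r$qname), r$sequenced_seq, "+",
                             strrep("I", nchar(r$sequenced_seq))))
    writeLines(lines, if (m == 1L) fq1 else fq2)
  }
  invisible(c(fq1, fq2))
}

#' Generate a complete simulated dataset on disk
#'
#' Emits reference FASTA (+ .fai), the FASTQ pair, a sorted indexed BAM,
#' the truth-junction TSV and the per-read truth placement TSV — everything
#' the pipeline and the benchmarking utilities need, with a known answer.
#'
#' @param cfg A `sim_config`.
#' @param dir Output directory (created).
#' @return List of paths plus the in-memory `models`, `reads`, `records`.
#' @export
simulate_dataset <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  models <- generate_reference_and_transcripts(cfg)
  reads <- simulate_paired_reads(models, cfg)
  rec <- emulate_aligner(reads, cfg)
  ref <- file.path(dir, "ref.fa")
  ss <- Biostrings::DNAStringSet(models$genome)
  Biostrings::writeXStringSet(ss, ref, width = 70L)
  Rsamtools::indexFa(ref)
  fq1 <- file.path(dir, "reads_1.fastq"); fq2 <- file.path(dir, "reads_2.fastq")
  write_sim_fastq(reads, fq1, fq2)
  bam <- file.path(dir, "aln.bam")
  write_sim_bam(rec, models$genome, bam)
  truth_path <- file.path(dir, "truth_junctions.tsv")
  fwrite(models$truth, truth_path, sep = "\t")
  read_truth <- reads[, .(qname, mate, contig, blocks)]
  rt_path <- file.path(dir, "read_truth.tsv")
  fwrite(read_truth, rt_path, sep = "\t")
  list(ref = ref, fastq1 = fq1, fastq2 = fq2, bam = bam,
       truth = truth_path, read_truth = rt_path,
       models = models, reads = reads, records = rec)
}

#' Truth junctions restricted to those with junction-spanning read support
#'
#' Benchmarks are computed only over junctions at least one simulated read
#' actually crosses (a junction no read spans is invisible to any caller).
#'
#' @param models Simulator models (for the exon map).
#' @param reads Read table.
#' @return Filtered truth junction table.
#' @export
covered_truth <- function(models, reads) {
  tr <- copy(models$truth)
  crossed <- logical(nrow(tr))
  for (i in seq_len(nrow(reads))) {
    bl <- strsplit(reads$blocks[i], ",", fixed = TRUE)[[1]]
    if (length(bl) < 2L) next
    parts <- do.call(rbind, strsplit(bl, ":", fixed = TRUE))
    gstart <- as.integer(parts[, 1]); glen <- as.integer(parts[, 2])
    for (k in seq_len(length(gstart) - 1L)) {
      d <- gstart[k] + glen[k]; a <- gstart[k + 1L]
      hit <- which(tr$contig == reads$contig[i] & tr$donor_pos == d &
                     tr$acceptor_pos == a)
      crossed[hit] <- TRUE
    }
  }
  tr[crossed]
}
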