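# Shared fixtures, built lazily in code and cached for the whole test run.
library(data.table)

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small two-contig dataset (3 transcripts/contig) for unit & property tests
tiny_sim <- function() {
  cache_get("tiny_sim", function() {
    cfg <- sim_config(seed = 11L, n_transcripts = 3L)
    dir <- file.path(tempdir(), "tiny_sim")
    simulate_dataset(cfg, dir)
  })
}

tiny_run <- function() {
  cache_get("tiny_run", function() {
    d <- tiny_sim()
    cfg <- pipeline_config(bam = d$bam, ref = d$ref,
                           fastq1 = d$fastq1, fastq2 = d$fastq2)
    run_pipeline(cfg, model = NULL)
  })
}

# full-size clean dataset (spec'd world: 20x, error 0, >= 50 junctions)
full_sim <- function(error_rate = 0, seed = 1L) {
  key <- sprintf("full_sim_%g_%d", error_rate, seed)
  cache_get(key, function() {
    cfg <- sim_config(seed = seed, error_rate = error_rate)
    dir <- file.path(tempdir(), key)
    simulate_dataset(cfg, dir)
  })
}

full_run <- function(error_rate = 0, seed = 1L) {
  key <- sprintf("full_run_%g_%d", error_rate, seed)
  cache_get(key, function() {
    d <- full_sim(error_rate, seed)
    cfg <- pipeline_config(bam = d$bam, ref = d$ref,
                           fastq1 = d$fastq1, fastq2 = d$fastq2)
    run_pipeline(cfg, model = NULL)
  })
}

# hand-built BAM from a record table (same columns write_sim_bam needs)
make_bam <- function(rec, genome, dir = tempdir(),
                     name = paste0("hand", as.integer(stats::runif(1, 1, 1e8)))) {
  bam <- file.path(dir, paste0(name, ".bam"))
  write_sim_bam(rec, genome, bam)
  bam
}

random_genome <- function(len, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# independent brute-force coverage oracle: O(reads x length)
brute_coverage <- function(aln, contig_lengths, mapq_min = 20L) {
  cls <- classify_read(aln$cigar, aln$mapq, aln$is_unmapped, mapq_min)
  out <- lapply(names(contig_lengths), function(ct) {
    d <- integer(contig_lengths[[ct]])
    rows <- which(aln$contig == ct & cls != "DISCARD" & !is.na(aln$cigar))
    for (i in rows) {
      ops <- GenomicAlignments::explodeCigarOps(aln$cigar[i])[[1]]
      lens <- GenomicAlignments::explodeCigarOpLengths(aln$cigar[i])[[1]]
      g <- aln$pos[i]
      for (k in seq_along(ops)) {
        if (ops[k] %in% c("M", "D", "=", "X")) {
          idx <- (g + 1):(g + lens[k])
          idx <- idx[idx >= 1 & idx <= length(d)]
          d[idx] <- d[idx] + 1L
          g <- g + lens[k]
        } else if (ops[k] == "N") g <- g + lens[k]
      }
    }
    d
  })
  names(out) <- names(contig_lengths)
  out
}

# independent re-alignment oracle: exhaustive scan over every in-bound site
# then every position, mirroring the documented rules
brute_realign <- function(event, sites, genome, model, pairs,
                          max_jump = 1500000L, mm_rate = 0.04) {
  seq <- event$clip_seq; len <- nchar(seq)
  b0 <- event$clip_pos
  gseq <- genome[[event$contig]]
  suffix <- event$side == "SUFFIX"
  max_mm <- max(0L, as.integer(ceiling(len * mm_rate)))
  mate <- clipjunc:::mate_span(event, pairs)
  if (suffix) {
    b1 <- b0
    b2 <- if (!is.null(mate) && mate$start >= b0) mate$end else b0 + max_jump
  } else {
    b1 <- if (!is.null(mate) && mate$end <= b0) mate$start else b0 - max_jump
    b2 <- b0
  }
  b1 <- max(0L, b1); b2 <- min(nchar(gseq), b2)
  dir <- if (suffix) "ACCEPTOR" else "DONOR"
  cand <- sites[sites$contig == event$contig & sites$direction == dir &
                  sites$pos >= b1 & sites$pos <= b2, ]
  best <- NULL
  for (k in seq_len(nrow(cand))) {
    p <- cand$pos[k]
    st <- if (suffix) p + 1L else p - len + 1L
    if (st < 1L || st + len - 1L > nchar(gseq)) next
    mm <- sum(charToRaw(substr(gseq, st, st + len - 1L)) != charToRaw(seq))
    if (mm > max_mm) next
    if (clipjunc:::placement_discordant(event, p, len, suffix, mate, model)) next
    if (is.null(best) || abs(p - b0) < abs(best$p - b0))
      best <- list(p = p, mm = mm, id = cand$site_id[k])
  }
  if (!is.null(best))
    return(list(status = "MATCHED_SITE", target_pos = best$p))
  hits <- integer(0)
  for (st in (b1 + 1L):(b2 - len + 1L)) {
    if (st < 1L) next
    mm <- sum(charToRaw(substr(gseq, st, st + len - 1L)) != charToRaw(seq))
    if (mm <= max_mm) hits <- c(hits, st)
  }
  pnew <- if (suffix) hits - 1L else hits - 1L + len
  pnew <- setdiff(pnew, b0)
  if (length(pnew) >= 1L && length(hits) <= 5L) {
    best <- pnew[which.min(abs(pnew - b0))]
    if (!clipjunc:::placement_discordant(event, best, len, suffix, mate, model))
      return(list(status = "NEW_SITE", target_pos = best))
  }
  list(status = "UNALIGNED", target_pos = NA_integer_)
}

# exhaustive optimal one-to-one slack matcher (max matching; tiny instances)
brute_match_tp <- function(called, benchmark, slack) {
  nc <- nrow(called); nb <- nrow(benchmark)
  ok <- matrix(FALSE, nc, nb)
  for (i in seq_len(nc)) for (j in seq_len(nb)) {
    ok[i, j] <- called$contig[i] == benchmark$contig[j] &&
      abs(called$donor_pos[i] - benchmark$donor_pos[j]) <= slack &&
      abs(called$acceptor_pos[i] - benchmark$acceptor_pos[j]) <= slack
  }
  best <- 0L
  rec <- function(i, used) {
    if (i > nc) return(0L)
    res <- rec(i + 1L, used)
    for (j in which(ok[i, ] & !used)) {
      used2 <- used; used2[j] <- TRUE
      res <- max(res, 1L + rec(i + 1L, used2))
    }
    res
  }
  if (nc == 0L || nb == 0L) return(0L)
  rec(1L, logical(nb))
}

# expected connection-edge set from simulator truth: junction-crossing reads
# whose shorter segment is long enough to form a clip event
expected_edges <- function(reads, min_clip_len = 8L) {
  out <- list()
  for (i in seq_len(nrow(reads))) {
    bl <- strsplit(reads$blocks[i], ",", fixed = TRUE)[[1]]
    if (length(bl) != 2L) next
    parts <- do.call(rbind, strsplit(bl, ":", fixed = TRUE))
    g <- as.integer(parts[, 1]); l <- as.integer(parts[, 2])
    if (min(l) < min_clip_len) next
    out[[length(out) + 1L]] <- data.table(contig = reads$contig[i],
                                          donor_pos = g[1] + l[1],
                                          acceptor_pos = g[2])
  }
  unique(rbindlist(out))
}
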