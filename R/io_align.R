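#' Read alignment records from a sorted, indexed BAM file
#'
#' Loads primary alignment records into a `data.table`, converting SAM's
#' 1-based coordinates to the 0-based half-open convention used throughout
#' the package. Secondary and supplementary records are dropped (an upstream
#' aligner such as BWA reports one primary alignment per read); unmapped
#' records are retained and flagged so downstream classification can discard
#' them explicitly rather than silently.
#'
#' @param bam_path Path to a coordinate-sorted BAM with a `.bai` index.
#' @param region Optional region as `list(contig =, start =, end =)` in
#'   0-based half-open coordinates; only overlapping records are returned.
#' @return A `data.table` with one row per record: `qname`, `flag`, `contig`,
#'   `pos` (0-based leftmost mapped base), `mapq`, `cigar`, `mate_contig`,
#'   `mate_pos` (0-based), `isize` (signed observed template length), `seq`,
#'   `is_reverse`, `is_unmapped`, `mate` (1 or 2).
#' @export
read_alignments <- function(bam_path, region = NULL) {
  if (!file.exists(bam_path)) stop("BAM file not found: ", bam_path)
  bai <- paste0(bam_path, ".bai")
  if (!file.exists(bai) && !file.exists(sub("\\.bam$", ".bai", bam_path)))
    stop("BAM index (.bai) not found for ", bam_path,
         "; input must be sorted and indexed")
  flags <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
            "mrnm", "mpos", "isize", "seq")
  if (is.null(region)) {
    param <- Rsamtools::ScanBamParam(flag = flags, what = what)
  } else {
    gr <- GenomicRanges::GRanges(region$contig,
                                 IRanges::IRanges(region$start + 1L, region$end))
    param <- Rsamtools::ScanBamParam(flag = flags, what = what, which = gr)
  }
  res <- tryCatch(Rsamtools::scanBam(bam_path, param = param),
                  error = function(e) stop("failed to read BAM (corrupt or truncated?): ",
                                           conditionMessage(e)))
  b <- res[[1]]
  dt <- data.table(
    qname = b$qname,
    flag = b$flag,
    contig = as.character(b$rname),
    pos = as.integer(b$pos) - 1L,
    mapq = as.integer(b$mapq),
    cigar = b$cigar,
    mate_contig = as.character(b$mrnm),
    mate_pos = as.integer(b$mpos) - 1L,
    isize = as.integer(b$isize),
    seq = as.character(b$seq)
  )
  dt[, is_unmapped := bitwAnd(flag, 4L) != 0L]
  dt[, is_reverse := bitwAnd(flag, 16L) != 0L]
  dt[, mate := ifelse(bitwAnd(flag, 128L) != 0L, 2L, 1L)]
  setorder(dt, contig, pos, qname, na.last = TRUE)
  dt[]
}

#' Classify a read by its alignment type
#'
#' Reads are grouped into fully mapped reads, clip-mapped reads (soft or
#' hard), and other reads; unmapped records and records below the mapping
#' quality threshold are discarded.
#'
#' @param cigar Character vector of CIGAR strings (`NA` for unmapped).
#' @param mapq Integer vector of mapping qualities.
#' @param is_unmapped Logical vector.
#' @param mapq_min Minimum mapping quality to keep a record (default 20).
#' @return Character vector with values `FULL`, `SOFT_CLIP`, `HARD_CLIP`,
#'   `OTHER`, `DISCARD`.
#' @export
classify_read <- function(cigar, mapq, is_unmapped = is.na(cigar), mapq_min = 20L) {
  out <- rep("OTHER", length(cigar))
  has_s <- !is.na(cigar) & grepl("S", cigar, fixed = TRUE)
  has_h <- !is.na(cigar) & grepl("H", cigar, fixed = TRUE)
  full <- !is.na(cigar) & !has_s & !has_h
  out[full] <- "FULL"
  out[has_h] <- "HARD_CLIP"
  out[has_s] <- "SOFT_CLIP"   # soft wins if both ends differ in clip type
  out[is_unmapped | is.na(mapq) | mapq < mapq_min] <- "DISCARD"
  out
}

#' Extract clip events from clip-mapped records
#'
#' Each clipped end of a record yields one event: a `PREFIX` event at the
#' start of the mapped span or a `SUFFIX` event at its end (a doubly-clipped
#' read yields two). A donor boundary is the first reference base after the
#' last exonic base; an acceptor boundary is the first exonic base — both
#' coincide with the clip positions computed here.
#'
#' @param aln `data.table` from [read_alignments()].
#' @param mapq_min Mapping-quality threshold passed to [classify_read()].
#' @param min_clip_len Events with clips shorter than this are suppressed
#'   (default 8 bp; too short to re-align unambiguously).
#' @return `data.table` of events: `event_id`, `qname`, `mate`, `contig`,
#'   `clip_pos`, `side`, `clip_len`, `clip_seq` (`NA` until hard-clip
#'   recovery), `hard`, `is_reverse`, `span_start`, `span_end`,
#'   `mate_contig`, `mate_pos`.
#' @export
extract_clip_events <- function(aln, mapq_min = 20L, min_clip_len = 8L) {
  cls <- classify_read(aln$cigar, aln$mapq, aln$is_unmapped, mapq_min)
  keep <- cls %in% c("SOFT_CLIP", "HARD_CLIP")
  a <- aln[keep]
  if (nrow(a) == 0L) return(empty_events())
  ops <- GenomicAlignments::explodeCigarOps(a$cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(a$cigar)
  refw <- cigar_ref_width(a$cigar)
  rows <- vector("list", nrow(a))
  for (i in seq_len(nrow(a))) {
    o <- ops[[i]]; l <- lens[[i]]
    first_clip <- o[1] %in% c("S", "H")
    last_clip <- o[length(o)] %in% c("S", "H")
    span_start <- a$pos[i]; span_end <- a$pos[i] + refw[i]
    ev <- list()
    if (first_clip && l[1] >= min_clip_len) {
      hard <- o[1] == "H"
      cs <- if (hard) NA_character_ else substr(a$seq[i], 1L, l[1])
      ev[[length(ev) + 1L]] <- data.table(
        qname = a$qname[i], mate = a$mate[i], contig = a$contig[i],
        clip_pos = span_start, side = "PREFIX", clip_len = l[1],
        clip_seq = cs, hard = hard, is_reverse = a$is_reverse[i],
        span_start = span_start, span_end = span_end,
        mate_contig = a$mate_contig[i], mate_pos = a$mate_pos[i])
    }
    if (last_clip && l[length(l)] >= min_clip_len) {
      hard <- o[length(o)] == "H"
      n <- nchar(a$seq[i]); ll <- l[length(l)]
      cs <- if (hard) NA_character_ else substr(a$seq[i], n - ll + 1L, n)
      ev[[length(ev) + 1L]] <- data.table(
        qname = a$qname[i], mate = a$mate[i], contig = a$contig[i],
        clip_pos = span_end, side = "SUFFIX", clip_len = ll,
        clip_seq = cs, hard = hard, is_reverse = a$is_reverse[i],
        span_start = span_start, span_end = span_end,
        mate_contig = a$mate_contig[i], mate_pos = a$mate_pos[i])
    }
    if (length(ev)) rows[[i]] <- rbindlist(ev)
  }
  out <- rbindlist(rows[!vapply(rows, is.null, logical(1))])
  if (nrow(out) == 0L) return(empty_events())
  out[, event_id := .I]
  setorder(out, contig, clip_pos, event_id)
  out[, event_id := .I]
  out[]
}

empty_events <- function() {
  data.table(qname = character(), mate = integer(), contig = character(),
             clip_pos = integer(), side = character(), clip_len = integer(),
             clip_seq = character(), hard = logical(), is_reverse = logical(),
             span_start = integer(), span_end = integer(),
             mate_contig = character(), mate_pos = integer(),
             event_id = integer())
}

#' Estimate the insert-size model
#'
#' The insert-size distribution is summarized by its mean `m` and standard
#' deviation `v`. In transcriptome reads aligned to the genome a large
#' fraction of observed template lengths is inflated by introns, so a plain
#' central trim cannot isolate the library insert. The estimator therefore
#' anchors on the histogram mode of the absolute template lengths (10 bp
#' bins), keeps values within a window around it, and tightens the window to
#' `[m - 3v, m + 3v]` over a few iterations — outlier trimming that
#' withstands heavy one-sided contamination.
#'
#' @param isizes Numeric vector of signed or absolute template lengths (one
#'   per pair; zero/NA entries are ignored).
#' @param min_sample Minimum number of usable pairs (default 20).
#' @param bin Histogram bin width in bp for the mode anchor (default 10).
#' @param iterations Trimming iterations (default 3).
#' @return An object of class `insert_model`: `list(m =, v =, n =)`.
#' @export
estimate_insert_model <- function(isizes, min_sample = 20L, bin = 10L,
                                  iterations = 3L) {
  x <- abs(as.numeric(isizes))
  x <- x[!is.na(x) & x > 0]
  if (length(x) < min_sample)
    stop("too few proper pairs (", length(x), ") to estimate the insert-size ",
         "model; supply m and v explicitly in the configuration")
  bins <- table(floor(x / bin))
  mode_c <- (as.integer(names(bins)[which.max(bins)]) + 0.5) * bin
  keep <- x[abs(x - mode_c) <= mode_c]      # generous first window
  for (it in seq_len(iterations)) {
    m <- mean(keep)
    v <- if (length(keep) > 1L) sd(keep) else 0
    keep2 <- x[x >= m - 3 * v & x <= m + 3 * v]
    if (length(keep2) < min_sample) break
    keep <- keep2
  }
  m <- mean(keep)
  v <- if (length(keep) > 1L) sd(keep) else 0
  structure(list(m = m, v = v, n = length(keep)), class = "insert_model")
}

#' @export
print.insert_model <- function(x, ...) {
  cat(sprintf("insert-size model: m = %.2f, v = %.2f (n = %d)\n", x$m, x$v, x$n))
  invisible(x)
}

#' Flag discordant pairs
#'
#' A pair is discordant when its observed absolute insert size falls outside
#' the closed range `[m - 3v, m + 3v]` (boundary values are concordant), or
#' when the two mates map to different contigs or in the same orientation.
#'
#' @param isize Signed or absolute template length(s).
#' @param model An `insert_model`.
#' @param same_contig,same_orientation Logical vectors (recycled).
#' @return Logical vector.
#' @export
is_discordant_pair <- function(isize, model, same_contig = TRUE,
                               same_orientation = FALSE) {
  a <- abs(as.numeric(isize))
  lo <- model$m - 3 * model$v
  hi <- model$m + 3 * model$v
  !same_contig | same_orientation | a < lo | a > hi
}

#' Build a per-contig coverage track
#'
#' Depth at position `i` counts the non-discarded reads whose aligned
#' (reference-consuming) bases cover `i`; soft/hard-clipped bases add no
#' coverage.
#'
#' @param aln `data.table` from [read_alignments()].
#' @param contig_lengths Named integer vector of contig lengths.
#' @param mapq_min Mapping-quality threshold.
#' @return Named list of integer vectors (one per contig), class
#'   `coverage_track`.
#' @export
build_coverage <- function(aln, contig_lengths, mapq_min = 20L) {
  cls <- classify_read(aln$cigar, aln$mapq, aln$is_unmapped, mapq_min)
  a <- aln[cls != "DISCARD" & !is.na(cigar)]
  out <- lapply(names(contig_lengths), function(ct) {
    len <- contig_lengths[[ct]]
    ai <- a[contig == ct]
    if (nrow(ai) == 0L) return(integer(len))
    rl <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      ai$cigar, pos = ai$pos + 1L, ops = c("M", "D", "=", "X"))
    ir <- unlist(rl, use.names = FALSE)
    ir <- IRanges::restrict(ir, start = 1L, end = len)
    as.integer(IRanges::coverage(ir, width = len))
  })
  names(out) <- names(contig_lengths)
  structure(out, class = "coverage_track")
}

#' Index mate pairs and mark discordant ones
#'
#' @param aln `data.table` from [read_alignments()] (mapped primary records).
#' @param model An `insert_model` used to flag discordance.
#' @param mapq_min Mapping-quality threshold.
#' @return `data.table` keyed by `qname`: mapped spans of the two mates,
#'   contigs, orientations, observed `isize` and the `discordant` flag.
#' @export
build_pair_index <- function(aln, model, mapq_min = 20L) {
  cls <- classify_read(aln$cigar, aln$mapq, aln$is_unmapped, mapq_min)
  a <- aln[cls != "DISCARD" & !is.na(cigar)]
  if (nrow(a) == 0L)
    return(data.table(qname = character(), contig1 = character(),
                      start1 = integer(), end1 = integer(), rev1 = logical(),
                      contig2 = character(), start2 = integer(),
                      end2 = integer(), rev2 = logical(), isize = integer(),
                      discordant = logical()))
  a[, `:=`(span_start = pos, span_end = pos + cigar_ref_width(cigar))]
  m1 <- a[mate == 1L, .(qname, contig1 = contig, start1 = span_start,
                        end1 = span_end, rev1 = is_reverse, isize1 = isize)]
  m2 <- a[mate == 2L, .(qname, contig2 = contig, start2 = span_start,
                        end2 = span_end, rev2 = is_reverse)]
  p <- merge(m1, m2, by = "qname")
  if (nrow(p) == 0L)
    return(p[, .(qname, contig1, start1, end1, rev1, contig2, start2, end2,
                 rev2, isize = integer(0), discordant = logical(0))])
  p[, isize := abs(isize1)][, isize1 := NULL]
  p[, discordant := is_discordant_pair(isize, model,
                                       same_contig = contig1 == contig2,
                                       same_orientation = rev1 == rev2)]
  setkey(p, qname)
  p[]
}

#' Recover hard-clipped sequence from the original FASTQ files
#'
#' Hard-clipped alignments do not carry the clipped bases, so the original
#' read is looked up by name in the raw FASTQ files and the clipped
#' prefix/suffix is recovered (reverse-complemented when the alignment is on
#' the reverse strand), turning every hard-clip event into the equivalent
#' soft-clip event. Events whose read name is absent are dropped with a
#' warning.
#'
#' @param events Event table from [extract_clip_events()].
#' @param fastq1,fastq2 Paths to the mate-1 and mate-2 FASTQ files.
#' @return The event table with `clip_seq` filled for recovered hard clips.
#' @export
recover_hard_clips <- function(events, fastq1, fastq2) {
  ev <- copy(events)
  idx <- which(ev$hard & is.na(ev$clip_seq))
  if (length(idx) == 0L) return(ev)
  lookup <- c(read_fastq_named(fastq1, 1L), read_fastq_named(fastq2, 2L))
  keys <- paste0(ev$qname[idx], "/", ev$mate[idx])
  seqs <- lookup[keys]
  missing <- is.na(seqs)
  if (any(missing)) {
    warning(sum(missing), " hard-clipped event(s) dropped: read name absent ",
            "from FASTQ")
    drop <- idx[missing]
    ev <- ev[-drop]
    idx <- which(ev$hard & is.na(ev$clip_seq))
    keys <- paste0(ev$qname[idx], "/", ev$mate[idx])
    seqs <- lookup[keys]
  }
  if (length(idx)) {
    oriented <- ifelse(ev$is_reverse[idx], revcomp(seqs), seqs)
    n <- nchar(oriented)
    cl <- ev$clip_len[idx]
    ev$clip_seq[idx] <- ifelse(ev$side[idx] == "PREFIX",
                               substr(oriented, 1L, cl),
                               substr(oriented, n - cl + 1L, n))
  }
  ev[]
}

read_fastq_named <- function(path, mate) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  nm <- sub("[/ ].*$", "", names(ss))
  out <- as.character(ss)
  names(out) <- paste0(nm, "/", mate)
  out
}
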