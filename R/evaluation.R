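# Benchmarking: slack-based one-to-one junction matching, precision/recall/
# F-value, call-set overlap counts, and mapped-base ratios.

#' Match called junctions against a benchmark with a slack value
#'
#' A called junction may match a benchmark junction when both its donor and
#' acceptor coordinates are within `slack` bp of the benchmark's. Matching is
#' greedy one-to-one, nearest pair (smallest donor+acceptor distance sum)
#' first, so clustered calls cannot double-count a single benchmark
#' junction. Unmatched calls are false positives; unmatched benchmark
#' junctions are false negatives.
#'
#' @param called,benchmark Junction tables (`contig`, `donor_pos`,
#'   `acceptor_pos`); only `status == "CALLED"` rows of `called` are used
#'   when a `status` column is present.
#' @param slack Per-side tolerance in bp.
#' @return List of class `match_result`: `TP`, `FP`, `FN`, `slack`,
#'   `matched` (data.table of matched index pairs).
#' @export
match_with_slack <- function(called, benchmark, slack = 0L) {
  ca <- as.data.table(called)
  if ("status" %in% names(ca)) ca <- ca[status == "CALLED"]
  be <- as.data.table(benchmark)
  nc <- nrow(ca); nb <- nrow(be)
  cand <- list()
  for (i in seq_len(nc)) {
    dd <- abs(be$donor_pos - ca$donor_pos[i])
    da <- abs(be$acceptor_pos - ca$acceptor_pos[i])
    ok <- which(be$contig == ca$contig[i] & dd <= slack & da <= slack)
    if (length(ok))
      cand[[length(cand) + 1L]] <- data.table(ci = i, bi = ok,
                                              d = dd[ok] + da[ok])
  }
  matched <- data.table(ci = integer(), bi = integer())
  if (length(cand)) {
    cand <- rbindlist(cand)
    setorder(cand, d, ci, bi)
    used_c <- logical(nc); used_b <- logical(nb)
    for (r in seq_len(nrow(cand))) {
      ci <- cand$ci[r]; bi <- cand$bi[r]
      if (!used_c[ci] && !used_b[bi]) {
        used_c[ci] <- TRUE; used_b[bi] <- TRUE
        matched <- rbind(matched, data.table(ci = ci, bi = bi))
      }
    }
  }
  tp <- nrow(matched)
  structure(list(TP = tp, FP = nc - tp, FN = nb - tp, slack = slack,
                 matched = matched), class = "match_result")
}

#' Precision, recall and F-value from match counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F = 2*P*R/(P+R)`; any 0/0 is 0 by convention.
#'
#' @param tp,fp,fn Non-negative counts (or a `match_result` as `tp`).
#' @return List of class `metrics`: `precision`, `recall`, `f_value`.
#' @export
compute_metrics <- function(tp, fp = NULL, fn = NULL) {
  if (inherits(tp, "match_result")) { fp <- tp$FP; fn <- tp$FN; tp <- tp$TP }
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(precision = precision, recall = recall, f_value = f),
            class = "metrics")
}

#' @export
print.metrics <- function(x, ...) {
  cat(sprintf("precision = %.4f  recall = %.4f  F-value = %.4f\n",
              x$precision, x$recall, x$f_value))
  invisible(x)
}

#' Count overlapping junctions between two call sets
#'
#' The number of junctions of `set_a` matching a junction of `set_b` within
#' the slack, i.e. the TP count of [match_with_slack()].
#'
#' @param set_a,set_b Junction tables.
#' @param slack Per-side tolerance in bp.
#' @export
overlap_count <- function(set_a, set_b, slack = 0L) {
  match_with_slack(set_a, set_b, slack)$TP
}

#' Mapped-base ratio of a pipeline run
#'
#' Without truth: total bases placed on the reference over total read bases.
#' With per-read truth placements: a base counts only when placed at its true
#' genomic coordinate (correctly-mapped ratio).
#'
#' @param read_report Report from [run_pipeline()] (`read_report` element).
#' @param truth Optional per-read truth from the simulator (`read_truth`
#'   table with encoded genomic blocks).
#' @param results,events Needed with `truth` to locate re-aligned clip bases.
#' @return A single ratio in `[0, 1]`.
#' @export
mapped_base_ratio <- function(read_report, truth = NULL, results = NULL,
                              events = NULL) {
  if (is.null(truth))
    return(sum(read_report$placed_bases) / sum(read_report$total_bases))
  tr <- as.data.table(truth)
  tr_key <- paste0(tr$qname, "/", tr$mate)
  correct <- 0
  total <- sum(read_report$total_bases)
  # mapped portions: correct where placed coordinates equal truth coordinates
  for (i in seq_len(nrow(read_report))) {
    row <- read_report[i]
    ti <- match(paste0(row$qname, "/", row$mate), tr_key)
    if (is.na(ti)) next
    tcoords <- decode_blocks(tr$blocks[ti])
    if (row$mapped_bases > 0) {
      pcoords <- placed_coords(row$cigar, row$pos)
      qoff <- pcoords$qoff
      correct <- correct + sum(tcoords[qoff] == pcoords$gpos, na.rm = TRUE)
    }
  }
  # re-aligned clipped segments
  if (!is.null(results) && nrow(results)) {
    ok <- results[status %in% c("MATCHED_SITE", "NEW_SITE")]
    for (i in seq_len(nrow(ok))) {
      e <- events[event_id == ok$event_id[i]]
      ti <- match(paste0(e$qname, "/", e$mate), tr_key)
      if (is.na(ti)) next
      tcoords <- decode_blocks(tr$blocks[ti])
      len <- e$clip_len
      if (e$side == "SUFFIX") {
        qidx <- (length(tcoords) - len + 1L):length(tcoords)
        gpos <- ok$target_pos[i] + 0:(len - 1L)
      } else {
        qidx <- 1:len
        gpos <- ok$target_pos[i] - len + 0:(len - 1L)
      }
      correct <- correct + sum(tcoords[qidx] == gpos, na.rm = TRUE)
    }
  }
  correct / total
}

# truth blocks encoded "start:len,start:len" -> per-base genomic coordinates
# in read (query, forward-genome) order
decode_blocks <- function(enc) {
  parts <- strsplit(strsplit(enc, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  unlist(lapply(parts, function(p) {
    s <- as.integer(p[1]); l <- as.integer(p[2]); s + 0:(l - 1L)
  }))
}

# genomic coordinate of each mapped query base of a record (query offsets are
# positions within the full oriented read, counting hard clips)
placed_coords <- function(cigar, pos) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  q <- 0L; g <- pos
  qoff <- integer(0); gpos <- integer(0)
  for (k in seq_along(ops)) {
    op <- ops[k]; l <- lens[k]
    if (op %in% c("S", "H", "I")) { q <- q + l }
    else if (op %in% c("D", "N")) { g <- g + l }
    else { # M, =, X
      qoff <- c(qoff, q + 1:l); gpos <- c(gpos, g + 0:(l - 1L))
      q <- q + l; g <- g + l
    }
  }
  list(qoff = qoff, gpos = gpos)
}

#' Slack sweep of F-values against a benchmark
#'
#' @param called,benchmark Junction tables.
#' @param slacks Integer vector of slack values (default 0:15).
#' @return `data.table`: `slack`, `TP`, `FP`, `FN`, `precision`, `recall`,
#'   `f_value`.
#' @export
slack_sweep <- function(called, benchmark, slacks = 0:15) {
  rbindlist(lapply(slacks, function(sl) {
    m <- match_with_slack(called, benchmark, sl)
    mt <- compute_metrics(m)
    data.table(slack = sl, TP = m$TP, FP = m$FP, FN = m$FN,
               precision = mt$precision, recall = mt$recall,
               f_value = mt$f_value)
  }))
}
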