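# Per-site evidence features and focal re-alignment of clipped segments.
#
# Each candidate site is described by four features: reads clipped at the
# site, clipped segments re-aligned at the site, discordant encompassing
# pairs, and the coverage difference between its two flanking regions. All
# four are normalized by the mean coverage of the site's anchor region (left
# flank for donors, right flank for acceptors) before classification.

max_mismatches <- function(clip_len, rate = 0.04) {
  pmax(0L, as.integer(ceiling(clip_len * rate)))
}

#' Re-align one clipped segment in its focal region
#'
#' A SUFFIX clip at `b0` (read clipped at a donor) searches candidate
#' ACCEPTOR sites downstream of `b0`; a PREFIX clip at `b0` (read clipped at
#' an acceptor) searches candidate DONOR sites upstream. When the mate maps
#' on the search side, the mate's far end bounds the search; otherwise the
#' bound is `b0 +/- max_jump`. Sites are tried nearest-first from `b0`; at
#' each site the segment is placed flush with the boundary (a SUFFIX segment
#' starts at the acceptor position; a PREFIX segment ends at the donor
#' position) and accepted when its mismatch count is at most
#' `ceiling(0.04 * clip_len)`. A placement that would make the read's pair
#' discordant is rejected; the nearest surviving placement wins. When no
#' site accepts the segment, an ungapped sliding scan over the whole focal
#' region may propose a new candidate site (`NEW_SITE`); more than
#' `max_new_hits` equally acceptable scan hits is declared ambiguous
#' (`UNALIGNED`).
#'
#' @param event One row of the event table (with `clip_seq` filled).
#' @param sites Merged candidate site table.
#' @param genome Named character vector of contig sequences.
#' @param model An `insert_model` (for the discordance veto).
#' @param pairs Pair index from [build_pair_index()] (or `NULL`: no veto).
#' @param max_jump Maximum junction size in bp (default 1,500,000).
#' @param mm_rate Mismatch tolerance per clipped base (default 0.04).
#' @param max_new_hits Ambiguity cap for the fallback scan (default 5).
#' @return A list: `status` (`MATCHED_SITE`, `NEW_SITE`, `UNALIGNED`),
#'   `target_pos`, `target_site_id`, `mismatches`.
#' @export
realign_clipped_segment <- function(event, sites, genome, model,
                                    pairs = NULL, max_jump = 1500000L,
                                    mm_rate = 0.04, max_new_hits = 5L) {
  if (is.na(event$clip_seq) || !nzchar(event$clip_seq))
    stop("clip_seq is empty: run recover_hard_clips() before re-alignment")
  seq <- event$clip_seq
  len <- nchar(seq)
  b0 <- event$clip_pos
  ct <- event$contig
  gseq <- genome[[ct]]
  glen <- nchar(gseq)
  max_mm <- max_mismatches(len, mm_rate)
  suffix <- event$side == "SUFFIX"
  target_dir <- if (suffix) "ACCEPTOR" else "DONOR"

  # mate-bounded focal region [b1, b2]
  mate <- mate_span(event, pairs)
  if (suffix) {
    b1 <- b0
    b2 <- if (!is.null(mate) && mate$start >= b0) mate$end else b0 + max_jump
  } else {
    b1 <- if (!is.null(mate) && mate$end <= b0) mate$start else b0 - max_jump
    b2 <- b0
  }
  b1 <- max(0L, b1); b2 <- min(glen, b2)

  cand <- sites[sites$contig == ct & sites$direction == target_dir &
                  sites$pos >= b1 & sites$pos <= b2, ]
  if (nrow(cand) > 0L) {
    cand <- cand[order(abs(cand$pos - b0)), ]
    for (k in seq_len(nrow(cand))) {
      p <- cand$pos[k]
      placed <- flush_mismatches(gseq, seq, p, suffix)
      if (is.na(placed) || placed > max_mm) next
      if (placement_discordant(event, p, len, suffix, mate, model)) next
      return(list(status = "MATCHED_SITE", target_pos = p,
                  target_site_id = cand$site_id[k], mismatches = placed))
    }
  }
  # local-alignment fallback: ungapped sliding scan over [b1, b2]
  lo <- b1 + 1L; hi <- b2  # 1-based substring bounds
  if (hi - lo + 1L >= len) {
    region <- substr(gseq, lo, hi)
    mm <- .sliding_mismatches(region, seq)
    hits <- which(mm <= max_mm)
    if (length(hits) >= 1L && length(hits) <= max_new_hits) {
      starts0 <- (lo - 1L) + hits - 1L            # 0-based placement starts
      pnew <- if (suffix) starts0 else starts0 + len
      pnew <- setdiff(pnew, b0)                    # placing back at the clip is no junction
      if (length(pnew)) {
        best <- pnew[which.min(abs(pnew - b0))]
        keep <- !placement_discordant(event, best, len, suffix, mate, model)
        if (keep) {
          bi <- which((if (suffix) starts0 else starts0 + len) == best)[1]
          return(list(status = "NEW_SITE", target_pos = best,
                      target_site_id = NA_integer_, mismatches = mm[hits[bi]]))
        }
      }
    } else if (length(hits) > max_new_hits) {
      return(list(status = "UNALIGNED", target_pos = NA_integer_,
                  target_site_id = NA_integer_, mismatches = NA_integer_))
    }
  }
  list(status = "UNALIGNED", target_pos = NA_integer_,
       target_site_id = NA_integer_, mismatches = NA_integer_)
}

# mismatches of the flush placement of `seq` at boundary p (NA if off-contig)
flush_mismatches <- function(gseq, seq, p, suffix) {
  len <- nchar(seq)
  if (suffix) { start <- p + 1L; end <- p + len }       # 1-based
  else { start <- p - len + 1L; end <- p }
  if (start < 1L || end > nchar(gseq)) return(NA_integer_)
  str_mismatches(substr(gseq, start, end), seq)
}

mate_span <- function(event, pairs) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(NULL)
  row <- pairs[J(event$qname), nomatch = NULL]
  if (nrow(row) == 0L) return(NULL)
  if (event$mate == 1L) {
    if (is.na(row$start2[1])) return(NULL)
    if (row$contig2[1] != event$contig) return(NULL)
    list(start = row$start2[1], end = row$end2[1])
  } else {
    if (is.na(row$start1[1])) return(NULL)
    if (row$contig1[1] != event$contig) return(NULL)
    list(start = row$start1[1], end = row$end1[1])
  }
}

# would placing the segment at p make the pair discordant? The implied insert
# is the reference outer span minus the intron gap the placement introduces
# (transcript-space insert).
placement_discordant <- function(event, p, len, suffix, mate, model) {
  if (is.null(mate)) return(FALSE)
  if (suffix) {
    outer <- max(p + len, mate$end, event$span_end) -
      min(event$span_start, mate$start)
    gap <- p - event$clip_pos
  } else {
    outer <- max(event$span_end, mate$end) -
      min(p - len, mate$start, event$span_start)
    gap <- event$clip_pos - p
  }
  implied <- outer - gap
  is_discordant_pair(implied, model)
}

#' Re-align all clipped segments
#'
#' Applies [realign_clipped_segment()] to every event with a non-empty
#' clipped sequence (both ends of a doubly-clipped read independently) and
#' appends any `NEW_SITE` positions to the candidate list with origin
#' `"REALIGN"`.
#'
#' @inheritParams realign_clipped_segment
#' @param events Event table (hard clips recovered).
#' @return `list(results =, sites =)`: the per-event result table and the
#'   (possibly extended) site table.
#' @export
realign_all <- function(events, sites, genome, model, pairs = NULL,
                        max_jump = 1500000L, mm_rate = 0.04,
                        max_new_hits = 5L) {
  usable <- which(!is.na(events$clip_seq) & nzchar(events$clip_seq))
  res <- vector("list", length(usable))
  for (i in seq_along(usable)) {
    e <- events[usable[i]]
    r <- realign_clipped_segment(e, sites, genome, model, pairs,
                                 max_jump, mm_rate, max_new_hits)
    res[[i]] <- data.table(event_id = e$event_id, qname = e$qname,
                           mate = e$mate, contig = e$contig,
                           side = e$side, b0 = e$clip_pos,
                           status = r$status, target_pos = r$target_pos,
                           target_site_id = r$target_site_id,
                           mismatches = r$mismatches)
  }
  results <- if (length(res)) rbindlist(res) else
    data.table(event_id = integer(), qname = character(), mate = integer(),
               contig = character(), side = character(), b0 = integer(),
               status = character(), target_pos = integer(),
               target_site_id = integer(), mismatches = integer())
  new_sites <- results[status == "NEW_SITE"]
  sites2 <- copy(sites)
  if (nrow(new_sites) > 0L) {
    ns <- new_sites[, .(n_events = 0L), by = .(contig, pos = target_pos,
                                               direction = ifelse(side == "SUFFIX",
                                                                  "ACCEPTOR", "DONOR"))]
    ns[, `:=`(origin = "REALIGN", event_ids = list(integer(0)),
              merged_from = lapply(pos, identity))]
    sites2 <- rbindlist(list(sites2, ns), use.names = TRUE, fill = TRUE)
    setorder(sites2, contig, pos, direction)
    sites2[, site_id := .I]
    # re-key results to the renumbered site table
    results[, target_site_id := NULL]
    key <- sites2[, .(contig, target_pos = pos,
                      dir = direction, target_site_id = site_id)]
    results[, dir := ifelse(side == "SUFFIX", "ACCEPTOR", "DONOR")]
    results <- merge(results, key, by = c("contig", "target_pos", "dir"),
                     all.x = TRUE, sort = FALSE)
    results[, dir := NULL]
    setorder(results, event_id)
  }
  list(results = results, sites = sites2)
}

#' Count reads clipped at a site
#'
#' @param site_row One row of the merged site table.
#' @param events Event table.
#' @return Number of distinct reads contributing a clip event merged into the
#'   site.
#' @export
count_clipped_reads <- function(site_row, events) {
  ids <- unlist(site_row$event_ids)
  if (!length(ids)) return(0L)
  ev <- events[event_id %in% ids]
  length(unique(paste0(ev$qname, "/", ev$mate)))
}

#' Count clipped segments re-aligned at a site
#'
#' @param site_row One row of the site table.
#' @param results Result table from [realign_all()].
#' @export
count_realigned_segments <- function(site_row, results) {
  sum(results$status %in% c("MATCHED_SITE", "NEW_SITE") &
        !is.na(results$target_site_id) &
        results$target_site_id == site_row$site_id)
}

#' Count discordant encompassing pairs at a site
#'
#' A pair encompasses the site when its two mapped reads lie entirely on
#' opposite sides of the site position (neither mate overlaps it).
#'
#' @param site_row One row of the site table.
#' @param pairs Pair index.
#' @export
count_discordant_encompassing <- function(site_row, pairs) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(0L)
  p <- site_row$pos
  ct <- site_row$contig
  with(pairs, sum(discordant & contig1 == ct & contig2 == ct &
                    ((end1 <= p & start2 >= p) | (end2 <= p & start1 >= p)),
                  na.rm = TRUE))
}

#' Coverage difference between the two flanking regions of a site
#'
#' For a donor site: mean depth over `[pos - l, pos)` minus mean depth over
#' `[pos, pos + l)`; the mirror difference for an acceptor. Regions are
#' clamped to the contig and means use the clamped length.
#'
#' @param site_row One row of the site table.
#' @param track A `coverage_track`.
#' @param l Flank length in bp (default 25).
#' @export
coverage_difference <- function(site_row, track, l = 25L) {
  d <- track[[site_row$contig]]
  left <- region_mean(d, site_row$pos - l, site_row$pos)
  right <- region_mean(d, site_row$pos, site_row$pos + l)
  if (site_row$direction == "DONOR") left - right else right - left
}

# mean depth over 0-based half-open [a, b), clamped to the track
region_mean <- function(d, a, b) {
  a <- max(0L, a); b <- min(length(d), b)
  if (b <= a) return(0)
  mean(d[(a + 1L):b])
}

anchor_mean <- function(site_row, track, l = 25L) {
  d <- track[[site_row$contig]]
  if (site_row$direction == "DONOR")
    region_mean(d, site_row$pos - l, site_row$pos)
  else
    region_mean(d, site_row$pos, site_row$pos + l)
}

#' Compute the full feature matrix for all candidate sites
#'
#' Raw features are the four counts/differences; normalized features divide
#' each raw value by the mean coverage of the site's anchor region (left
#' flank for donors, right flank for acceptors). A zero anchor mean yields an
#' all-zero normalized vector: such a site has no local expression and should
#' look weak to the classifier.
#'
#' @param sites Merged site table (after [realign_all()]).
#' @param events Event table.
#' @param results Re-alignment result table.
#' @param pairs Pair index.
#' @param track Coverage track.
#' @param l Flank length in bp (default 25).
#' @return `data.table`: site columns plus `f_clip`, `f_seg`, `f_disc`,
#'   `f_cov`, `anchor`, `nf_clip`, `nf_seg`, `nf_disc`, `nf_cov`.
#' @export
compute_features <- function(sites, events, results, pairs, track, l = 25L) {
  n <- nrow(sites)
  f_clip <- f_seg <- f_disc <- integer(n)
  f_cov <- anchor <- numeric(n)
  seg_counts <- if (nrow(results)) {
    tab <- results[status %in% c("MATCHED_SITE", "NEW_SITE") &
                     !is.na(target_site_id), .N, by = target_site_id]
    setkey(tab, target_site_id); tab
  } else NULL
  for (i in seq_len(n)) {
    row <- sites[i]
    f_clip[i] <- count_clipped_reads(row, events)
    f_seg[i] <- if (is.null(seg_counts)) 0L else {
      hit <- seg_counts[J(row$site_id), nomatch = NULL]
      if (nrow(hit)) hit$N else 0L
    }
    f_disc[i] <- count_discordant_encompassing(row, pairs)
    f_cov[i] <- coverage_difference(row, track, l)
    anchor[i] <- anchor_mean(row, track, l)
  }
  out <- copy(sites)
  out[, `:=`(f_clip = f_clip, f_seg = f_seg, f_disc = f_disc, f_cov = f_cov,
             anchor = anchor)]
  out[, `:=`(nf_clip = ifelse(anchor > 0, f_clip / anchor, 0),
             nf_seg = ifelse(anchor > 0, f_seg / anchor, 0),
             nf_disc = ifelse(anchor > 0, f_disc / anchor, 0),
             nf_cov = ifelse(anchor > 0, f_cov / anchor, 0))]
  out[]
}

#' Write the feature matrix to a TSV file
#' @param features Feature table from [compute_features()].
#' @param path Output path.
#' @export
write_features_tsv <- function(features, path) {
  fwrite(features[, .(contig, pos, direction, f_clip, f_seg, f_disc, f_cov,
                      nf_clip, nf_seg, nf_disc, nf_cov)], path, sep = "\t")
  invisible(path)
}
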