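# Candidate splice-site calling: clip positions and coverage-change positions,
# then per-direction greedy merging within s bp.

#' Call raw candidate sites from clip events
#'
#' One raw site per distinct clip position. The site direction is the
#' majority clip side at that position in reference-forward orientation: a
#' SUFFIX-clipped read (left segment mapped) supports a DONOR site, a
#' PREFIX-clipped read supports an ACCEPTOR site; ties break to DONOR.
#'
#' @param events Event table from [extract_clip_events()].
#' @return `data.table` of raw sites: `contig`, `pos`, `direction`, `origin`
#'   (`"CLIP"`), `n_events`, `event_ids` (list column).
#' @export
call_clip_sites <- function(events) {
  if (nrow(events) == 0L) return(empty_sites())
  ev <- copy(events)
  s <- ev[, {
    n_suf <- sum(side == "SUFFIX"); n_pre <- .N - n_suf
    .(direction = if (n_suf >= n_pre) "DONOR" else "ACCEPTOR",
      origin = "CLIP", n_events = .N, event_ids = list(event_id))
  }, by = .(contig, pos = clip_pos)]
  setorder(s, contig, pos)
  s[]
}

#' Call candidate sites from coverage-change positions
#'
#' Wherever read depth drops to zero a candidate DONOR is emitted at the
#' first zero-depth position; wherever depth rises from zero a candidate
#' ACCEPTOR is emitted at the first covered position. This recovers splice
#' sites in regions too thinly covered to produce clipped reads (e.g. a
#' single read fully mapped inside an exon flanks itself with two sites).
#'
#' @param track A `coverage_track` from [build_coverage()].
#' @return `data.table` of raw sites with origin `"COVERAGE_CHANGE"`.
#' @export
call_coverage_change_sites <- function(track) {
  out <- lapply(names(track), function(ct) {
    d <- track[[ct]]
    if (length(d) == 0L) return(NULL)
    prev <- c(0L, d[-length(d)])
    donor <- which(prev > 0L & d == 0L) - 1L      # 0-based position i
    acceptor <- which(prev == 0L & d > 0L) - 1L
    rows <- list()
    if (length(donor))
      rows[[1]] <- data.table(contig = ct, pos = donor, direction = "DONOR")
    if (length(acceptor))
      rows[[2]] <- data.table(contig = ct, pos = acceptor, direction = "ACCEPTOR")
    if (d[length(d)] > 0L)                         # depth falls off the contig end
      rows[[3]] <- data.table(contig = ct, pos = length(d), direction = "DONOR")
    rbindlist(rows)
  })
  s <- rbindlist(out[!vapply(out, is.null, logical(1))])
  if (nrow(s) == 0L) return(empty_sites())
  s[, `:=`(origin = "COVERAGE_CHANGE", n_events = 0L,
           event_ids = list(integer(0)))]
  setorder(s, contig, pos)
  s[]
}

empty_sites <- function() {
  data.table(contig = character(), pos = integer(), direction = character(),
             origin = character(), n_events = integer(),
             event_ids = list())
}

#' Merge nearby candidate sites and fix their direction
#'
#' Greedy left-to-right clustering per contig and per direction: a site is
#' absorbed into the current cluster when it lies within `s` bp of the
#' cluster representative; the representative is the member with the most
#' clip events (ties to the leftmost). Donor and acceptor sites are never
#' merged together. Coverage-change sites lying within `s` bp of a clip site
#' of the same direction are suppressed first (clip evidence is strictly
#' stronger).
#'
#' @param raw_sites Raw site table (clip and/or coverage-change origin).
#' @param s Merge distance in bp (default 10).
#' @return Merged `data.table` of sites with `site_id`, `merged_from` (list
#'   of absorbed raw positions) and pooled `event_ids`.
#' @export
merge_and_orient <- function(raw_sites, s = 10L) {
  if (nrow(raw_sites) == 0L) {
    out <- empty_sites()
    out[, `:=`(site_id = integer(0), merged_from = list())]
    return(out[])
  }
  st <- copy(raw_sites)
  # suppress coverage-change sites shadowed by a clip site of same direction
  clip <- st[origin == "CLIP"]
  if (nrow(clip) > 0L) {
    keep <- rep(TRUE, nrow(st))
    for (i in which(st$origin == "COVERAGE_CHANGE")) {
      near <- clip[contig == st$contig[i] & direction == st$direction[i] &
                     abs(pos - st$pos[i]) <= s]
      if (nrow(near) > 0L) keep[i] <- FALSE
    }
    st <- st[keep]
  }
  setorder(st, contig, direction, pos)
  groups <- split(seq_len(nrow(st)), paste(st$contig, st$direction))
  merged <- list()
  for (g in groups) {
    cluster <- integer(0)
    rep_i <- NA_integer_
    flush_cluster <- function() {
      if (!length(cluster)) return(NULL)
      data.table(
        contig = st$contig[rep_i], pos = st$pos[rep_i],
        direction = st$direction[rep_i],
        origin = if (any(st$origin[cluster] == "CLIP")) "CLIP"
                 else st$origin[rep_i],
        n_events = sum(st$n_events[cluster]),
        event_ids = list(unlist(st$event_ids[cluster])),
        merged_from = list(st$pos[cluster]))
    }
    for (i in g) {
      if (!length(cluster)) {
        cluster <- i; rep_i <- i
      } else if (st$pos[i] - st$pos[rep_i] <= s) {
        cluster <- c(cluster, i)
        if (st$n_events[i] > st$n_events[rep_i]) rep_i <- i
      } else {
        merged[[length(merged) + 1L]] <- flush_cluster()
        cluster <- i; rep_i <- i
      }
    }
    merged[[length(merged) + 1L]] <- flush_cluster()
  }
  out <- rbindlist(merged)
  setorder(out, contig, pos, direction)
  out[, site_id := .I]
  out[]
}

#' Write candidate sites to a TSV file
#'
#' @param sites Merged site table.
#' @param path Output path.
#' @export
write_sites_tsv <- function(sites, path) {
  fwrite(sites[, .(contig, pos, direction, origin, n_clip_events = n_events)],
         path, sep = "\t")
  invisible(path)
}
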