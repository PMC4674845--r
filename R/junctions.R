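# Junction assembly: connection graph from re-aligned clipped segments,
# insert-size conflict filter, the three calling conditions, and the
# end-to-end pipeline orchestrator.

#' Build the connection graph between candidate sites
#'
#' Two sites are connected when at least one read clipped at one of them has
#' its clipped segment re-aligned at the other. Each edge is oriented
#' donor -> acceptor and records its supporting re-alignment results.
#'
#' @param sites Site table (after [realign_all()]).
#' @param results Re-alignment result table.
#' @param events Event table (to locate each read's own clip site).
#' @return `data.table` of edges: `contig`, `donor_site`, `acceptor_site`,
#'   `donor_pos`, `acceptor_pos`, `n_support`, `support_events` (list).
#' @export
build_connection_graph <- function(sites, results, events) {
  empty <- data.table(contig = character(), donor_site = integer(),
                      acceptor_site = integer(), donor_pos = integer(),
                      acceptor_pos = integer(), n_support = integer(),
                      support_events = list())
  ok <- results[status %in% c("MATCHED_SITE", "NEW_SITE") &
                  !is.na(target_site_id)]
  if (nrow(ok) == 0L) return(empty)
  # map each event to the merged site its clip position belongs to
  ev2site <- data.table(
    event_id = unlist(sites$event_ids),
    own_site = rep(sites$site_id, vapply(sites$event_ids, length, integer(1))))
  ok <- merge(ok, ev2site, by = "event_id", all.x = TRUE, sort = FALSE)
  ok <- ok[!is.na(own_site)]
  if (nrow(ok) == 0L) return(empty)
  # SUFFIX events: own site is the donor, target the acceptor; PREFIX mirror
  ok[, `:=`(donor_site = ifelse(side == "SUFFIX", own_site, target_site_id),
            acceptor_site = ifelse(side == "SUFFIX", target_site_id, own_site))]
  edges <- ok[, .(n_support = .N, support_events = list(event_id)),
              by = .(contig, donor_site, acceptor_site)]
  pos_of <- sites$pos[match(edges$donor_site, sites$site_id)]
  edges[, donor_pos := pos_of]
  edges[, acceptor_pos := sites$pos[match(acceptor_site, sites$site_id)]]
  edges <- edges[donor_pos != acceptor_pos]
  setorder(edges, contig, donor_pos, acceptor_pos)
  edges[]
}

#' Insert-size conflict check for one edge
#'
#' For each supporting read, the implied insert size is the pair's reference
#' outer span minus the intron length of the junction under test
#' (transcript-space insert). A supporting read whose implied pair is
#' discordant votes "conflict"; reads with an unmapped or absent mate
#' abstain. The edge is a conflict only when every voting support conflicts —
#' one clean placement is positive evidence for the junction.
#'
#' @param edge One row of the edge table.
#' @param events Event table.
#' @param pairs Pair index.
#' @param model An `insert_model`.
#' @return `"ok"` or `"conflict"`.
#' @export
conflict_check <- function(edge, events, pairs, model) {
  ids <- unlist(edge$support_events)
  votes <- logical(0)
  gap <- edge$acceptor_pos - edge$donor_pos
  for (id in ids) {
    e <- events[event_id == id]
    if (nrow(e) == 0L) next
    mate <- mate_span(e, pairs)
    if (is.null(mate)) next                      # abstain
    suffix <- e$side == "SUFFIX"
    p <- if (suffix) edge$acceptor_pos else edge$donor_pos
    len <- e$clip_len
    if (suffix) {
      outer <- max(p + len, mate$end, e$span_end) - min(e$span_start, mate$start)
    } else {
      outer <- max(e$span_end, mate$end) - min(p - len, mate$start, e$span_start)
    }
    votes <- c(votes, is_discordant_pair(outer - gap, model))
  }
  if (length(votes) && all(votes)) "conflict" else "ok"
}

#' Call splice junctions
#'
#' A junction is CALLED when (1) both its donor and acceptor sites are
#' classified true, (2) a connection edge exists (at least one split-mapped
#' read), and (3) the insert-size conflict check passes. Edges failing only
#' condition (3) are retained with status `CONFLICT_FILTERED` for reporting.
#'
#' @param edges Edge table from [build_connection_graph()].
#' @param sites Site table.
#' @param predicted Logical vector aligned with `sites` rows
#'   ([predict_sites()] output).
#' @param events Event table.
#' @param pairs Pair index.
#' @param model An `insert_model`.
#' @return `data.table` of junctions: `contig`, `donor_pos`, `acceptor_pos`,
#'   `n_clip`, `n_seg`, `n_disc`, `status`.
#' @export
call_junctions <- function(edges, sites, predicted, events, pairs, model) {
  empty <- data.table(contig = character(), donor_pos = integer(),
                      acceptor_pos = integer(), n_clip = integer(),
                      n_seg = integer(), n_disc = integer(),
                      status = character())
  if (nrow(edges) == 0L) return(empty)
  true_ids <- sites$site_id[predicted]
  rows <- vector("list", nrow(edges))
  for (i in seq_len(nrow(edges))) {
    e <- edges[i]
    if (!(e$donor_site %in% true_ids) || !(e$acceptor_site %in% true_ids))
      next
    st <- if (conflict_check(e, events, pairs, model) == "ok") "CALLED"
          else "CONFLICT_FILTERED"
    d <- sites[site_id == e$donor_site]
    a <- sites[site_id == e$acceptor_site]
    rows[[i]] <- data.table(
      contig = e$contig, donor_pos = e$donor_pos,
      acceptor_pos = e$acceptor_pos,
      n_clip = count_clipped_reads(d, events) + count_clipped_reads(a, events),
      n_seg = e$n_support,
      n_disc = count_discordant_encompassing(d, pairs),
      status = st)
  }
  out <- rbindlist(rows[!vapply(rows, is.null, logical(1))])
  if (nrow(out) == 0L) return(empty)
  # deduplicate edges collapsing to the same junction coordinates
  out <- out[, .(n_clip = max(n_clip), n_seg = sum(n_seg),
                 n_disc = max(n_disc),
                 status = if (any(status == "CALLED")) "CALLED"
                          else "CONFLICT_FILTERED"),
             by = .(contig, donor_pos, acceptor_pos)]
  setorder(out, contig, donor_pos, acceptor_pos)
  out[]
}

#' Default pipeline configuration
#'
#' @param bam,ref,fastq1,fastq2 Input paths.
#' @param s Site merge distance in bp (10).
#' @param l Flank-region length in bp (25).
#' @param max_jump Maximum junction size in bp (1,500,000).
#' @param mapq_min Minimum mapping quality (20).
#' @param min_clip_len Minimum clip length to keep an event (8).
#' @param mm_rate Re-alignment mismatch tolerance per base (0.04).
#' @param seed Seed for any stochastic step (42).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(bam = NULL, ref = NULL, fastq1 = NULL,
                            fastq2 = NULL, s = 10L, l = 25L,
                            max_jump = 1500000L, mapq_min = 20L,
                            min_clip_len = 8L, mm_rate = 0.04, seed = 42L) {
  structure(list(bam = bam, ref = ref, fastq1 = fastq1, fastq2 = fastq2,
                 s = s, l = l, max_jump = max_jump, mapq_min = mapq_min,
                 min_clip_len = min_clip_len, mm_rate = mm_rate, seed = seed),
            class = "pipeline_config")
}

#' Run the full junction-calling pipeline
#'
#' Orchestrates: alignment loading, read classification, coverage and
#' insert-model estimation, clip-event extraction with hard-clip recovery,
#' candidate-site calling and merging, focal re-alignment, feature
#' computation, site classification, and junction calling with the conflict
#' filter. Deterministic given the configuration seed.
#'
#' @param cfg A `pipeline_config`.
#' @param model A trained `cj_model` (or `NULL` to stop after features, e.g.
#'   for training).
#' @param insert_model Optional `insert_model` overriding estimation.
#' @param out_dir Optional directory to write `junctions.tsv`, `sites.tsv`,
#'   `features.tsv`.
#' @return List with `junctions`, `sites`, `features`, `events`, `results`,
#'   `pairs`, `track`, `insert_model`, `predicted`, `read_report`, `counts`.
#' @export
run_pipeline <- function(cfg, model = NULL, insert_model = NULL,
                         out_dir = NULL) {
  genome_ss <- Biostrings::readDNAStringSet(cfg$ref)
  names(genome_ss) <- sub("\\s.*$", "", names(genome_ss))
  genome <- as.character(genome_ss)
  contig_lengths <- stats::setNames(nchar(genome), names(genome))

  aln <- read_alignments(cfg$bam)
  counts <- list(records = nrow(aln))
  if (nrow(aln) == 0L) {
    empty <- call_junctions(
      data.table(contig = character(), donor_site = integer(),
                 acceptor_site = integer(), donor_pos = integer(),
                 acceptor_pos = integer(), n_support = integer(),
                 support_events = list()),
      empty_sites()[, `:=`(site_id = integer(0))], logical(0),
      empty_events(), NULL, NULL)
    return(list(junctions = empty, sites = empty_sites(),
                features = NULL, events = empty_events(),
                results = NULL, pairs = NULL, track = NULL,
                insert_model = insert_model, predicted = logical(0),
                read_report = NULL, counts = counts))
  }
  cls <- classify_read(aln$cigar, aln$mapq, aln$is_unmapped, cfg$mapq_min)
  counts$discarded <- sum(cls == "DISCARD")
  track <- build_coverage(aln, contig_lengths, cfg$mapq_min)
  imodel <- insert_model %||% estimate_insert_model(aln[mate == 1L]$isize)
  pairs <- build_pair_index(aln, imodel, cfg$mapq_min)

  events <- extract_clip_events(aln, cfg$mapq_min, cfg$min_clip_len)
  if (any(events$hard) && !is.null(cfg$fastq1))
    events <- recover_hard_clips(events, cfg$fastq1, cfg$fastq2)
  counts$clip_events <- nrow(events)

  raw <- rbindlist(list(call_clip_sites(events),
                        call_coverage_change_sites(track)),
                   use.names = TRUE)
  sites <- merge_and_orient(raw, cfg$s)
  counts$candidate_sites <- nrow(sites)

  ra <- realign_all(events, sites, genome, imodel, pairs,
                    cfg$max_jump, cfg$mm_rate)
  sites <- ra$sites; results <- ra$results
  counts$realigned <- sum(results$status %in% c("MATCHED_SITE", "NEW_SITE"))

  features <- compute_features(sites, events, results, pairs, track, cfg$l)
  if (is.null(model))
    return(list(junctions = NULL, sites = sites, features = features,
                events = events, results = results, pairs = pairs,
                track = track, insert_model = imodel, predicted = NULL,
                read_report = NULL, counts = counts))

  predicted <- predict_sites(model, features)
  counts$true_sites <- sum(predicted)
  edges <- build_connection_graph(sites, results, events)
  junctions <- call_junctions(edges, sites, predicted, events, pairs, imodel)
  counts$called <- sum(junctions$status == "CALLED")

  report <- read_placement_report(aln, cls, events, results)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_junctions_tsv(junctions, file.path(out_dir, "junctions.tsv"))
    write_sites_tsv(sites, file.path(out_dir, "sites.tsv"))
    write_features_tsv(features, file.path(out_dir, "features.tsv"))
  }
  list(junctions = junctions, sites = sites, features = features,
       events = events, results = results, pairs = pairs, track = track,
       insert_model = imodel, predicted = predicted,
       read_report = report, counts = counts)
}

# per-read placement: mapped bases from the primary alignment plus clipped
# bases placed by re-alignment; coordinates retained for truth comparison
read_placement_report <- function(aln, cls, events, results) {
  a <- copy(aln)[, cls := cls]
  a <- a[!is.na(cigar)]
  qw <- GenomicAlignments::cigarWidthAlongQuerySpace(a$cigar,
                                                     after.soft.clipping = FALSE)
  hard <- vapply(seq_len(nrow(a)), function(i) {
    ops <- GenomicAlignments::explodeCigarOps(a$cigar[i])[[1]]
    lens <- GenomicAlignments::explodeCigarOpLengths(a$cigar[i])[[1]]
    sum(lens[ops == "H"])
  }, numeric(1))
  total <- qw + hard
  soft <- vapply(seq_len(nrow(a)), function(i) {
    ops <- GenomicAlignments::explodeCigarOps(a$cigar[i])[[1]]
    lens <- GenomicAlignments::explodeCigarOpLengths(a$cigar[i])[[1]]
    sum(lens[ops == "S"])
  }, numeric(1))
  mapped <- total - hard - soft
  rep <- data.table(qname = a$qname, mate = a$mate, contig = a$contig,
                    pos = a$pos, cigar = a$cigar, total_bases = total,
                    mapped_bases = ifelse(a$cls == "DISCARD", 0, mapped))
  placed_clip <- rep(0L, nrow(rep))
  if (nrow(results)) {
    ok <- results[status %in% c("MATCHED_SITE", "NEW_SITE")]
    if (nrow(ok)) {
      ev <- events[match(ok$event_id, events$event_id)]
      key <- paste0(rep$qname, "/", rep$mate)
      for (i in seq_len(nrow(ok))) {
        j <- match(paste0(ok$qname[i], "/", ok$mate[i]), key)
        if (!is.na(j)) placed_clip[j] <- placed_clip[j] + ev$clip_len[i]
      }
    }
  }
  rep[, placed_bases := mapped_bases + placed_clip]
  rep[]
}

#' Write called junctions to a TSV file
#'
#' Columns: contig, donor_pos, acceptor_pos (0-based; donor_pos is the first
#' intronic base, acceptor_pos the first exonic base after the intron),
#' n_clip, n_seg, n_disc, status.
#'
#' @param junctions Junction table.
#' @param path Output path.
#' @export
write_junctions_tsv <- function(junctions, path) {
  fwrite(junctions, path, sep = "\t")
  invisible(path)
}

#' Read a junction TSV (same columns as [write_junctions_tsv()])
#' @param path File path.
#' @export
read_junctions_tsv <- function(path) fread(path, sep = "\t")

#' Export called junctions as BED12 for genome-browser viewing
#'
#' Each junction becomes a two-block BED12 line with 1 bp anchors flanking
#' the intron.
#'
#' @param junctions Junction table.
#' @param path Output path.
#' @export
write_junctions_bed <- function(junctions, path) {
  j <- junctions[status == "CALLED"]
  if (nrow(j) == 0L) { writeLines(character(0), path); return(invisible(path)) }
  start <- j$donor_pos - 1L
  end <- j$acceptor_pos + 1L
  lines <- sprintf("%s\t%d\t%d\tjunc%d\t%d\t+\t%d\t%d\t0,0,255\t2\t1,1\t0,%d",
                   j$contig, start, end, seq_len(nrow(j)),
                   pmin(1000L, j$n_seg * 100L), start, end,
                   j$acceptor_pos - start)
  writeLines(lines, path)
  invisible(path)
}
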