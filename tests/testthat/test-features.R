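imodel <- function(m = 300, v = 30)
  structure(list(m = m, v = v), class = "insert_model")

mk_event <- function(contig, clip_pos, side, clip_seq, span, qname = "r1",
                     mate = 1L) {
  data.table(qname = qname, mate = mate, contig = contig,
             clip_pos = as.integer(clip_pos), side = side,
             clip_len = nchar(clip_seq), clip_seq = clip_seq, hard = FALSE,
             is_reverse = FALSE, span_start = as.integer(span[1]),
             span_end = as.integer(span[2]), mate_contig = contig,
             mate_pos = NA_integer_, event_id = 1L)
}

mk_sites <- function(pos, direction, contig = "chrS") {
  data.table(contig = contig, pos = as.integer(pos), direction = direction,
             origin = "CLIP", n_events = 1L,
             event_ids = replicate(length(pos), integer(0), simplify = FALSE),
             merged_from = replicate(length(pos), integer(0), simplify = FALSE),
             site_id = seq_along(pos))
}

test_that("long-jump focal re-alignment recovers a distal boundary (2,447 bp intron)", {
  g <- random_genome(6000, 41)
  donor <- 1000L; acceptor <- donor + 2447L
  for (len in c(14L, 21L)) {
    seg <- substr(g, acceptor + 1L, acceptor + len)
    sites <- mk_sites(c(1500, 2200, 3000, acceptor), rep("ACCEPTOR", 4))
    ev <- mk_event("chrS", donor, "SUFFIX", seg, c(donor - 86L, donor))
    r <- realign_clipped_segment(ev, sites, c(chrS = g), imodel())
    expect_equal(r$status, "MATCHED_SITE")
    expect_equal(r$target_pos, acceptor)
    expect_equal(r$mismatches, 0L)
    # agreement with the exhaustive oracle
    o <- brute_realign(ev, sites, c(chrS = g), imodel(), NULL)
    expect_equal(o$status, r$status)
    expect_equal(o$target_pos, r$target_pos)
  }
})

test_that("mate-bounded search rejects placements implying a discordant pair", {
  # two candidate donors match the segment; the nearer one would make the
  # pair discordant, so the farther one is chosen
  g0 <- random_genome(5000, 42)
  seg <- substr(g0, 101, 120)                   # arbitrary 20-mer
  plant <- function(g, at) paste0(substr(g, 1, at), seg,
                                  substr(g, at + 21, nchar(g)))
  g <- plant(plant(g0, 3580), 3880)             # donors at 3600 and 3900
  genome <- c(chrS = g)
  b0 <- 4000L
  sites <- mk_sites(c(3600, 3900), c("DONOR", "DONOR"))
  ev <- mk_event("chrS", b0, "PREFIX", seg, c(4000, 4100), qname = "p1")
  pairs <- data.table(qname = "p1", contig1 = "chrS", start1 = 4000L,
                      end1 = 4100L, rev1 = FALSE, contig2 = "chrS",
                      start2 = 3420L, end2 = 3520L, rev2 = TRUE,
                      isize = 680L, discordant = FALSE)
  setkey(pairs, qname)
  r <- realign_clipped_segment(ev, sites, genome, imodel(), pairs)
  expect_equal(r$status, "MATCHED_SITE")
  expect_equal(r$target_pos, 3600L)             # 3900 vetoed
  # without the mate there is no veto: nearest match wins
  r2 <- realign_clipped_segment(ev, sites, genome, imodel(), NULL)
  expect_equal(r2$target_pos, 3900L)
})

test_that("unalignable segments and new-site fallback behave", {
  g <- random_genome(3000, 43)
  genome <- c(chrS = g)
  ev <- mk_event("chrS", 500L, "SUFFIX", strrep("A", 30), c(400, 500))
  sites <- mk_sites(1500, "ACCEPTOR")
  r <- realign_clipped_segment(ev, sites, genome, imodel())
  expect_equal(r$status, "UNALIGNED")
  # a unique off-site match becomes a NEW_SITE
  seg <- substr(g, 2001, 2025)
  ev2 <- mk_event("chrS", 500L, "SUFFIX", seg, c(400, 500))
  r2 <- realign_clipped_segment(ev2, sites, genome, imodel())
  expect_equal(r2$status, "NEW_SITE")
  expect_equal(r2$target_pos, 2000L)
  o <- brute_realign(ev2, sites, genome, imodel(), NULL)
  expect_equal(list(o$status, o$target_pos), list(r2$status, r2$target_pos))
  # empty clip_seq is a contract violation
  ev3 <- mk_event("chrS", 500L, "SUFFIX", "A", c(400, 500))
  ev3$clip_seq <- NA_character_
  expect_error(realign_clipped_segment(ev3, sites, genome, imodel()),
               "recover_hard_clips")
})

test_that("re-alignment agrees with the exhaustive oracle on fixture events", {
  d <- tiny_sim()
  run <- tiny_run()
  genome <- d$models$genome
  ev <- run$events[!is.na(clip_seq)]
  set.seed(1)
  idx <- sample(nrow(ev), min(40L, nrow(ev)))
  base_sites <- run$sites[origin != "REALIGN"]
  for (i in idx) {
    got <- realign_clipped_segment(ev[i], base_sites, genome,
                                   run$insert_model, run$pairs)
    want <- brute_realign(ev[i], base_sites, genome,
                          run$insert_model, run$pairs)
    expect_equal(got$status, want$status)
    if (got$status != "UNALIGNED")
      expect_equal(got$target_pos, want$target_pos)
  }
})

test_that("re-alignment is side-consistent and bounded", {
  run <- tiny_run()
  res <- run$results[status %in% c("MATCHED_SITE", "NEW_SITE")]
  s <- run$sites
  hit_dir <- s$direction[match(res$target_site_id, s$site_id)]
  expect_true(all(hit_dir[res$side == "SUFFIX"] == "ACCEPTOR", na.rm = TRUE))
  expect_true(all(hit_dir[res$side == "PREFIX"] == "DONOR", na.rm = TRUE))
  expect_true(all(abs(res$target_pos - res$b0) <= 1500000L))
  # f_seg at a site never exceeds events whose search interval contains it
  fx <- run$features
  expect_true(all(fx$f_seg <= nrow(run$events)))
})

test_that("coverage difference follows the two-flank formula", {
  track <- structure(list(chrS = c(rep(10L, 100), rep(0L, 100))),
                     class = "coverage_track")
  sdon <- mk_sites(100, "DONOR")
  expect_equal(coverage_difference(sdon[1], track, l = 25L), 10)
  sacc <- mk_sites(100, "ACCEPTOR")
  expect_equal(coverage_difference(sacc[1], track, l = 25L), -10)
  # uniform coverage -> 0
  flat <- structure(list(chrS = rep(7L, 200)), class = "coverage_track")
  expect_equal(coverage_difference(sdon[1], flat, 25L), 0)
  # random array vs direct summation
  set.seed(8)
  arr <- structure(list(chrS = as.integer(rpois(400, 5))),
                   class = "coverage_track")
  st <- mk_sites(200, "DONOR")
  expect_equal(coverage_difference(st[1], arr, 25L),
               sum(arr$chrS[176:200]) / 25 - sum(arr$chrS[201:225]) / 25)
  # clamped at the contig edge: uses the actual region length
  st2 <- mk_sites(10, "DONOR")
  expect_equal(coverage_difference(st2[1], arr, 25L),
               mean(arr$chrS[1:10]) - mean(arr$chrS[11:35]))
})

test_that("normalization divides by the anchor mean; zero anchor gives zeros", {
  track <- structure(list(chrS = c(rep(10L, 100), rep(0L, 100))),
                     class = "coverage_track")
  sites <- mk_sites(100, "DONOR")
  sites$event_ids <- list(1:3)
  ev <- rbindlist(lapply(1:3, function(i)
    mk_event("chrS", 100L, "SUFFIX", strrep("A", 10), c(50, 100),
             qname = paste0("r", i))))
  ev[, event_id := 1:3]
  res <- data.table(event_id = integer(), qname = character(),
                    mate = integer(), contig = character(), side = character(),
                    b0 = integer(), status = character(),
                    target_pos = integer(), target_site_id = integer(),
                    mismatches = integer())
  fx <- compute_features(sites, ev, res, NULL, track, l = 25L)
  expect_equal(fx$f_clip, 3L)
  expect_equal(fx$anchor, 10)
  expect_equal(fx$nf_clip, 0.3)
  expect_equal(fx$nf_cov, 1)
  # zero anchor: acceptor site with nothing to its right
  sz <- mk_sites(150, "ACCEPTOR")
  fz <- compute_features(sz, clipjunc:::empty_events(), res, NULL, track, 25L)
  expect_equal(fz$anchor, 0)
  expect_equal(unlist(fz[, .(nf_clip, nf_seg, nf_disc, nf_cov)]),
               c(nf_clip = 0, nf_seg = 0, nf_disc = 0, nf_cov = 0))
})

test_that("discordant encompassing pairs require opposite non-overlapping sides", {
  pairs <- data.table(
    qname = c("d1", "c1", "ov"),
    contig1 = "chrS", start1 = c(100L, 900L, 950L), end1 = c(200L, 1000L, 1050L),
    rev1 = FALSE, contig2 = "chrS",
    start2 = c(5000L, 1000L, 1200L), end2 = c(5100L, 1100L, 1300L),
    rev2 = TRUE, isize = c(5000L, 300L, 350L),
    discordant = c(TRUE, FALSE, TRUE))
  setkey(pairs, qname)
  site <- mk_sites(1000, "DONOR")
  # d1 encompasses and is discordant; c1 concordant; ov overlaps the site
  expect_equal(count_discordant_encompassing(site[1], pairs), 1L)
  site2 <- mk_sites(960, "DONOR")   # inside ov's first mate
  expect_equal(count_discordant_encompassing(site2[1], pairs), 1L)  # only d1
})

test_that("fixture discordant-encompassing counts match a brute-force pair scan", {
  run <- tiny_run()
  fx <- run$features
  p <- run$pairs
  set.seed(2)
  for (i in sample(nrow(fx), 25L)) {
    row <- fx[i]
    manual <- sum(p$discordant & p$contig1 == row$contig &
                    p$contig2 == row$contig &
                    ((p$end1 <= row$pos & p$start2 >= row$pos) |
                       (p$end2 <= row$pos & p$start1 >= row$pos)), na.rm = TRUE)
    expect_equal(row$f_disc, manual)
  }
})

test_that("clipped-read counts at truth boundaries match an independent scan", {
  d <- tiny_sim()
  run <- tiny_run()
  fx <- run$features
  ev <- run$events
  tr <- d$models$truth
  for (i in head(seq_len(nrow(tr)), 10)) {
    site <- fx[contig == tr$contig[i] & direction == "DONOR" &
                 pos == tr$donor_pos[i]]
    if (nrow(site) == 0L) next
    manual <- length(unique(paste0(
      ev[contig == tr$contig[i] & side == "SUFFIX" &
           abs(clip_pos - tr$donor_pos[i]) <= 10L]$qname, "/",
      ev[contig == tr$contig[i] & side == "SUFFIX" &
           abs(clip_pos - tr$donor_pos[i]) <= 10L]$mate)))
    expect_equal(site$f_clip, manual)
  }
})
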