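imodel <- function(m = 300, v = 30)
  structure(list(m = m, v = v), class = "insert_model")

# Hand-built scene mirroring the paired-end conflict illustration: junction
# [A,B] is supported by a read whose implied transcript-space insert is
# concordant; junction [C,D]'s sole support implies a discordant pair.
conflict_scene <- function() {
  events <- data.table(
    qname = c("r1", "r2", "r3"), mate = 1L, contig = "chrS",
    clip_pos = c(1000L, 2000L, 1000L),
    side = "SUFFIX", clip_len = 20L, clip_seq = strrep("A", 20),
    hard = FALSE, is_reverse = FALSE,
    span_start = c(900L, 1900L, 920L), span_end = c(1000L, 2000L, 1000L),
    mate_contig = "chrS", mate_pos = NA_integer_, event_id = 1:3)
  pairs <- data.table(
    qname = c("r1", "r2", "r3"),
    contig1 = "chrS", start1 = c(900L, 1900L, 920L),
    end1 = c(1000L, 2000L, 1000L), rev1 = FALSE,
    contig2 = "chrS", start2 = c(1450L, 2100L, 1430L),
    end2 = c(1550L, 2200L, 1530L), rev2 = TRUE,
    isize = c(650L, 300L, 610L), discordant = FALSE)
  setkey(pairs, qname)
  list(events = events, pairs = pairs)
}

test_that("conflict filter discards [C,D] and keeps [A,B]", {
  sc <- conflict_scene()
  # [A,B]: donor 1000 -> acceptor 1400, gap 400; outer span 650;
  # implied insert 250 in [210, 390] -> ok
  ab <- data.table(contig = "chrS", donor_site = 1L, acceptor_site = 2L,
                   donor_pos = 1000L, acceptor_pos = 1400L, n_support = 1L,
                   support_events = list(1L))
  expect_equal(conflict_check(ab[1], sc$events, sc$pairs, imodel()), "ok")
  # [C,D]: donor 2000 -> acceptor 3000, gap 1000; mate sits inside the
  # intron-adjacent exon; outer span 1120; implied insert 120 -> conflict
  cd <- data.table(contig = "chrS", donor_site = 3L, acceptor_site = 4L,
                   donor_pos = 2000L, acceptor_pos = 3000L, n_support = 1L,
                   support_events = list(2L))
  expect_equal(conflict_check(cd[1], sc$events, sc$pairs, imodel()),
               "conflict")
  # one clean support outvotes a conflicting one
  mixed <- data.table(contig = "chrS", donor_site = 1L, acceptor_site = 2L,
                      donor_pos = 1000L, acceptor_pos = 1400L,
                      n_support = 2L, support_events = list(c(1L, 2L)))
  expect_equal(conflict_check(mixed[1], sc$events, sc$pairs, imodel()), "ok")
  # mate-less supports abstain; all-abstain edges pass
  ev2 <- copy(sc$events)
  expect_equal(conflict_check(ab[1], ev2, sc$pairs[0], imodel()), "ok")
})

test_that("junction calling enforces all three conditions", {
  sc <- conflict_scene()
  sites <- data.table(contig = "chrS", pos = c(1000L, 1400L, 2000L, 3000L),
                      direction = c("DONOR", "ACCEPTOR", "DONOR", "ACCEPTOR"),
                      origin = "CLIP", n_events = 1L,
                      event_ids = list(1L, integer(0), 2L, integer(0)),
                      merged_from = list(1L, 1L, 1L, 1L), site_id = 1:4)
  edges <- data.table(contig = "chrS", donor_site = c(1L, 3L),
                      acceptor_site = c(2L, 4L),
                      donor_pos = c(1000L, 2000L),
                      acceptor_pos = c(1400L, 3000L), n_support = 1L,
                      support_events = list(1L, 2L))
  all_true <- rep(TRUE, 4)
  j <- call_junctions(edges, sites, all_true, sc$events, sc$pairs, imodel())
  expect_equal(nrow(j), 2L)
  expect_equal(j[donor_pos == 1000L]$status, "CALLED")
  expect_equal(j[donor_pos == 2000L]$status, "CONFLICT_FILTERED")
  # condition 1: an endpoint classified false kills the junction
  pred <- c(TRUE, FALSE, TRUE, TRUE)
  j2 <- call_junctions(edges, sites, pred, sc$events, sc$pairs, imodel())
  expect_false(1000L %in% j2$donor_pos)
  # condition 2: no edge, no junction (site pair 1-4 has no edge)
  j3 <- call_junctions(edges[0], sites, all_true, sc$events, sc$pairs,
                       imodel())
  expect_equal(nrow(j3), 0L)
})

test_that("connection graph matches brute-force truth pairing on the fixture", {
  d <- tiny_sim()
  run <- tiny_run()
  edges <- build_connection_graph(run$sites, run$results, run$events)
  want <- expected_edges(d$reads)
  got <- unique(edges[, .(contig, donor_pos, acceptor_pos)])
  setkey(want, contig, donor_pos, acceptor_pos)
  setkey(got, contig, donor_pos, acceptor_pos)
  expect_equal(got, want)
})

test_that("removing discordant-pair information never adds junctions", {
  run <- tiny_run()
  d <- tiny_sim()
  edges <- build_connection_graph(run$sites, run$results, run$events)
  all_true <- rep(TRUE, nrow(run$sites))
  with_pairs <- call_junctions(edges, run$sites, all_true, run$events,
                               run$pairs, run$insert_model)
  no_pairs <- call_junctions(edges, run$sites, all_true, run$events,
                             run$pairs[0], run$insert_model)
  called_with <- with_pairs[status == "CALLED"]
  called_wo <- no_pairs[status == "CALLED"]
  expect_true(all(paste(called_with$contig, called_with$donor_pos) %in%
                    paste(called_wo$contig, called_wo$donor_pos)))
})

test_that("pipeline handles an empty BAM cleanly", {
  g <- c(chrS = random_genome(1000, 50))
  dir <- file.path(tempdir(), "emptybam")
  dir.create(dir, showWarnings = FALSE)
  ref <- file.path(dir, "ref.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(g), ref)
  Rsamtools::indexFa(ref)
  rec <- data.table(qname = character(), mate = integer(), contig = character(),
                    pos = integer(), cigar = character(), seq = character(),
                    is_reverse = logical(), mate_pos = integer(),
                    isize = integer())
  bam <- file.path(dir, "empty.bam")
  write_sim_bam(rec, g, bam)
  cfg <- pipeline_config(bam = bam, ref = ref)
  run <- run_pipeline(cfg, model = NULL,
                      insert_model = imodel())
  expect_equal(run$counts$records, 0L)
})

test_that("called junctions satisfy the three conditions on simulated data", {
  d <- tiny_sim()
  run <- tiny_run()
  ex <- build_training_set(run$features, truth = d$models$truth)
  model <- train_model(ex[contig == "train"],
                       list(C_grid = c(1, 32), gamma_grid = c(0.125, 2)))
  pred <- predict_sites(model, run$features)
  edges <- build_connection_graph(run$sites, run$results, run$events)
  j <- call_junctions(edges, run$sites, pred, run$events, run$pairs,
                      run$insert_model)
  called <- j[status == "CALLED"]
  expect_gt(nrow(called), 0L)
  expect_true(all(called$donor_pos < called$acceptor_pos))
  expect_true(all(called$n_seg >= 1L))
  # both endpoints of every called junction are predicted-true sites
  true_sites <- run$sites[pred]
  for (i in seq_len(nrow(called))) {
    expect_true(any(true_sites$contig == called$contig[i] &
                      true_sites$direction == "DONOR" &
                      true_sites$pos == called$donor_pos[i]))
    expect_true(any(true_sites$contig == called$contig[i] &
                      true_sites$direction == "ACCEPTOR" &
                      true_sites$pos == called$acceptor_pos[i]))
  }
})

test_that("junction files are byte-identical across reruns (same seed)", {
  d <- tiny_sim()
  run <- tiny_run()
  ex <- build_training_set(run$features, truth = d$models$truth)
  model <- train_model(ex[contig == "train"],
                       list(C_grid = 1, gamma_grid = 1))
  cfg <- pipeline_config(bam = d$bam, ref = d$ref, fastq1 = d$fastq1,
                         fastq2 = d$fastq2)
  out1 <- file.path(tempdir(), "det1"); out2 <- file.path(tempdir(), "det2")
  run_pipeline(cfg, model, out_dir = out1)
  run_pipeline(cfg, model, out_dir = out2)
  f1 <- file.path(out1, "junctions.tsv"); f2 <- file.path(out2, "junctions.tsv")
  expect_identical(readLines(f1), readLines(f2))
  expect_gt(length(readLines(f1)), 1L)
})
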