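test_that("coverage_track marks nucleotides under any motif occurrence", {
  cov <- coverage_track("AAUGGUGGAA", "UGGUGG")
  expect_equal(cov, c(0, 0, 1, 1, 1, 1, 1, 1, 0, 0))
  expect_equal(coverage_track("AAAAAA", "UGGUGG"), rep(0L, 6))
  # overlapping occurrences merge into one covered run
  expect_equal(coverage_track("GUGGUGGUG", "GUGGUG"), rep(1L, 9))
  expect_equal(coverage_track("", "UGG"), integer(0))
})

test_that("window scores are the covered fraction of each full window", {
  seq50 <- paste0(strrep("A", 20), "UGGUGG", strrep("C", 24))
  ws <- window_scores(seq50, "UGGUGG", window = 50)
  expect_equal(nrow(ws), 1L)
  expect_equal(ws$score, 6 / 50)
  tiled <- strrep("UGGUGG", 20)
  expect_true(all(window_scores(tiled, "UGGUGG")$score == 1))
  expect_true(all(window_scores(strrep("A", 80), "UGGUGG")$score == 0))
  # shorter than one window -> empty
  expect_equal(nrow(window_scores("UGGUGG", "UGGUGG", window = 50)), 0L)
  expect_warning(window_scores(strrep("U", 60), "UGGUGG", window = 4),
                 "shorter than the longest motif")
})

test_that("window scores equal the brute-force per-nucleotide counter", {
  set.seed(88)
  motifs <- c("UGGUGG", "GGUGGU", "GUG")
  for (i in 1:30) {
    seq <- random_rna_seq(sample(50:120, 1))
    ws <- window_scores(seq, motifs, window = 50)
    cov <- naive_coverage(seq, motifs)
    brute <- vapply(seq_len(nchar(seq) - 49), function(s)
      sum(cov[s:(s + 49)]) / 50, numeric(1))
    expect_equal(ws$score, brute, tolerance = 1e-12)
    expect_equal(ws$offset, 0:(nchar(seq) - 50))
  }
})

toy_segments <- function(n, upI_fun, seed = 7) {
  set.seed(seed)
  data.frame(
    event_id = sprintf("s%03d", seq_len(n)),
    upstream_exon = vapply(seq_len(n), function(i) random_rna_seq(120), ""),
    upstream_intron = vapply(seq_len(n), function(i) upI_fun(), ""),
    cassette_exon = vapply(seq_len(n), function(i) random_rna_seq(100), ""),
    downstream_intron = vapply(seq_len(n), function(i) random_rna_seq(250), ""),
    downstream_exon = vapply(seq_len(n), function(i) random_rna_seq(120), ""),
    stringsAsFactors = FALSE)
}

test_that("a single-event set reproduces that event's window scores", {
  segs <- toy_segments(1, function() random_rna_seq(250))
  prof <- build_map(list(solo = "s001"), segs, esrp_motifs())
  up <- prof[prof$segment == "upstream_intron", ]
  ws <- window_scores(segs$upstream_intron, esrp_motifs(), window = 50)
  expect_equal(up$mean_score, ws$score)
  # upstream-intron positions anchored at the 3'ss: -250 .. -50
  expect_equal(up$position, -250:-50)
  expect_true(all(up$n_events == 1L))
  dn <- prof[prof$segment == "downstream_intron", ]
  expect_equal(dn$position, 0:200)
})

test_that("profiles are invariant to event order and averaged over contributors", {
  segs <- toy_segments(6, function() random_rna_seq(sample(150:250, 1)))
  p1 <- build_map(list(all = segs$event_id), segs, "UGGUGG")
  p2 <- build_map(list(all = rev(segs$event_id)), segs, "UGGUGG")
  expect_equal(p1, p2)
  # contributing-event counts never exceed the set size, and events define
  # windows only where their segment is long enough
  expect_true(all(p1$n_events <= 6L))
  up <- p1[p1$segment == "upstream_intron", ]
  expect_equal(max(up$n_events), 6L)
  expect_true(min(up$n_events) >= 1L)
})

test_that("planting motifs never decreases the upstream-intron profile", {
  segs <- toy_segments(8, function() random_rna_seq(250), seed = 21)
  before <- build_map(list(s = segs$event_id), segs, "UGGUGG")
  set.seed(33)
  segs2 <- segs
  segs2$upstream_intron <- vapply(segs2$upstream_intron, function(s)
    plant_motifs(s, "UGGUGG", 3)$seq, character(1), USE.NAMES = FALSE)
  after <- build_map(list(s = segs2$event_id), segs2, "UGGUGG")
  b <- before[before$segment == "upstream_intron", ]
  a <- after[after$segment == "upstream_intron", ]
  expect_equal(a$position, b$position)
  expect_true(all(a$mean_score >= b$mean_score - 1e-12))
  expect_true(sum(a$mean_score) > sum(b$mean_score))
})

test_that("exon segments are anchored from both edges", {
  segs <- toy_segments(1, function() random_rna_seq(250))
  prof <- build_map(list(s = "s001"), segs, "UGGUGG",
                    map_config(anchor_windows = 20))
  ex <- prof[prof$segment == "cassette_exon", ]
  # 100-nt exon, 51 windows: 20 kept from each edge
  expect_equal(sum(ex$position >= 0), 20L)
  expect_equal(sum(ex$position < 0), 20L)
  expect_equal(ex$position[ex$position >= 0], 0:19)
})

test_that("build_map validates its inputs", {
  segs <- toy_segments(2, function() random_rna_seq(250))
  expect_error(build_map(list(s = segs$event_id), segs, character(0)),
               "empty")
  expect_error(build_map(list(s = "missing"), segs, "UGGUGG"), "no rows")
  expect_error(build_map(list(segs$event_id), segs, "UGGUGG"), "named")
})

test_that("planted architecture shows up in the right segment of the map", {
  set.seed(55)
  n <- 15
  segs <- toy_segments(n, function() random_rna_seq(250), seed = 61)
  ctl <- toy_segments(n, function() random_rna_seq(250), seed = 62)
  ctl$event_id <- sub("s", "c", ctl$event_id)
  segs$upstream_intron <- vapply(segs$upstream_intron, function(s)
    plant_motifs(s, "UGGUGG", 4)$seq, character(1), USE.NAMES = FALSE)
  both <- rbind(segs, ctl)
  prof <- build_map(list(silenced = segs$event_id, control = ctl$event_id),
                    both, esrp_motifs())
  mean_by <- function(set, segment)
    mean(prof$mean_score[prof$event_set == set & prof$segment == segment])
  expect_gt(mean_by("silenced", "upstream_intron"),
            mean_by("control", "upstream_intron") + 0.02)
  # un-planted segments stay near the control level
  expect_lt(abs(mean_by("silenced", "downstream_intron") -
                mean_by("control", "downstream_intron")), 0.02)
})
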