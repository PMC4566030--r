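se_header <- paste("ID", "GeneID", "chr", "strand", "exonStart_0base",
                   "exonEnd", "upstreamES", "upstreamEE", "downstreamES",
                   "downstreamEE", "PValue", "FDR", "IncLevel1", "IncLevel2",
                   "IncLevelDifference", sep = "\t")

write_se_fixture <- function(rows) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(c(se_header, rows), path)
  path
}

se_row <- function(id = "ev1", strand = "+", inc1 = "0.9,0.85",
                   inc2 = "0.2,0.25,NA", p = "0.001", fdr = "0.01") {
  paste(id, "geneA", "chr1", strand, "500", "600", "100", "200", "900",
        "1000", p, fdr, inc1, inc2, "0.65", sep = "\t")
}

test_that("read_se_table parses rows, replicate PSI strings and NA replicates", {
  path <- write_se_fixture(se_row())
  ev <- read_se_table(path, groups = c("WT", "KO"))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$psi[[1]]$WT, c(0.9, 0.85))
  expect_equal(ev$psi[[1]]$KO, c(0.2, 0.25))
  expect_equal(ev$exon_start, 500)
  expect_equal(ev$exon_end, 600)
  expect_equal(ev$fdr, 0.01)
  expect_identical(attr(ev, "groups"), c("WT", "KO"))

  # header-only file -> empty event list
  empty <- read_se_table(write_se_fixture(character(0)))
  expect_equal(nrow(empty), 0L)
})

test_that("read_se_table rejects malformed tables with informative errors", {
  expect_error(read_se_table(write_se_fixture(se_row(strand = "."))),
               "strand")
  expect_error(read_se_table(write_se_fixture(se_row(inc1 = "1.2,0.5"))),
               "PSI.*\\[0, 1\\]")
  # missing mandatory column is named
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(sub("\tFDR", "\tXYZ", se_header), sub("0.01", "0.01", se_row())),
             path)
  expect_error(read_se_table(path), "FDR")
  # one-based dialect shifts starts only
  p2 <- write_se_fixture(se_row())
  ev2 <- read_se_table(p2, dialect = se_dialect(coord_system = "one_based"))
  expect_equal(ev2$exon_start, 499)
  expect_equal(ev2$exon_end, 600)
})

test_that("summarize_groups computes arithmetic group means", {
  ev <- make_events(list(list(WT = c(0.9, 0.85), KO = c(0.2, 0.25)),
                         list(WT = 0.5, KO = c(0.8, 0.9))),
                    fdr = c(0.01, 0.2))
  s <- summarize_groups(ev)
  expect_equal(s$mean_psi[s$event_id == "e1" & s$group == "WT"], 0.875)
  expect_equal(s$mean_psi[s$event_id == "e1" & s$group == "KO"], 0.225)
  expect_equal(s$mean_psi[s$event_id == "e2" & s$group == "WT"], 0.5)
  expect_equal(s$n_reps[s$event_id == "e2" & s$group == "WT"], 1L)
  expect_equal(s$mean_psi[s$event_id == "e2" & s$group == "KO"], 0.85)

  ev_bad <- make_events(list(list(WT = numeric(0), KO = 0.5)), fdr = 0.5)
  expect_error(summarize_groups(ev_bad), "no usable replicate")
})

test_that("classify_events applies the regulated and control rules", {
  expr <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                     fpkm_1 = c(10, 6, 6, 0.5), fpkm_2 = c(10, 1, 6, 0.5),
                     q_value = 0.5, stringsAsFactors = FALSE)
  ev <- make_events(list(
    # fdr 0.01, delta exactly +0.05 -> enhanced (inclusive threshold)
    list(WT = c(0.55, 0.55), KO = c(0.50, 0.50)),
    # fdr 0.80, means 0.50/0.55, gene FPKM (6, 1) -> control
    list(WT = c(0.5, 0.5), KO = c(0.55, 0.55)),
    # fdr 0.80, means 0.90/0.88 -> unclassified (PSI outside (0.15, 0.85))
    list(WT = c(0.9, 0.9), KO = c(0.88, 0.88)),
    # low-FPKM gene -> unclassified even though PSI/FDR fit the control rule
    list(WT = c(0.5, 0.5), KO = c(0.5, 0.5))),
    fdr = c(0.01, 0.80, 0.80, 0.80))
  cl <- classify_events(ev, expr)
  expect_equal(as.character(cl$label), c("enhanced", "control",
                                         "unclassified", "unclassified"))
  expect_equal(cl$delta_psi, c(0.05, -0.05, 0.02, 0), tolerance = 1e-12)
  # silenced at the mirrored boundary
  ev2 <- make_events(list(list(WT = c(0.5, 0.5), KO = c(0.55, 0.55))),
                     fdr = 0.01, gene_id = "g3")
  expect_equal(as.character(classify_events(ev2, expr)$label), "silenced")
  # gene missing from the expression table -> warning, never control
  ev3 <- make_events(list(list(WT = c(0.5, 0.5), KO = c(0.5, 0.5))),
                     fdr = 0.8, gene_id = "absent")
  expect_warning(cl3 <- classify_events(ev3, expr), "expression")
  expect_equal(as.character(cl3$label), "unclassified")
})

test_that("classification is a partition with consistent counts", {
  set.seed(11)
  psi <- lapply(seq_len(50), function(i) {
    m <- runif(2)
    list(WT = pmin(pmax(rnorm(3, m[1], 0.05), 0), 1),
         KO = pmin(pmax(rnorm(3, m[2], 0.05), 0), 1))
  })
  ev <- make_events(psi, fdr = runif(50))
  expr <- data.frame(gene_id = ev$gene_id, fpkm_1 = runif(50, 0, 20),
                     fpkm_2 = runif(50, 0, 20), q_value = 0.5,
                     stringsAsFactors = FALSE)
  cl <- classify_events(ev, expr)
  expect_false(anyNA(cl$label))
  expect_equal(sum(attr(cl, "counts")), 50)
  expect_equal(nrow(cl), length(unique(cl$event_id)))
})

test_that("compare_event_sets computes exclusive intersection regions", {
  out <- compare_event_sets(list(A = c("1", "2"), B = c("2", "3")))
  expect_equal(out$count[out$region == "A"], 1L)
  expect_equal(out$count[out$region == "B"], 1L)
  expect_equal(out$count[out$region == "A&B"], 1L)
  expect_equal(attr(out, "totals"), c(A = 2L, B = 2L))

  same <- compare_event_sets(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(same$count[same$region == "A&B"], 2L)
  expect_equal(sum(same$count), 2L)

  disj <- compare_event_sets(list(A = "x", B = "y", C = "z"))
  expect_equal(disj$count[disj$region == "A&B&C"], 0L)
  expect_equal(sum(disj$count), 3L)

  expect_error(compare_event_sets(list(A = "x")), "at least two")
})

test_that("classifications round-trip through TSV with identical labels", {
  ev <- make_events(list(list(WT = c(0.9, 0.8), KO = c(0.3, 0.2)),
                         list(WT = c(0.2, 0.3), KO = c(0.7, 0.8))),
                    fdr = c(0.001, 0.001))
  cl <- classify_events(ev, NULL) |> suppressWarnings()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_classifications(cl, path)
  back <- read_classifications(path)
  expect_identical(as.character(back$label), as.character(cl$label))
  expect_equal(back$delta_psi, cl$delta_psi, tolerance = 1e-12)
  expect_identical(back$event_id, cl$event_id)
})
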