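test_that("count_occurrences counts overlapping hits by-NT and presence by-Sequence", {
  expect_equal(count_occurrences("GUGGUGGUG", "GUGGUG", "by_nt"), 2L)
  expect_equal(count_occurrences("GUGGUGGUG", "GUGGUG", "by_seq"), 1L)
  expect_equal(count_occurrences("", "UGGUGG", "by_nt"), 0L)
  expect_equal(count_occurrences("AAACCC", "UGGUGG", "by_nt"), 0L)
  expect_equal(count_occurrences("AAA", "UGGUGG", "by_nt"), 0L)  # motif > seq
  # N in the sequence matches nothing; IUPAC degeneracy in the pattern does
  expect_equal(count_occurrences("UGNUGG", "UGGUGG", "by_nt"), 0L)
  expect_equal(count_occurrences("UACUCG", "URG", "by_nt"), 0L)
  expect_equal(count_occurrences("UAGUGG", "URG", "by_nt"), 2L)
})

test_that("counting agrees with a naive scanner and by_seq = min(1, by_nt)", {
  set.seed(31)
  motifs <- c("UGGUGG", "GUG", "URGN", "AC")
  for (i in 1:40) {
    seq <- random_rna_seq(sample(0:40, 1))
    if (runif(1) < 0.3 && nchar(seq) > 3)
      substr(seq, 2, 2) <- "N"
    for (m in motifs) {
      by_nt <- count_occurrences(seq, m, "by_nt")
      expect_equal(by_nt, naive_count(seq, m), info = paste(seq, m))
      expect_equal(count_occurrences(seq, m, "by_seq"), min(1L, by_nt))
    }
  }
})

test_that("fisher_right is the right-tail hypergeometric probability", {
  expect_equal(fisher_right(2, 0, 0, 2), 1 / 6, tolerance = 1e-12)
  expect_equal(fisher_right(0, 5, 3, 2), 1, tolerance = 1e-12)
  expect_error(fisher_right(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_right(1.5, 2, 3, 4), "non-negative")
  set.seed(19)
  for (i in 1:60) {
    tb <- sample(0:15, 4, replace = TRUE)
    p <- fisher_right(tb[1], tb[2], tb[3], tb[4])
    expect_equal(p, fisher_enum(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-12, info = paste(tb, collapse = ","))
    # cross-check against the standard exact-test implementation
    if (sum(tb) > 0) {
      ft <- stats::fisher.test(matrix(tb, 2, byrow = TRUE),
                               alternative = "greater")
      expect_equal(p, ft$p.value, tolerance = 1e-9)
    }
  }
})

test_that("bh_adjust reproduces the step-up adjustment", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(1:30, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_hand(p), tolerance = 1e-12)
    # monotone in sorted order, permutation-equivariant
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    perm <- sample(seq_along(p))
    expect_equal(bh_adjust(p[perm]), adj[perm], tolerance = 1e-12)
  }
})

test_that("enumerate_kmers lists all k-mers in order", {
  expect_equal(enumerate_kmers(1)$pattern, c("A", "C", "G", "U"))
  k2 <- enumerate_kmers(2)
  expect_equal(nrow(k2), 16L)
  expect_identical(k2$pattern, sort(k2$pattern))
  expect_equal(nrow(enumerate_kmers(6)), 4096L)
  expect_identical(unique(enumerate_kmers(3)$source), "kmer_enumeration")
})

test_that("motif sets validate their alphabet and read from TSV", {
  expect_error(motif_set("bad", "UGGXGG"), "IUPAC")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tpattern\tsource", "Esrp1\tUGGUGG\tesrp_selex",
               "Degenerate\tURGUKG\tknown_rbp_set"), path)
  ms <- read_motifs(path)
  expect_s3_class(ms, "motif_set")
  expect_equal(nrow(ms), 2L)
  expect_equal(ms$pattern[1], "UGGUGG")
  expect_equal(nrow(esrp_motifs()), 12L)
  expect_true(all(grepl("UGG", esrp_motifs()$pattern)))
})

planted_region_sets <- function(n_reg = 30, n_ctl = 120, rate = 3, seed = 99) {
  set.seed(seed)
  reg <- simulate_region_set(n_reg)
  ctl <- simulate_region_set(n_ctl)
  reg$upstream_intron <- vapply(reg$upstream_intron, function(s)
    plant_motifs(s, "UGGUGG", rate)$seq, character(1), USE.NAMES = FALSE)
  list(reg = reg, ctl = ctl)
}

test_that("enrich flags a planted motif in the planted region only", {
  sets <- planted_region_sets()
  res <- enrich(list(silenced = sets$reg), sets$ctl,
                motif_set(c("Esrp1", "CtrlMotif"), c("UGGUGG", "ACGCGA")))
  hit <- res[res$motif == "Esrp1" & res$region == "upstream_intron", ]
  expect_true(hit$enriched)
  expect_true(hit$fdr_by_nt < 0.05 && hit$p_by_seq < 0.01)
  other <- res[!(res$motif == "Esrp1" & res$region == "upstream_intron"), ]
  expect_false(any(other$enriched))
  # by-NT table margins: a + b = scannable positions of the regulated set
  expect_equal(hit$a + hit$b, sum(pmax(0, nchar(sets$reg$upstream_intron) - 5)))
})

test_that("enrich handles degenerate inputs per contract", {
  sets <- planted_region_sets(n_reg = 10, n_ctl = 10, rate = 0)
  # a motif absent everywhere scores p = 1 in both modes
  res <- enrich(list(silenced = sets$reg), sets$ctl,
                motif_set("none", "ACGCGACGCA"))
  expect_true(all(res$p_by_nt == 1))
  expect_true(all(res$p_by_seq == 1))
  expect_false(any(res$enriched))
  # regulated identical to control -> nothing enriched
  res2 <- enrich(list(silenced = sets$ctl), sets$ctl, esrp_motifs())
  expect_false(any(res2$enriched))
  # empty sets are configuration errors
  expect_error(enrich(list(silenced = sets$reg[0, ]), sets$ctl,
                      esrp_motifs()), "empty")
  expect_error(enrich(list(silenced = sets$reg), sets$ctl[0, ],
                      esrp_motifs()), "empty")
})

test_that("coverage counting mode builds nucleotide-based tables", {
  sets <- planted_region_sets(n_reg = 15, n_ctl = 30)
  res <- enrich(list(silenced = sets$reg), sets$ctl, motif_set("m", "UGGUGG"),
                enrichment_config(counting = "coverage"))
  expect_identical(attr(res, "counting"), "coverage")
  row <- res[res$region == "upstream_intron", ]
  expect_equal(row$a + row$b, sum(nchar(sets$reg$upstream_intron)))
  # covered nucleotides match the naive coverage oracle
  expect_equal(row$a, sum(vapply(sets$reg$upstream_intron, function(s)
    sum(naive_coverage(s, "UGGUGG")), numeric(1))))
})
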