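# Independent brute-force oracles and small fixture builders used across
# the test files.  These deliberately avoid the package's own code paths
# (and Biostrings matching) so they can serve as references.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U"))

# Sliding-window motif matcher; N (or any non-ACGU) in the sequence
# matches nothing.
naive_match_starts <- function(seq, pattern) {
  k <- nchar(pattern)
  L <- nchar(seq)
  if (L < k) return(integer(0))
  sc <- strsplit(seq, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  hits <- integer(0)
  for (s in seq_len(L - k + 1)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      base <- sc[s + j - 1]
      if (!base %in% c("A", "C", "G", "U") ||
          !base %in% IUPAC_SETS[[pc[j]]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

naive_count <- function(seq, pattern, mode = "by_nt") {
  n <- length(naive_match_starts(seq, pattern))
  if (mode == "by_seq") min(n, 1L) else n
}

naive_coverage <- function(seq, patterns) {
  L <- nchar(seq)
  cov <- integer(L)
  for (p in patterns) {
    k <- nchar(p)
    for (s in naive_match_starts(seq, p)) cov[s:(s + k - 1)] <- 1L
  }
  cov
}

# Right-tail Fisher p by explicit enumeration of all tables with the same
# margins, probabilities from the hypergeometric mass written out with
# binomial coefficients.
fisher_enum <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  logp <- lchoose(r1, xs) + lchoose(n - r1, c1 - xs) - lchoose(n, c1)
  sum(exp(logp[xs >= a]))
}

# Step-up BH by hand: p * m / rank on the sorted values, cumulative
# minimum from the largest, mapped back to the input order.
bh_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

random_rna_seq <- function(n, freqs = c(A = .25, C = .25, G = .25, U = .25)) {
  paste(sample(names(freqs), n, replace = TRUE, prob = freqs), collapse = "")
}

# Build a one-event toy dataset: a single chromosome holding
# upE | upI | cassette | dnI | dnE, written for the requested strand
# (minus-strand loci are stored reverse-complemented so that the supplied
# segment strings are the transcript-orientation RNA).  Returns the
# genome (named character), the events data frame and the segment
# strings.
toy_event <- function(upE, upI, cas, dnI, dnE, strand = "+",
                      event_id = "ev1", pad = 5) {
  rna <- c(upE = upE, upI = upI, cas = cas, dnI = dnI, dnE = dnE)
  locus_dna <- chartr("U", "T", paste0(upE, upI, cas, dnI, dnE))
  if (strand == "-") {
    locus_dna <- paste(rev(strsplit(chartr("ACGT", "TGCA", locus_dna),
                                    "")[[1]]), collapse = "")
  }
  chrom <- paste0(strrep("N", pad), locus_dna, strrep("N", pad))
  seg <- nchar(rna)
  if (strand == "+") {
    bounds <- unname(pad + cumsum(c(0, seg)))
    coord <- c(upstream_start = bounds[1], upstream_end = bounds[2],
               exon_start = bounds[3], exon_end = bounds[4],
               downstream_start = bounds[5], downstream_end = bounds[6])
  } else {
    bounds <- unname(pad + cumsum(c(0, rev(seg))))
    coord <- c(upstream_start = bounds[5], upstream_end = bounds[6],
               exon_start = bounds[3], exon_end = bounds[4],
               downstream_start = bounds[1], downstream_end = bounds[2])
  }
  events <- data.frame(event_id = event_id, gene_id = "g1", chrom = "chrT",
                       strand = strand, t(coord), p_value = 0.5, fdr = 0.5,
                       stringsAsFactors = FALSE)
  events$psi <- I(list(list(WT = c(0.5, 0.5), KO = c(0.5, 0.5))))
  attr(events, "groups") <- c("WT", "KO")
  list(genome = c(chrT = chrom), events = events, rna = rna)
}

# Minimal events data frame with given per-group PSI replicate lists and
# fdr values (no genome attached).
make_events <- function(psi_list, fdr, gene_id = NULL) {
  n <- length(psi_list)
  if (is.null(gene_id)) gene_id <- sprintf("g%d", seq_len(n))
  ev <- data.frame(event_id = sprintf("e%d", seq_len(n)), gene_id = gene_id,
                   chrom = "chr1", strand = "+",
                   upstream_start = 0, upstream_end = 10,
                   exon_start = 20, exon_end = 30,
                   downstream_start = 40, downstream_end = 50,
                   p_value = fdr, fdr = fdr, stringsAsFactors = FALSE)
  ev$psi <- I(psi_list)
  attr(ev, "groups") <- names(psi_list[[1]])
  ev
}
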