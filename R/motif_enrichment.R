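# Motif enrichment: dual counting modes (by-NT / by-Sequence), right-sided
# Fisher exact test, per-region Benjamini-Hochberg correction, and k-mer
# enumeration.

#' Construct a motif set
#'
#' A motif set is a data frame of named RNA-alphabet motifs.  Patterns may
#' use IUPAC degeneracy codes; `N` in a *scanned sequence* never matches
#' any motif position.
#'
#' @param name Character vector of motif names.
#' @param pattern Character vector of RNA patterns (same length).
#' @param source Provenance label(s): e.g. `"known_rbp_set"`,
#'   `"kmer_enumeration"`, `"esrp_selex"`.
#' @return A data frame of class `"motif_set"` with columns `name`,
#'   `pattern`, `source`.
#' @export
motif_set <- function(name, pattern, source = "known_rbp_set") {
  stopifnot(length(name) == length(pattern))
  .check_rna_pattern(pattern)
  out <- data.frame(name = as.character(name), pattern = as.character(pattern),
                    source = rep_len(as.character(source), length(name)),
                    stringsAsFactors = FALSE)
  class(out) <- c("motif_set", "data.frame")
  out
}

#' Read a motif definition file
#'
#' Reads a TSV with columns `name`, `pattern` and optionally `source`.
#'
#' @param path Path to the motif TSV.
#' @return A [motif_set()].
#' @export
read_motifs <- function(path) {
  if (!file.exists(path)) .stopf("motif file not found: %s", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("name", "pattern") %in% names(tab)))
    .stopf("motif file must have columns 'name' and 'pattern'")
  src <- if ("source" %in% names(tab)) tab$source else "known_rbp_set"
  motif_set(tab$name, toupper(tab$pattern), src)
}

#' Default GU-rich RNA-map motif panel
#'
#' A stand-in panel of twelve GU-rich, UGG-containing 6-mers representing
#' the high-affinity Esrp1 binding sites selected in vitro.  Only three of
#' the published top twelve SELEX-derived 6-mers are named in print
#' (UGGUGG, GGUGGU, GUGGUG); the remaining nine entries here are
#' synthetic stand-ins sharing the documented UGG-core/GU-rich character
#' and are *not* the experimentally ranked list.  Supply your own
#' [motif_set()] wherever the exact panel matters.
#'
#' @return A [motif_set()] of twelve 6-mers with source `"esrp_selex"` for
#'   the three published motifs and `"esrp_selex_standin"` for the rest.
#' @export
esrp_motifs <- function() {
  published <- c("UGGUGG", "GGUGGU", "GUGGUG")
  standin <- c("UUGGUG", "UGGUGU", "GUUGGU", "UGGUUG", "GGUUGG",
               "UGUGGU", "GUGGUU", "UGGGUG", "AUGGUG")
  motif_set(c(published, standin), c(published, standin),
            c(rep("esrp_selex", 3L), rep("esrp_selex_standin", 9L)))
}

#' Count motif occurrences in a sequence
#'
#' `by_nt` counts every matching start position, including overlapping
#' matches; `by_seq` records presence/absence (0 or 1).  A motif longer
#' than the sequence yields 0.
#'
#' @param seq RNA sequence (single string; `N` matches nothing).
#' @param motif Motif pattern string (IUPAC RNA codes allowed).
#' @param mode `"by_nt"` or `"by_seq"`.
#' @return Integer count.
#' @export
count_occurrences <- function(seq, motif, mode = c("by_nt", "by_seq")) {
  mode <- match.arg(mode)
  stopifnot(is.character(seq), length(seq) == 1L)
  .check_rna_pattern(motif)
  n <- .count_hits(seq, motif)
  if (mode == "by_seq") min(n, 1L) else n
}

#' Right-sided Fisher exact test for a 2x2 table
#'
#' Computes the right-tail hypergeometric probability P(X >= a) for the
#' table `[[a, b], [c, d]]` with fixed margins, i.e. the one-sided Fisher
#' exact p-value for enrichment of the top-left cell.  Vectorised over the
#' four counts.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @return P(X >= a) under the fixed-margin hypergeometric null.
#' @export
fisher_right <- function(a, b, c, d) {
  if (!.is_count(a) || !.is_count(b) || !.is_count(c) || !.is_count(d))
    .stopf("all four counts must be non-negative integers")
  stats::phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjusted p-values (monotone, capped at 1).  Intended to
#' be applied within each region family separately.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  .check_probability(pvalues)
  stats::p.adjust(pvalues, method = "BH")
}

#' Enumerate all RNA k-mers
#'
#' @param k Word length (k >= 1).
#' @return A [motif_set()] of all `4^k` literal k-mers in lexicographic
#'   order (A < C < G < U), with source `"kmer_enumeration"`.
#' @export
enumerate_kmers <- function(k) {
  stopifnot(length(k) == 1L, k >= 1, k == floor(k))
  bases <- c("A", "C", "G", "U")
  grid <- expand.grid(rep(list(bases), k), stringsAsFactors = FALSE)
  kmers <- sort(do.call(paste0, grid))
  motif_set(kmers, kmers, "kmer_enumeration")
}

#' Enrichment configuration
#'
#' @param counting How the by-NT contingency table is built:
#'   `"positions"` (default) uses occurrence counts versus remaining
#'   scannable start positions (positions = sum of
#'   `max(0, len(seq) - len(motif) + 1)`); `"coverage"` uses
#'   motif-covered nucleotides versus uncovered nucleotides.
#' @param fdr_threshold Enrichment requires by-NT BH FDR below this value.
#' @param p_seq_threshold ... and a raw by-Sequence p-value below this one.
#' @return A named list of class `"enrichment_config"`.
#' @export
enrichment_config <- function(counting = c("positions", "coverage"),
                              fdr_threshold = 0.05, p_seq_threshold = 0.01) {
  counting <- match.arg(counting)
  stopifnot(fdr_threshold > 0, fdr_threshold <= 1,
            p_seq_threshold > 0, p_seq_threshold <= 1)
  structure(list(counting = counting, fdr_threshold = fdr_threshold,
                 p_seq_threshold = p_seq_threshold),
            class = "enrichment_config")
}

.covered_nt <- function(seqs, pattern) {
  total <- 0L
  for (s in seqs) {
    st <- .match_starts(s, pattern)
    if (!length(st)) next
    k <- nchar(pattern)
    L <- nchar(s)
    d <- numeric(L + 1L)
    d[st] <- d[st] + 1
    d[st + k] <- d[st + k] - 1
    total <- total + sum(cumsum(d[seq_len(L)]) > 0)
  }
  total
}

#' Region-wise motif enrichment in regulated versus control events
#'
#' For every motif, scanned region (exon body, upstream intron, downstream
#' intron) and regulation direction, builds two 2x2 tables against the
#' control set and tests enrichment with a right-sided Fisher exact test:
#' the by-NT table from (possibly overlapping) occurrence counts, and the
#' by-Sequence table from the number of sequences with at least one hit.
#' Benjamini-Hochberg correction is applied to the by-NT p-values across
#' motifs within each region (and direction) separately; by-Sequence
#' p-values are reported unadjusted.  A motif is flagged `enriched` when
#' its by-NT FDR is below 5\% and its by-Sequence p-value below 0.01
#' (configurable).
#'
#' @param regulated Either a regions data frame from [extract_regions()]
#'   (a single direction) or a named list of such data frames, e.g.
#'   `list(enhanced = ..., silenced = ...)`.
#' @param control Regions data frame for the control events.
#' @param motifs A [motif_set()], or character vector of patterns.
#' @param config An [enrichment_config()].
#' @return A data frame with one row per motif x region x direction:
#'   `motif`, `pattern`, `region`, `direction`, counts `a`, `b`, `c`, `d`
#'   (by-NT table), `p_by_nt`, `fdr_by_nt`, `p_by_seq`, `enriched`.  The
#'   counting mode is recorded in the `"counting"` attribute.
#' @export
enrich <- function(regulated, control, motifs, config = enrichment_config()) {
  if (is.data.frame(regulated)) regulated <- list(regulated = regulated)
  if (!length(regulated) || any(!vapply(regulated, nrow, integer(1))))
    .stopf("the regulated event set is empty")
  if (is.null(control) || !nrow(control))
    .stopf("the control event set is empty")
  pats <- .motif_patterns(motifs)
  regions <- c("exon_body", "upstream_intron", "downstream_intron")
  res <- list()
  for (dir in names(regulated)) {
    reg <- regulated[[dir]]
    for (region in regions) {
      seqs_r <- reg[[region]]
      seqs_c <- control[[region]]
      seqs_r[is.na(seqs_r)] <- ""
      seqs_c[is.na(seqs_c)] <- ""
      rows <- lapply(seq_along(pats), function(j) {
        pat <- pats[[j]]
        k <- nchar(pat)
        hits_r <- .count_hits(seqs_r, pat)
        hits_c <- .count_hits(seqs_c, pat)
        if (config$counting == "positions") {
          a <- sum(hits_r)
          b <- sum(pmax(0L, nchar(seqs_r) - k + 1L)) - a
          cc <- sum(hits_c)
          d <- sum(pmax(0L, nchar(seqs_c) - k + 1L)) - cc
        } else {
          a <- .covered_nt(seqs_r, pat)
          b <- sum(nchar(seqs_r)) - a
          cc <- .covered_nt(seqs_c, pat)
          d <- sum(nchar(seqs_c)) - cc
        }
        a2 <- sum(hits_r > 0L)
        c2 <- sum(hits_c > 0L)
        data.frame(
          motif = names(pats)[j], pattern = pat, region = region,
          direction = dir, a = a, b = b, c = cc, d = d,
          p_by_nt = fisher_right(a, b, cc, d),
          p_by_seq = fisher_right(a2, length(seqs_r) - a2,
                                  c2, length(seqs_c) - c2),
          stringsAsFactors = FALSE)
      })
      block <- do.call(rbind, rows)
      block$fdr_by_nt <- bh_adjust(block$p_by_nt)
      res[[length(res) + 1L]] <- block
    }
  }
  out <- do.call(rbind, res)
  out$enriched <- out$fdr_by_nt < config$fdr_threshold &
    out$p_by_seq < config$p_seq_threshold
  out <- out[, c("motif", "pattern", "region", "direction",
                 "a", "b", "c", "d", "p_by_nt", "fdr_by_nt",
                 "p_by_seq", "enriched")]
  rownames(out) <- NULL
  attr(out, "counting") <- config$counting
  out
}

#' Write enrichment results
#'
#' @param results Data frame from [enrich()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
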