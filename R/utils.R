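# Internal helpers shared across modules.

# IUPAC RNA codes accepted in motif patterns.
.IUPAC_RNA <- c("A", "C", "G", "U", "R", "Y", "S", "W", "K", "M",
                "B", "D", "H", "V", "N")

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.is_count <- function(x) {
  is.numeric(x) && length(x) >= 1L && all(is.finite(x)) &&
    all(x >= 0) && all(x == floor(x))
}

.check_probability <- function(p, what = "p-value") {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    .stopf("%s values must lie in [0, 1]", what)
  invisible(p)
}

# Validate a character vector of RNA motif patterns (IUPAC codes allowed).
.check_rna_pattern <- function(pattern) {
  if (!is.character(pattern) || anyNA(pattern) || any(!nzchar(pattern)))
    .stopf("motif patterns must be non-empty strings")
  letters <- strsplit(pattern, "", fixed = TRUE)
  bad <- vapply(letters, function(x) any(!x %in% .IUPAC_RNA), logical(1))
  if (any(bad))
    .stopf("motif pattern '%s' contains characters outside the IUPAC RNA alphabet",
           pattern[which(bad)[1L]])
  invisible(pattern)
}

# DNA genomic substring -> RNA in transcript orientation.
# `x` is a chromosome as a plain character string (uppercase DNA),
# interval is 0-based half-open genomic, strand "+"/"-".
.region_rna <- function(x, start, end, strand) {
  if (end <= start) return("")
  s <- substr(x, start + 1L, end)
  if (strand == "-")
    s <- intToUtf8(rev(utf8ToInt(
      chartr("ACGTURYSWKMBDHVacgturyswkmbdhv",
             "TGCAAYRSWMKVHDBtgcaayrswmkvhdb", s))))
  chartr("Tt", "Uu", s)
}

# Count motif occurrences (overlapping start positions) for each sequence.
# Patterns may carry IUPAC degeneracy; non-ACGU letters in the subject
# (e.g. N) never match.
.count_hits <- function(seqs, pattern) {
  k <- nchar(pattern)
  out <- integer(length(seqs))
  ok <- !is.na(seqs) & nchar(seqs) >= k
  if (any(ok)) {
    subj <- Biostrings::RNAStringSet(seqs[ok])
    out[ok] <- Biostrings::vcountPattern(pattern, subj, fixed = "subject")
  }
  out
}

# Start positions (1-based) of motif matches in a single sequence.
.match_starts <- function(seq, pattern) {
  if (is.na(seq) || nchar(seq) < nchar(pattern)) return(integer(0))
  Biostrings::start(Biostrings::matchPattern(
    pattern, Biostrings::RNAString(seq), fixed = "subject"))
}

# Extract the pattern column from a motif_set, data.frame or character vector.
.motif_patterns <- function(motifs) {
  if (is.character(motifs)) {
    pats <- motifs
    if (is.null(names(pats)) || any(!nzchar(names(pats)))) names(pats) <- pats
  } else if (is.data.frame(motifs) && "pattern" %in% names(motifs)) {
    pats <- motifs$pattern
    names(pats) <- if ("name" %in% names(motifs)) motifs$name else pats
  } else {
    .stopf("`motifs` must be a motif_set data.frame or a character vector of patterns")
  }
  .check_rna_pattern(pats)
  pats
}

# Random RNA sequence of length n with the given base frequencies.
.random_rna <- function(n, base_freqs) {
  if (n <= 0L) return("")
  paste(sample(names(base_freqs), n, replace = TRUE, prob = base_freqs),
        collapse = "")
}
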