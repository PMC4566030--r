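# Strand-aware extraction of scanned sequences around cassette exons:
# exon body, 250-nt flanking intronic windows with splice-site exclusions,
# and the five aligned segments used by the RNA map.

#' Read a genome FASTA
#'
#' Loads a genome into a named `DNAStringSet`.  Soft-masked (lowercase)
#' bases are uppercased; ambiguity codes are retained (they never match a
#' motif during scanning).
#'
#' @param path Path to a FASTA file.
#' @return A `Biostrings::DNAStringSet` named by chromosome.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) .stopf("genome FASTA not found: %s", path)
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  Biostrings::DNAStringSet(toupper(g))
}

#' Region-extraction configuration
#'
#' @param intron_window Length (nt) of the intronic window taken adjacent
#'   to the cassette exon.
#' @param three_ss_exclusion Intronic nucleotides excluded at each 3'
#'   splice site (intron end abutting a downstream exon).
#' @param five_ss_exclusion Intronic nucleotides excluded at each 5' splice
#'   site (intron start following an exon).
#' @param apply_exclusions Mask splice-site nucleotides out of the scanned
#'   window (`TRUE`, default).  With `FALSE` the raw window is returned.
#' @param shift_exclusions If `TRUE`, the window is shifted away from the
#'   exon instead of masked, so the scanned length stays at
#'   `intron_window` where the intron allows.  Masking is the default
#'   interpretation.
#' @return A named list of class `"region_config"`.
#' @export
region_config <- function(intron_window = 250L, three_ss_exclusion = 20L,
                          five_ss_exclusion = 6L, apply_exclusions = TRUE,
                          shift_exclusions = FALSE) {
  stopifnot(intron_window > 0, three_ss_exclusion >= 0, five_ss_exclusion >= 0)
  structure(list(intron_window = as.integer(intron_window),
                 three_ss_exclusion = as.integer(three_ss_exclusion),
                 five_ss_exclusion = as.integer(five_ss_exclusion),
                 apply_exclusions = isTRUE(apply_exclusions),
                 shift_exclusions = isTRUE(shift_exclusions)),
            class = "region_config")
}

# Scanned sub-interval of the upstream intron, in transcript coordinates
# [0, L).  The window sits against the cassette exon (intron 3' end); the
# 3'ss exclusion removes the exon-proximal nucleotides and the 5'ss
# exclusion applies when the window reaches the upstream exon.
.upstream_scan_interval <- function(L, cfg) {
  if (cfg$shift_exclusions && cfg$apply_exclusions) {
    e <- L - cfg$three_ss_exclusion
    s <- max(e - cfg$intron_window, 0L)
    if (s < cfg$five_ss_exclusion) s <- min(cfg$five_ss_exclusion, e)
    return(c(max(s, 0L), max(e, 0L)))
  }
  s <- max(L - cfg$intron_window, 0L)
  e <- L
  if (cfg$apply_exclusions) {
    e <- L - cfg$three_ss_exclusion
    if (s < cfg$five_ss_exclusion) s <- cfg$five_ss_exclusion
  }
  c(s, e)
}

# Scanned sub-interval of the downstream intron (window at the intron 5'
# end, against the cassette exon).
.downstream_scan_interval <- function(L, cfg) {
  if (cfg$shift_exclusions && cfg$apply_exclusions) {
    s <- min(cfg$five_ss_exclusion, L)
    e <- min(s + cfg$intron_window, L - cfg$three_ss_exclusion)
    return(c(s, max(e, s)))
  }
  s <- 0L
  e <- min(cfg$intron_window, L)
  if (cfg$apply_exclusions) {
    s <- cfg$five_ss_exclusion
    if (e > L - cfg$three_ss_exclusion) e <- L - cfg$three_ss_exclusion
  }
  c(s, e)
}

# Events data frame -> list of plain per-event lists (cheap row access).
.event_rows <- function(events) {
  cols <- c("event_id", "chrom", "strand", "upstream_start", "upstream_end",
            "exon_start", "exon_end", "downstream_start", "downstream_end")
  vals <- lapply(cols, function(cl) events[[cl]])
  names(vals) <- cols
  lapply(seq_len(nrow(events)), function(i) lapply(vals, `[[`, i))
}

# Genome (DNAStringSet or named character) -> named character vector of
# uppercase chromosome strings.
.genome_chars <- function(genome) {
  if (is.character(genome)) return(toupper(genome))
  toupper(as.character(genome))
}

# Transcript-orientation building blocks for one event.  Returns RNA
# strings (5'->3' in transcript direction) for the two flanking exons, the
# cassette exon and the two full introns, plus intron lengths.  `genome`
# is a named character vector of chromosome strings (see .genome_chars).
.event_transcript_parts <- function(event, genome) {
  chrom <- event$chrom
  if (!chrom %in% names(genome))
    .stopf("event '%s': chromosome '%s' not in genome", event$event_id, chrom)
  x <- genome[[chrom]]
  len <- nchar(x)
  iv <- rbind(c(event$upstream_start, event$upstream_end),
              c(event$exon_start, event$exon_end),
              c(event$downstream_start, event$downstream_end))
  if (any(iv[, 1L] < 0) || any(iv[, 2L] > len) || any(iv[, 1L] > iv[, 2L]))
    .stopf("event '%s': interval outside chromosome bounds [0, %d)",
           event$event_id, len)
  strand <- event$strand
  if (strand == "+") {
    up_intron <- c(event$upstream_end, event$exon_start)
    dn_intron <- c(event$exon_end, event$downstream_start)
  } else {
    # transcript-upstream exon lies at higher genomic coordinates
    up_intron <- c(event$exon_end, event$upstream_start)
    dn_intron <- c(event$downstream_end, event$exon_start)
  }
  if (up_intron[2L] < up_intron[1L] || dn_intron[2L] < dn_intron[1L])
    .stopf("event '%s': intron with negative length (check strand and exon order)",
           event$event_id)
  list(
    upstream_exon = .region_rna(x, event$upstream_start, event$upstream_end, strand),
    cassette_exon = .region_rna(x, event$exon_start, event$exon_end, strand),
    downstream_exon = .region_rna(x, event$downstream_start, event$downstream_end, strand),
    upstream_intron = .region_rna(x, up_intron[1L], up_intron[2L], strand),
    downstream_intron = .region_rna(x, dn_intron[1L], dn_intron[2L], strand),
    up_intron_len = up_intron[2L] - up_intron[1L],
    dn_intron_len = dn_intron[2L] - dn_intron[1L])
}

#' Extract scanned regions for motif enrichment
#'
#' For every event, returns the cassette exon body plus the flanking
#' intronic windows taken adjacent to the exon (default 250 nt), with the
#' splice-site nucleotides masked out of the scanned window: 20 nt inside
#' each 3' splice site and 6 nt inside each 5' splice site, wherever the
#' window covers them.  Windows are truncated on introns shorter than the
#' window; an intron shorter than the exclusions yields an empty region
#' with its truncation flag set.  All sequences are RNA, 5'->3' in
#' transcript direction (minus-strand events are reverse-complemented).
#'
#' @param events Event data frame (see [read_se_table()]).
#' @param genome A `DNAStringSet` from [read_genome()].
#' @param config A [region_config()].
#' @return A data frame with columns `event_id`, `upstream_intron`,
#'   `exon_body`, `downstream_intron`, `upstream_exon`, `downstream_exon`
#'   (RNA strings) and logical `upstream_truncated`, `downstream_truncated`.
#' @export
extract_regions <- function(events, genome, config = region_config()) {
  cfg <- config
  n <- nrow(events)
  masked <- cfg$apply_exclusions && !cfg$shift_exclusions
  full_up <- cfg$intron_window - if (masked) cfg$three_ss_exclusion else 0L
  full_dn <- cfg$intron_window - if (masked) cfg$five_ss_exclusion else 0L
  ev <- .event_rows(events)
  chars <- .genome_chars(genome)
  up_seq <- dn_seq <- exon <- upE <- dnE <- character(n)
  for (i in seq_len(n)) {
    parts <- .event_transcript_parts(ev[[i]], chars)
    up <- .upstream_scan_interval(parts$up_intron_len, cfg)
    dn <- .downstream_scan_interval(parts$dn_intron_len, cfg)
    up_seq[i] <- if (up[2L] > up[1L])
      substr(parts$upstream_intron, up[1L] + 1L, up[2L]) else ""
    dn_seq[i] <- if (dn[2L] > dn[1L])
      substr(parts$downstream_intron, dn[1L] + 1L, dn[2L]) else ""
    exon[i] <- parts$cassette_exon
    upE[i] <- parts$upstream_exon
    dnE[i] <- parts$downstream_exon
  }
  out <- data.frame(
    event_id = events$event_id,
    upstream_intron = up_seq,
    exon_body = exon,
    downstream_intron = dn_seq,
    upstream_exon = upE,
    downstream_exon = dnE,
    upstream_truncated = nchar(up_seq) < full_up,
    downstream_truncated = nchar(dn_seq) < full_dn,
    stringsAsFactors = FALSE)
  attr(out, "config") <- cfg
  out
}

#' Extract the five aligned RNA-map segments
#'
#' Returns, for every event, the five ordered segments scanned by the RNA
#' map: upstream exon, upstream intron window (default 250 nt, adjacent to
#' the cassette exon), cassette exon, downstream intron window, downstream
#' exon.  No splice-site exclusions are applied; intron windows are
#' truncated to the available intron length.  Sequences are RNA, 5'->3' in
#' transcript direction.
#'
#' @inheritParams extract_regions
#' @return A data frame with columns `event_id`, `upstream_exon`,
#'   `upstream_intron`, `cassette_exon`, `downstream_intron`,
#'   `downstream_exon`, and logical truncation flags for the two introns.
#' @export
extract_map_segments <- function(events, genome, config = region_config()) {
  cfg <- config
  W <- cfg$intron_window
  n <- nrow(events)
  ev <- .event_rows(events)
  chars <- .genome_chars(genome)
  up_seq <- dn_seq <- exon <- upE <- dnE <- character(n)
  Lu <- Ld <- integer(n)
  for (i in seq_len(n)) {
    parts <- .event_transcript_parts(ev[[i]], chars)
    Lu[i] <- parts$up_intron_len
    Ld[i] <- parts$dn_intron_len
    up_seq[i] <- if (Lu[i] > 0L)
      substr(parts$upstream_intron, max(Lu[i] - W, 0L) + 1L, Lu[i]) else ""
    dn_seq[i] <- if (Ld[i] > 0L)
      substr(parts$downstream_intron, 1L, min(W, Ld[i])) else ""
    exon[i] <- parts$cassette_exon
    upE[i] <- parts$upstream_exon
    dnE[i] <- parts$downstream_exon
  }
  out <- data.frame(
    event_id = events$event_id,
    upstream_exon = upE,
    upstream_intron = up_seq,
    cassette_exon = exon,
    downstream_intron = dn_seq,
    downstream_exon = dnE,
    upstream_truncated = Lu < W,
    downstream_truncated = Ld < W,
    stringsAsFactors = FALSE)
  attr(out, "config") <- cfg
  out
}

#' Export region sequences as FASTA
#'
#' Writes the extracted region sequences to a FASTA file with provenance
#' headers of the form `eventid|region`.
#'
#' @param regions Data frame from [extract_regions()] or
#'   [extract_map_segments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
regions_to_fasta <- function(regions, path) {
  seq_cols <- intersect(c("upstream_exon", "upstream_intron", "exon_body",
                          "cassette_exon", "downstream_intron",
                          "downstream_exon"), names(regions))
  seqs <- character(0)
  for (col in seq_cols) {
    s <- regions[[col]]
    names(s) <- paste(regions$event_id, col, sep = "|")
    seqs <- c(seqs, s[nzchar(s)])
  }
  Biostrings::writeXStringSet(Biostrings::RNAStringSet(seqs), path)
  invisible(path)
}
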