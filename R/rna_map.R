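# Positional RNA map: motif coverage tracks, sliding-window scores, and
# aligned mean profiles across the five segments of each event set.

#' Per-nucleotide motif coverage
#'
#' Marks every nucleotide lying inside at least one motif occurrence
#' (occurrences may overlap, across motifs or within one motif).
#'
#' @param seq RNA sequence (single string).
#' @param motifs A [motif_set()] or character vector of patterns.
#' @return Integer 0/1 vector of length `nchar(seq)`.
#' @export
coverage_track <- function(seq, motifs) {
  stopifnot(is.character(seq), length(seq) == 1L)
  pats <- .motif_patterns(motifs)
  L <- nchar(seq)
  if (L == 0L) return(integer(0))
  d <- numeric(L + 1L)
  for (pat in pats) {
    k <- nchar(pat)
    st <- .match_starts(seq, pat)
    if (!length(st)) next
    d[st] <- d[st] + 1
    d[st + k] <- d[st + k] - 1
  }
  as.integer(cumsum(d[seq_len(L)]) > 0)
}

#' Sliding-window motif-coverage scores
#'
#' Slides a fixed window (default 50 nt, 1-nt step) across the sequence
#' and scores each full window by the fraction of its nucleotides covered
#' by any motif occurrence.  Sequences shorter than one window yield an
#' empty result.
#'
#' @param seq RNA sequence (single string).
#' @param motifs A [motif_set()] or character vector of patterns.
#' @param window Window length in nt.
#' @param step Step between window starts in nt.
#' @return A data frame with columns `offset` (0-based window start) and
#'   `score` in \[0, 1\].
#' @export
window_scores <- function(seq, motifs, window = 50L, step = 1L) {
  stopifnot(window >= 1L, step >= 1L)
  pats <- .motif_patterns(motifs)
  if (window < max(nchar(pats)))
    .warnf("window (%d nt) is shorter than the longest motif (%d nt)",
           window, max(nchar(pats)))
  L <- nchar(seq)
  if (is.na(L) || L < window)
    return(data.frame(offset = integer(0), score = numeric(0)))
  cov <- coverage_track(seq, pats)
  cs <- c(0, cumsum(cov))
  starts <- seq.int(0L, L - window, by = step)
  data.frame(offset = starts,
             score = (cs[starts + window + 1L] - cs[starts + 1L]) / window)
}

#' RNA-map configuration
#'
#' @param window Sliding-window length (nt).
#' @param step Window step (nt).
#' @param anchor_windows For exon segments, how many windows to keep from
#'   each exon edge (edge-anchored alignment; positions beyond a given
#'   exon simply contribute nothing).
#' @return A named list of class `"map_config"`.
#' @export
map_config <- function(window = 50L, step = 1L, anchor_windows = 100L) {
  stopifnot(window >= 1L, step >= 1L, anchor_windows >= 1L)
  structure(list(window = as.integer(window), step = as.integer(step),
                 anchor_windows = as.integer(anchor_windows)),
            class = "map_config")
}

.MAP_SEGMENTS <- c("upstream_exon", "upstream_intron", "cassette_exon",
                   "downstream_intron", "downstream_exon")

# Coverage vectors for a character vector of sequences, using one
# vmatchPattern call per motif.
.coverage_list <- function(seqs, pats) {
  n <- length(seqs)
  lens <- nchar(seqs)
  diffs <- lapply(lens, function(L) numeric(L + 1L))
  subj <- Biostrings::RNAStringSet(ifelse(is.na(seqs), "", seqs))
  for (pat in pats) {
    k <- nchar(pat)
    m <- Biostrings::vmatchPattern(pat, subj, fixed = "subject")
    st <- Biostrings::startIndex(m)
    for (i in seq_len(n)) {
      s <- st[[i]]
      if (is.null(s) || !length(s)) next
      s <- s[s >= 1L & s + k - 1L <= lens[i]]
      if (!length(s)) next
      d <- diffs[[i]]
      d[s] <- d[s] + 1
      d[s + k] <- d[s + k] - 1
      diffs[[i]] <- d
    }
  }
  lapply(seq_len(n), function(i) {
    L <- lens[i]
    if (L == 0L) integer(0) else as.integer(cumsum(diffs[[i]][seq_len(L)]) > 0)
  })
}

# Aligned positions for the full windows of one segment.  Intron windows
# are anchored at the exon-proximal boundary; exon windows are anchored at
# both edges up to `anchor` windows per edge.  Returns NULL when no full
# window fits.
.aligned_positions <- function(L, segment, window, step, anchor) {
  if (L < window) return(NULL)
  starts <- seq.int(0L, L - window, by = step)
  if (segment == "upstream_intron") {
    # anchored at the intron 3' end: position of the window start relative
    # to the exon boundary (-window = window flush against the exon)
    return(data.frame(start = starts, position = starts - L))
  }
  if (segment == "downstream_intron") {
    return(data.frame(start = starts, position = starts))
  }
  nw <- length(starts)
  keep5 <- seq_len(min(anchor, nw))
  keep3 <- seq.int(nw, by = -1L, length.out = min(anchor, nw))
  rbind(
    data.frame(start = starts[keep5], position = starts[keep5]),
    data.frame(start = starts[keep3], position = starts[keep3] - L))
}

#' Build positional RNA-map profiles
#'
#' Computes, for each event set, the mean windowed motif-coverage score at
#' every aligned position of the five segments.  Intron segments are
#' aligned at the exon-proximal boundary (upstream intron positions are
#' negative offsets of the window start from the 3' splice site;
#' downstream intron positions count from the 5' splice site).  Exon
#' segments are aligned from both edges: non-negative positions count
#' windows from the segment 5' end, negative positions from its 3' end,
#' each up to `anchor_windows` windows.  Only windows fully inside a
#' segment are scored; the number of events contributing at each position
#' is reported.
#'
#' @param event_sets Named list mapping a set label (e.g. `enhanced`,
#'   `silenced`, `control`) to a character vector of event ids.
#' @param segments Data frame from [extract_map_segments()].
#' @param motifs A [motif_set()] or character vector of patterns (e.g.
#'   [esrp_motifs()]).
#' @param config A [map_config()].
#' @return A data frame with columns `event_set`, `segment` (ordered
#'   factor), `position`, `mean_score`, `n_events`.
#' @export
build_map <- function(event_sets, segments, motifs, config = map_config()) {
  if (!length(event_sets) || is.null(names(event_sets)))
    .stopf("`event_sets` must be a named list of event-id vectors")
  pats <- .motif_patterns(motifs)
  if (!length(pats)) .stopf("the motif set is empty")
  cfg <- config
  out <- list()
  for (label in names(event_sets)) {
    ids <- event_sets[[label]]
    sub <- segments[segments$event_id %in% ids, , drop = FALSE]
    if (!nrow(sub))
      .stopf("event set '%s' matches no rows of `segments`", label)
    for (segment in .MAP_SEGMENTS) {
      seqs <- sub[[segment]]
      covs <- .coverage_list(seqs, pats)
      pos_all <- list()
      score_all <- list()
      for (i in seq_along(seqs)) {
        L <- nchar(seqs[i])
        al <- .aligned_positions(L, segment, cfg$window, cfg$step,
                                 cfg$anchor_windows)
        if (is.null(al)) next
        cs <- c(0, cumsum(covs[[i]]))
        pos_all[[length(pos_all) + 1L]] <- al$position
        score_all[[length(score_all) + 1L]] <-
          (cs[al$start + cfg$window + 1L] - cs[al$start + 1L]) / cfg$window
      }
      if (!length(pos_all)) next
      pos <- unlist(pos_all)
      score <- unlist(score_all)
      sums <- rowsum(score, pos)
      counts <- rowsum(rep(1L, length(pos)), pos)
      upos <- as.integer(rownames(sums))
      out[[length(out) + 1L]] <- data.frame(
        event_set = label, segment = segment, position = upos,
        mean_score = as.numeric(sums) / as.numeric(counts),
        n_events = as.integer(counts), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$segment <- factor(res$segment, levels = .MAP_SEGMENTS)
  res <- res[order(res$event_set, res$segment, res$position), ]
  rownames(res) <- NULL
  attr(res, "config") <- cfg
  res
}

#' Plot RNA-map profiles
#'
#' Simple five-panel profile plot (one panel per segment), with one line
#' per event set.
#'
#' @param profile Data frame from [build_map()].
#' @param col Optional named vector of colours per event set.
#' @return Invisibly, `NULL`.  Draws on the current graphics device.
#' @export
plot_rna_map <- function(profile, col = NULL) {
  sets <- unique(profile$event_set)
  if (is.null(col))
    col <- stats::setNames(seq_along(sets) + 1L, sets)
  old <- graphics::par(mfrow = c(1, 5), mar = c(4, 3, 3, 1))
  on.exit(graphics::par(old))
  for (segment in levels(profile$segment)) {
    sub <- profile[profile$segment == segment, ]
    ylim <- c(0, max(sub$mean_score, 0.01))
    graphics::plot(NA, xlim = range(sub$position), ylim = ylim,
                   xlab = "position (nt)", ylab = "mean coverage",
                   main = gsub("_", " ", segment))
    for (s in sets) {
      ss <- sub[sub$event_set == s, ]
      graphics::lines(ss$position, ss$mean_score, col = col[[s]])
    }
  }
  invisible(NULL)
}

#' Write RNA-map profiles
#'
#' @param profile Data frame from [build_map()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_rna_map <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
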