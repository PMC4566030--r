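# Event I/O: parsing rMATS-style skipped-exon tables, PSI summaries and
# classification into enhanced / silenced / control sets.

#' Column dialect for rMATS-style skipped-exon tables
#'
#' Describes how the columns of a tab-delimited skipped-exon (SE) result
#' table map onto the fields used by [read_se_table()].  The default mirrors
#' the rMATS SE output: exon coordinates with 0-based starts and 1-based
#' ends (numerically identical to 0-based half-open intervals, so no shift
#' is applied), and per-group replicate inclusion levels as comma-separated
#' strings.
#'
#' @param columns Named list mapping internal field names to column names in
#'   the file.  Fields: `event_id`, `gene_id`, `chrom`, `strand`,
#'   `exon_start`, `exon_end`, `upstream_start`, `upstream_end`,
#'   `downstream_start`, `downstream_end`, `inc_level_1`, `inc_level_2`,
#'   `p_value`, `fdr`.
#' @param coord_system Either `"rmats"` (0-based start / 1-based end, read
#'   as-is into 0-based half-open) or `"one_based"` (fully 1-based closed
#'   intervals; starts are decremented on read).
#' @return A list of class `"se_dialect"`.
#' @export
se_dialect <- function(columns = list(), coord_system = c("rmats", "one_based")) {
  coord_system <- match.arg(coord_system)
  default <- list(
    event_id = "ID", gene_id = "GeneID", chrom = "chr", strand = "strand",
    exon_start = "exonStart_0base", exon_end = "exonEnd",
    upstream_start = "upstreamES", upstream_end = "upstreamEE",
    downstream_start = "downstreamES", downstream_end = "downstreamEE",
    inc_level_1 = "IncLevel1", inc_level_2 = "IncLevel2",
    p_value = "PValue", fdr = "FDR")
  default[names(columns)] <- columns
  structure(list(columns = default, coord_system = coord_system),
            class = "se_dialect")
}

.parse_psi <- function(x, row, column) {
  if (is.na(x) || !nzchar(x)) return(numeric(0))
  parts <- trimws(strsplit(x, ",", fixed = TRUE)[[1L]])
  vals <- suppressWarnings(as.numeric(parts))
  vals[parts %in% c("NA", "na", "")] <- NA_real_
  bad <- !is.na(vals) & (vals < 0 | vals > 1)
  if (any(is.na(vals) & !parts %in% c("NA", "na", "")))
    .stopf("row %d: cannot parse replicate PSI string '%s' in column %s",
           row, x, column)
  if (any(bad))
    .stopf("row %d: PSI value outside [0, 1] in column %s", row, column)
  vals[!is.na(vals)]
}

#' Read a skipped-exon result table
#'
#' Parses a tab-delimited rMATS-style SE table into an event data frame.
#' Replicate inclusion levels (PSI) are split on commas, `NA` replicates are
#' dropped, and coordinates are normalised to 0-based half-open intervals.
#' The upstream/downstream flanking exons are interpreted in transcript
#' orientation (as in rMATS output): on the minus strand the upstream exon
#' has the larger genomic coordinates.
#'
#' @param path Path to the table (header row required).
#' @param dialect A [se_dialect()] describing the column layout.
#' @param groups Character vector of two group labels; the first is the
#'   reference (wild-type) group used for the delta-PSI sign convention.
#' @return A data frame with one row per event: identifier and coordinate
#'   columns, `p_value`, `fdr`, and a list column `psi` holding per-group
#'   replicate PSI vectors.  Group labels are kept in the `"groups"`
#'   attribute.
#' @export
read_se_table <- function(path, dialect = se_dialect(), groups = c("WT", "KO")) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (length(groups) != 2L) .stopf("`groups` must name exactly two groups")
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  cols <- dialect$columns
  missing <- setdiff(unlist(cols), names(tab))
  if (length(missing))
    .stopf("missing mandatory column '%s' in %s", missing[1L], path)
  n <- nrow(tab)
  off <- if (dialect$coord_system == "one_based") 1L else 0L
  num <- function(field) as.numeric(tab[[cols[[field]]]])
  events <- data.frame(
    event_id = tab[[cols$event_id]],
    gene_id = tab[[cols$gene_id]],
    chrom = tab[[cols$chrom]],
    strand = tab[[cols$strand]],
    upstream_start = num("upstream_start") - off,
    upstream_end = num("upstream_end"),
    exon_start = num("exon_start") - off,
    exon_end = num("exon_end"),
    downstream_start = num("downstream_start") - off,
    downstream_end = num("downstream_end"),
    p_value = num("p_value"),
    fdr = num("fdr"),
    stringsAsFactors = FALSE)
  bad_strand <- which(!events$strand %in% c("+", "-"))
  if (length(bad_strand))
    .stopf("row %d: invalid strand '%s' (must be '+' or '-')",
           bad_strand[1L], events$strand[bad_strand[1L]])
  psi <- vector("list", n)
  for (i in seq_len(n)) {
    g1 <- .parse_psi(tab[[cols$inc_level_1]][i], i, cols$inc_level_1)
    g2 <- .parse_psi(tab[[cols$inc_level_2]][i], i, cols$inc_level_2)
    psi[[i]] <- stats::setNames(list(g1, g2), groups)
  }
  events$psi <- I(psi)
  attr(events, "groups") <- groups
  events
}

#' Per-group PSI summaries
#'
#' Computes the arithmetic mean replicate PSI and replicate count for each
#' group of each event.
#'
#' @param events Event data frame from [read_se_table()] or
#'   [simulate_dataset()].
#' @return A data frame with columns `event_id`, `group`, `mean_psi`,
#'   `n_reps`.
#' @export
summarize_groups <- function(events) {
  if (!nrow(events)) {
    return(data.frame(event_id = character(0), group = character(0),
                      mean_psi = numeric(0), n_reps = integer(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(events)), function(i) {
    psi <- events$psi[[i]]
    n <- vapply(psi, length, integer(1))
    if (any(n == 0L))
      .stopf("event '%s': group '%s' has no usable replicate PSI values",
             events$event_id[i], names(psi)[which(n == 0L)[1L]])
    data.frame(event_id = events$event_id[i], group = names(psi),
               mean_psi = vapply(psi, mean, numeric(1)), n_reps = n,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Classification thresholds
#'
#' Threshold set used by [classify_events()], pre-filled with the standard
#' values: regulated events at FDR < 5% and |delta PSI| >= 5% (inclusive);
#' control exons at FDR > 50%, every group-mean PSI strictly inside
#' (0.15, 0.85), and average gene FPKM > 5.0 in at least one group.
#'
#' @param fdr_regulated FDR ceiling for regulated (enhanced/silenced) calls.
#' @param min_abs_delta_psi Minimum |delta PSI| for regulated calls
#'   (inclusive).
#' @param fdr_control FDR floor for control calls (strict).
#' @param control_psi_range Open interval that every group-mean PSI of a
#'   control exon must fall inside.
#' @param control_min_fpkm Average-FPKM floor (strict, in at least one
#'   group) for the control exon's gene.
#' @return A named list of thresholds.
#' @export
classification_thresholds <- function(fdr_regulated = 0.05,
                                      min_abs_delta_psi = 0.05,
                                      fdr_control = 0.5,
                                      control_psi_range = c(0.15, 0.85),
                                      control_min_fpkm = 5.0) {
  stopifnot(fdr_regulated > 0, min_abs_delta_psi >= 0, fdr_control > 0,
            length(control_psi_range) == 2L,
            control_psi_range[1L] < control_psi_range[2L],
            control_min_fpkm >= 0)
  list(fdr_regulated = fdr_regulated,
       min_abs_delta_psi = min_abs_delta_psi,
       fdr_control = fdr_control,
       control_psi_range = control_psi_range,
       control_min_fpkm = control_min_fpkm)
}

#' Classify skipped-exon events
#'
#' Partitions events into `enhanced`, `silenced`, `control` and
#' `unclassified` labels.  The delta-PSI sign convention is
#' mean PSI(reference group) minus mean PSI(comparison group), so exons
#' whose inclusion the regulator promotes (high PSI in wild type) are
#' `enhanced` with positive delta PSI.  Control exons additionally require
#' expression support: the event's gene must have average FPKM above the
#' control floor in at least one group.  Events whose gene is absent from
#' the expression table are never control (a warning reports how many).
#'
#' @param events Event data frame (see [read_se_table()]).
#' @param expression Optional expression data frame with columns `gene_id`,
#'   `fpkm_1`, `fpkm_2` (see [read_expression_table()]).  Without it no
#'   event can satisfy the control criteria.
#' @param thresholds A [classification_thresholds()] list.
#' @return A data frame with columns `event_id`, `label` (factor with
#'   levels enhanced/silenced/control/unclassified), `delta_psi`, `fdr`.
#'   Label counts are attached as the `"counts"` attribute.
#' @export
classify_events <- function(events, expression = NULL,
                            thresholds = classification_thresholds()) {
  th <- thresholds
  groups <- attr(events, "groups")
  summ <- summarize_groups(events)
  n <- nrow(events)
  labels <- character(n)
  delta <- numeric(n)
  fpkm_ok <- logical(n)
  missing_expr <- 0L
  if (!is.null(expression)) {
    idx <- match(events$gene_id, expression$gene_id)
    fpkm_max <- pmax(expression$fpkm_1[idx], expression$fpkm_2[idx])
    fpkm_ok <- !is.na(fpkm_max) & fpkm_max > th$control_min_fpkm
    missing_expr <- sum(is.na(idx))
  }
  lo <- th$control_psi_range[1L]
  hi <- th$control_psi_range[2L]
  for (i in seq_len(n)) {
    m <- summ$mean_psi[summ$event_id == events$event_id[i]]
    delta[i] <- m[1L] - m[2L]
    fdr <- events$fdr[i]
    if (fdr < th$fdr_regulated && delta[i] >= th$min_abs_delta_psi) {
      labels[i] <- "enhanced"
    } else if (fdr < th$fdr_regulated && delta[i] <= -th$min_abs_delta_psi) {
      labels[i] <- "silenced"
    } else if (fdr > th$fdr_control && all(m > lo & m < hi) && fpkm_ok[i]) {
      labels[i] <- "control"
    } else {
      labels[i] <- "unclassified"
    }
  }
  if (missing_expr > 0L)
    .warnf("%d event(s) have no expression record for their gene; they cannot be control exons",
           missing_expr)
  out <- data.frame(
    event_id = events$event_id,
    label = factor(labels,
                   levels = c("enhanced", "silenced", "control", "unclassified")),
    delta_psi = delta,
    fdr = events$fdr,
    stringsAsFactors = FALSE)
  attr(out, "counts") <- table(out$label)
  attr(out, "groups") <- groups
  out
}

#' Overlaps between event sets
#'
#' Computes the cardinality of every exclusive intersection region (as in a
#' Venn diagram) across two or more named sets of event identifiers.
#'
#' @param sets Named list (length >= 2) of character vectors of event ids.
#' @return A data frame with columns `region` (sets joined by `&`) and
#'   `count`, covering all non-empty combinations of sets; per-set totals
#'   are attached as the `"totals"` attribute.
#' @export
compare_event_sets <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || is.null(names(sets)))
    .stopf("`sets` must be a named list of at least two event-id vectors")
  ids <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  if (length(ids) == 1L) member <- matrix(member, nrow = 1L,
                                          dimnames = list(NULL, names(sets)))
  k <- length(sets)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
  names(combos) <- names(sets)
  region <- apply(combos, 1L, function(r) paste(names(sets)[as.logical(r)],
                                                collapse = "&"))
  count <- apply(combos, 1L, function(r) {
    sum(apply(member, 1L, function(m) all(m == as.logical(r))))
  })
  if (!length(ids)) count <- rep(0L, nrow(combos))
  out <- data.frame(region = region, count = as.integer(count),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "totals") <- vapply(sets, function(s) length(unique(s)), integer(1))
  out
}

#' Write / read event classifications
#'
#' Round-trippable TSV of classification results (`event_id`, `label`,
#' `delta_psi`, `fdr`).
#'
#' @param classification Data frame from [classify_events()].
#' @param path Output (input) path.
#' @return `write_classifications` returns `path` invisibly;
#'   `read_classifications` returns the classification data frame.
#' @export
write_classifications <- function(classification, path) {
  out <- classification
  out$delta_psi <- format(out$delta_psi, digits = 15, trim = TRUE,
                          scientific = FALSE)
  out$fdr <- format(out$fdr, digits = 15, trim = TRUE, scientific = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_classifications
#' @export
read_classifications <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  tab$label <- factor(tab$label,
                      levels = c("enhanced", "silenced", "control",
                                 "unclassified"))
  tab$event_id <- as.character(tab$event_id)
  tab
}
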