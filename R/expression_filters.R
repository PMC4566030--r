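# Differential-expression filters over Cuffdiff-style gene tables and the
# splicing-factor (RBP) panel filter.

#' Column dialect for Cuffdiff-style expression tables
#'
#' @param columns Named list mapping the internal fields `gene_id`,
#'   `gene_name`, `fpkm_1`, `fpkm_2`, `q_value` to column names.  The
#'   defaults follow the Cuffdiff `gene_exp.diff` layout.
#' @return A list of class `"expression_dialect"`.
#' @export
expression_dialect <- function(columns = list()) {
  default <- list(gene_id = "gene_id", gene_name = "gene",
                  fpkm_1 = "value_1", fpkm_2 = "value_2",
                  q_value = "q_value")
  default[names(columns)] <- columns
  structure(list(columns = default), class = "expression_dialect")
}

#' Read a gene-expression table
#'
#' Parses a tab-delimited Cuffdiff-style differential-expression table into
#' records with per-group average FPKM and q-value.
#'
#' @param path Path to the table.
#' @param dialect An [expression_dialect()].
#' @return A data frame with columns `gene_id`, `gene_name`, `fpkm_1`,
#'   `fpkm_2`, `q_value`.
#' @export
read_expression_table <- function(path, dialect = expression_dialect()) {
  if (!file.exists(path)) .stopf("expression table not found: %s", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  cols <- dialect$columns
  needed <- unlist(cols[c("gene_id", "fpkm_1", "fpkm_2", "q_value")])
  missing <- setdiff(needed, names(tab))
  if (length(missing))
    .stopf("missing mandatory column '%s' in %s", missing[1L], path)
  out <- data.frame(
    gene_id = as.character(tab[[cols$gene_id]]),
    gene_name = if (cols$gene_name %in% names(tab))
      as.character(tab[[cols$gene_name]]) else as.character(tab[[cols$gene_id]]),
    fpkm_1 = as.numeric(tab[[cols$fpkm_1]]),
    fpkm_2 = as.numeric(tab[[cols$fpkm_2]]),
    q_value = as.numeric(tab[[cols$q_value]]),
    stringsAsFactors = FALSE)
  if (any(out$fpkm_1 < 0, na.rm = TRUE) || any(out$fpkm_2 < 0, na.rm = TRUE))
    .stopf("FPKM values must be non-negative")
  .check_probability(out$q_value[!is.na(out$q_value)], "q")
  out
}

#' Differential-expression thresholds
#'
#' Defaults reproduce the standard filter: FDR < 5\%, more than twofold
#' difference in average FPKM (strict), and a minimum FPKM above 0.1.
#'
#' @param max_q q-value ceiling (strict `<`).
#' @param min_fold Fold-change floor (strict `>`), computed as the ratio of
#'   the larger to the smaller group-mean FPKM.
#' @param min_fpkm Expression floor (strict `>`).
#' @param fpkm_rule Which mean the floor applies to: `"max"` (default; the
#'   larger group mean must exceed the floor) or `"both"`.
#' @param pseudocount Optional pseudocount added to both means before the
#'   fold-change ratio (0 = off; genes with one zero mean then pass the
#'   fold criterion via an infinite ratio).
#' @return A named list.
#' @export
deg_thresholds <- function(max_q = 0.05, min_fold = 2, min_fpkm = 0.1,
                           fpkm_rule = c("max", "both"), pseudocount = 0) {
  fpkm_rule <- match.arg(fpkm_rule)
  stopifnot(max_q > 0, min_fold >= 1, min_fpkm >= 0, pseudocount >= 0)
  list(max_q = max_q, min_fold = min_fold, min_fpkm = min_fpkm,
       fpkm_rule = fpkm_rule, pseudocount = pseudocount)
}

.fold_change <- function(f1, f2, pseudocount = 0) {
  hi <- pmax(f1, f2) + pseudocount
  lo <- pmin(f1, f2) + pseudocount
  ifelse(hi == 0, 1, ifelse(lo == 0, Inf, hi / lo))
}

#' Call differentially expressed genes
#'
#' A gene is a DEG iff its q-value is below the ceiling, the ratio of the
#' larger to the smaller group-mean FPKM strictly exceeds the fold floor,
#' and the expression floor holds (by default: the larger group mean
#' exceeds it).  Genes with zero expression in both groups are never DEGs.
#'
#' @param records Expression data frame (see [read_expression_table()]).
#' @param thresholds A [deg_thresholds()] list.
#' @return A data frame with columns `gene_id`, `is_deg`, `direction`
#'   (`"up"` when the comparison group is higher, `"down"` otherwise),
#'   `fold`, `q_value`; up/down counts in the `"counts"` attribute.
#' @export
deg_filter <- function(records, thresholds = deg_thresholds()) {
  th <- thresholds
  fold <- .fold_change(records$fpkm_1, records$fpkm_2, th$pseudocount)
  floor_ok <- if (th$fpkm_rule == "max")
    pmax(records$fpkm_1, records$fpkm_2) > th$min_fpkm
  else
    pmin(records$fpkm_1, records$fpkm_2) > th$min_fpkm
  both_zero <- records$fpkm_1 == 0 & records$fpkm_2 == 0
  if (any(both_zero))
    message(sum(both_zero), " gene(s) with zero FPKM in both groups were never DEGs")
  is_deg <- !is.na(records$q_value) & records$q_value < th$max_q &
    fold > th$min_fold & floor_ok & !both_zero
  out <- data.frame(
    gene_id = records$gene_id,
    is_deg = is_deg,
    direction = ifelse(records$fpkm_2 > records$fpkm_1, "up", "down"),
    fold = fold,
    q_value = records$q_value,
    stringsAsFactors = FALSE)
  attr(out, "counts") <- c(up = sum(is_deg & out$direction == "up"),
                           down = sum(is_deg & out$direction == "down"))
  out
}

#' Filter a splicing-factor / RBP panel by fold change
#'
#' Restricts the expression records to a supplied panel of gene identifiers
#' (e.g. the RBP and splicing-factor orthologue panel of a knockout study)
#' and keeps members whose fold change is at least `min_fold` (inclusive).
#' Results are sorted by decreasing |log2 fold change|.
#'
#' @param records Expression data frame (see [read_expression_table()]).
#' @param panel Non-empty character vector of gene ids or names.
#' @param min_fold Fold-change floor, inclusive (default 1.5).
#' @return The filtered records with additional `fold` and `log2_fold`
#'   columns (`log2_fold` signed by the comparison-over-reference ratio).
#' @export
rbp_panel <- function(records, panel, min_fold = 1.5) {
  if (missing(panel) || !length(panel))
    .stopf("`panel` must be a non-empty vector of gene identifiers")
  keep <- records$gene_id %in% panel | records$gene_name %in% panel
  out <- records[keep, , drop = FALSE]
  out$fold <- .fold_change(out$fpkm_1, out$fpkm_2)
  out$log2_fold <- log2(ifelse(out$fpkm_1 == 0 | out$fpkm_2 == 0, NA,
                               out$fpkm_2 / out$fpkm_1))
  out$log2_fold[is.na(out$log2_fold)] <-
    (sign(out$fpkm_2 - out$fpkm_1) * Inf)[is.na(out$log2_fold)]
  out <- out[out$fold >= min_fold, , drop = FALSE]
  out <- out[order(-abs(out$log2_fold)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
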