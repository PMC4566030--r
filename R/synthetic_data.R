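# Seeded synthetic-data generator: genome FASTA, rMATS-like SE tables with
# replicate PSIs and test-derived FDRs, expression tables, planted motif
# occurrences, and a truth bundle for end-to-end validation.

#' Simulation configuration
#'
#' Describes the synthetic world the generator emits.  Defaults mirror the
#' double-knockout comparison of the motivating study: 119 enhanced and 95
#' silenced events against 500 control exons, 3 biological replicates per
#' genotype group, a replicate-PSI beta model with within-group SD 0.05 and
#' a regulated effect size of delta PSI 0.4, and a GU-rich motif planted in
#' the regions where positional regulation is expected (upstream intron and
#' exon body of silenced exons, downstream intron of enhanced exons) at a
#' roughly tenfold excess over the uniform planted background.
#'
#' @param n_enhanced,n_silenced,n_control Event counts per set.
#' @param n_reps Replicates per genotype group.
#' @param groups Two group labels; the first is the reference (wild type).
#' @param psi_high,psi_low Group-mean PSI of the high/low-inclusion side of
#'   a regulated event (enhanced: reference high; silenced: reference low).
#' @param psi_sd Within-group replicate SD of the beta model.
#' @param control_psi_range Range the per-event control PSI mean is drawn
#'   from (uniform), shared by both groups.
#' @param exon_length,flank_exon_length,intron_length Integer ranges
#'   (min, max) for cassette exon, flanking exon and intron lengths.
#' @param base_freqs Background base frequencies (RNA alphabet).
#' @param plant_motif Motif planted into regulated regions.
#' @param plant_rates Named list (`enhanced`, `silenced`, `control`) of
#'   per-region expected planted occurrence counts
#'   (`upstream_intron`, `exon_body`, `downstream_intron`).
#' @param fdr_model `"ttest"` (default): event p-values come from a
#'   two-sample t-test on the simulated replicate PSIs, FDRs from BH across
#'   events, so the FDR column behaves like a real screen.  `"fixed"`:
#'   FDRs are set deterministically beyond the classification thresholds
#'   (`fixed_fdr_regulated`, `fixed_fdr_null`), for exact
#'   truth-recovery checks.
#' @param fixed_fdr_regulated,fixed_fdr_null FDR values used by the
#'   `"fixed"` model.
#' @param n_null_genes,n_deg_genes Extra genes without/with a planted
#'   expression change.
#' @param deg_fold,deg_q Ranges for planted DEG fold changes and q-values.
#' @param null_fold,null_q Ranges for null genes.
#' @param control_fpkm FPKM range for control-event genes (kept above the
#'   control-exon expression floor).
#' @param regulated_fpkm FPKM range for regulated-event genes.
#' @param events_per_chrom,spacer Genome layout: events per synthetic
#'   chromosome and spacer length between loci.
#' @param seed Integer seed; everything the generator emits is a pure
#'   function of the configuration including this seed.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_enhanced = 119L, n_silenced = 95L, n_control = 500L,
                       n_reps = 3L, groups = c("WT", "KO"),
                       psi_high = 0.7, psi_low = 0.3, psi_sd = 0.05,
                       control_psi_range = c(0.3, 0.7),
                       exon_length = c(80L, 200L),
                       flank_exon_length = c(100L, 250L),
                       intron_length = c(300L, 800L),
                       base_freqs = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25),
                       plant_motif = "UGGUGG",
                       plant_rates = list(
                         enhanced = c(upstream_intron = 0.2, exon_body = 0.2,
                                      downstream_intron = 2),
                         silenced = c(upstream_intron = 2, exon_body = 1,
                                      downstream_intron = 0.2),
                         control = c(upstream_intron = 0.2, exon_body = 0.2,
                                     downstream_intron = 0.2)),
                       fdr_model = c("ttest", "fixed"),
                       fixed_fdr_regulated = 0.001, fixed_fdr_null = 0.9,
                       n_null_genes = 200L, n_deg_genes = 50L,
                       deg_fold = c(2.5, 8), deg_q = c(1e-4, 0.01),
                       null_fold = c(0.8, 1.25), null_q = c(0.2, 1),
                       control_fpkm = c(6, 60), regulated_fpkm = c(0.5, 30),
                       events_per_chrom = 50L, spacer = 100L, seed = 1L) {
  fdr_model <- match.arg(fdr_model)
  .check_rna_pattern(plant_motif)
  stopifnot(n_enhanced >= 0, n_silenced >= 0, n_control >= 0, n_reps >= 2,
            length(groups) == 2L,
            psi_high > psi_low, psi_sd > 0,
            all(unlist(plant_rates) >= 0),
            all(abs(sum(base_freqs) - 1) < 1e-8),
            exon_length[1L] <= exon_length[2L],
            intron_length[1L] <= intron_length[2L])
  if (n_control == 0L)
    .stopf("n_control must be positive: the enrichment stage requires a non-empty control set")
  if (n_enhanced + n_silenced == 0L)
    .stopf("at least one regulated event is required")
  if (exon_length[1L] < nchar(plant_motif) ||
      intron_length[1L] < nchar(plant_motif))
    .stopf("regions shorter than the planted motif are infeasible")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# Non-overlapping start positions (1-based) for `count` copies of a
# k-length motif among candidate starts lo..hi in a sequence of length L.
.place_nonoverlap <- function(L, k, count, lo, hi) {
  chosen <- integer(0)
  occupied <- logical(L)
  cand <- if (hi >= lo) lo:hi else integer(0)
  while (count > 0L && length(cand)) {
    free <- cand[vapply(cand, function(s) !any(occupied[s:(s + k - 1L)]),
                        logical(1))]
    if (!length(free)) break
    s <- if (length(free) == 1L) free else sample(free, 1L)
    chosen <- c(chosen, s)
    occupied[s:(s + k - 1L)] <- TRUE
    count <- count - 1L
  }
  sort(chosen)
}

#' Plant motif occurrences into a sequence
#'
#' Overwrites background bases with a Poisson-distributed number of
#' non-overlapping copies of `motif` at uniform random positions; the
#' sequence length is preserved.  If fewer non-overlapping placements are
#' feasible than drawn, the count is truncated with a warning.
#'
#' @param seq RNA sequence (single string).
#' @param motif Literal motif to insert.
#' @param rate Expected number of occurrences (Poisson mean, >= 0).
#' @param interval Optional 0-based half-open interval `(s, e)` restricting
#'   planting to a sub-window of `seq` (motifs are kept fully inside).
#' @return A list with `seq` (modified sequence) and `positions` (1-based
#'   start positions of the planted copies).
#' @export
plant_motifs <- function(seq, motif, rate, interval = NULL) {
  stopifnot(rate >= 0, is.character(seq), length(seq) == 1L)
  k <- nchar(motif)
  L <- nchar(seq)
  if (k > L) {
    if (rate > 0) .warnf("motif (%d nt) longer than sequence (%d nt); nothing planted", k, L)
    return(list(seq = seq, positions = integer(0)))
  }
  count <- stats::rpois(1L, rate)
  if (count == 0L) return(list(seq = seq, positions = integer(0)))
  if (is.null(interval)) interval <- c(0L, L)
  lo <- interval[1L] + 1L
  hi <- interval[2L] - k + 1L
  pos <- .place_nonoverlap(L, k, count, lo, hi)
  if (length(pos) < count)
    .warnf("only %d of %d requested motif copies could be placed without overlap",
           length(pos), count)
  for (s in pos) substr(seq, s, s + k - 1L) <- motif
  list(seq = seq, positions = pos)
}

.beta_shapes <- function(m, s) {
  nu <- m * (1 - m) / s^2 - 1
  if (nu <= 0) nu <- 1e-3
  c(shape1 = m * nu, shape2 = (1 - m) * nu)
}

.draw_psi <- function(n, m, s) {
  sh <- .beta_shapes(m, s)
  pmin(pmax(stats::rbeta(n, sh[1L], sh[2L]), 1e-4), 1 - 1e-4)
}

#' Simulate a complete synthetic splicing dataset
#'
#' Generates a genome, one cassette-exon event per locus (random strand,
#' non-overlapping loci), per-group replicate PSI values from the beta
#' model, event p-values/FDRs, planted motif occurrences at the configured
#' region rates, and a gene-expression table with planted fold changes.
#' All randomness is driven by `config$seed`, so a configuration maps to a
#' byte-identical dataset.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory; when given, writes `genome.fa`,
#'   `se_table.tsv`, `expression.tsv` and `truth.json` and records their
#'   paths in the result.
#' @return A list with elements `genome` (`DNAStringSet`), `events`
#'   (parsed event data frame as from [read_se_table()]), `expression`
#'   (records as from [read_expression_table()]), `truth` (list with
#'   per-event labels/delta/planted positions and per-gene DEG status),
#'   `config`, and `paths` when `dir` was given.
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL) {
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_enhanced + cfg$n_silenced + cfg$n_control
  labels <- c(rep("enhanced", cfg$n_enhanced),
              rep("silenced", cfg$n_silenced),
              rep("control", cfg$n_control))
  k <- nchar(cfg$plant_motif)
  rcfg <- region_config()

  event_id <- sprintf("ev%04d", seq_len(n))
  gene_id <- sprintf("gene%04d", seq_len(n))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  ilen <- function(r, m) sample(seq.int(r[1L], r[2L]), m, replace = TRUE)
  L_upE <- ilen(cfg$flank_exon_length, n)
  L_upI <- ilen(cfg$intron_length, n)
  L_cas <- ilen(cfg$exon_length, n)
  L_dnI <- ilen(cfg$intron_length, n)
  L_dnE <- ilen(cfg$flank_exon_length, n)

  planted <- vector("list", n)
  names(planted) <- event_id
  loci <- character(n)
  for (i in seq_len(n)) {
    upE <- .random_rna(L_upE[i], cfg$base_freqs)
    upI <- .random_rna(L_upI[i], cfg$base_freqs)
    cas <- .random_rna(L_cas[i], cfg$base_freqs)
    dnI <- .random_rna(L_dnI[i], cfg$base_freqs)
    dnE <- .random_rna(L_dnE[i], cfg$base_freqs)
    rates <- cfg$plant_rates[[labels[i]]]
    up_iv <- .upstream_scan_interval(L_upI[i], rcfg)
    p_up <- plant_motifs(upI, cfg$plant_motif, rates[["upstream_intron"]],
                         interval = up_iv)
    upI <- p_up$seq
    p_ex <- plant_motifs(cas, cfg$plant_motif, rates[["exon_body"]])
    cas <- p_ex$seq
    dn_iv <- .downstream_scan_interval(L_dnI[i], rcfg)
    p_dn <- plant_motifs(dnI, cfg$plant_motif, rates[["downstream_intron"]],
                         interval = dn_iv)
    dnI <- p_dn$seq
    planted[[i]] <- list(upstream_intron = p_up$positions,
                         exon_body = p_ex$positions,
                         downstream_intron = p_dn$positions)
    loci[i] <- paste0(upE, upI, cas, dnI, dnE)
  }

  # genome layout: transcript 5'->3' runs left-to-right on "+", right-to-
  # left on "-" (locus written as its reverse complement)
  n_chrom <- ceiling(n / cfg$events_per_chrom)
  chrom <- paste0("chr", rep(seq_len(n_chrom),
                             each = cfg$events_per_chrom)[seq_len(n)])
  chrom_seqs <- stats::setNames(vector("list", n_chrom),
                                paste0("chr", seq_len(n_chrom)))
  coords <- matrix(0L, nrow = n, ncol = 6L,
                   dimnames = list(NULL, c("upstream_start", "upstream_end",
                                           "exon_start", "exon_end",
                                           "downstream_start", "downstream_end")))
  spacer_dna <- strrep("N", cfg$spacer)
  for (cc in names(chrom_seqs)) {
    idx <- which(chrom == cc)
    pieces <- character(0)
    pos <- 0L
    for (i in idx) {
      pieces <- c(pieces, spacer_dna)
      pos <- pos + cfg$spacer
      locus_dna <- chartr("U", "T", loci[i])
      seg <- c(L_upE[i], L_upI[i], L_cas[i], L_dnI[i], L_dnE[i])
      if (strand[i] == "+") {
        bounds <- pos + cumsum(c(0L, seg))
        coords[i, ] <- c(bounds[1L], bounds[2L], bounds[3L], bounds[4L],
                         bounds[5L], bounds[6L])
      } else {
        locus_dna <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(locus_dna)))
        # genomic left-to-right: dnE, dnI, cas, upI, upE
        bounds <- pos + cumsum(c(0L, rev(seg)))
        coords[i, ] <- c(bounds[5L], bounds[6L], bounds[3L], bounds[4L],
                         bounds[1L], bounds[2L])
      }
      pieces <- c(pieces, locus_dna)
      pos <- pos + sum(seg)
    }
    pieces <- c(pieces, spacer_dna)
    chrom_seqs[[cc]] <- paste(pieces, collapse = "")
  }
  genome <- Biostrings::DNAStringSet(unlist(chrom_seqs))

  # replicate PSIs per group and event statistics
  true_delta <- numeric(n)
  psi <- vector("list", n)
  p_value <- numeric(n)
  for (i in seq_len(n)) {
    if (labels[i] == "enhanced") {
      m1 <- cfg$psi_high; m2 <- cfg$psi_low
    } else if (labels[i] == "silenced") {
      m1 <- cfg$psi_low; m2 <- cfg$psi_high
    } else {
      m1 <- m2 <- stats::runif(1L, cfg$control_psi_range[1L],
                               cfg$control_psi_range[2L])
    }
    true_delta[i] <- m1 - m2
    g1 <- .draw_psi(cfg$n_reps, m1, cfg$psi_sd)
    g2 <- .draw_psi(cfg$n_reps, m2, cfg$psi_sd)
    psi[[i]] <- stats::setNames(list(g1, g2), cfg$groups)
    p_value[i] <- tryCatch(stats::t.test(g1, g2)$p.value,
                           error = function(e) 1)
  }
  if (cfg$fdr_model == "ttest") {
    fdr <- stats::p.adjust(p_value, method = "BH")
  } else {
    fdr <- ifelse(labels == "control", cfg$fixed_fdr_null,
                  cfg$fixed_fdr_regulated)
    p_value <- fdr
  }

  events <- data.frame(event_id = event_id, gene_id = gene_id, chrom = chrom,
                       strand = strand, coords, p_value = p_value, fdr = fdr,
                       stringsAsFactors = FALSE)
  events$psi <- I(psi)
  attr(events, "groups") <- cfg$groups

  # expression: event genes (controls highly expressed) + extras
  fp <- function(m, r) stats::runif(m, r[1L], r[2L])
  ev_base <- ifelse(labels == "control", fp(n, cfg$control_fpkm),
                    fp(n, cfg$regulated_fpkm))
  ev_f1 <- ev_base * stats::runif(n, 0.9, 1.1)
  ev_f2 <- ev_base * stats::runif(n, 0.9, 1.1)
  nn <- cfg$n_null_genes
  nd <- cfg$n_deg_genes
  extra_id <- sprintf("xgene%04d", seq_len(nn + nd))
  ex_base <- fp(nn + nd, c(1, 50))
  ex_fold <- c(fp(nn, cfg$null_fold), fp(nd, cfg$deg_fold))
  deg_dir <- c(rep(NA, nn), sample(c("up", "down"), nd, replace = TRUE))
  ex_f1 <- ex_base
  ex_f2 <- ifelse(is.na(deg_dir), ex_base * ex_fold,
                  ifelse(deg_dir == "up", ex_base * ex_fold,
                         ex_base / ex_fold))
  qv <- c(fp(n, cfg$null_q), fp(nn, cfg$null_q), fp(nd, cfg$deg_q))
  expression <- data.frame(
    gene_id = c(gene_id, extra_id),
    gene_name = c(gene_id, extra_id),
    fpkm_1 = c(ev_f1, ex_f1),
    fpkm_2 = c(ev_f2, ex_f2),
    q_value = pmin(qv, 1),
    stringsAsFactors = FALSE)

  truth <- list(
    events = data.frame(event_id = event_id, gene_id = gene_id,
                        label = labels, true_delta_psi = true_delta,
                        stringsAsFactors = FALSE),
    planted = planted,
    genes = data.frame(gene_id = extra_id,
                       is_deg = !is.na(deg_dir),
                       direction = deg_dir,
                       stringsAsFactors = FALSE))

  out <- list(genome = genome, events = events, expression = expression,
              truth = truth, config = cfg)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(genome = file.path(dir, "genome.fa"),
                  se_table = file.path(dir, "se_table.tsv"),
                  expression = file.path(dir, "expression.tsv"),
                  truth = file.path(dir, "truth.json"))
    Biostrings::writeXStringSet(genome, paths$genome)
    write_se_table(events, paths$se_table)
    expr_out <- data.frame(gene_id = expression$gene_id,
                           gene = expression$gene_name,
                           value_1 = sprintf("%.6f", expression$fpkm_1),
                           value_2 = sprintf("%.6f", expression$fpkm_2),
                           q_value = sprintf("%.6g", expression$q_value),
                           stringsAsFactors = FALSE)
    utils::write.table(expr_out, paths$expression, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                         pretty = FALSE)
    out$paths <- paths
  }
  out
}

#' Write an event data frame as an rMATS-style SE table
#'
#' Inverse of [read_se_table()] under the default dialect.
#'
#' @param events Event data frame with `psi` list column.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_se_table <- function(events, path) {
  fmt_psi <- function(v) paste(sprintf("%.6f", v), collapse = ",")
  g1 <- vapply(events$psi, function(p) fmt_psi(p[[1L]]), character(1))
  g2 <- vapply(events$psi, function(p) fmt_psi(p[[2L]]), character(1))
  d <- vapply(events$psi, function(p) mean(p[[1L]]) - mean(p[[2L]]), numeric(1))
  tab <- data.frame(
    ID = events$event_id, GeneID = events$gene_id, chr = events$chrom,
    strand = events$strand,
    exonStart_0base = events$exon_start, exonEnd = events$exon_end,
    upstreamES = events$upstream_start, upstreamEE = events$upstream_end,
    downstreamES = events$downstream_start, downstreamEE = events$downstream_end,
    PValue = sprintf("%.8g", events$p_value),
    FDR = sprintf("%.8g", events$fdr),
    IncLevel1 = g1, IncLevel2 = g2,
    IncLevelDifference = sprintf("%.6f", d),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate bare region sequence sets
#'
#' Draws independent i.i.d.-background region sequences (no planting, no
#' genome bookkeeping) in the layout [enrich()] consumes.  Used for null
#' calibration, where regulated and control sets must share the same base
#' composition.
#'
#' @param n Number of events.
#' @param region_lengths Named lengths for `upstream_intron`, `exon_body`,
#'   `downstream_intron`.
#' @param base_freqs Base frequencies (RNA alphabet).
#' @return A regions data frame compatible with [enrich()].
#' @export
simulate_region_set <- function(n,
                                region_lengths = c(upstream_intron = 230L,
                                                   exon_body = 150L,
                                                   downstream_intron = 244L),
                                base_freqs = c(A = 0.25, C = 0.25,
                                               G = 0.25, U = 0.25)) {
  stopifnot(n >= 1, all(region_lengths >= 1))
  mk <- function(L) vapply(seq_len(n), function(i) .random_rna(L, base_freqs),
                           character(1))
  data.frame(event_id = sprintf("r%04d", seq_len(n)),
             upstream_intron = mk(region_lengths[["upstream_intron"]]),
             exon_body = mk(region_lengths[["exon_body"]]),
             downstream_intron = mk(region_lengths[["downstream_intron"]]),
             stringsAsFactors = FALSE)
}
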