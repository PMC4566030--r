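# Pipeline orchestration: configuration, staged execution, manifest with
# input/output hashes, and resume support.

#' Pipeline configuration
#'
#' Collects paths, thresholds and stage toggles for [run_pipeline()].  All
#' thresholds default to the standard profile used throughout the package.
#'
#' @param se_table Path to the skipped-exon table.
#' @param genome Path to the genome FASTA.
#' @param expression Optional path to the expression table.
#' @param out_dir Output directory (created if needed).
#' @param motif_file Optional motif TSV for the enrichment stage; when
#'   `NULL` the default GU-rich panel [esrp_motifs()] is used.
#' @param map_motifs Motif set for the RNA-map stage.
#' @param panel Optional character vector of panel gene ids for the
#'   RBP-panel filter.
#' @param groups Two group labels (reference first).
#' @param thresholds A [classification_thresholds()] list.
#' @param region A [region_config()].
#' @param enrichment An [enrichment_config()].
#' @param map A [map_config()].
#' @param deg A [deg_thresholds()] list.
#' @param stages Character vector of stages to run, in order, from
#'   `classify`, `extract`, `enrich`, `rnamap`, `deg`, `stats`.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return A list of class `"pipeline_config"`, validated.
#' @export
pipeline_config <- function(se_table, genome, expression = NULL, out_dir,
                            motif_file = NULL, map_motifs = esrp_motifs(),
                            panel = NULL, groups = c("WT", "KO"),
                            thresholds = classification_thresholds(),
                            region = region_config(),
                            enrichment = enrichment_config(),
                            map = map_config(),
                            deg = deg_thresholds(),
                            stages = c("classify", "extract", "enrich",
                                       "rnamap", "deg", "stats"),
                            seed = 1L) {
  stopifnot(is.character(se_table), is.character(genome))
  stages <- match.arg(stages, c("classify", "extract", "enrich", "rnamap",
                                "deg", "stats"), several.ok = TRUE)
  if (!file.exists(se_table)) .stopf("se_table not found: %s", se_table)
  if (!file.exists(genome)) .stopf("genome not found: %s", genome)
  if (!is.null(expression) && !file.exists(expression))
    .stopf("expression table not found: %s", expression)
  cfg <- list(se_table = se_table, genome = genome, expression = expression,
              out_dir = out_dir, motif_file = motif_file,
              map_motifs = map_motifs, panel = panel, groups = groups,
              thresholds = thresholds, region = region,
              enrichment = enrichment, map = map, deg = deg,
              stages = stages, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

.input_hashes <- function(cfg) {
  paths <- c(se_table = cfg$se_table, genome = cfg$genome,
             expression = cfg$expression, motif_file = cfg$motif_file)
  as.list(tools::md5sum(paths[!vapply(paths, is.null, logical(1))]))
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in order (classify, extract, enrich,
#' rnamap, deg, stats), writing each stage's outputs under `out_dir` and a
#' `manifest.json` recording input hashes, output hashes and the resolved
#' threshold profile.  With `resume = TRUE`, a run whose manifest already
#' matches the current inputs and configuration is skipped.
#'
#' @param config A [pipeline_config()].
#' @param resume Skip the run if an up-to-date manifest exists.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, resume = FALSE) {
  cfg <- config
  if (!inherits(cfg, "pipeline_config"))
    .stopf("`config` must come from pipeline_config()")
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  inputs <- .input_hashes(cfg)
  if (resume && file.exists(manifest_path)) {
    old <- jsonlite::read_json(manifest_path)
    if (identical(lapply(old$inputs, as.character),
                  lapply(inputs, as.character))) {
      message("pipeline: inputs unchanged, resuming from existing outputs")
      return(invisible(old))
    }
  }
  outp <- function(name) file.path(cfg$out_dir, name)
  outputs <- character(0)

  events <- read_se_table(cfg$se_table, groups = cfg$groups)
  expression <- if (!is.null(cfg$expression))
    read_expression_table(cfg$expression) else NULL
  classification <- NULL
  sets <- NULL
  regions <- NULL
  segments <- NULL

  if ("classify" %in% cfg$stages) {
    classification <- classify_events(events, expression, cfg$thresholds)
    write_classifications(classification, outp("classifications.tsv"))
    counts <- attr(classification, "counts")
    jsonlite::write_json(as.list(counts), outp("set_sizes.json"),
                         auto_unbox = TRUE)
    outputs <- c(outputs, "classifications.tsv", "set_sizes.json")
  }
  if (any(c("extract", "enrich", "rnamap") %in% cfg$stages)) {
    genome <- read_genome(cfg$genome)
    regions <- extract_regions(events, genome, cfg$region)
    segments <- extract_map_segments(events, genome, cfg$region)
    if ("extract" %in% cfg$stages) {
      regions_to_fasta(regions, outp("regions.fa"))
      outputs <- c(outputs, "regions.fa")
    }
  }
  if (!is.null(classification)) {
    sets <- split(as.character(classification$event_id),
                  classification$label)
  }
  if ("enrich" %in% cfg$stages) {
    if (is.null(sets)) .stopf("the enrich stage requires the classify stage")
    motifs <- if (!is.null(cfg$motif_file)) read_motifs(cfg$motif_file)
              else esrp_motifs()
    regulated <- list()
    for (dir in c("enhanced", "silenced")) {
      if (length(sets[[dir]]))
        regulated[[dir]] <- regions[regions$event_id %in% sets[[dir]], ]
    }
    control <- regions[regions$event_id %in% sets[["control"]], ]
    enr <- enrich(regulated, control, motifs, cfg$enrichment)
    write_enrichment(enr, outp("enrichment.tsv"))
    outputs <- c(outputs, "enrichment.tsv")
  }
  if ("rnamap" %in% cfg$stages) {
    if (is.null(sets)) .stopf("the rnamap stage requires the classify stage")
    map_sets <- Filter(length, sets[c("enhanced", "silenced", "control")])
    profile <- build_map(map_sets, segments, cfg$map_motifs, cfg$map)
    write_rna_map(profile, outp("rna_map.tsv"))
    outputs <- c(outputs, "rna_map.tsv")
  }
  if ("deg" %in% cfg$stages && !is.null(expression)) {
    degs <- deg_filter(expression, cfg$deg)
    utils::write.table(degs, outp("deg.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs <- c(outputs, "deg.tsv")
    if (!is.null(cfg$panel)) {
      pan <- rbp_panel(expression, cfg$panel)
      utils::write.table(pan, outp("rbp_panel.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, "rbp_panel.tsv")
    }
  }
  if ("stats" %in% cfg$stages && !is.null(classification)) {
    summ <- summarize_groups(events)
    utils::write.table(summ, outp("psi_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, "psi_summary.tsv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("semotif")),
    seed = cfg$seed,
    inputs = inputs,
    outputs = stats::setNames(as.list(tools::md5sum(
      file.path(cfg$out_dir, outputs))), outputs),
    thresholds = cfg$thresholds,
    stages = cfg$stages)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
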