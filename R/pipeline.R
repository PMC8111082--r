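#' Validate a pipeline configuration
#'
#' The configuration is a named list (or a path to a JSON file) with input
#' paths and parameters. Required: `expr`, `meta`, `cerna`, `gmt`,
#' `early_set`, `late_set`, `out`. Optional (defaults in parentheses):
#' `annotation`, `alpha_edge` (0.05), `alpha_diff` (0.05), `alpha_ref`
#' (0.05), `direction_rule` ("delta_positive"), `edge_universe`
#' ("perturbed"), `min_value` (1), `min_fraction` (0.25), `alpha_classify`
#' (0.05), `top_k_markers` (20), `presence_rule` ("present_only"),
#' `hub_subtype` ("early_response"), `background_rule` ("cerna" or
#' "all_filtered"; default "cerna"), `seed` (1). All referenced input
#' files must exist at validation time.
#'
#' @param config Named list or path to a JSON config file.
#' @return The validated, default-filled config list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  req <- c("expr", "meta", "cerna", "gmt", "early_set", "late_set", "out")
  missing <- setdiff(req, names(config))
  if (length(missing))
    ccn_abort("config", "missing config field(s): %s", paste(missing, collapse = ", "))
  defaults <- list(annotation = NULL, alpha_edge = 0.05, alpha_diff = 0.05,
                   alpha_ref = 0.05, direction_rule = "delta_positive",
                   edge_universe = "perturbed", min_value = 1,
                   min_fraction = 0.25, alpha_classify = 0.05,
                   top_k_markers = 20, presence_rule = "present_only",
                   hub_subtype = "early_response", background_rule = "cerna",
                   seed = 1)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[nm] <- defaults[nm]
  for (a in c("alpha_edge", "alpha_diff", "alpha_ref", "alpha_classify"))
    if (!(config[[a]] > 0 && config[[a]] < 1))
      ccn_abort("config", "%s must be in (0, 1)", a)
  paths <- c("expr", "meta", "cerna", "gmt")
  if (!is.null(config$annotation)) paths <- c(paths, "annotation")
  for (p in paths)
    if (!file.exists(config[[p]]))
      ccn_abort("config", "input file not found: %s = %s", p, config[[p]])
  config
}

.stage_entry <- function(name, n_rows, outputs = character(0)) {
  list(stage = name, n_rows = n_rows, outputs = as.list(outputs))
}

#' Run the full cell-specific ceRNA network pipeline
#'
#' Stages, in order: read inputs; expression filter; reference panel;
#' per-cell differential networks intersected with the ceRNA reference;
#' subtype classification; subtype-exclusive edge markers; topology and
#' hub-lncRNA ranking. Writes per-stage TSV outputs under `config$out` and
#' a `manifest.json` recording the package version, parameters, input
#' checksums, per-stage row counts, and output checksums. Identical config
#' and inputs produce identical output checksums.
#'
#' @param config Named list or JSON path; see [validate_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  out_files <- character(0)
  emit <- function(df, file) {
    path <- file.path(cfg$out, file)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    out_files <<- c(out_files, path)
    path
  }

  # 1: read inputs
  expr <- read_expression(cfg$expr, cfg$meta)
  cerna <- read_cerna_reference(cfg$cerna)
  gs <- read_gene_sets(cfg$gmt)
  for (nm in c("early_set", "late_set"))
    if (!cfg[[nm]] %in% names(gs$sets))
      ccn_abort("config", "gene set '%s' not in %s", cfg[[nm]], cfg$gmt)
  ann <- if (!is.null(cfg$annotation)) read_annotation(cfg$annotation) else NULL
  if (!is.null(ann)) expr <- harmonize_symbols(expr, ann)
  stages$data_io <- .stage_entry("data_io", nrow(expr$values))

  # 2: expression filter
  expr <- filter_by_expression(expr, cfg$min_value, cfg$min_fraction)
  flog <- attr(expr, "filter_log")
  stages$filter <- c(.stage_entry("filter", nrow(expr$values)),
                     list(cell_threshold = flog$cell_threshold))

  # 3: reference panel
  panel <- build_reference_panel(expr, alpha = cfg$alpha_ref)
  stages$reference_panel <- .stage_entry("reference_panel", panel$N)

  # 4: CCNs
  ccns <- build_all_ccns(expr, cerna, alpha_edge = cfg$alpha_edge,
                         alpha_diff = cfg$alpha_diff,
                         direction_rule = cfg$direction_rule,
                         edge_universe = cfg$edge_universe,
                         alpha_ref = cfg$alpha_ref)
  log <- attr(ccns, "log")
  emit(log, "ccn_log.tsv")
  ccn_dir <- file.path(cfg$out, "ccn")
  dir.create(ccn_dir, showWarnings = FALSE)
  for (cid in names(ccns))
    out_files <- c(out_files, write_network(ccns[[cid]],
                                            file.path(ccn_dir, paste0(cid, ".tsv"))))
  qmeta <- expr$cell_meta[!expr$cell_meta$is_reference, ]
  groups <- stats::setNames(qmeta$group, qmeta$cell_id)
  summ <- summarize_ccns(ccns, ann, groups)
  emit(summ$summary, "ccn_group_summary.tsv")
  emit(summ$per_cell, "ccn_per_cell.tsv")
  stages$ccn <- .stage_entry("ccn", length(ccns))

  # 5: classify
  background <- switch(cfg$background_rule,
    cerna = intersect(gene_ids(expr), unique(c(cerna$gene_a, cerna$gene_b))),
    all_filtered = gene_ids(expr),
    ccn_abort("config", "unknown background_rule: %s", cfg$background_rule))
  calls <- classify_cells(ccns, gs$sets[[cfg$early_set]],
                          gs$sets[[cfg$late_set]], background,
                          alpha = cfg$alpha_classify)
  calls_out <- cbind(calls, group = unname(groups[calls$cell_id]))
  emit(calls_out, "subtype_calls.tsv")
  stages$classify <- .stage_entry("classify", nrow(calls))

  # 6: edge markers
  markers <- tryCatch(
    select_edge_markers(ccns, calls, top_k = cfg$top_k_markers),
    ccnet_error = function(e) NULL)
  if (!is.null(markers) && nrow(markers$edges)) {
    emit(markers$edges, "marker_edges.tsv")
    dm <- data.frame(edge = rownames(markers$delta), markers$delta,
                     check.names = FALSE, stringsAsFactors = FALSE)
    emit(dm, "marker_delta_matrix.tsv")
    stages$markers <- .stage_entry("markers", nrow(markers$edges))
  } else {
    stages$markers <- .stage_entry("markers", 0L)
  }

  # 7: topology + hub lncRNAs
  topo <- topology_table(ccns)
  emit(topo, "topology.tsv")
  if (!is.null(ann) && any(calls$label == cfg$hub_subtype)) {
    hubs <- rank_hub_lncrnas(ccns, calls, subtype = cfg$hub_subtype,
                             ann = ann, presence_rule = cfg$presence_rule)
    emit(hubs, "hub_lncrnas.tsv")
  }
  stages$topology <- .stage_entry("topology", nrow(topo))

  manifest <- list(
    package = "ccnet",
    version = as.character(utils::packageVersion("ccnet")),
    parameters = cfg[setdiff(names(cfg), "out")],
    input_checksums = as.list(tools::md5sum(unlist(cfg[c("expr", "meta", "cerna", "gmt")]))),
    stages = unname(stages),
    output_checksums = as.list(tools::md5sum(sort(out_files)))
  )
  jsonlite::write_json(manifest, file.path(cfg$out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
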