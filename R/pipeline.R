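#' Run the full prioritization pipeline from a configuration
#'
#' Orchestrates the germline cascade (shared carriers, frequency filters,
#' segregation, tiering), interaction-path annotation, and optionally the
#' somatic cascade, writing TSV reports with embedded filter-trace lines
#' plus JSON trace sidecars. Deterministic given identical inputs.
#'
#' @param config a named list or path to a JSON file. Required fields:
#'   `ped`, `germline_vcf`, `annotations`, `carriers`. Optional: `dbs`,
#'   `pop_threshold`, `internal_threshold`, `tpm_threshold`,
#'   `splice_rules`, `edges`, `somatic_panel`, `susceptibility_panel`,
#'   `tumor_vcf`, `tumor_germline_vcf`, `tumor_individual`,
#'   `somatic_annotations`, `max_edges`.
#' @param out_dir output directory for reports.
#' @return invisibly, a list with `germline` (cascade result and
#'   annotated report rows) and `somatic` (or NULL).
#' @export
run_full <- function(config, out_dir) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  for (field in c("ped", "germline_vcf", "annotations", "carriers")) {
    if (is.null(config[[field]])) stop("config field missing: ", field)
  }
  for (field in c("ped", "germline_vcf", "annotations")) {
    if (!file.exists(config[[field]])) {
      stop("missing input file for ", field, ": ", config[[field]])
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ped <- read_ped(config$ped)
  cohort <- read_cohort_vcf(config$germline_vcf, ped)
  ann <- read_annotation_table(config$annotations)
  res <- run_germline_cascade(cohort, ped, ann, config)

  rows <- merge(res$cohort$variants, res$tiers[, c("variant_id", "tier", "reason")],
                by = "variant_id", sort = FALSE)
  if (!is.null(config$edges)) {
    graph <- read_edges(config$edges)
    targets <- if (!is.null(config$somatic_panel)) read_panel(config$somatic_panel)
               else somatic_gene_panel()
    cand_genes <- rows$gene[rows$tier != "excluded"]
    paths <- find_paths(graph, unique(cand_genes), targets,
                        max_edges = config$max_edges %||% 2)
    rows <- annotate_candidates(rows, paths)
  }
  write_report(rows, res$trace, file.path(out_dir, "germline_report.tsv"))
  jsonlite::write_json(as.data.frame(res$trace),
                       file.path(out_dir, "germline_trace.json"))

  somatic <- NULL
  if (!is.null(config$tumor_vcf)) {
    tum <- read_cohort_vcf(config$tumor_vcf)
    germ <- read_cohort_vcf(config$tumor_germline_vcf %||% config$germline_vcf)
    som_ann <- if (!is.null(config$somatic_annotations)) {
      read_annotation_table(config$somatic_annotations)
    } else ann
    somatic <- run_somatic_cascade(
      tum, germ, config$tumor_individual,
      annotations = som_ann,
      dbs = config$somatic_dbs %||% config$dbs %||% c("1kg", "evs", "exac", "gnomad"),
      threshold = config$somatic_threshold %||% 0.05,
      somatic_panel = if (!is.null(config$somatic_panel)) read_panel(config$somatic_panel) else somatic_gene_panel(),
      susceptibility_panel = if (!is.null(config$susceptibility_panel)) read_panel(config$susceptibility_panel) else susceptibility_gene_panel(),
      candidate_genes = rows$gene[rows$tier != "excluded"])
    write_report(somatic$candidates, somatic$trace,
                 file.path(out_dir, "somatic_report.tsv"))
    jsonlite::write_json(as.data.frame(somatic$trace),
                         file.path(out_dir, "somatic_trace.json"))
  }
  invisible(list(germline = c(res, list(report = rows)), somatic = somatic))
}
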