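# End-to-end orchestration: io -> inference -> annotation ->
# quantification -> concordance -> screen -> report, with a run
# manifest (checksums, row counts, seed) for reproducibility.

#' Build a pipeline configuration
#'
#' @param evidence,annotations,sheet paths to the three input TSVs.
#' @param ko_map optional path to a two-column KO-to-pathway table.
#' @param out_dir output directory.
#' @param min_peptides protein validation threshold (default 2
#'   distinct peptides across the dataset).
#' @param stages screening stages for [iterative_screen()].
#' @param pseudocount heatmap log-transform pseudocount (default 1).
#' @param alpha adjusted-p significance threshold (default 0.05).
#' @param concordance_threshold pairs at or below this Pearson r are
#'   flagged discordant (default 0.9).
#' @param taxon_ranks ranks at which to write taxon-aggregated
#'   abundance matrices.
#' @param seed stored in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(evidence, annotations, sheet, out_dir,
                            ko_map = NULL, min_peptides = 2L,
                            stages = c("ibd_vs_ctrl",
                                       "cdic_vs_other_ibd",
                                       "cdc_vs_uc"),
                            pseudocount = 1, alpha = 0.05,
                            concordance_threshold = 0.9,
                            taxon_ranks = c("phylum", "genus", "species"),
                            seed = 1L) {
  stopifnot(min_peptides >= 1L, pseudocount > 0,
            alpha > 0, alpha < 1)
  structure(list(evidence = evidence, annotations = annotations,
                 sheet = sheet, ko_map = ko_map, out_dir = out_dir,
                 min_peptides = as.integer(min_peptides),
                 stages = stages, pseudocount = pseudocount,
                 alpha = alpha,
                 concordance_threshold = concordance_threshold,
                 taxon_ranks = taxon_ranks, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with the fields of [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

stage_log <- function(stage, t0, ...) {
  counts <- c(...)
  message(sprintf("[%s] %s elapsed=%.2fs", stage,
                  paste(names(counts), counts, sep = "=",
                        collapse = " "),
                  as.numeric(proc.time()[3] - t0)))
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order, writes all result tables under
#' `config$out_dir` and returns (and writes) a manifest listing input
#' checksums, per-stage row counts and output checksums.  Identical
#' configuration and inputs yield byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- c(evidence = config$evidence,
              annotations = config$annotations, sheet = config$sheet)
  if (!is.null(config$ko_map)) inputs["ko_map"] <- config$ko_map
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outp <- function(name) file.path(config$out_dir, name)
  manifest <- list(package = "metapro",
                   version = as.character(utils::packageVersion("metapro")),
                   seed = config$seed,
                   parameters = config[c("min_peptides", "stages",
                                         "pseudocount", "alpha",
                                         "concordance_threshold",
                                         "taxon_ranks")],
                   inputs = lapply(inputs, function(p)
                     list(path = p, md5 = unname(tools::md5sum(p)))),
                   stages = list(), outputs = list())

  t0 <- proc.time()[3]
  evidence <- read_evidence(config$evidence)
  sheet <- read_sample_sheet(config$sheet)
  miss <- setdiff(colnames(evidence$counts), sheet$sample)
  if (length(miss)) {
    stop("evidence sample(s) absent from sample sheet: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  annotations <- resolve_annotations(evidence,
                                     read_annotations(config$annotations))
  ko_map <- if (!is.null(config$ko_map)) {
    read_table_raw(config$ko_map)
  }
  manifest$stages$io <- list(
    n_peptides = length(evidence$peptide),
    n_samples = ncol(evidence$counts),
    n_accessions = length(unique(unlist(evidence$accessions))),
    n_unannotated = length(attr(annotations, "unannotated")))
  stage_log("io", t0, n_peptides = length(evidence$peptide),
            n_samples = ncol(evidence$counts))

  t0 <- proc.time()[3]
  validation <- validate_proteins(evidence, config$min_peptides)
  inference <- infer_subgroups(evidence, validation)
  write_table_plain(subgroups_table(inference), outp("subgroups.tsv"))
  write_table_plain(discarded_table(inference), outp("discarded.tsv"))
  manifest$stages$inference <- list(
    n_retained_accessions = length(validation$retained),
    n_subgroups = length(inference$subgroups),
    n_discarded = length(inference$discarded))
  stage_log("inference", t0, n_subgroups = length(inference$subgroups))

  t0 <- proc.time()[3]
  ann <- annotate_subgroups(inference, annotations)
  write_subgroup_annotations(ann, outp("subgroup_annotations.tsv"))
  manifest$stages$annotation <- list(
    n_annotated_species = sum(ann$consensus_rank == "species"),
    n_with_ko = sum(lengths(ann$kos) > 0))
  stage_log("annotation", t0,
            n_species = sum(ann$consensus_rank == "species"))

  t0 <- proc.time()[3]
  ab <- subgroup_abundance(evidence, inference)
  write_matrix(ab, outp("abundance.tsv"))
  write_matrix(normalize_by_group_size(ab, sheet),
               outp("abundance_group_mean.tsv"))
  for (rank in config$taxon_ranks) {
    write_matrix(aggregate_by_taxon(ab, ann, rank),
                 outp(sprintf("abundance_%s.tsv", rank)))
  }
  write_matrix(aggregate_by_ko(ab, ann), outp("abundance_ko.tsv"))
  if (!is.null(ko_map)) {
    write_matrix(aggregate_by_pathway(ab, ann, ko_map),
                 outp("abundance_pathway.tsv"))
  }
  div <- diversity_summary(ab, ann)
  write_table_plain(div, outp("diversity.tsv"))
  manifest$stages$quantification <- list(
    n_subgroups = nrow(ab), n_samples = ncol(ab),
    total_specific_counts = sum(ab))
  stage_log("quantification", t0, n_subgroups = nrow(ab))

  t0 <- proc.time()[3]
  corr <- pearson_matrix(ab)
  write_matrix(round(corr, 12), outp("correlation.tsv"))
  pairs <- flag_discordant_pairs(corr, sheet,
                                 config$concordance_threshold)
  write_table_plain(pairs, outp("pairs.tsv"))
  cl <- cluster_samples(corr)
  writeLines(cl$newick, outp("dendrogram.nwk"))
  tests <- wilcoxon_bh(div, sheet, alpha = config$alpha)
  write_table_plain(tests, outp("tests.tsv"))
  manifest$stages$concordance <- list(
    n_pairs = nrow(pairs), n_flagged = sum(pairs$flagged),
    n_tests = nrow(tests), n_significant = sum(tests$significant,
                                               na.rm = TRUE))
  stage_log("concordance", t0, n_pairs = nrow(pairs),
            n_flagged = sum(pairs$flagged))

  t0 <- proc.time()[3]
  hits <- iterative_screen(ab, sheet, stages = config$stages)
  write_table_plain(hits, outp("hits.tsv"))
  if (nrow(hits)) {
    write_matrix(heatmap_export(ab, hits, config$pseudocount),
                 outp("heatmap.tsv"))
    report <- proteotypic_report(hits, inference, evidence, ann, sheet)
    write_table_plain(report, outp("biomarker_report.tsv"))
  }
  manifest$stages$screen <- as.list(
    c(n_hits = nrow(hits),
      stats::setNames(
        vapply(config$stages, function(s) sum(hits$stage == s),
               integer(1)),
        paste0("n_", config$stages))))
  stage_log("screen", t0, n_hits = nrow(hits))

  outputs <- list.files(config$out_dir, full.names = FALSE)
  outputs <- setdiff(outputs, "manifest.json")
  manifest$outputs <- lapply(stats::setNames(nm = sort(outputs)),
                             function(f)
                               list(md5 = unname(tools::md5sum(outp(f)))))
  jsonlite::write_json(manifest, outp("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
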