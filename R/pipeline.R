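#' Pipeline configuration
#'
#' Collects every input path and tunable threshold of the integration
#' pipeline. Thresholds default to the values used throughout the package:
#' expression filter CPM >= 5 in >= 3 samples, dysregulation at linear fold
#' change >= 2 and FDR <= 0.05, peak groups at binding fold change 1.5, TSS
#' proximity at 1 kb, association at 10 kb, and 10 random sets of 200 genes.
#'
#' @param input_dir Directory holding `genes.tsv`, `counts.tsv`,
#'   `design.tsv`, `peaks.bed` (as written by [write_fixture()]); individual
#'   paths may be overridden.
#' @param genes_path,counts_path,design_path,peaks_path Explicit input paths.
#' @param known_lists_paths,literature_index_path,druggable_path Optional
#'   triage inputs; triage is skipped when they are `NULL`.
#' @param min_cpm,min_samples Expression filter.
#' @param fc_thresh,fdr_thresh Dysregulation thresholds.
#' @param peak_fc_thresh Peak-group threshold.
#' @param proximity_thresh Proximal/distal boundary, bp.
#' @param assoc_distance Peak-to-gene association distance, bp.
#' @param n_random_sets,random_set_size Random gene-set sampling.
#' @param k_clusters Number of response clusters.
#' @param eligible_clusters Programs eligible for direct-target calls.
#' @param mapping `"distance"` (center-to-TSS) or `"great"`
#'   (basal-plus-extension domains) for the association step.
#' @param seed Pipeline seed; every stochastic stage derives from it.
#' @param output_dir Where [run_pipeline()] writes its tables.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL,
                            genes_path = file.path(input_dir, "genes.tsv"),
                            counts_path = file.path(input_dir, "counts.tsv"),
                            design_path = file.path(input_dir, "design.tsv"),
                            peaks_path = file.path(input_dir, "peaks.bed"),
                            known_lists_paths = NULL,
                            literature_index_path = NULL,
                            druggable_path = NULL,
                            min_cpm = 5, min_samples = 3,
                            fc_thresh = 2, fdr_thresh = 0.05,
                            peak_fc_thresh = 1.5, proximity_thresh = 1000,
                            assoc_distance = 10000, n_random_sets = 10,
                            random_set_size = 200, k_clusters = 3,
                            eligible_clusters = c("A", "C"),
                            mapping = c("distance", "great"),
                            seed = 1, output_dir = NULL) {
  mapping <- match.arg(mapping)
  cfg <- as.list(environment())
  cfg$input_dir <- NULL
  stopifnot(cfg$min_cpm > 0, cfg$min_samples > 0, cfg$fc_thresh > 1,
            cfg$fdr_thresh > 0, cfg$fdr_thresh <= 1, cfg$peak_fc_thresh > 1,
            cfg$proximity_thresh > 0, cfg$assoc_distance >= 0,
            cfg$n_random_sets >= 1, cfg$random_set_size >= 1,
            cfg$k_clusters >= 2)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  keep <- intersect(names(vals), names(formals(pipeline_config)))
  do.call(pipeline_config, vals[keep])
}

#' Integrate expression and binding data in memory
#'
#' The pipeline core, free of file handling: runs both DE contrasts
#' (irradiated wild type vs untreated wild type; irradiated knockout vs
#' untreated wild type), takes the union of dysregulated genes, clusters
#' them into labelled response programs, classifies peaks, builds the
#' cluster-by-peak-group enrichment grid against random gene sets, and calls
#' direct targets.
#'
#' @param genes,counts,design,peaks Input tibbles in the reader shapes.
#' @param config A [pipeline_config()] (paths ignored here).
#' @return A `tf_result` list: `de_wtir`, `de_koir`, `dysregulated`,
#'   `clusters`, `cluster_means`, `peaks`, `association`, `targets`,
#'   `expressed_genes`, `random_sets`, `config`.
#' @export
integrate_targets <- function(genes, counts, design,
                              peaks, config = pipeline_config()) {
  vc <- validate_counts(counts, design)
  counts <- vc$counts
  design <- vc$design

  cpm_raw <- compute_cpm(counts)
  keep <- rowSums(counts_as_matrix(cpm_raw) >= config$min_cpm) >=
    config$min_samples
  counts_f <- counts[keep, , drop = FALSE]
  if (nrow(counts_f) < config$k_clusters) {
    abort("expression stage: too few genes pass the filter")
  }
  norm_factors <- tmm_factors(counts_f)
  de_wtir <- de_contrast(counts_f, design,
                         contrast = list(genotype = "WT", treatment = "IR"),
                         min_cpm = config$min_cpm,
                         min_samples = config$min_samples,
                         norm_factors = norm_factors) %>%
    call_dysregulated(config$fc_thresh, config$fdr_thresh)
  de_koir <- de_contrast(counts_f, design,
                         contrast = list(genotype = "KO", treatment = "IR"),
                         min_cpm = config$min_cpm,
                         min_samples = config$min_samples,
                         norm_factors = norm_factors) %>%
    call_dysregulated(config$fc_thresh, config$fdr_thresh)
  dysregulated <- union(de_wtir$gene_id[de_wtir$called],
                        de_koir$gene_id[de_koir$called])
  if (length(dysregulated) < config$k_clusters) {
    abort("expression stage: too few dysregulated genes to cluster")
  }

  rel <- relative_expression(counts_f, design, norm_factors = norm_factors)
  rel_dys <- rel[rel$gene_id %in% dysregulated, , drop = FALSE]
  clusters <- cluster_programs(rel_dys, design = design,
                               k = config$k_clusters)
  cmeans <- cluster_condition_means(clusters, rel_dys, design)
  clusters <- label_clusters(clusters, cmeans)

  peaks_cl <- peak_analyze(peaks, genes,
                           peak_fc_thresh = config$peak_fc_thresh,
                           proximity_thresh = config$proximity_thresh)

  expressed <- counts_f$gene_id
  random_sets <- sample_random_gene_sets(
    expressed, n_sets = config$n_random_sets,
    set_size = min(config$random_set_size, length(expressed)),
    seed = config$seed + 1L
  )
  if (config$mapping == "great") {
    chrom_sizes <- genes %>%
      group_by(.data$chrom) %>%
      summarise(size = max(.data$end) + 250000, .groups = "drop")
    domains <- great_domains(
      genes, chrom_sizes = setNames(chrom_sizes$size, chrom_sizes$chrom))
    assignment <- peaks_in_domains(peaks_cl, domains)
  } else {
    assignment <- NULL
  }
  association <- association_table(clusters, peaks_cl, genes, random_sets,
                                   d = config$assoc_distance)
  targets <- call_direct_targets(clusters, peaks_cl, genes,
                                 d = config$assoc_distance,
                                 eligible_clusters = config$eligible_clusters)
  structure(
    list(de_wtir = de_wtir, de_koir = de_koir, dysregulated = dysregulated,
         clusters = clusters, cluster_means = cmeans, peaks = peaks_cl,
         association = association, targets = targets,
         domain_assignment = assignment, expressed_genes = expressed,
         random_sets = random_sets, config = config),
    class = "tf_result"
  )
}

#' Run the full pipeline from files
#'
#' Reads the configured inputs, runs [integrate_targets()], optionally runs
#' triage when reference lists are configured, and writes `de_results.tsv`,
#' `clusters.tsv`, `peak_groups.tsv`, `association_stats.tsv`,
#' `direct_targets.tsv`, `triage_report.tsv` (when applicable), `summary.tsv`
#' and `run_log.txt` to the output directory. Every table carries a header
#' comment with the configuration hash; a failing stage aborts with the
#' stage name.
#'
#' @param config A [pipeline_config()] with paths and `output_dir` set.
#' @return The output directory, invisibly; the `tf_result` is attached as
#'   attribute `"result"`.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$output_dir)) abort("config$output_dir is not set")
  inputs <- c(config$genes_path, config$counts_path, config$design_path,
              config$peaks_path)
  for (p in inputs) {
    if (!file.exists(p)) abort(sprintf("input stage: file not found: %s", p))
  }
  genes <- read_gene_models(config$genes_path)
  peaks <- read_peaks(config$peaks_path)
  cm <- read_count_matrix(config$counts_path, config$design_path)

  res <- withCallingHandlers(
    integrate_targets(genes, cm$counts, cm$design, peaks, config),
    error = function(e) abort(sprintf("pipeline failed: %s", conditionMessage(e)))
  )

  triage <- NULL
  if (!is.null(config$known_lists_paths) &&
      !is.null(config$literature_index_path) &&
      !is.null(config$druggable_path)) {
    triage <- triage_targets(
      res$targets,
      known_lists = load_gene_lists(config$known_lists_paths),
      index = read_literature_index(config$literature_index_path),
      druggable_set = read_druggable_set(config$druggable_path)
    )
    res$triage <- triage
  }

  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  wt <- function(x, name) write_result_tsv(x, file.path(config$output_dir, name), hash)
  de_out <- dplyr::bind_rows(
    de_wtir = as_tibble(res$de_wtir), de_koir = as_tibble(res$de_koir),
    .id = "contrast"
  )
  wt(de_out, "de_results.tsv")
  wt(res$clusters, "clusters.tsv")
  wt(as_tibble(res$peaks), "peak_groups.tsv")
  wt(as_tibble(res$association), "association_stats.tsv")
  wt(as_tibble(res$targets), "direct_targets.tsv")
  if (!is.null(triage)) wt(as_tibble(triage), "triage_report.tsv")
  summary_tbl <- summarize_result(res)
  wt(summary_tbl, "summary.tsv")
  writeLines(c(
    sprintf("# targetfuse run %s", hash),
    sprintf("package_version: %s", as.character(utils::packageVersion("targetfuse"))),
    sprintf("seed: %d", config$seed),
    sprintf("mapping: %s", config$mapping),
    paste0("params: ", paste(sprintf("%s=%s",
      c("min_cpm", "min_samples", "fc_thresh", "fdr_thresh", "peak_fc_thresh",
        "proximity_thresh", "assoc_distance", "n_random_sets",
        "random_set_size", "k_clusters"),
      vapply(config[c("min_cpm", "min_samples", "fc_thresh", "fdr_thresh",
                      "peak_fc_thresh", "proximity_thresh", "assoc_distance",
                      "n_random_sets", "random_set_size", "k_clusters")],
             function(x) format(x, scientific = FALSE), "")), collapse = " ")),
    sprintf("eligible_clusters: %s", paste(config$eligible_clusters, collapse = ",")),
    sprintf("n_genes_input: %d", nrow(cm$counts)),
    sprintf("n_expressed: %d", length(res$expressed_genes)),
    sprintf("n_dysregulated: %d", length(res$dysregulated)),
    sprintf("n_peaks: %d", nrow(res$peaks)),
    sprintf("n_direct_targets: %d", length(direct_target_genes(res$targets)))
  ), file.path(config$output_dir, "run_log.txt"))
  out <- config$output_dir
  attr(out, "result") <- res
  invisible(out)
}

#' One-page summary of a pipeline result
#'
#' @param res A `tf_result` from [integrate_targets()].
#' @return A two-column tibble (`quantity`, `value`) with expressed,
#'   dysregulated (up/down), cluster, peak-group, proximity, target and
#'   novelty counts; proximity also as percentages.
#' @export
summarize_result <- function(res) {
  de_union <- dplyr::bind_rows(res$de_wtir, res$de_koir) %>%
    filter(.data$called) %>%
    group_by(.data$gene_id) %>%
    summarise(direction = .data$direction[1], .groups = "drop")
  ps <- peak_group_summary(res$peaks)
  cl_sizes <- table(factor(res$clusters$label, levels = c("A", "B", "C")))
  vals <- c(
    n_expressed = length(res$expressed_genes),
    n_dysregulated = nrow(de_union),
    n_up = sum(de_union$direction == "up"),
    n_down = sum(de_union$direction == "down"),
    n_cluster_A = unname(cl_sizes["A"]),
    n_cluster_B = unname(cl_sizes["B"]),
    n_cluster_C = unname(cl_sizes["C"]),
    n_peaks = ps$n_peaks, n_group_I = ps$n_group_I,
    n_group_II = ps$n_group_II, n_group_III = ps$n_group_III,
    n_proximal = ps$n_proximal, n_distal = ps$n_distal,
    pct_proximal = ps$pct_proximal, pct_distal = ps$pct_distal,
    n_direct_targets = length(direct_target_genes(res$targets)),
    n_novel = if (!is.null(res$triage)) sum(res$triage$novel) else NA_real_
  )
  tibble(quantity = names(vals), value = unname(vals))
}

#' Summarize a completed run directory
#'
#' Recomputes the one-page summary from the tables a [run_pipeline()] call
#' wrote.
#'
#' @param output_dir A completed run directory.
#' @return A tibble (`quantity`, `value`).
#' @export
summarize_run <- function(output_dir) {
  need <- c("de_results.tsv", "clusters.tsv", "peak_groups.tsv",
            "direct_targets.tsv")
  missing <- need[!file.exists(file.path(output_dir, need))]
  if (length(missing) > 0) {
    abort(sprintf("incomplete run directory; missing: %s",
                  paste(missing, collapse = ", ")))
  }
  rd <- function(name) readr::read_tsv(file.path(output_dir, name),
                                       comment = "#", show_col_types = FALSE,
                                       progress = FALSE)
  de <- rd("de_results.tsv")
  clusters <- rd("clusters.tsv")
  peaks <- rd("peak_groups.tsv")
  targets <- rd("direct_targets.tsv")
  de_union <- de %>%
    filter(.data$called) %>%
    group_by(.data$gene_id) %>%
    summarise(direction = .data$direction[1], .groups = "drop")
  n_prox <- sum(peaks$proximity == "proximal", na.rm = TRUE)
  n_dist <- sum(peaks$proximity == "distal", na.rm = TRUE)
  cl_sizes <- table(factor(clusters$label, levels = c("A", "B", "C")))
  triage_path <- file.path(output_dir, "triage_report.tsv")
  vals <- c(
    n_expressed = length(unique(de$gene_id)),
    n_dysregulated = nrow(de_union),
    n_up = sum(de_union$direction == "up"),
    n_down = sum(de_union$direction == "down"),
    n_cluster_A = unname(cl_sizes["A"]),
    n_cluster_B = unname(cl_sizes["B"]),
    n_cluster_C = unname(cl_sizes["C"]),
    n_peaks = nrow(peaks),
    n_group_I = sum(peaks$group == "I"),
    n_group_II = sum(peaks$group == "II"),
    n_group_III = sum(peaks$group == "III"),
    n_proximal = n_prox, n_distal = n_dist,
    pct_proximal = 100 * n_prox / nrow(peaks),
    pct_distal = 100 * n_dist / nrow(peaks),
    n_direct_targets = length(unique(targets$gene_id[targets$is_direct_target])),
    n_novel = if (file.exists(triage_path)) sum(rd("triage_report.tsv")$novel)
      else NA_real_
  )
  tibble(quantity = names(vals), value = unname(vals))
}

config_hash <- function(config) {
  config <- config[setdiff(names(config), "output_dir")]
  flat <- paste(names(config),
                vapply(config, function(x) paste(format(x), collapse = ","), ""),
                sep = "=", collapse = ";")
  # small rolling hash; auditability only, not cryptographic
  h <- 0
  for (ch in utf8ToInt(flat)) h <- (h * 31 + ch) %% 2147483647
  sprintf("cfg_%08x", h)
}

write_result_tsv <- function(x, path, hash) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
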