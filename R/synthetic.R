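#' Synthetic-scenario configuration
#'
#' Defaults describe a desk-scale analogue of a 2-genotype x 2-treatment
#' irradiation study: one 50-Mb chromosome, 2,000 expressed genes, three
#' planted response programs (150 A-like genes, TF-dependent induction with
#' log2 fold changes ~ Normal(2, 0.5); 50 B-like, TF-independent induction;
#' 80 C-like, TF-dependent repression with mean -2), NB dispersion 0.1,
#' 3 replicates per condition, 600/50/100 Group I/II/III peaks, and 70% of
#' A-like genes receiving a planted Group-I peak within the association
#' distance.
#'
#' @param n_genes Number of genes.
#' @param chrom_length Chromosome length in bp.
#' @param chrom Chromosome name.
#' @param n_a,n_b,n_c Planted program gene counts.
#' @param lfc_mean_a,lfc_mean_b,lfc_mean_c,lfc_sd Planted log2 fold-change
#'   distributions per program.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param baseline_meanlog,baseline_sdlog,baseline_min Log-normal baseline
#'   mean-count distribution, floored at `baseline_min` (the generator
#'   emulates a post-filter panel of expressed genes, so very low baselines
#'   are excluded).
#' @param replicates Replicates per condition (4 conditions).
#' @param n_peaks_i,n_peaks_ii,n_peaks_iii Peak counts per group.
#' @param planted_fraction Fraction of A-like genes receiving a planted
#'   Group-I peak within `assoc_distance`.
#' @param assoc_distance Planting (and downstream association) distance, bp.
#' @param peak_width Peak interval width, bp.
#' @param signal_meanlog,signal_sdlog Log-normal untreated binding-signal
#'   distribution (arbitrary units).
#' @param peak_fc_min,peak_fc_max True binding fold-change range for Group I
#'   (Group III uses the reciprocal range).
#' @param signal_noise_sd SD of multiplicative log-normal noise applied to
#'   each emitted signal.
#' @param seed Integer seed; identical seeds give byte-identical fixtures.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_genes = 2000, chrom_length = 5e7,
                            chrom = "chr1", n_a = 150, n_b = 50, n_c = 80,
                            lfc_mean_a = 2, lfc_mean_b = 2, lfc_mean_c = -2,
                            lfc_sd = 0.5, dispersion = 0.1,
                            baseline_meanlog = log(100), baseline_sdlog = 1,
                            baseline_min = 10, replicates = 3,
                            n_peaks_i = 600, n_peaks_ii = 50,
                            n_peaks_iii = 100, planted_fraction = 0.7,
                            assoc_distance = 10000, peak_width = 400,
                            signal_meanlog = log(5), signal_sdlog = 0.5,
                            peak_fc_min = 2, peak_fc_max = 6,
                            signal_noise_sd = 0.15, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_a + cfg$n_b + cfg$n_c <= cfg$n_genes,
            cfg$n_genes > 0, cfg$replicates >= 2, cfg$dispersion > 0,
            cfg$planted_fraction >= 0, cfg$planted_fraction <= 1)
  structure(cfg, class = "scenario_config")
}

#' Generate a synthetic scenario with a truth manifest
#'
#' Places non-overlapping genes along the chromosome, assigns planted
#' response programs, draws NB counts with program-specific mean shifts
#' (A and C shift in WT-IR only; B shifts in both IR conditions), places
#' Group-I peaks near a configured fraction of A-like TSSs plus uniform
#' background peaks of all three groups, draws untreated/irradiated binding
#' signals consistent with the group labels plus multiplicative noise, and
#' records every planted fact in a truth manifest. True direct targets are
#' the A/C-program genes with at least one emitted peak center within the
#' association distance of their TSS (background peaks can create genuine
#' associations, so the manifest is computed from the emitted peak set, not
#' only from the planted links).
#'
#' @param config A [scenario_config()].
#' @return A `tf_scenario` list: `genes`, `counts`, `design`, `peaks`,
#'   `coverage_ut`, `coverage_ir`, `truth`, `config`.
#' @export
generate_scenario <- function(config = scenario_config()) {
  withr::with_seed(config$seed, generate_scenario_impl(config))
}

generate_scenario_impl <- function(cfg) {
  genes <- place_genes(cfg)
  program <- rep("null", cfg$n_genes)
  planted_idx <- sample(cfg$n_genes, cfg$n_a + cfg$n_b + cfg$n_c)
  program[planted_idx] <- rep(c("A", "B", "C"), c(cfg$n_a, cfg$n_b, cfg$n_c))

  lfc <- numeric(cfg$n_genes)
  lfc[program == "A"] <- rnorm(cfg$n_a, cfg$lfc_mean_a, cfg$lfc_sd)
  lfc[program == "B"] <- rnorm(cfg$n_b, cfg$lfc_mean_b, cfg$lfc_sd)
  lfc[program == "C"] <- rnorm(cfg$n_c, cfg$lfc_mean_c, cfg$lfc_sd)

  baseline <- pmax(cfg$baseline_min,
                   rlnorm(cfg$n_genes, cfg$baseline_meanlog, cfg$baseline_sdlog))
  # true linear fold changes per contrast (vs untreated WT)
  fc_wtir <- ifelse(program %in% c("A", "B", "C"), 2^lfc, 1)
  fc_koir <- ifelse(program == "B", 2^lfc, 1)

  design <- tidyr::expand_grid(
    genotype = c("WT", "KO"), treatment = c("UT", "IR"),
    replicate = seq_len(cfg$replicates)
  ) %>%
    mutate(sample = sprintf("%s_%s_%d", .data$genotype, .data$treatment,
                            .data$replicate)) %>%
    select("sample", "genotype", "treatment", "replicate")

  cond_fc <- list(WT_UT = rep(1, cfg$n_genes), WT_IR = fc_wtir,
                  KO_UT = rep(1, cfg$n_genes), KO_IR = fc_koir)
  counts <- tibble(gene_id = genes$gene_id)
  for (s in design$sample) {
    key <- sub("_[0-9]+$", "", s)
    mu <- baseline * cond_fc[[key]]
    counts[[s]] <- rnbinom(cfg$n_genes, mu = mu, size = 1 / cfg$dispersion)
  }

  pk <- place_peaks(cfg, genes, program)
  peaks <- pk$peaks
  coverage_ut <- peaks %>%
    select("chrom", "start", "end") %>%
    mutate(value = round(peaks$signal_ut, 4)) %>%
    arrange(.data$chrom, .data$start)
  coverage_ir <- peaks %>%
    select("chrom", "start", "end") %>%
    mutate(value = round(peaks$signal_ir, 4)) %>%
    arrange(.data$chrom, .data$start)

  # truth: direct targets judged against the emitted peak set
  assoc <- genes_with_peak_within(
    genes %>% mutate(tss = ifelse(.data$strand == "+", .data$start,
                                  .data$end - 1L)),
    peaks, d = cfg$assoc_distance
  )
  # a planted gene whose drawn effect is below the study's 2-fold
  # dysregulation definition is not a true dysregulated gene; truth gates on
  # the same effect-size definition the analysis uses
  truly_dysregulated <- program != "null" & abs(lfc) >= 1
  truth <- list(
    gene_programs = tibble(gene_id = genes$gene_id, program = program,
                           true_log2fc_wtir = ifelse(program == "null", 0, lfc),
                           true_log2fc_koir = ifelse(program == "B", lfc, 0),
                           truly_dysregulated = truly_dysregulated),
    peak_truth = pk$peak_truth,
    direct_targets = genes$gene_id[program %in% c("A", "C") &
                                     truly_dysregulated &
                                     genes$gene_id %in% assoc]
  )
  structure(list(genes = genes, counts = counts, design = design,
                 peaks = peaks, coverage_ut = coverage_ut,
                 coverage_ir = coverage_ir, truth = truth, config = cfg),
            class = "tf_scenario")
}

place_genes <- function(cfg) {
  spacing <- cfg$chrom_length / cfg$n_genes
  max_len <- 10000
  margin <- 2500 # keeps 2-kb basal domains of neighbours from overlapping
  if (spacing < max_len + 2 * margin + 1) {
    abort(sprintf("cannot place %d genes on %g bp without basal overlap",
                  cfg$n_genes, cfg$chrom_length))
  }
  len <- as.integer(round(runif(cfg$n_genes, 1000, max_len)))
  slot <- (seq_len(cfg$n_genes) - 1) * spacing
  start <- as.integer(floor(slot + margin +
                              runif(cfg$n_genes) * (spacing - len - 2 * margin)))
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  tibble(
    gene_id = sprintf("gene_%04d", seq_len(cfg$n_genes)),
    symbol = sprintf("Gene%04d", seq_len(cfg$n_genes)),
    chrom = cfg$chrom,
    start = start,
    end = start + len,
    strand = strand,
    tss = ifelse(strand == "+", start, start + len - 1L)
  )
}

place_peaks <- function(cfg, genes, program) {
  w <- cfg$peak_width
  half <- w %/% 2
  a_idx <- which(program == "A")
  n_planted <- round(cfg$planted_fraction * length(a_idx))
  planted_genes <- if (n_planted > 0) sort(sample(a_idx, n_planted)) else integer()

  centers <- integer(0)
  group <- character(0)
  linked <- character(0)
  if (n_planted > 0) {
    max_off <- cfg$assoc_distance - 1L
    off <- as.integer(round(runif(n_planted, -max_off, max_off)))
    centers <- genes$tss[planted_genes] + off
    group <- rep("I", n_planted)
    linked <- genes$gene_id[planted_genes]
  }
  n_bg <- c(I = cfg$n_peaks_i - n_planted, II = cfg$n_peaks_ii,
            III = cfg$n_peaks_iii)
  if (any(n_bg < 0)) abort("more planted peaks than configured Group-I peaks")
  for (grp in names(n_bg)) {
    centers <- c(centers, as.integer(round(
      runif(n_bg[[grp]], half + 1, cfg$chrom_length - half - 1))))
    group <- c(group, rep(grp, n_bg[[grp]]))
    linked <- c(linked, rep(NA_character_, n_bg[[grp]]))
  }
  centers <- pmin(pmax(centers, half + 1L), as.integer(cfg$chrom_length - half - 1L))

  # enforce non-overlapping peak intervals (valid bedGraph output) by
  # nudging any colliding peak; collisions are rare at default density
  for (iter in 1:200) {
    o <- order(centers)
    gap_ok <- diff(centers[o]) >= w + 2L
    if (all(gap_ok)) break
    bump <- o[which(!gap_ok) + 1]
    centers[bump] <- centers[bump] +
      as.integer(round(runif(length(bump), w + 2, 5 * w)))
    centers <- pmin(pmax(centers, half + 1L),
                    as.integer(cfg$chrom_length - half - 1L))
    if (iter == 200) abort("could not place non-overlapping peaks")
  }

  n <- length(centers)
  true_fc <- rep(1, n)
  true_fc[group == "I"] <- runif(sum(group == "I"), cfg$peak_fc_min,
                                 cfg$peak_fc_max)
  true_fc[group == "III"] <- 1 / runif(sum(group == "III"), cfg$peak_fc_min,
                                       cfg$peak_fc_max)
  signal_ut <- rlnorm(n, cfg$signal_meanlog, cfg$signal_sdlog)
  noise <- function(k) rlnorm(k, 0, cfg$signal_noise_sd)
  peaks <- tibble(
    peak_id = sprintf("peak_%05d", seq_len(n)),
    chrom = cfg$chrom,
    start = as.integer(centers - half),
    end = as.integer(centers - half + w),
    signal_ut = round(signal_ut * noise(n), 4),
    signal_ir = round(signal_ut * true_fc * noise(n), 4)
  )
  peak_truth <- tibble(peak_id = peaks$peak_id, true_group = group,
                       true_fc = true_fc, linked_gene = linked)
  list(peaks = peaks, peak_truth = peak_truth)
}

#' Write a scenario to disk as a fixture directory
#'
#' Emits `genes.tsv`, `counts.tsv`, `design.tsv`, `peaks.bed`,
#' `coverage_ut.bedGraph`, `coverage_ir.bedGraph` and `truth.json` in the
#' formats the package readers accept; a seeded scenario writes byte-identical
#' files on every run.
#'
#' @param scenario A `tf_scenario` from [generate_scenario()].
#' @param directory Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_fixture <- function(scenario, directory) {
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE)
  if (!ok) abort(sprintf("cannot create directory: %s", directory))
  write_gene_models(scenario$genes, file.path(directory, "genes.tsv"))
  readr::write_tsv(scenario$counts, file.path(directory, "counts.tsv"),
                   progress = FALSE)
  readr::write_tsv(scenario$design, file.path(directory, "design.tsv"),
                   progress = FALSE)
  write_peaks(scenario$peaks, file.path(directory, "peaks.bed"))
  write_bedgraph(scenario$coverage_ut,
                 file.path(directory, "coverage_ut.bedGraph"))
  write_bedgraph(scenario$coverage_ir,
                 file.path(directory, "coverage_ir.bedGraph"))
  truth <- scenario$truth
  jsonlite::write_json(
    list(gene_programs = truth$gene_programs, peak_truth = truth$peak_truth,
         direct_targets = truth$direct_targets,
         config = scenario$config[setdiff(names(scenario$config), "")]),
    file.path(directory, "truth.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(directory)
}

#' Read a truth manifest back from a fixture directory
#'
#' @param directory Fixture directory written by [write_fixture()].
#' @return A list with `gene_programs`, `peak_truth` (tibbles),
#'   `direct_targets` (character) and `config`.
#' @export
read_truth <- function(directory) {
  path <- file.path(directory, "truth.json")
  if (!file.exists(path)) abort(sprintf("truth manifest not found: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(gene_programs = as_tibble(raw$gene_programs),
       peak_truth = as_tibble(raw$peak_truth),
       direct_targets = as.character(unlist(raw$direct_targets)),
       config = raw$config)
}
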