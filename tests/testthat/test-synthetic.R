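small_cfg <- function(seed = 3) {
  scenario_config(n_genes = 300, chrom_length = 1e7, n_a = 30, n_b = 10,
                  n_c = 15, n_peaks_i = 90, n_peaks_ii = 10, n_peaks_iii = 20,
                  seed = seed)
}

test_that("identical seeds give byte-identical fixtures", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture(generate_scenario(small_cfg(seed = 5)), d1)
  write_fixture(generate_scenario(small_cfg(seed = 5)), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # and a different seed differs
  d3 <- withr::local_tempdir()
  write_fixture(generate_scenario(small_cfg(seed = 6)), d3)
  expect_false(identical(readLines(file.path(d1, "counts.tsv")),
                         readLines(file.path(d3, "counts.tsv"))))
})

test_that("manifest program counts equal the configuration", {
  sc <- generate_scenario(small_cfg())
  tab <- table(sc$truth$gene_programs$program)
  expect_equal(unname(tab[c("A", "B", "C")]), c(30, 10, 15),
               ignore_attr = TRUE)
  expect_equal(sum(tab), 300)
  expect_equal(nrow(sc$counts), 300)
  expect_equal(nrow(sc$design), 12)
})

test_that("planted effect sizes match the generating distribution", {
  sc <- generate_scenario(scenario_config(seed = 21))
  gp <- sc$truth$gene_programs
  a <- gp$true_log2fc_wtir[gp$program == "A"]
  # mean of 150 draws from Normal(2, 0.5): within 3 SE
  expect_lt(abs(mean(a) - 2), 3 * 0.5 / sqrt(length(a)))
  c_l2 <- gp$true_log2fc_wtir[gp$program == "C"]
  expect_lt(abs(mean(c_l2) + 2), 3 * 0.5 / sqrt(length(c_l2)))
  # B-like genes shift in both irradiated conditions, A/C only in wild type
  expect_true(all(gp$true_log2fc_koir[gp$program %in% c("A", "C")] == 0))
  expect_equal(gp$true_log2fc_koir[gp$program == "B"],
               gp$true_log2fc_wtir[gp$program == "B"])
})

test_that("realized counts carry the planted fold changes", {
  sc <- generate_scenario(scenario_config(seed = 33))
  gp <- sc$truth$gene_programs
  m <- as.matrix(sc$counts[, -1])
  wt <- sc$design$sample[sc$design$genotype == "WT" & sc$design$treatment == "UT"]
  wtir <- sc$design$sample[sc$design$genotype == "WT" & sc$design$treatment == "IR"]
  obs_l2 <- log2((rowMeans(m[, wtir]) + 0.5) / (rowMeans(m[, wt]) + 0.5))
  a_rows <- gp$program == "A"
  expect_equal(mean(obs_l2[a_rows]), mean(gp$true_log2fc_wtir[a_rows]),
               tolerance = 0.1)
  null_rows <- gp$program == "null"
  expect_lt(abs(mean(obs_l2[null_rows])), 0.05)
})

test_that("fixtures round-trip through the package readers", {
  dir <- withr::local_tempdir()
  sc <- generate_scenario(small_cfg())
  write_fixture(sc, dir)
  genes <- read_gene_models(file.path(dir, "genes.tsv"))
  expect_equal(genes, sc$genes)
  peaks <- read_peaks(file.path(dir, "peaks.bed"))
  expect_equal(peaks, sc$peaks)
  cm <- read_count_matrix(file.path(dir, "counts.tsv"),
                          file.path(dir, "design.tsv"))
  expect_equal(cm$counts, sc$counts)
  expect_equal(as.data.frame(cm$design), as.data.frame(sc$design))
  cov <- read_bedgraph_file(file.path(dir, "coverage_ut.bedGraph"))
  expect_equal(nrow(cov), nrow(sc$peaks))
  truth <- read_truth(dir)
  expect_equal(truth$direct_targets, sc$truth$direct_targets)
  expect_equal(nrow(truth$gene_programs), 300)
})

test_that("planted peak-gene links satisfy the association distance", {
  sc <- generate_scenario(small_cfg(seed = 12))
  pt <- sc$truth$peak_truth
  linked <- pt[!is.na(pt$linked_gene), ]
  expect_gt(nrow(linked), 0)
  peaks <- sc$peaks %>%
    dplyr::mutate(center = peak_center(.data$start, .data$end))
  for (i in seq_len(nrow(linked))) {
    tss <- sc$genes$tss[sc$genes$gene_id == linked$linked_gene[i]]
    center <- peaks$center[peaks$peak_id == linked$peak_id[i]]
    expect_lte(abs(center - tss), sc$config$assoc_distance)
  }
  expect_true(all(linked$true_group == "I"))
  # coverage runs are the emitted peak intervals: non-overlapping, sorted
  expect_true(all(diff(sc$coverage_ut$start) > 0))
})

test_that("infeasible gene placement errors out", {
  expect_error(generate_scenario(scenario_config(n_genes = 5000,
                                                 chrom_length = 1e6,
                                                 n_a = 0, n_b = 0, n_c = 0)),
               "cannot place")
})
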