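test_that("nearest_tss finds the closest TSS with lexicographic tie-breaks", {
  genes <- parse_gene_models(c("gb\tB\tchr1\t400\t900\t+",
                               "gc\tC\tchr1\t700\t1200\t+"))
  peaks <- tibble::tibble(peak_id = "p", chrom = "chr1", center = 500L)
  nt <- nearest_tss(peaks, genes)
  expect_equal(nt$nearest_gene, "gb")
  expect_equal(nt$distance, 100L)

  # equidistant TSSs -> lexicographically smaller id
  genes2 <- parse_gene_models(c("gz\tZ\tchr1\t400\t900\t+",
                                "ga\tA\tchr1\t600\t1200\t+"))
  nt2 <- nearest_tss(peaks, genes2)
  expect_equal(nt2$nearest_gene, "ga")

  # peak on a chromosome without genes -> NA
  peaks3 <- tibble::tibble(peak_id = "p3", chrom = "chrX", center = 5L)
  expect_true(is.na(nearest_tss(peaks3, genes)$nearest_gene))
})

test_that("nearest_tss equals an exhaustive scan on random layouts", {
  set.seed(17)
  for (rep in 1:25) {
    n_g <- sample(3:30, 1)
    genes <- tibble::tibble(
      gene_id = sprintf("g%02d", sample(n_g)),
      chrom = sample(c("chr1", "chr2"), n_g, replace = TRUE),
      tss = sample.int(10000, n_g, replace = TRUE)
    )
    peaks <- tibble::tibble(peak_id = sprintf("p%02d", 1:10),
                            chrom = sample(c("chr1", "chr2"), 10, TRUE),
                            center = sample.int(10000, 10, TRUE))
    got <- nearest_tss(peaks, genes)
    for (i in 1:10) {
      g <- genes[genes$chrom == peaks$chrom[i], ]
      if (nrow(g) == 0) {
        expect_true(is.na(got$nearest_gene[i]))
        next
      }
      d <- abs(peaks$center[i] - g$tss)
      expect_equal(got$distance[i], as.integer(min(d)))
      expect_equal(got$nearest_gene[i], min(g$gene_id[d == min(d)]))
    }
  }
})

test_that("distance association is inclusive at d and monotone in d", {
  genes <- parse_gene_models("g1\tG\tchr1\t5000\t6000\t+")
  mk_peak <- function(center) {
    tibble::tibble(peak_id = "p", chrom = "chr1", center = as.integer(center))
  }
  expect_equal(genes_with_peak_within(genes, mk_peak(15000), d = 10000), "g1")
  expect_equal(genes_with_peak_within(genes, mk_peak(15001), d = 10000),
               character())
  expect_equal(genes_with_peak_within(genes, mk_peak(15000)[0, ], d = 10000),
               character())

  set.seed(23)
  genes_r <- tibble::tibble(gene_id = sprintf("g%03d", 1:50), chrom = "chr1",
                            tss = sample.int(1e6, 50))
  peaks_r <- tibble::tibble(peak_id = sprintf("p%03d", 1:30), chrom = "chr1",
                            center = sample.int(1e6, 30))
  prev <- character()
  for (d in c(0, 100, 1000, 10000, 1e5, 1e6)) {
    cur <- genes_with_peak_within(genes_r, peaks_r, d = d)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("regulatory domains: basal, extension capping, neighbour stops", {
  sizes <- c(chr1 = 1e6)
  solo <- tibble::tibble(gene_id = "g1", symbol = "G", chrom = "chr1",
                         start = 500000L, end = 510000L, strand = "+",
                         tss = 500000L)
  dom <- great_domains(solo, chrom_sizes = sizes)
  expect_equal(dom$start, 298000L)
  expect_equal(dom$end, 702000L)

  # neighbour 10 kb away stops the extension at its basal edge
  pair <- tibble::tibble(
    gene_id = c("g1", "g2"), symbol = c("A", "B"), chrom = "chr1",
    start = c(100000L, 110000L), end = c(105000L, 115000L),
    strand = "+", tss = c(100000L, 110000L)
  )
  dp <- great_domains(pair, chrom_sizes = sizes)
  expect_equal(dp$end[dp$gene_id == "g1"], 108000L)   # g2 basal start
  expect_equal(dp$start[dp$gene_id == "g2"], 102000L) # g1 basal end

  # clipping at chromosome start
  edge <- tibble::tibble(gene_id = "g1", symbol = "G", chrom = "chr1",
                         start = 1000L, end = 3000L, strand = "+",
                         tss = 1000L)
  expect_equal(great_domains(edge, chrom_sizes = sizes)$start, 0L)
})

test_that("regulatory domains respect invariants on random layouts", {
  set.seed(41)
  sizes <- c(chr1 = 2e6)
  for (rep in 1:15) {
    n <- sample(5:25, 1)
    tss <- sort(sample.int(2e6 - 1000, n))
    genes <- tibble::tibble(
      gene_id = sprintf("g%02d", 1:n), symbol = sprintf("G%02d", 1:n),
      chrom = "chr1", start = tss, end = tss + 500L,
      strand = "+", tss = tss
    )
    dom <- great_domains(genes, chrom_sizes = sizes)
    # basal contained in domain; domain within chromosome
    expect_true(all(dom$start <= dom$basal_start))
    expect_true(all(dom$end >= dom$basal_end))
    expect_true(all(dom$start >= 0 & dom$end <= 2e6))
    # no extension crosses a neighbour's basal region
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      left_ext <- c(dom$start[i], dom$basal_start[i])
      right_ext <- c(dom$basal_end[i], dom$end[i])
      for (ext in list(left_ext, right_ext)) {
        ov <- min(ext[2], dom$basal_end[j]) - max(ext[1], dom$basal_start[j])
        expect_lte(ov, 0)
      }
    }
  }
})

test_that("peaks map to every domain containing their center", {
  domains <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1",
                            start = c(0L, 500L), end = c(1000L, 1500L))
  peaks <- tibble::tibble(peak_id = c("pa", "pb", "pc"), chrom = "chr1",
                          center = c(100L, 700L, 1400L))
  got <- peaks_in_domains(peaks, domains)
  expect_equal(got$gene_id[got$peak_id == "pa"], "g1")
  expect_setequal(got$gene_id[got$peak_id == "pb"], c("g1", "g2"))
  expect_equal(got$gene_id[got$peak_id == "pc"], "g2")
  outside <- tibble::tibble(peak_id = "px", chrom = "chr1", center = 5000L)
  expect_equal(nrow(peaks_in_domains(outside, domains)), 0)
})

test_that("random gene sets are seeded, within-population, duplicate-free", {
  pop <- sprintf("g%03d", 1:300)
  s1 <- sample_random_gene_sets(pop, n_sets = 10, set_size = 200, seed = 5)
  s2 <- sample_random_gene_sets(pop, n_sets = 10, set_size = 200, seed = 5)
  expect_identical(s1, s2)
  expect_true(all(unlist(s1) %in% pop))
  expect_true(all(vapply(s1, anyDuplicated, 1L) == 0))

  full <- sample_random_gene_sets(pop, n_sets = 2, set_size = 300, seed = 1)
  expect_true(all(vapply(full, setequal, TRUE, y = pop)))
  expect_error(sample_random_gene_sets(pop, set_size = 301), "population")
})

test_that("fold enrichment reproduces hand-computed fixtures", {
  # 10 cluster genes, 4 associated; each random set hits exactly 1 of 10
  genes <- tibble::tibble(gene_id = sprintf("g%02d", 1:60), chrom = "chr1",
                          tss = c(seq(0, 3000, length.out = 4),
                                  seq(1e6, 1e6 + 56 * 50000, length.out = 56)))
  genes$tss <- as.integer(genes$tss)
  peaks <- tibble::tibble(peak_id = "p1", chrom = "chr1", center = 1500L)
  cluster <- sprintf("g%02d", 1:10)       # g01-g04 associated
  random_sets <- lapply(0:4, function(i) {
    c(sprintf("g%02d", 4 - (i %% 4)), sprintf("g%02d", 11:19 + i))
  })
  fe <- fold_enrichment(cluster, random_sets, genes, peaks, d = 10000)
  expect_equal(fe$f_obs, 0.4)
  expect_equal(fe$f_rand, 0.1)
  expect_equal(fe$fold_enrichment, 4)

  none <- fold_enrichment(sprintf("g%02d", 21:30), random_sets, genes, peaks,
                          d = 10000)
  expect_equal(none$fold_enrichment, 0)
})

test_that("null clusters give fold enrichment near 1", {
  set.seed(13)
  genes <- tibble::tibble(gene_id = sprintf("g%04d", 1:1000), chrom = "chr1",
                          tss = sort(sample.int(5e7, 1000)))
  peaks <- tibble::tibble(peak_id = sprintf("p%03d", 1:400), chrom = "chr1",
                          center = sample.int(5e7, 400))
  sets <- sample_random_gene_sets(genes$gene_id, 10, 200, seed = 3)
  cluster <- sample(genes$gene_id, 200)
  fe <- fold_enrichment(cluster, sets, genes, peaks, d = 10000)
  expect_gt(fe$fold_enrichment, 0.7)
  expect_lt(fe$fold_enrichment, 1.4)
})

test_that("two-tailed Fisher matches enumeration oracle and spot values", {
  expect_equal(fisher_exact_two_tailed(3, 1, 1, 3), 34 / 70)
  expect_equal(fisher_exact_two_tailed(2, 0, 0, 2), 1 / 3)
  expect_equal(fisher_exact_two_tailed(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_two_tailed(0, 0, 0, 0), 1)

  # exhaustive small tables plus random tables with margins <= 30,
  # against the choose()-based oracle and stats::fisher.test
  for (a in 0:5) for (b in 0:5) for (c in 0:5) for (d in 0:5) {
    expect_equal(fisher_exact_two_tailed(a, b, c, d),
                 fisher_oracle(a, b, c, d))
  }
  set.seed(29)
  for (i in 1:250) {
    r1 <- sample(0:30, 1); r2 <- sample(0:30, 1)
    a <- if (r1 > 0) sample(0:r1, 1) else 0
    c <- if (r2 > 0) sample(0:r2, 1) else 0
    tab <- c(a, r1 - a, c, r2 - c)
    got <- fisher_exact_two_tailed(tab[1], tab[2], tab[3], tab[4])
    expect_equal(got, fisher_oracle(tab[1], tab[2], tab[3], tab[4]))
    if (sum(tab) > 0) {
      ft <- stats::fisher.test(matrix(tab, 2, byrow = TRUE))$p.value
      expect_equal(got, ft, tolerance = 1e-9)
    }
  }
})

test_that("association grid has one labelled cell per cluster and group", {
  sc <- generate_scenario(scenario_config(seed = 19))
  res <- suppressWarnings(integrate_targets(sc$genes, sc$counts, sc$design,
                                            sc$peaks,
                                            pipeline_config(seed = 19)))
  grid <- res$association
  expect_equal(nrow(grid), 9)
  expect_setequal(grid$cluster_label, c("A", "B", "C"))
  expect_setequal(grid$peak_group, c("I", "II", "III"))
  expect_true(all(grid$n_associated <= grid$n_cluster_genes))
  expect_true(all(grid$fisher_p > 0 & grid$fisher_p <= 1))
  expect_equal(grid$fisher_fdr, bh_adjust(grid$fisher_p))

  # the planted program-A / Group-I association is the grid minimum p
  amin <- grid[which.min(grid$fisher_p), ]
  expect_equal(amin$cluster_label, "A")
  expect_equal(amin$peak_group, "I")
})

test_that("direct-target calls respect eligibility and distance", {
  clusters <- tibble::tibble(gene_id = c("ga", "gb", "gc"),
                             label = c("A", "B", "C"))
  genes <- tibble::tibble(
    gene_id = c("ga", "gb", "gc"), chrom = "chr1",
    tss = c(10000L, 50000L, 100000L)
  )
  peaks <- tibble::tibble(peak_id = c("p1", "p2", "p3"), chrom = "chr1",
                          center = c(13000L, 52000L, 112000L),
                          group = c("I", "I", "II"))
  calls <- call_direct_targets(clusters, peaks, genes, d = 10000)
  expect_true(calls$is_direct_target[calls$gene_id == "ga"])
  expect_false("gb" %in% calls$gene_id)    # cluster B ineligible
  expect_false(calls$is_direct_target[calls$gene_id == "gc"]) # 12 kb away
  expect_equal(direct_target_genes(calls), "ga")
  expect_equal(calls$distance[calls$gene_id == "ga"], 3000L)
})
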