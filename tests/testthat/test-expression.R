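test_that("CPM scales by library size and is scale invariant", {
  counts <- tibble::tibble(gene_id = c("g1", "g2"),
                           s1 = c(5L, 999995L), s2 = c(0L, 10L))
  cpm <- compute_cpm(counts)
  expect_equal(cpm$s1, c(5, 999995))
  expect_equal(cpm$s2[1], 0)

  doubled <- counts
  doubled$s1 <- doubled$s1 * 2L
  expect_equal(compute_cpm(doubled)$s1, cpm$s1)

  zero <- tibble::tibble(gene_id = "g1", s1 = 0L)
  expect_error(compute_cpm(zero), "library size")
})

test_that("expression filter is inclusive at both boundaries", {
  cpm <- tibble::tibble(
    gene_id = c("kept", "boundary", "zero", "two_samples"),
    s1 = c(6, 5, 0, 6), s2 = c(6, 5, 0, 6),
    s3 = c(6, 5, 0, 4.9), s4 = c(0, 0, 0, 0),
    s5 = c(0, 0, 0, 0), s6 = c(0, 0, 0, 0)
  )
  kept <- filter_expressed(cpm, min_cpm = 5, min_samples = 3)
  expect_setequal(kept$gene_id, c("kept", "boundary"))
  expect_error(filter_expressed(cpm, min_samples = 7), "min_samples")
})

test_that("quantile normalization forces shared order statistics", {
  x <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(1, 2), s2 = c(3, 4))
  qn <- quantile_normalize(x)
  expect_equal(qn$s1, c(2, 3))
  expect_equal(qn$s2, c(2, 3))

  same <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(1, 5), s2 = c(1, 5))
  expect_equal(quantile_normalize(same), same)

  set.seed(1)
  m <- matrix(rlnorm(200, 3, 1), ncol = 4) # tie-free, so means equalize
  qn2 <- quantile_normalize(m)
  expect_equal(colMeans(qn2), rep(mean(colMeans(qn2)), 4))
})

test_that("TMM factors match edgeR and have geometric mean 1", {
  set.seed(42)
  m <- matrix(rnbinom(4000, mu = 100, size = 10), ncol = 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  m[, 2] <- m[, 2] * 3L # library-size only difference
  f <- tmm_factors(m, reference_sample = "s1")
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  # pure library scaling needs no composition correction
  expect_equal(unname(f["s2"] / f["s1"]), 1, tolerance = 0.02)

  skip_if_not_installed("edgeR")
  f_edger <- edgeR::calcNormFactors(m, method = "TMM", refColumn = 1)
  expect_equal(unname(f), unname(f_edger), tolerance = 0.02)

  identical_cols <- matrix(rep(m[, 1], 3), ncol = 3,
                           dimnames = list(NULL, paste0("s", 1:3)))
  expect_equal(unname(tmm_factors(identical_cols)), rep(1, 3))
})

test_that("NB exact test: identical groups give p = 1, all-zero genes p = 1", {
  counts <- matrix(c(5L, 5L, 5L, 5L, 0L, 0L, 0L, 0L), nrow = 2, byrow = TRUE,
                   dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  res <- nb_exact_test(counts[, 1:2], counts[, 3:4], dispersion = 0.1)
  expect_equal(res$p_value, c(1, 1))
})

test_that("NB exact test approaches the binomial test as dispersion -> 0", {
  # ballast gene keeps all library sizes at 1030, so no pseudo-count
  # rescaling happens and the conditional law is exactly binomial
  ca <- matrix(c(30, 34, 1000, 996), nrow = 2, byrow = TRUE,
               dimnames = list(c("g", "ballast"), c("a1", "a2")))
  cb <- matrix(c(60, 68, 970, 962), nrow = 2, byrow = TRUE,
               dimnames = list(c("g", "ballast"), c("b1", "b2")))
  p_nb <- nb_exact_test(ca, cb, dispersion = 1e-8)$p_value[1]
  p_binom <- stats::binom.test(64, 64 + 128, p = 0.5)$p.value
  expect_equal(p_nb, p_binom, tolerance = 1e-4)
})

test_that("NB exact test p-values fall as the mean shift grows", {
  mk <- function(count) {
    matrix(rep(c(count, 1000 - count), each = 3), nrow = 2, byrow = TRUE,
           dimnames = list(c("g", "ballast"), paste0("s", count, "_", 1:3)))
  }
  base <- mk(50)
  ps <- vapply(c(50, 75, 100, 150, 250), function(shifted) {
    nb_exact_test(base, mk(shifted), dispersion = 0.1)$p_value[1]
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("common dispersion is recovered from null data", {
  set.seed(7)
  m <- matrix(rnbinom(2000 * 12, mu = 100, size = 10), ncol = 12,
              dimnames = list(NULL, paste0("s", 1:12)))
  res <- nb_exact_test(m[, 1:6], m[, 7:12])
  expect_equal(attr(res, "dispersion"), 0.1, tolerance = 0.02)
})

test_that("BH adjustment matches a brute-force step-up oracle", {
  step_up <- function(p) {
    n <- length(p)
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(p[o] * n / (n:1)))[ro]
  }
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(11)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), step_up(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.5, -0.1)), "0, 1")
})

test_that("dysregulation thresholds are inclusive and direction-aware", {
  de <- tibble::tibble(
    gene_id = c("at_both_bounds", "fc_below", "down_called", "fdr_above"),
    fold_change = c(2.0, 1.9, 0.4, 3.0),
    fdr = c(0.05, 0.001, 0.01, 0.051)
  )
  out <- call_dysregulated(de)
  expect_equal(out$called, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(out$direction, c("up", "none", "down", "none"))
})

test_that("hierarchical clustering recovers blocks and matches brute force", {
  # three perfectly internally correlated blocks
  base <- rbind(c(1, 2, 3, 4), c(4, 3, 2, 1), c(1, 3, 1, 3))
  expr <- tibble::tibble(
    gene_id = paste0("g", 1:6),
    s1 = c(base[1, 1] * c(1, 2), base[2, 1] * c(1, 2), base[3, 1] * c(1, 2)),
    s2 = c(base[1, 2] * c(1, 2), base[2, 2] * c(1, 2), base[3, 2] * c(1, 2)),
    s3 = c(base[1, 3] * c(1, 2), base[2, 3] * c(1, 2), base[3, 3] * c(1, 2)),
    s4 = c(base[1, 4] * c(1, 2), base[2, 4] * c(1, 2), base[3, 4] * c(1, 2))
  )
  cl <- cluster_dysregulated(expr, k = 3)
  expect_equal(length(unique(cl$cluster)), 3)
  expect_equal(cl$cluster[1], cl$cluster[2])
  expect_equal(cl$cluster[3], cl$cluster[4])
  expect_equal(cl$cluster[5], cl$cluster[6])

  # brute-force agglomeration oracle on <= 6 random genes
  brute_complete <- function(m, k) {
    d <- 1 - stats::cor(t(m))
    clusters <- as.list(seq_len(nrow(m)))
    while (length(clusters) > k) {
      best <- c(Inf, NA, NA)
      for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
      clusters[[best[3]]] <- c(clusters[[best[3]]], clusters[[best[2]]])
      clusters[[best[2]]] <- NULL
    }
    out <- integer(nrow(m))
    for (i in seq_along(clusters)) out[clusters[[i]]] <- i
    out
  }
  set.seed(3)
  for (rep in 1:20) {
    m <- matrix(rnorm(6 * 5), nrow = 6)
    expr2 <- dplyr::bind_cols(tibble::tibble(gene_id = paste0("g", 1:6)),
                              tibble::as_tibble(as.data.frame(m)))
    got <- cluster_dysregulated(expr2, k = 3)$cluster
    want <- brute_complete(m, 3)
    # compare partitions up to label permutation
    expect_equal(outer(got, got, "=="), outer(want, want, "=="))
  }
})

test_that("clustering is invariant to gene order and drops constant profiles", {
  set.seed(5)
  m <- matrix(rnorm(8 * 6), nrow = 8)
  expr <- dplyr::bind_cols(tibble::tibble(gene_id = paste0("g", 1:8)),
                           tibble::as_tibble(as.data.frame(m)))
  cl1 <- cluster_dysregulated(expr, k = 3)
  perm <- sample(8)
  cl2 <- cluster_dysregulated(expr[perm, ], k = 3)
  joined <- dplyr::inner_join(cl1, cl2, by = "gene_id")
  expect_equal(outer(joined$cluster.x, joined$cluster.x, "=="),
               outer(joined$cluster.y, joined$cluster.y, "=="))

  flat <- expr
  flat[3, -1] <- as.list(rep(2, ncol(flat) - 1))
  expect_warning(cl3 <- cluster_dysregulated(flat, k = 3), "constant")
  expect_false("g3" %in% cl3$gene_id)
})

test_that("cluster labelling follows the program criteria", {
  clusters <- tibble::tibble(gene_id = paste0("g", 1:3), cluster = 1:3)
  gm <- tibble::tibble(cluster = 1:3,
                       WT = c(0, 0, 0), WT_IR = c(2, 2, -2),
                       KO = c(0, 0, 0), KO_IR = c(0, 1.5, 0))
  labelled <- label_clusters(clusters, gm)
  expect_equal(labelled$label, c("A", "B", "C"))

  # ambiguous centroids fall back to nearest prototype with a warning
  gm_dup <- tibble::tibble(cluster = 1:3,
                           WT = c(0, 0, 0), WT_IR = c(2, 1.8, -2),
                           KO = c(0, 0, 0), KO_IR = c(0.2, 0.1, 0))
  expect_warning(lab2 <- label_clusters(clusters, gm_dup), "prototype")
  expect_setequal(lab2$label, c("A", "B", "C"))
})
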