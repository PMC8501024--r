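#' Counts per million
#'
#' Scales each sample's counts to its (optionally normalized) library size.
#'
#' @param counts Count tibble (`gene_id` + one column per sample) or a
#'   numeric matrix with genes in rows.
#' @param norm_factors Optional named per-sample scaling factors (e.g. from
#'   [tmm_factors()]); effective library size is `library_size * factor`.
#' @return A tibble of the same shape with CPM values.
#' @examples
#' counts <- tibble::tibble(gene_id = "g1", s1 = 5L)
#' compute_cpm(counts) # library size 5 -> CPM 1e6
#' @export
compute_cpm <- function(counts, norm_factors = NULL) {
  m <- counts_as_matrix(counts)
  lib <- colSums(m)
  if (any(lib <= 0)) {
    abort(sprintf("zero library size in sample %s",
                  colnames(m)[which(lib <= 0)[1]]))
  }
  if (!is.null(norm_factors)) {
    lib <- lib * norm_factors[colnames(m)]
  }
  cpm <- sweep(m, 2, lib, "/") * 1e6
  matrix_as_counts(cpm, counts)
}

#' Filter to expressed genes
#'
#' Retains genes with CPM at or above `min_cpm` in at least `min_samples`
#' samples (both boundaries inclusive).
#'
#' @param cpm CPM tibble from [compute_cpm()] (or matrix).
#' @param min_cpm Minimum CPM, default 5.
#' @param min_samples Minimum number of samples meeting `min_cpm`, default 3.
#' @return The retained rows of `cpm`.
#' @export
filter_expressed <- function(cpm, min_cpm = 5, min_samples = 3) {
  stopifnot(min_cpm > 0, min_samples > 0)
  m <- counts_as_matrix(cpm)
  if (min_samples > ncol(m)) {
    abort(sprintf("min_samples (%d) exceeds the number of samples (%d)",
                  min_samples, ncol(m)))
  }
  keep <- rowSums(m >= min_cpm) >= min_samples
  if (is_tibble(cpm) || is.data.frame(cpm)) {
    cpm[keep, , drop = FALSE]
  } else {
    m[keep, , drop = FALSE]
  }
}

#' Quantile normalization
#'
#' Forces every sample onto the same empirical distribution: each column's
#' sorted values are replaced by the across-column means of the order
#' statistics, with ties receiving the mean of their tied reference values
#' (via [limma::normalizeQuantiles()]).
#'
#' @param x Expression tibble (`gene_id` + samples) or matrix.
#' @return Normalized data of the same shape.
#' @export
quantile_normalize <- function(x) {
  m <- counts_as_matrix(x)
  if (anyNA(m)) abort("quantile_normalize requires complete data")
  qn <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(qn) <- dimnames(m)
  matrix_as_counts(qn, x)
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values between-sample normalization: for each sample
#' versus the reference, gene-wise log2 ratios (M) of library-scaled counts
#' are trimmed by 30% on each tail, genes are additionally trimmed by 5% on
#' each tail of average log intensity (A), and the factor is 2 to the
#' precision-weighted mean of the surviving M values. Genes with a zero count
#' in either sample are excluded. Factors are rescaled to geometric mean 1.
#'
#' @param counts Count tibble or matrix.
#' @param reference_sample Name of the reference sample; defaults to the
#'   sample whose upper-quartile scaled count is closest to the mean.
#' @param logratio_trim,sum_trim Trim fractions for M and A, defaults 0.3
#'   and 0.05.
#' @return Named numeric vector of per-sample factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, reference_sample = NULL,
                        logratio_trim = 0.3, sum_trim = 0.05) {
  m <- counts_as_matrix(counts)
  lib <- colSums(m)
  if (is.null(reference_sample)) {
    uq <- apply(sweep(m, 2, lib, "/"), 2, quantile, probs = 0.75)
    reference_sample <- colnames(m)[which.min(abs(uq - mean(uq)))]
  }
  if (!reference_sample %in% colnames(m)) {
    abort(sprintf("reference sample %s not in counts", reference_sample))
  }
  yr <- m[, reference_sample]
  nr <- lib[reference_sample]
  if (nr <= 0) abort("reference sample has zero library size")
  f <- vapply(colnames(m), function(s) {
    tmm_pair(m[, s], lib[s], yr, nr, logratio_trim, sum_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(m))
}

tmm_pair <- function(yk, nk, yr, nr, logratio_trim, sum_trim) {
  use <- yk > 0 & yr > 0
  if (sum(use) < 10) {
    warn("fewer than 10 usable genes for TMM; factor set to 1")
    return(1)
  }
  yk <- yk[use]; yr <- yr[use]
  M <- log2((yk / nk) / (yr / nr))
  A <- 0.5 * log2((yk / nk) * (yr / nr))
  # delta-method precision weights (inverse asymptotic variance of M)
  w <- (nk - yk) / (nk * yk) + (nr - yr) / (nr * yr)
  if (max(abs(M)) < 1e-6) return(1) # identical profiles
  n <- length(M)
  lo_m <- floor(n * logratio_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * sum_trim) + 1
  hi_a <- n + 1 - lo_a
  keep <- rank(M, ties.method = "first") >= lo_m &
    rank(M, ties.method = "first") <= hi_m &
    rank(A, ties.method = "first") >= lo_a &
    rank(A, ties.method = "first") <= hi_a
  if (!any(keep)) return(1)
  2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
}

#' Exact negative-binomial test between two sample groups
#'
#' A documented stand-in for full differential-expression machinery: a common
#' NB dispersion is estimated by a pooled method of moments on
#' library-equalized pseudo-counts (floored at 1e-4), then each gene is
#' tested with an exact conditional two-sided test of the group sums given
#' their total, the two-sided p being the total probability of outcomes no
#' more likely than the observed one.
#'
#' @param counts_a,counts_b Count tibbles or matrices for the two groups
#'   (same genes, >= 2 replicates each).
#' @param norm_factors Optional named normalization factors covering the
#'   samples of both groups.
#' @param dispersion Optional fixed common dispersion; estimated when `NULL`.
#' @param dispersion_method `"cml"` (default): maximize the exact
#'   within-group conditional NB likelihood over genes, which is stable at
#'   2-3 replicates; `"moments"`: pooled debiased method of moments.
#' @return A tibble with `gene_id`, `p_value`, and the estimated common
#'   `dispersion` as an attribute.
#' @export
nb_exact_test <- function(counts_a, counts_b, norm_factors = NULL,
                          dispersion = NULL,
                          dispersion_method = c("cml", "moments")) {
  ma <- counts_as_matrix(counts_a)
  mb <- counts_as_matrix(counts_b)
  if (nrow(ma) != nrow(mb)) abort("group count tables differ in genes")
  if (ncol(ma) < 2 || ncol(mb) < 2) {
    abort("nb_exact_test requires >= 2 replicates per group")
  }
  m <- cbind(ma, mb)
  lib <- colSums(m)
  if (!is.null(norm_factors)) lib <- lib * norm_factors[colnames(m)]
  # pseudo-equalize library sizes to their geometric mean
  target <- exp(mean(log(lib)))
  pseudo <- sweep(m, 2, target / lib, "*")
  idx_a <- seq_len(ncol(ma))
  if (is.null(dispersion)) {
    dispersion_method <- match.arg(dispersion_method)
    dispersion <- if (dispersion_method == "cml") {
      cml_dispersion(pseudo, idx_a)
    } else {
      moment_dispersion(pseudo, idx_a)
    }
  }
  dispersion <- max(dispersion, 1e-4)
  sa <- round(rowSums(pseudo[, idx_a, drop = FALSE]))
  sb <- round(rowSums(pseudo[, -idx_a, drop = FALSE]))
  ra <- ncol(ma) / dispersion
  rb <- ncol(mb) / dispersion
  p <- vapply(seq_along(sa), function(g) {
    nb_conditional_p(sa[g], sa[g] + sb[g], ra, rb)
  }, numeric(1))
  out <- tibble(gene_id = gene_ids_of(counts_a, nrow(ma)), p_value = p)
  attr(out, "dispersion") <- dispersion
  out
}

# Pooled moment estimator of the common dispersion phi in
# var = mu + phi mu^2, on library-equalized counts: within-group unbiased
# variances and means are pooled across genes as a ratio of sums, which keeps
# the estimator stable for low-count genes.
moment_dispersion <- function(pseudo, idx_a) {
  num <- 0
  den <- 0
  for (idx in list(idx_a, setdiff(seq_len(ncol(pseudo)), idx_a))) {
    grp <- pseudo[, idx, drop = FALSE]
    n <- ncol(grp)
    mu <- rowMeans(grp)
    v <- apply(grp, 1, var)
    num <- num + sum(v - mu)
    # E[mean^2] = mu^2 + var/n, so subtract v/n to debias the denominator
    den <- den + sum(pmax(mu^2 - v / n, 0))
  }
  if (den <= 0) return(1e-4)
  num / den
}

# Common dispersion by conditional maximum likelihood: within each group the
# replicate counts given their sum follow a distribution free of the mean,
# P(y_1..y_n | t) = [prod_i C(y_i + r - 1, y_i)] / C(t + n r - 1, t) with
# r = 1/phi, so the summed conditional log-likelihood can be maximized over
# phi alone. Stable at 2-3 replicates where per-gene moment estimates are
# extremely noisy.
cml_dispersion <- function(pseudo, idx_a) {
  groups <- list(round(pseudo[, idx_a, drop = FALSE]),
                 round(pseudo[, -idx_a, drop = FALSE]))
  ll <- function(log_phi) {
    r <- exp(-log_phi)
    total <- 0
    for (grp in groups) {
      n <- ncol(grp)
      t <- rowSums(grp)
      term <- rowSums(lgamma(grp + r) - lgamma(grp + 1)) - n * lgamma(r)
      denom <- lgamma(t + n * r) - lgamma(t + 1) - lgamma(n * r)
      total <- total + sum(term - denom)
    }
    total
  }
  opt <- stats::optimize(ll, interval = log(c(1e-4, 5)), maximum = TRUE)
  exp(opt$maximum)
}

# Exact conditional two-sided test: S_a ~ NB(size ra), S_b ~ NB(size rb) with
# a shared success probability; conditional on S_a + S_b = t the distribution
# of S_a has weights Gamma(a+ra)/a! * Gamma(t-a+rb)/(t-a)!. Two-sided p sums
# the probabilities of all outcomes with probability <= the observed one
# (small-p method, with a 1e-7 relative tolerance for floating-point ties).
nb_conditional_p <- function(a_obs, t, ra, rb) {
  if (t == 0) return(1)
  a <- 0:t
  lw <- lgamma(a + ra) - lgamma(a + 1) + lgamma(t - a + rb) - lgamma(t - a + 1)
  lw <- lw - max(lw)
  w <- exp(lw)
  w <- w / sum(w)
  min(1, sum(w[w <= w[a_obs + 1] * (1 + 1e-7)]))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with enforced monotonicity, capped at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values of the same length.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Differential expression for one contrast
#'
#' Runs the full DE stand-in for a contrast versus a reference condition:
#' CPM filter over all samples, TMM factors, exact NB test, BH adjustment,
#' and linear fold changes from TMM-normalized mean CPM (pseudocount 0.5 CPM
#' guards zero means in the ratio; the reported `mean_cpm_*` columns are
#' unpadded).
#'
#' @param counts Count tibble (`gene_id` + samples).
#' @param design Design tibble (`sample`, `genotype`, `treatment`,
#'   `replicate`).
#' @param contrast,reference Lists with `genotype` and `treatment` naming the
#'   two conditions, e.g. `list(genotype = "WT", treatment = "IR")`.
#' @param min_cpm,min_samples Expression filter, see [filter_expressed()].
#' @param norm_factors Optional precomputed TMM factors over all samples.
#' @return A `tf_de` tibble: `gene_id`, `mean_cpm_ref`, `mean_cpm_contrast`,
#'   `fold_change`, `log2fc`, `p_value`, `fdr`.
#' @export
de_contrast <- function(counts, design,
                        contrast = list(genotype = "WT", treatment = "IR"),
                        reference = list(genotype = "WT", treatment = "UT"),
                        min_cpm = 5, min_samples = 3, norm_factors = NULL) {
  vc <- validate_counts(counts, design)
  counts <- vc$counts
  design <- vc$design
  cpm_all <- compute_cpm(counts)
  counts <- counts[rowSums(counts_as_matrix(cpm_all) >= min_cpm) >= min_samples, ]
  if (nrow(counts) == 0) abort("no genes pass the expression filter")
  if (is.null(norm_factors)) norm_factors <- tmm_factors(counts)
  s_ref <- condition_samples(design, reference)
  s_con <- condition_samples(design, contrast)
  if (length(s_ref) < 2 || length(s_con) < 2) {
    abort("each condition needs >= 2 replicates")
  }
  res <- nb_exact_test(counts[, c("gene_id", s_ref)],
                       counts[, c("gene_id", s_con)],
                       norm_factors = norm_factors)
  cpm_n <- compute_cpm(counts, norm_factors = norm_factors)
  cm <- counts_as_matrix(cpm_n)
  mean_ref <- rowMeans(cm[, s_ref, drop = FALSE])
  mean_con <- rowMeans(cm[, s_con, drop = FALSE])
  fc <- (mean_con + 0.5) / (mean_ref + 0.5)
  out <- tibble(
    gene_id = counts$gene_id,
    mean_cpm_ref = mean_ref,
    mean_cpm_contrast = mean_con,
    fold_change = fc,
    log2fc = log2(fc),
    p_value = res$p_value,
    fdr = bh_adjust(res$p_value)
  )
  attr(out, "dispersion") <- attr(res, "dispersion")
  attr(out, "contrast") <- contrast
  attr(out, "reference") <- reference
  class(out) <- c("tf_de", class(out))
  out
}

condition_samples <- function(design, cond) {
  design %>%
    filter(.data$genotype == cond$genotype,
           .data$treatment == cond$treatment) %>%
    pull("sample")
}

#' Call dysregulated genes
#'
#' Flags genes with `max(FC, 1/FC) >= fc_thresh` and `fdr <= fdr_thresh`
#' (both inclusive, as the thresholds are printed); direction is `up` for
#' FC > 1 and `down` for FC < 1.
#'
#' @param de_results A `tf_de` tibble from [de_contrast()].
#' @param fc_thresh Linear fold-change threshold (> 1), default 2.
#' @param fdr_thresh FDR threshold in (0, 1], default 0.05.
#' @return `de_results` with added `called` (logical) and `direction`
#'   (`"up"`, `"down"`, `"none"`) columns.
#' @export
call_dysregulated <- function(de_results, fc_thresh = 2, fdr_thresh = 0.05) {
  stopifnot(fc_thresh > 1, fdr_thresh > 0, fdr_thresh <= 1)
  de_results %>%
    mutate(
      called = pmax(.data$fold_change, 1 / .data$fold_change) >= fc_thresh &
        .data$fdr <= fdr_thresh,
      direction = case_when(
        .data$called & .data$fold_change > 1 ~ "up",
        .data$called & .data$fold_change < 1 ~ "down",
        .default = "none"
      )
    )
}

#' Relative expression for clustering
#'
#' log2(CPM + 1), centered per gene on the mean of the untreated wild-type
#' samples, the expression scale used for response-program clustering.
#'
#' @param counts Count tibble.
#' @param design Design tibble.
#' @param norm_factors Optional TMM factors.
#' @return A tibble `gene_id` + one column per sample.
#' @export
relative_expression <- function(counts, design, norm_factors = NULL) {
  cpm <- compute_cpm(counts, norm_factors = norm_factors)
  m <- log2(counts_as_matrix(cpm) + 1)
  base_samples <- condition_samples(design,
                                    list(genotype = "WT", treatment = "UT"))
  if (length(base_samples) == 0) abort("no WT/UT samples in design")
  m <- m - rowMeans(m[, base_samples, drop = FALSE])
  matrix_as_counts(m, cpm)
}

#' Cluster dysregulated genes by expression profile
#'
#' Agglomerative clustering with distance 1 - Pearson correlation and
#' complete linkage, cut into exactly `k` clusters. Genes with a constant
#' profile (undefined correlation) are dropped with a warning.
#'
#' @param relative_expr Tibble (`gene_id` + samples) from
#'   [relative_expression()], restricted to the genes to cluster.
#' @param k Number of clusters, default 3.
#' @return A tibble `gene_id`, `cluster` (integer).
#' @export
cluster_dysregulated <- function(relative_expr, k = 3) {
  m <- counts_as_matrix(relative_expr)
  ids <- gene_ids_of(relative_expr, nrow(m))
  keep <- apply(m, 1, sd) > 0
  if (!all(keep)) {
    warn(sprintf("%d constant-profile gene(s) excluded from clustering",
                 sum(!keep)))
    m <- m[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  if (nrow(m) < k) abort(sprintf("need >= %d genes to cut %d clusters", k, k))
  d <- stats::as.dist(1 - cor(t(m)))
  tree <- hclust(d, method = "complete")
  tibble(gene_id = ids, cluster = unname(cutree(tree, k = k)))
}

#' Outlier-robust program clustering
#'
#' [cluster_dysregulated()] with iterative micro-cluster trimming: after each
#' k-cut, clusters smaller than `min_frac` of the genes (at least 3) are set
#' aside as outliers and the remaining genes are re-cut, until all `k`
#' clusters are of credible size. A handful of aberrantly-profiled genes
#' (e.g. borderline false-positive calls with a pattern matching no response
#' program) would otherwise claim a cluster of their own under a forced
#' k-cut and merge two genuine programs.
#'
#' @param relative_expr Relative-expression tibble of the genes to cluster.
#' @param design Optional design tibble; when given, a 3-cut whose clusters
#'   do not map one-to-one onto the three response programs is refined by
#'   cutting the dendrogram deeper (k+1 .. k+3) and merging sub-clusters
#'   that share a program signature. The response to perturbation can hold
#'   more raw expression patterns than programs (a few aberrant
#'   false-positive calls form patterns of their own), and a forced shallow
#'   cut then merges two genuine programs.
#' @param k Number of clusters, default 3.
#' @param min_frac Minimum credible cluster size as a fraction of the genes,
#'   default 0.02.
#' @param max_iter Trimming iterations, default 10.
#' @return A tibble `gene_id`, `cluster`; trimmed genes are reported in the
#'   `"outliers"` attribute (character vector) and carry no row.
#' @export
cluster_programs <- function(relative_expr, design = NULL, k = 3,
                             min_frac = 0.02, max_iter = 10) {
  expr <- relative_expr
  outliers <- character()
  for (i in seq_len(max_iter)) {
    cl <- cluster_dysregulated(expr, k = k)
    sizes <- table(cl$cluster)
    min_size <- max(3, ceiling(min_frac * nrow(cl)))
    small <- names(sizes)[sizes < min_size]
    if (length(small) == 0) break
    drop <- cl$gene_id[cl$cluster %in% as.integer(small)]
    if (nrow(expr) - length(drop) < k * min_size) break
    outliers <- c(outliers, drop)
    expr <- expr[!expr$gene_id %in% drop, , drop = FALSE]
  }
  if (!is.null(design) && k == 3 && !programs_separated(cl, expr, design)) {
    for (k_deep in (k + 1):(k + 3)) {
      deep <- cluster_dysregulated(expr, k = k_deep)
      gm <- cluster_condition_means(deep, expr, design)
      labs <- program_criterion(gm$WT_IR - gm$WT, gm$KO_IR - gm$WT)
      if (!setequal(unique(labs), c("A", "B", "C"))) next
      merged <- deep %>%
        left_join(tibble(cluster = gm$cluster,
                         program = match(labs, c("A", "B", "C"))),
                  by = "cluster") %>%
        mutate(cluster = .data$program) %>%
        select("gene_id", "cluster")
      warn(sprintf("3-cut did not separate the response programs; using a %d-cut merged by program signature", k_deep))
      cl <- merged
      break
    }
  }
  if (length(outliers) > 0) {
    warn(sprintf("%d outlier gene(s) set aside before program labelling",
                 length(outliers)))
  }
  attr(cl, "outliers") <- outliers
  cl
}

programs_separated <- function(cl, expr, design) {
  gm <- cluster_condition_means(cl, expr, design)
  labs <- program_criterion(gm$WT_IR - gm$WT, gm$KO_IR - gm$WT)
  setequal(labs, c("A", "B", "C")) && anyDuplicated(labs) == 0
}

# shared program criterion: u = WT-IR shift, v = KO-IR shift (both vs
# untreated WT); down -> C, up in both (v at least half of u) -> B, else A
program_criterion <- function(u, v) {
  dplyr::case_when(u < 0 ~ "C", u >= 0 & v >= u / 2 ~ "B", .default = "A")
}

#' Condition means of cluster centroids
#'
#' @param clusters Tibble `gene_id`, `cluster` from [cluster_dysregulated()].
#' @param relative_expr Relative-expression tibble covering the clustered
#'   genes.
#' @param design Design tibble.
#' @return A tibble with one row per cluster and columns `WT`, `WT_IR`, `KO`,
#'   `KO_IR` holding the centroid's mean relative expression per condition.
#' @export
cluster_condition_means <- function(clusters, relative_expr, design) {
  m <- counts_as_matrix(relative_expr)
  ids <- gene_ids_of(relative_expr, nrow(m))
  conds <- list(WT = list(genotype = "WT", treatment = "UT"),
                WT_IR = list(genotype = "WT", treatment = "IR"),
                KO = list(genotype = "KO", treatment = "UT"),
                KO_IR = list(genotype = "KO", treatment = "IR"))
  purrr::map_dfr(sort(unique(clusters$cluster)), function(cl) {
    rows <- ids %in% clusters$gene_id[clusters$cluster == cl]
    centroid <- colMeans(m[rows, , drop = FALSE])
    vals <- purrr::map_dbl(conds, function(cond) {
      s <- condition_samples(design, cond)
      if (length(s) == 0) NA_real_ else mean(centroid[s])
    })
    tibble(cluster = cl, WT = vals[["WT"]], WT_IR = vals[["WT_IR"]],
           KO = vals[["KO"]], KO_IR = vals[["KO_IR"]])
  })
}

#' Label clusters as response programs A, B, C
#'
#' Programs, all relative to the untreated wild-type group: A = up after
#' irradiation in wild type but not in the knockout (TF-dependent
#' induction), B = up in both genotypes (TF-independent induction), C = down
#' after irradiation in wild type (TF-dependent repression). A cluster counts
#' as "up in the knockout" when its KO-IR shift reaches half its WT-IR
#' shift. If the per-cluster criteria do not produce a one-to-one labelling,
#' labels are assigned by the permutation closest to the three program
#' prototypes, with a warning.
#'
#' @param clusters Tibble `gene_id`, `cluster`.
#' @param group_means Tibble from [cluster_condition_means()].
#' @return `clusters` with an added `label` column (`"A"`, `"B"`, `"C"`).
#' @export
label_clusters <- function(clusters, group_means) {
  gm <- group_means %>%
    mutate(u = .data$WT_IR - .data$WT, v = .data$KO_IR - .data$WT)
  labels <- program_criterion(gm$u, gm$v)
  if (nrow(gm) != 3) abort("label_clusters expects exactly 3 clusters")
  if (!setequal(labels, c("A", "B", "C"))) {
    warn("cluster centroids do not map one-to-one onto programs A/B/C; assigning by nearest prototype")
    sizes <- vapply(gm$cluster, function(cl) sum(clusters$cluster == cl),
                    numeric(1))
    labels <- assign_by_prototype(gm$u, gm$v, sizes)
  }
  clusters %>%
    left_join(tibble(cluster = gm$cluster, label = labels), by = "cluster")
}

# size-weighted assignment so a small aberrant cluster cannot steal the
# label that fits a large, well-populated one
assign_by_prototype <- function(u, v, sizes = rep(1, 3)) {
  m <- max(mean(abs(u)), 1e-8)
  proto <- list(A = c(m, 0), B = c(m, m), C = c(-m, 0))
  perms <- list(c("A", "B", "C"), c("A", "C", "B"), c("B", "A", "C"),
                c("B", "C", "A"), c("C", "A", "B"), c("C", "B", "A"))
  cost <- vapply(perms, function(p) {
    sum(vapply(1:3, function(i) {
      sizes[i] * sum((c(u[i], v[i]) - proto[[p[i]]])^2)
    }, numeric(1)))
  }, numeric(1))
  perms[[which.min(cost)]]
}

# ---- shared matrix/tibble plumbing -----------------------------------------

counts_as_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  x <- as_tibble(x)
  id_col <- intersect(names(x), "gene_id")
  m <- as.matrix(x[setdiff(names(x), id_col)])
  if (length(id_col) == 1) rownames(m) <- x$gene_id
  storage.mode(m) <- "double"
  m
}

matrix_as_counts <- function(m, template) {
  if (is.matrix(template)) return(m)
  out <- as_tibble(as.data.frame(m))
  if ("gene_id" %in% names(template)) {
    out <- dplyr::bind_cols(tibble(gene_id = template$gene_id), out)
  }
  out
}

gene_ids_of <- function(x, n) {
  if (!is.matrix(x) && "gene_id" %in% names(x)) return(x$gene_id)
  if (is.matrix(x) && !is.null(rownames(x))) return(rownames(x))
  sprintf("gene_%05d", seq_len(n))
}
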