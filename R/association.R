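#' Nearest TSS for each peak
#'
#' Distance is `|peak_center - tss|`; ties are broken by the
#' lexicographically smallest `gene_id`. Peaks on chromosomes without genes
#' get `NA` (they never associate).
#'
#' @param peaks Peak tibble (needs `peak_id`, `chrom`, and either `center` or
#'   `start`/`end`).
#' @param genes Gene-model tibble (needs `gene_id`, `chrom`, `tss`).
#' @return A tibble `peak_id`, `nearest_gene`, `distance`.
#' @export
nearest_tss <- function(peaks, genes) {
  if (!"center" %in% names(peaks)) {
    peaks <- peaks %>% mutate(center = peak_center(.data$start, .data$end))
  }
  out <- tibble(peak_id = peaks$peak_id,
                nearest_gene = NA_character_,
                distance = NA_integer_)
  for (ch in unique(peaks$chrom)) {
    g <- genes %>% filter(.data$chrom == ch)
    rows <- which(peaks$chrom == ch)
    if (nrow(g) == 0 || length(rows) == 0) next
    for (k in rows) {
      dd <- abs(peaks$center[k] - g$tss)
      best_d <- min(dd)
      cand <- g$gene_id[dd == best_d]
      out$nearest_gene[k] <- min(cand)
      out$distance[k] <- as.integer(best_d)
    }
  }
  out
}

#' Genes with a peak within a distance
#'
#' A gene is associated when at least one peak (optionally restricted by
#' `peak_filter`) has `|peak_center - tss| <= d` (inclusive).
#'
#' @param genes Gene-model tibble.
#' @param peaks Peak tibble (with `center` or `start`/`end`; a `group` column
#'   if `peak_filter` uses one).
#' @param d Association distance in bp, default 10000.
#' @param peak_filter Optional predicate on the peak tibble (a function
#'   returning a logical vector), e.g. `function(p) p$group == "I"`.
#' @return Character vector of associated `gene_id`s.
#' @export
genes_with_peak_within <- function(genes, peaks, d = 10000,
                                   peak_filter = NULL) {
  stopifnot(d >= 0)
  if (!"center" %in% names(peaks)) {
    peaks <- peaks %>% mutate(center = peak_center(.data$start, .data$end))
  }
  if (!is.null(peak_filter)) {
    peaks <- peaks[peak_filter(peaks), , drop = FALSE]
  }
  if (nrow(peaks) == 0) return(character())
  hit <- logical(nrow(genes))
  for (ch in unique(genes$chrom)) {
    centers <- sort(peaks$center[peaks$chrom == ch])
    rows <- which(genes$chrom == ch)
    if (length(centers) == 0 || length(rows) == 0) next
    tss <- genes$tss[rows]
    # nearest sorted center to each TSS
    idx <- findInterval(tss, centers)
    d_lo <- ifelse(idx >= 1, abs(tss - centers[pmax(idx, 1L)]), Inf)
    d_hi <- ifelse(idx < length(centers),
                   abs(tss - centers[pmin(idx + 1L, length(centers))]), Inf)
    hit[rows] <- pmin(d_lo, d_hi) <= d
  }
  genes$gene_id[hit]
}

#' Basal-plus-extension regulatory domains
#'
#' Each gene gets a strand-oriented basal domain around its TSS
#' (`basal_up` bp upstream, `basal_down` bp downstream), then each side is
#' extended outward by up to `max_ext` bp but stops at the nearest other
#' gene's basal boundary, and is clipped to the chromosome. Overlapping basal
#' domains are left overlapping.
#'
#' @param genes Gene-model tibble.
#' @param basal_up,basal_down Basal extent upstream/downstream of the TSS in
#'   bp, defaults 2000/2000.
#' @param max_ext Maximum distal extension in bp, default 200000.
#' @param chrom_sizes Named vector of chromosome lengths covering all gene
#'   chromosomes.
#' @return A tibble `gene_id`, `chrom`, `start`, `end` (the full domain) plus
#'   `basal_start`, `basal_end`.
#' @export
great_domains <- function(genes, basal_up = 2000, basal_down = 2000,
                          max_ext = 200000, chrom_sizes) {
  missing_chr <- setdiff(unique(genes$chrom), names(chrom_sizes))
  if (length(missing_chr) > 0) {
    abort(sprintf("chrom_sizes missing: %s", paste(missing_chr, collapse = ", ")))
  }
  g <- genes %>%
    mutate(
      basal_start = pmax(0L, as.integer(
        ifelse(.data$strand == "+", .data$tss - basal_up,
               .data$tss - basal_down))),
      basal_end = pmin(as.integer(chrom_sizes[.data$chrom]), as.integer(
        ifelse(.data$strand == "+", .data$tss + basal_down,
               .data$tss + basal_up)))
    )
  res <- g %>% mutate(start = NA_integer_, end = NA_integer_)
  for (ch in unique(g$chrom)) {
    rows <- which(g$chrom == ch)
    size <- as.integer(chrom_sizes[ch])
    bs <- g$basal_start[rows]
    be <- g$basal_end[rows]
    for (i in seq_along(rows)) {
      others <- setdiff(seq_along(rows), i)
      # left extension stops at the nearest other basal end (no extension at
      # all if a neighbour's basal already reaches past our basal start)
      left_lim <- 0L
      right_lim <- size
      if (length(others) > 0) {
        lcand <- pmin(be[others], bs[i])
        lcand <- lcand[bs[others] < bs[i] | be[others] <= bs[i]]
        if (length(lcand) > 0) left_lim <- max(0L, max(lcand))
        rcand <- pmax(bs[others], be[i])
        rcand <- rcand[be[others] > be[i] | bs[others] >= be[i]]
        if (length(rcand) > 0) right_lim <- min(size, min(rcand))
      }
      res$start[rows[i]] <- max(bs[i] - max_ext, left_lim, 0L)
      res$end[rows[i]] <- min(be[i] + max_ext, right_lim, size)
    }
  }
  res %>%
    select("gene_id", "chrom", "start", "end", "basal_start", "basal_end")
}

#' Assign peaks to regulatory domains
#'
#' A peak belongs to every domain that contains its center; a center inside
#' overlapping domains maps to all of their genes.
#'
#' @param peaks Peak tibble (with `center` or `start`/`end`).
#' @param domains Domain tibble from [great_domains()].
#' @return A tibble `peak_id`, `gene_id`, one row per assignment.
#' @export
peaks_in_domains <- function(peaks, domains) {
  if (!"center" %in% names(peaks)) {
    peaks <- peaks %>% mutate(center = peak_center(.data$start, .data$end))
  }
  peaks %>%
    select("peak_id", "chrom", "center") %>%
    dplyr::inner_join(domains, by = "chrom", relationship = "many-to-many") %>%
    filter(.data$center >= .data$start, .data$center < .data$end) %>%
    select("peak_id", "gene_id")
}

#' Sample random gene sets
#'
#' Draws `n_sets` gene sets of `set_size` without replacement within a set;
#' sets are drawn independently and may overlap across sets. The same seed
#' reproduces the same sets.
#'
#' @param population Character vector of gene ids (e.g. all expressed genes).
#' @param n_sets Number of sets, default 10.
#' @param set_size Genes per set, default 200.
#' @param seed Integer seed.
#' @return A list of character vectors.
#' @export
sample_random_gene_sets <- function(population, n_sets = 10, set_size = 200,
                                    seed = 1) {
  if (set_size > length(population)) {
    abort(sprintf("set_size (%d) exceeds population size (%d)",
                  set_size, length(population)))
  }
  withr::with_seed(seed, {
    purrr::map(seq_len(n_sets), function(i) sample(population, set_size))
  })
}

#' Fold enrichment of peak association against random gene sets
#'
#' `f_obs` is the fraction of cluster genes with a peak within `d`; `f_rand`
#' is the mean of that fraction over the random sets; fold enrichment is
#' their ratio (0 when `f_obs` is 0; `Inf` flags `f_rand` = 0 with
#' `f_obs` > 0).
#'
#' @param cluster_genes Character vector of gene ids.
#' @param random_sets List of gene-id vectors from
#'   [sample_random_gene_sets()].
#' @param genes,peaks,d,peak_filter As in [genes_with_peak_within()].
#' @return A list: `fold_enrichment`, `f_obs`, `f_rand`, `n_cluster_genes`,
#'   `n_associated`, `random_set_proportions`, `n_random_associated`,
#'   `n_random_total`.
#' @export
fold_enrichment <- function(cluster_genes, random_sets, genes, peaks,
                            d = 10000, peak_filter = NULL) {
  stopifnot(length(cluster_genes) > 0, length(random_sets) >= 1)
  assoc <- genes_with_peak_within(genes, peaks, d = d,
                                  peak_filter = peak_filter)
  n_assoc <- sum(cluster_genes %in% assoc)
  f_obs <- n_assoc / length(cluster_genes)
  rand_hits <- vapply(random_sets, function(s) sum(s %in% assoc), numeric(1))
  rand_prop <- rand_hits / lengths(random_sets)
  f_rand <- mean(rand_prop)
  fe <- if (f_obs == 0) 0 else if (f_rand == 0) Inf else f_obs / f_rand
  list(fold_enrichment = fe, f_obs = f_obs, f_rand = f_rand,
       n_cluster_genes = length(cluster_genes), n_associated = n_assoc,
       random_set_proportions = rand_prop,
       n_random_associated = sum(rand_hits),
       n_random_total = sum(lengths(random_sets)))
}

#' Two-tailed Fisher exact test
#'
#' Exact hypergeometric enumeration over all 2x2 tables with the observed
#' margins; the two-tailed p-value sums the probabilities of all tables whose
#' probability does not exceed the observed table's (small-p method, with a
#' 1e-7 relative tolerance for floating-point ties).
#'
#' @param a,b,c,d Non-negative integer cells, rows `(a, b)` and `(c, d)`.
#' @return The p-value (1 for an all-zero table).
#' @examples
#' fisher_exact_two_tailed(3, 1, 1, 3) # 34/70
#' @export
fisher_exact_two_tailed <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("Fisher cells must be non-negative integers")
  }
  n <- a + b + c + d
  if (n == 0) return(1)
  r1 <- a + b
  c1 <- a + c
  support <- max(0, r1 + c1 - n):min(r1, c1)
  lp <- lgamma(r1 + 1) - lgamma(support + 1) - lgamma(r1 - support + 1) +
    lgamma(n - r1 + 1) - lgamma(c1 - support + 1) -
    lgamma(n - r1 - c1 + support + 1) +
    lgamma(c1 + 1) + lgamma(n - c1 + 1) - lgamma(n + 1)
  p_tab <- exp(lp)
  p_obs <- p_tab[support == a]
  min(1, sum(p_tab[p_tab <= p_obs * (1 + 1e-7)]))
}

#' Cluster-by-peak-group association grid
#'
#' One cell per (cluster label, peak group): the fraction of the cluster's
#' genes with a group-restricted peak within `d`, the same fraction in the
#' random sets, their ratio (fold enrichment), and a two-tailed Fisher exact
#' test of the 2x2 table `[[n_associated, n_cluster - n_associated],
#' [pooled random associated, pooled random not associated]]` (the random
#' sets are pooled into one comparison group). BH-adjusted p-values across
#' the grid are reported alongside raw p.
#'
#' @param cluster_members Tibble `gene_id`, `label` (from [label_clusters()]).
#' @param peaks A `tf_peaks` tibble with `group` assigned.
#' @param genes Gene-model tibble.
#' @param random_sets List from [sample_random_gene_sets()].
#' @param d Association distance, default 10000.
#' @return A `tf_assoc` tibble, one row per cell: `cluster_label`,
#'   `peak_group`, `n_cluster_genes`, `n_associated`, `f_obs`, `f_rand`,
#'   `fold_enrichment`, `fisher_p`, `fisher_fdr`.
#' @export
association_table <- function(cluster_members, peaks, genes, random_sets,
                              d = 10000) {
  labels <- sort(unique(cluster_members$label))
  groups <- c("I", "II", "III")
  grid <- tidyr::expand_grid(cluster_label = labels, peak_group = groups)
  cells <- purrr::pmap_dfr(grid, function(cluster_label, peak_group) {
    members <- cluster_members$gene_id[cluster_members$label == cluster_label]
    fe <- fold_enrichment(members, random_sets, genes, peaks, d = d,
                          peak_filter = function(p) p$group == peak_group)
    p <- fisher_exact_two_tailed(
      fe$n_associated, fe$n_cluster_genes - fe$n_associated,
      fe$n_random_associated, fe$n_random_total - fe$n_random_associated
    )
    tibble(cluster_label = cluster_label, peak_group = peak_group,
           n_cluster_genes = fe$n_cluster_genes,
           n_associated = fe$n_associated, f_obs = fe$f_obs,
           f_rand = fe$f_rand, fold_enrichment = fe$fold_enrichment,
           fisher_p = p)
  })
  cells$fisher_fdr <- bh_adjust(cells$fisher_p)
  structure(cells, class = c("tf_assoc", class(cells)))
}

#' Call direct targets
#'
#' A gene is a direct target when it belongs to one of the eligible
#' (TF-dependent) response programs and has at least one peak within `d` of
#' its TSS. All qualifying peaks and distances are recorded.
#'
#' @param cluster_members Tibble `gene_id`, `label`.
#' @param peaks A `tf_peaks` tibble (needs `peak_id`, `chrom`, `center`,
#'   `group`).
#' @param genes Gene-model tibble.
#' @param d Association distance, default 10000 (inclusive).
#' @param eligible_clusters Program labels eligible for target calls,
#'   default `c("A", "C")`.
#' @return A `tf_targets` tibble, one row per gene-peak link plus one row
#'   (with `NA` peak) per eligible gene without a qualifying peak:
#'   `gene_id`, `cluster_label`, `peak_id`, `distance`, `peak_group`,
#'   `is_direct_target`.
#' @export
call_direct_targets <- function(cluster_members, peaks, genes, d = 10000,
                                eligible_clusters = c("A", "C")) {
  if (!"center" %in% names(peaks)) {
    peaks <- peaks %>% mutate(center = peak_center(.data$start, .data$end))
  }
  eligible <- cluster_members %>%
    filter(.data$label %in% eligible_clusters)
  g <- genes %>%
    filter(.data$gene_id %in% eligible$gene_id) %>%
    left_join(select(eligible, "gene_id", "label"), by = "gene_id")
  links <- purrr::map_dfr(seq_len(nrow(g)), function(i) {
    p <- peaks %>%
      filter(.data$chrom == g$chrom[i],
             abs(.data$center - g$tss[i]) <= d)
    if (nrow(p) == 0) {
      return(tibble(gene_id = g$gene_id[i], cluster_label = g$label[i],
                    peak_id = NA_character_, distance = NA_integer_,
                    peak_group = NA_character_, is_direct_target = FALSE))
    }
    tibble(gene_id = g$gene_id[i], cluster_label = g$label[i],
           peak_id = p$peak_id,
           distance = as.integer(abs(p$center - g$tss[i])),
           peak_group = p$group, is_direct_target = TRUE)
  })
  structure(links, class = c("tf_targets", class(links)))
}

#' Direct-target gene list
#'
#' @param targets A `tf_targets` tibble from [call_direct_targets()].
#' @return Character vector of unique direct-target gene ids.
#' @export
direct_target_genes <- function(targets) {
  unique(targets$gene_id[targets$is_direct_target])
}
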