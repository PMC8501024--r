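#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a differential-expression result
#'
#' @param x A `tf_de` tibble from [de_contrast()].
#' @param ... Unused.
#' @return A plain tibble, one row per gene.
#' @export
tidy.tf_de <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "tf_de")
  out
}

#' @rdname tidy.tf_de
#' @export
glance.tf_de <- function(x, ...) {
  contrast <- attr(x, "contrast")
  reference <- attr(x, "reference")
  tibble(
    n_genes = nrow(x),
    n_called = if ("called" %in% names(x)) sum(x$called) else NA_integer_,
    dispersion = attr(x, "dispersion") %||% NA_real_,
    contrast = paste(contrast$genotype, contrast$treatment, sep = "-"),
    reference = paste(reference$genotype, reference$treatment, sep = "-")
  )
}

#' Tidy an association grid
#'
#' @param x A `tf_assoc` tibble from [association_table()].
#' @param ... Unused.
#' @return A plain tibble, one row per cluster-by-group cell.
#' @export
tidy.tf_assoc <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "tf_assoc")
  out
}

#' @rdname tidy.tf_assoc
#' @export
glance.tf_assoc <- function(x, ...) {
  tibble(
    n_cells = nrow(x),
    min_fisher_p = min(x$fisher_p),
    max_fold_enrichment = max(x$fold_enrichment[is.finite(x$fold_enrichment)]),
    n_significant = sum(x$fisher_p <= 0.05)
  )
}

#' Tidy a target-call table
#'
#' @param x A `tf_targets` tibble from [call_direct_targets()].
#' @param ... Unused.
#' @return A plain tibble, one row per gene-peak link.
#' @export
tidy.tf_targets <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "tf_targets")
  out
}

#' @rdname tidy.tf_targets
#' @export
glance.tf_targets <- function(x, ...) {
  tibble(
    n_genes_considered = length(unique(x$gene_id)),
    n_direct_targets = length(unique(x$gene_id[x$is_direct_target])),
    median_distance = median(x$distance[x$is_direct_target], na.rm = TRUE)
  )
}

#' Tidy a triage report
#'
#' @param x A `tf_triage` tibble from [triage_targets()].
#' @param ... Unused.
#' @return A plain tibble, one row per triaged gene.
#' @export
tidy.tf_triage <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "tf_triage")
  out
}

#' @rdname tidy.tf_triage
#' @export
glance.tf_triage <- function(x, ...) {
  tibble(
    n_targets = nrow(x),
    n_novel = sum(x$novel),
    n_druggable = sum(x$druggable),
    n_novel_druggable = sum(x$novel & x$druggable)
  )
}

#' Glance at a full pipeline result
#'
#' @param x A `tf_result` from [integrate_targets()].
#' @param ... Unused.
#' @return A one-row tibble with the headline counts.
#' @export
glance.tf_result <- function(x, ...) {
  tibble(
    n_expressed = length(x$expressed_genes),
    n_dysregulated = length(x$dysregulated),
    n_peaks = nrow(x$peaks),
    n_direct_targets = length(direct_target_genes(x$targets)),
    min_fisher_p = min(x$association$fisher_p)
  )
}

#' @export
print.tf_result <- function(x, ...) {
  g <- glance.tf_result(x)
  cat("<targetfuse result>\n")
  cat(sprintf("  expressed genes:   %d\n", g$n_expressed))
  cat(sprintf("  dysregulated:      %d\n", g$n_dysregulated))
  cat(sprintf("  peaks:             %d\n", g$n_peaks))
  cat(sprintf("  direct targets:    %d\n", g$n_direct_targets))
  cat(sprintf("  min association p: %.3g\n", g$min_fisher_p))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
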