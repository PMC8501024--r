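#' Load known-target gene lists
#'
#' One gene symbol per line per file; the list name is the file stem. Symbols
#' are normalized case-insensitively and deduplicated.
#'
#' @param files Character vector of paths.
#' @return A named list of character vectors (normalized, lower-case
#'   symbols).
#' @export
load_gene_lists <- function(files) {
  out <- purrr::map(files, function(f) {
    if (!file.exists(f)) abort(sprintf("gene list not found: %s", f))
    symbols <- trimws(readLines(f, warn = FALSE))
    symbols <- unique(normalize_symbol(symbols[nzchar(symbols)]))
    if (length(symbols) == 0) warn(sprintf("gene list %s is empty", f))
    symbols
  })
  names(out) <- sub("\\.[^.]*$", "", basename(files))
  out
}

normalize_symbol <- function(x) tolower(trimws(x))

#' Read an offline literature co-mention index
#'
#' @param path TSV with columns `id`, `title`, `abstract` (a pre-exported
#'   snapshot of title/abstract records; no live queries are made).
#' @return A tibble with those columns.
#' @export
read_literature_index <- function(path) {
  if (!file.exists(path)) abort(sprintf("literature index not found: %s", path))
  idx <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("id", "title", "abstract")
  if (!all(need %in% names(idx))) {
    abort(sprintf("literature index needs columns: %s",
                  paste(need, collapse = ", ")))
  }
  idx
}

#' Count literature co-mentions of a gene with the factor
#'
#' Counts index records whose title or abstract contains the gene symbol AND
#' the token defined by `factor_term`, both matched case-insensitively at
#' word boundaries (so `"p53"` does not hit inside `"Trp53bp1"`). An offline
#' approximation of a title/abstract database query.
#'
#' @param gene_symbol Gene symbol to search for.
#' @param index Literature index tibble from [read_literature_index()].
#' @param factor_term Co-mention token, default `"p53"`.
#' @return Non-negative integer count.
#' @export
literature_hits <- function(gene_symbol, index, factor_term = "p53") {
  if (nrow(index) == 0) {
    warn("literature index is empty; reporting 0 hits")
    return(0L)
  }
  text <- paste(index$title, index$abstract)
  has_gene <- grepl(word_regex(gene_symbol), text, ignore.case = TRUE,
                    perl = TRUE)
  has_factor <- grepl(word_regex(factor_term), text, ignore.case = TRUE,
                      perl = TRUE)
  sum(has_gene & has_factor)
}

word_regex <- function(term) {
  sprintf("(?<![[:alnum:]])%s(?![[:alnum:]])",
          gsub("([^[:alnum:]_])", "\\\\\\1", term))
}

#' Flag druggable genes
#'
#' @param gene_symbol Gene symbol (or vector).
#' @param druggable_set Character vector of druggable symbols (e.g. from a
#'   drug-gene interaction database export); matching is case-insensitive.
#' @return Logical vector.
#' @export
flag_druggable <- function(gene_symbol, druggable_set) {
  normalize_symbol(gene_symbol) %in% normalize_symbol(druggable_set)
}

#' Read a druggable-gene TSV export
#'
#' @param path TSV whose first column holds gene symbols (header optional).
#' @return Character vector of symbols.
#' @export
read_druggable_set <- function(path) {
  if (!file.exists(path)) abort(sprintf("druggable list not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  symbols <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1)
  symbols <- symbols[!tolower(symbols) %in% c("gene", "symbol", "gene_symbol")]
  unique(symbols)
}

#' Triage called targets for novelty and druggability
#'
#' A target is novel when it appears in none of the known-target lists and
#' has zero literature co-mentions with the factor; druggability is
#' membership of the druggable set. Records are sorted novel-and-druggable
#' first.
#'
#' @param target_genes Character vector of direct-target gene symbols (or a
#'   `tf_targets` tibble, from which unique direct targets are taken).
#' @param known_lists Named list from [load_gene_lists()].
#' @param index Literature index tibble.
#' @param druggable_set Character vector of druggable symbols.
#' @param factor_term Co-mention token, default `"p53"`.
#' @return A `tf_triage` tibble: `gene_id`, `known_lists_hit`
#'   (comma-separated names, `""` when none), `literature_hits`, `druggable`,
#'   `novel`.
#' @export
triage_targets <- function(target_genes, known_lists, index, druggable_set,
                           factor_term = "p53") {
  if (inherits(target_genes, "tf_targets")) {
    target_genes <- direct_target_genes(target_genes)
  }
  records <- purrr::map_dfr(target_genes, function(g) {
    hits <- names(known_lists)[vapply(known_lists, function(s) {
      normalize_symbol(g) %in% s
    }, logical(1))]
    lit <- literature_hits(g, index, factor_term = factor_term)
    tibble(
      gene_id = g,
      known_lists_hit = paste(hits, collapse = ","),
      literature_hits = as.integer(lit),
      druggable = flag_druggable(g, druggable_set),
      novel = length(hits) == 0 && lit == 0
    )
  })
  records <- records %>%
    arrange(dplyr::desc(.data$novel & .data$druggable),
            dplyr::desc(.data$novel), .data$gene_id)
  structure(records, class = c("tf_triage", class(records)))
}
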