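#' Parse BED-like interval lines
#'
#' Parses BED3+ text into a tibble of genomic intervals. Coordinates are
#' 0-based, half-open, as in the BED standard, and are kept that way by every
#' downstream function. Columns beyond the third are optional: column 4 is an
#' interval name, columns 5 and 6 are per-condition binding signals
#' (untreated and irradiated) when the file carries peaks.
#'
#' @param lines Character vector of tab-separated lines (or a length-1 path
#'   read with [read_peaks()]). Blank lines and lines starting with `#` or
#'   `track` are skipped.
#' @return A tibble with columns `chrom`, `start`, `end` and, when present,
#'   `name`, `signal_ut`, `signal_ir`. Input order is preserved.
#' @examples
#' parse_bed(c("chr1\t100\t200", "chr2\t0\t50"))
#' @export
parse_bed <- function(lines) {
  lines <- drop_comment_lines(lines)
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("BED line %d has fewer than 3 columns", which(nf < 3)[1]))
  }
  chrom <- vapply(fields, `[[`, "", 1)
  start <- parse_coord(vapply(fields, `[[`, "", 2), "start")
  end <- parse_coord(vapply(fields, `[[`, "", 3), "end")
  bad <- which(start >= end)
  if (length(bad) > 0) {
    abort(sprintf("BED line %d: start (%s) must be < end (%s)",
                  bad[1], start[bad[1]], end[bad[1]]))
  }
  if (any(!nzchar(chrom))) abort("empty chromosome name in BED input")
  out <- tibble(chrom = chrom, start = start, end = end)
  if (all(nf >= 4)) out$name <- vapply(fields, `[[`, "", 4)
  if (all(nf >= 6)) {
    out$signal_ut <- parse_signal(vapply(fields, `[[`, "", 5), "signal_ut")
    out$signal_ir <- parse_signal(vapply(fields, `[[`, "", 6), "signal_ir")
  }
  out
}

#' Read a peak file
#'
#' Reads a BED3+ peak file. If name/signal columns are absent, peak ids are
#' synthesized (`peak_00001`, ...) and signals left `NA` to be filled from
#' coverage tracks.
#'
#' @param path Path to a BED3+ file.
#' @return A tibble with columns `peak_id`, `chrom`, `start`, `end`,
#'   `signal_ut`, `signal_ir`.
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) abort(sprintf("peak file not found: %s", path))
  out <- parse_bed(readLines(path, warn = FALSE))
  if (!"name" %in% names(out)) {
    out$name <- sprintf("peak_%05d", seq_len(nrow(out)))
  }
  if (!"signal_ut" %in% names(out)) {
    out$signal_ut <- NA_real_
    out$signal_ir <- NA_real_
  }
  out %>%
    rename(peak_id = "name") %>%
    select("peak_id", "chrom", "start", "end", "signal_ut", "signal_ir")
}

#' Parse gene models with strand-derived TSS
#'
#' Accepts either a 6-column TSV (`gene_id`, `symbol`, `chrom`, `start`,
#' `end`, `strand`; 0-based half-open) or GTF-lite (9-column GTF `gene`
#' records with 1-based inclusive coordinates, converted on read; `gene_id`
#' and optional `gene_name` taken from the attributes field). The TSS is
#' derived from the strand: `start` for `+` genes, `end - 1` for `-` genes.
#'
#' @param lines Character vector of input lines.
#' @param format `"tsv"` or `"gtf"`.
#' @return A tibble with columns `gene_id`, `symbol`, `chrom`, `start`,
#'   `end`, `strand`, `tss`.
#' @examples
#' parse_gene_models("g1\tGene1\tchr1\t10\t100\t+")
#' @export
parse_gene_models <- function(lines, format = c("tsv", "gtf")) {
  format <- match.arg(format)
  lines <- drop_comment_lines(lines)
  if (format == "tsv") {
    genes <- parse_gene_tsv(lines)
  } else {
    genes <- parse_gene_gtf(lines)
  }
  if (anyDuplicated(genes$gene_id) > 0) {
    dup <- genes$gene_id[duplicated(genes$gene_id)][1]
    abort(sprintf("duplicate gene_id: %s", dup))
  }
  bad_strand <- !genes$strand %in% c("+", "-")
  if (any(bad_strand)) {
    abort(sprintf("gene %s has strand '%s'; '+' or '-' required (TSS undefined otherwise)",
                  genes$gene_id[bad_strand][1], genes$strand[bad_strand][1]))
  }
  if (any(genes$start >= genes$end)) {
    bad <- which(genes$start >= genes$end)[1]
    abort(sprintf("gene %s: start must be < end", genes$gene_id[bad]))
  }
  genes %>%
    mutate(tss = ifelse(.data$strand == "+", .data$start, .data$end - 1L)) %>%
    select("gene_id", "symbol", "chrom", "start", "end", "strand", "tss")
}

parse_gene_tsv <- function(lines) {
  if (length(lines) == 0) {
    return(tibble(gene_id = character(), symbol = character(),
                  chrom = character(), start = integer(), end = integer(),
                  strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 6)) {
    abort("gene TSV requires 6 columns: gene_id, symbol, chrom, start, end, strand")
  }
  # tolerate a header row
  if (identical(tolower(fields[[1]][1]), "gene_id")) fields <- fields[-1]
  tibble(
    gene_id = vapply(fields, `[[`, "", 1),
    symbol = vapply(fields, `[[`, "", 2),
    chrom = vapply(fields, `[[`, "", 3),
    start = parse_coord(vapply(fields, `[[`, "", 4), "start"),
    end = parse_coord(vapply(fields, `[[`, "", 5), "end"),
    strand = vapply(fields, `[[`, "", 6)
  )
}

parse_gene_gtf <- function(lines) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  fields <- fields[vapply(fields, function(f) length(f) >= 9 && f[3] == "gene",
                          logical(1))]
  if (length(fields) == 0) {
    return(tibble(gene_id = character(), symbol = character(),
                  chrom = character(), start = integer(), end = integer(),
                  strand = character()))
  }
  attr_field <- vapply(fields, `[[`, "", 9)
  get_attr <- function(key) {
    m <- regmatches(attr_field,
                    regexpr(sprintf('%s "[^"]*"', key), attr_field))
    out <- rep(NA_character_, length(attr_field))
    hit <- regexpr(sprintf('%s "[^"]*"', key), attr_field) > 0
    out[hit] <- sub(sprintf('%s "([^"]*)"', key), "\\1", m)
    out
  }
  gene_id <- get_attr("gene_id")
  if (anyNA(gene_id)) abort("GTF gene record without gene_id attribute")
  symbol <- get_attr("gene_name")
  symbol[is.na(symbol)] <- gene_id[is.na(symbol)]
  tibble(
    gene_id = gene_id,
    symbol = symbol,
    chrom = vapply(fields, `[[`, "", 1),
    # GTF is 1-based inclusive; convert to 0-based half-open
    start = parse_coord(vapply(fields, `[[`, "", 4), "start") - 1L,
    end = parse_coord(vapply(fields, `[[`, "", 5), "end"),
    strand = vapply(fields, `[[`, "", 7)
  )
}

#' Read gene models from a file
#'
#' @param path Path to a gene TSV or GTF file.
#' @param format `"tsv"` (default) or `"gtf"`; see [parse_gene_models()].
#' @return A gene-model tibble; see [parse_gene_models()].
#' @export
read_gene_models <- function(path, format = c("tsv", "gtf")) {
  if (!file.exists(path)) abort(sprintf("gene file not found: %s", path))
  parse_gene_models(readLines(path, warn = FALSE), format = match.arg(format))
}

#' Read a count matrix with its sample design
#'
#' The count table is a TSV whose first column holds gene ids and whose
#' header names the samples. The design table maps each sample to a genotype
#' (`WT`/`KO`), treatment (`UT`/`IR`) and replicate. Every sample in the
#' count header must appear in the design.
#'
#' @param counts_path Path to the counts TSV.
#' @param design_path Path to the design TSV (columns `sample`, `genotype`,
#'   `treatment`, `replicate`).
#' @return A list with `counts` (tibble, `gene_id` + one integer column per
#'   sample) and `design` (tibble).
#' @export
read_count_matrix <- function(counts_path, design_path) {
  for (p in c(counts_path, design_path)) {
    if (!file.exists(p)) abort(sprintf("file not found: %s", p))
  }
  counts <- readr::read_tsv(counts_path, show_col_types = FALSE,
                            progress = FALSE)
  names(counts)[1] <- "gene_id"
  design <- readr::read_tsv(design_path, show_col_types = FALSE,
                            progress = FALSE)
  validate_counts(counts, design)
}

#' Validate a count table against a sample design
#'
#' @param counts Tibble: `gene_id` plus one numeric column per sample.
#' @param design Tibble with columns `sample`, `genotype`, `treatment`,
#'   `replicate`.
#' @return A list with validated `counts` and `design`.
#' @export
validate_counts <- function(counts, design) {
  counts <- as_tibble(counts)
  design <- as_tibble(design)
  need <- c("sample", "genotype", "treatment", "replicate")
  if (!all(need %in% names(design))) {
    abort(sprintf("design is missing column(s): %s",
                  paste(setdiff(need, names(design)), collapse = ", ")))
  }
  samples <- setdiff(names(counts), "gene_id")
  if (length(samples) == 0) abort("count table has no sample columns")
  missing <- setdiff(samples, design$sample)
  if (length(missing) > 0) {
    abort(sprintf("sample(s) in count header missing from design: %s",
                  paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(counts$gene_id) > 0) abort("duplicate gene_id in counts")
  bad_geno <- setdiff(unique(design$genotype), c("WT", "KO"))
  if (length(bad_geno) > 0) {
    abort(sprintf("unknown genotype level: %s", bad_geno[1]))
  }
  bad_trt <- setdiff(unique(design$treatment), c("UT", "IR"))
  if (length(bad_trt) > 0) {
    abort(sprintf("unknown treatment level: %s", bad_trt[1]))
  }
  for (s in samples) {
    v <- counts[[s]]
    if (!is.numeric(v)) abort(sprintf("non-numeric counts in sample %s", s))
    if (anyNA(v)) abort(sprintf("missing counts in sample %s", s))
    if (any(v < 0)) abort(sprintf("negative count in sample %s", s))
    if (any(v != round(v))) {
      abort(sprintf("non-integer count in sample %s", s))
    }
    counts[[s]] <- as.integer(round(v))
  }
  design <- design %>% filter(.data$sample %in% samples)
  list(counts = counts, design = design)
}

#' Read a bedGraph coverage track
#'
#' @param lines Character vector of 4-column bedGraph lines, or use
#'   [read_bedgraph_file()] for a path. Runs are sorted per chromosome on
#'   load; overlapping runs are an error.
#' @return A coverage tibble with columns `chrom`, `start`, `end`, `value`,
#'   sorted by chromosome and start.
#' @examples
#' read_bedgraph(c("chr1\t0\t10\t2.0", "chr1\t10\t20\t1.0"))
#' @export
read_bedgraph <- function(lines) {
  lines <- drop_comment_lines(lines)
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  value = double()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4)) abort("bedGraph requires 4 columns")
  track <- tibble(
    chrom = vapply(fields, `[[`, "", 1),
    start = parse_coord(vapply(fields, `[[`, "", 2), "start"),
    end = parse_coord(vapply(fields, `[[`, "", 3), "end"),
    value = parse_signal(vapply(fields, `[[`, "", 4), "value")
  )
  if (any(track$start >= track$end)) abort("bedGraph run with start >= end")
  if (any(track$value < 0)) abort("negative coverage value")
  track <- track %>% arrange(.data$chrom, .data$start)
  overlap <- track %>%
    group_by(.data$chrom) %>%
    summarise(bad = any(head(.data$end, -1) > tail(.data$start, -1)),
              .groups = "drop")
  if (any(overlap$bad)) {
    abort(sprintf("overlapping bedGraph runs on %s",
                  overlap$chrom[overlap$bad][1]))
  }
  track
}

#' @rdname read_bedgraph
#' @param path Path to a bedGraph file.
#' @export
read_bedgraph_file <- function(path) {
  if (!file.exists(path)) abort(sprintf("bedGraph file not found: %s", path))
  read_bedgraph(readLines(path, warn = FALSE))
}

#' Write tables back out
#'
#' Writers mirroring the readers, used by the pipeline and the fixture
#' generator so that a write-then-read round trip is the identity.
#'
#' @param peaks,genes,track Tibbles in the package's standard shapes.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", peaks$chrom, peaks$start,
                   peaks$end, peaks$peak_id, num_str(peaks$signal_ut),
                   num_str(peaks$signal_ir))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_peaks
#' @export
write_gene_models <- function(genes, path) {
  lines <- c("gene_id\tsymbol\tchrom\tstart\tend\tstrand",
             sprintf("%s\t%s\t%s\t%d\t%d\t%s", genes$gene_id, genes$symbol,
                     genes$chrom, genes$start, genes$end, genes$strand))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_peaks
#' @export
write_bedgraph <- function(track, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", track$chrom, track$start, track$end,
                     num_str(track$value)), path)
  invisible(path)
}

# ---- internal helpers -------------------------------------------------------

drop_comment_lines <- function(lines) {
  lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
}

parse_coord <- function(x, what) {
  suppressWarnings(v <- as.numeric(x))
  if (anyNA(v) || any(v != floor(v)) || any(v < 0)) {
    bad <- which(is.na(v) | v != floor(v) | v < 0)[1]
    abort(sprintf("non-integer %s coordinate: '%s'", what, x[bad]))
  }
  as.integer(v)
}

parse_signal <- function(x, what) {
  suppressWarnings(v <- as.numeric(x))
  if (anyNA(v)) abort(sprintf("non-numeric %s: '%s'", what, x[which(is.na(v))[1]]))
  if (any(v < 0)) abort(sprintf("negative %s", what))
  v
}

num_str <- function(x) {
  ifelse(is.na(x), "NA", format(x, trim = TRUE, scientific = FALSE, digits = 10))
}
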