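#' Mean coverage over an interval
#'
#' Length-weighted mean of a coverage track over `[start, end)`; bases not
#' covered by any run contribute 0.
#'
#' @param track Coverage tibble (`chrom`, `start`, `end`, `value`) from
#'   [read_bedgraph()].
#' @param chrom,start,end Query interval (0-based, half-open). `start`/`end`
#'   may be vectors for many intervals on the same chromosome.
#' @return Numeric vector of mean coverage values.
#' @export
mean_signal <- function(track, chrom, start, end) {
  if (any(end <= start)) abort("interval length must be > 0")
  runs <- track %>% filter(.data$chrom == .env$chrom)
  vapply(seq_along(start), function(i) {
    ov <- pmin(runs$end, end[i]) - pmax(runs$start, start[i])
    sum(runs$value[ov > 0] * ov[ov > 0]) / (end[i] - start[i])
  }, numeric(1))
}

#' Peak center
#'
#' Midpoint of a 0-based half-open interval: `floor((start + end - 1) / 2)`.
#'
#' @param start,end Interval bounds (vectors allowed).
#' @return Integer vector of center positions.
#' @examples
#' peak_center(100, 200) # 149
#' @export
peak_center <- function(start, end) {
  stopifnot(all(start < end))
  as.integer(floor((start + end - 1) / 2))
}

#' Binding fold change with pseudocount
#'
#' `fc = (signal_ir + pseudocount) / (signal_ut + pseudocount)`; the
#' pseudocount guards zero-signal windows and makes fc symmetric there
#' (0/0 -> 1).
#'
#' @param signal_ut,signal_ir Non-negative binding signals.
#' @param pseudocount Added to both signals, default 0.5.
#' @return Numeric vector of fold changes.
#' @export
binding_fold_change <- function(signal_ut, signal_ir, pseudocount = 0.5) {
  if (any(signal_ut < 0) || any(signal_ir < 0)) {
    abort("binding signals must be >= 0")
  }
  (signal_ir + pseudocount) / (signal_ut + pseudocount)
}

#' Classify peaks into binding-dynamics groups
#'
#' Group I: fold change >= `thresh` (binding increased after irradiation);
#' Group III: fold change <= `1/thresh` (binding decreased); Group II:
#' everything between (minimal change). Both boundaries belong to I/III.
#'
#' @param fc Positive binding fold changes.
#' @param thresh Fold-change threshold, default 1.5.
#' @return Character vector in `c("I", "II", "III")`.
#' @examples
#' classify_peak_group(c(1.5, 1.0, 1 / 1.5))
#' @export
classify_peak_group <- function(fc, thresh = 1.5) {
  stopifnot(all(fc > 0), thresh > 1)
  case_when(fc >= thresh ~ "I", fc <= 1 / thresh ~ "III", .default = "II")
}

#' Classify TSS proximity
#'
#' @param distance_bp Non-negative distances from peak center to nearest TSS.
#' @param thresh Proximal/distal boundary in bp, default 1000 (inclusive:
#'   a peak exactly at the threshold is proximal).
#' @return Character vector in `c("proximal", "distal")`; `NA` distances stay
#'   `NA`.
#' @export
classify_proximity <- function(distance_bp, thresh = 1000) {
  stopifnot(all(distance_bp >= 0, na.rm = TRUE))
  ifelse(distance_bp <= thresh, "proximal", "distal")
}

#' Binned signal profiles around peak centers
#'
#' For each center, the window `[center - halfwidth, center + halfwidth)` is
#' split into `n_bins` equal bins and [mean_signal()] computed per bin — the
#' matrix behind binding-intensity heatmaps.
#'
#' @param track Coverage tibble.
#' @param chrom Chromosome of the centers.
#' @param centers Integer vector of center positions.
#' @param halfwidth Window half-width in bp (> 0), e.g. 1000.
#' @param n_bins Number of bins (>= 1); bin width must be >= 1 bp.
#' @return Numeric matrix, one row per center, one column per bin.
#' @export
signal_matrix <- function(track, chrom, centers, halfwidth, n_bins = 50) {
  stopifnot(halfwidth > 0, n_bins >= 1)
  width <- 2 * halfwidth / n_bins
  if (width < 1) abort("bin width < 1 bp; reduce n_bins or widen the window")
  edges <- seq(-halfwidth, halfwidth, length.out = n_bins + 1)
  out <- matrix(0, nrow = length(centers), ncol = n_bins)
  for (b in seq_len(n_bins)) {
    out[, b] <- mean_signal(track, chrom,
                            floor(centers + edges[b]),
                            floor(centers + edges[b + 1]))
  }
  rownames(out) <- names(centers)
  out
}

#' Quantify and classify peaks
#'
#' Fills per-peak untreated/irradiated signals (from peak-file columns when
#' present, otherwise as window means of the two coverage tracks), computes
#' binding fold changes, assigns Groups I-III, and annotates the nearest TSS
#' with a proximal/distal call.
#'
#' @param peaks Peak tibble from [read_peaks()].
#' @param genes Gene-model tibble from [read_gene_models()].
#' @param track_ut,track_ir Optional coverage tibbles used when the peak file
#'   carries no signal columns; signals are window means over
#'   `center +/- signal_halfwidth`.
#' @param signal_halfwidth Window half-width for track summarization,
#'   default 1000.
#' @param peak_fc_thresh Group threshold, default 1.5.
#' @param proximity_thresh Proximal/distal boundary, default 1000.
#' @param pseudocount Passed to [binding_fold_change()].
#' @return A `tf_peaks` tibble: `peak_id`, `chrom`, `start`, `end`, `center`,
#'   `signal_ut`, `signal_ir`, `fc`, `group`, `nearest_gene`, `distance`,
#'   `proximity`.
#' @export
peak_analyze <- function(peaks, genes, track_ut = NULL, track_ir = NULL,
                         signal_halfwidth = 1000, peak_fc_thresh = 1.5,
                         proximity_thresh = 1000, pseudocount = 0.5) {
  peaks <- peaks %>% mutate(center = peak_center(.data$start, .data$end))
  if (anyNA(peaks$signal_ut) || anyNA(peaks$signal_ir)) {
    if (is.null(track_ut) || is.null(track_ir)) {
      abort("peaks carry no signal columns and no coverage tracks were given")
    }
    for (ch in unique(peaks$chrom)) {
      rows <- peaks$chrom == ch
      s <- pmax(peaks$center[rows] - signal_halfwidth, 0)
      e <- peaks$center[rows] + signal_halfwidth
      peaks$signal_ut[rows] <- mean_signal(track_ut, ch, s, e)
      peaks$signal_ir[rows] <- mean_signal(track_ir, ch, s, e)
    }
  }
  nt <- nearest_tss(peaks, genes)
  peaks %>%
    mutate(
      fc = binding_fold_change(.data$signal_ut, .data$signal_ir, pseudocount),
      group = classify_peak_group(.data$fc, peak_fc_thresh)
    ) %>%
    left_join(nt, by = "peak_id") %>%
    mutate(proximity = classify_proximity(.data$distance, proximity_thresh)) %>%
    structure(class = c("tf_peaks", class(peaks)))
}

#' Summarize peak groups
#'
#' @param peaks A `tf_peaks` tibble from [peak_analyze()].
#' @return A one-row tibble with group counts and proximal/distal counts and
#'   percentages.
#' @export
peak_group_summary <- function(peaks) {
  n_prox <- sum(peaks$proximity == "proximal", na.rm = TRUE)
  n_dist <- sum(peaks$proximity == "distal", na.rm = TRUE)
  tibble(
    n_peaks = nrow(peaks),
    n_group_I = sum(peaks$group == "I"),
    n_group_II = sum(peaks$group == "II"),
    n_group_III = sum(peaks$group == "III"),
    n_proximal = n_prox,
    n_distal = n_dist,
    pct_proximal = 100 * n_prox / nrow(peaks),
    pct_distal = 100 * n_dist / nrow(peaks)
  )
}
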