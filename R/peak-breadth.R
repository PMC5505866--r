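#' Widths of peaks spanning TSSs
#'
#' For each transcript, peaks whose half-open interval contains the TSS base
#' are found; a peak ending exactly at the TSS does not span it. When
#' several peaks contain one TSS the widest is taken (deterministic, and
#' conservative toward the breadth comparison); transcripts without a
#' spanning peak are omitted.
#'
#' @param peaks `GRanges` of called peaks (e.g. [read_broadpeak()]); must be
#'   sorted per chromosome or `auto_sort` must be TRUE.
#' @param tss width-1 `GRanges` of TSS bases named by transcript.
#' @param transcript_set optional character vector restricting the
#'   transcripts considered.
#' @param auto_sort sort unsorted peaks with a warning instead of erroring.
#' @return A data.frame (`breadth_sample`): `transcript_id`, `width` in bp.
#' @examples
#' peaks <- GenomicRanges::GRanges("chrS", IRanges::IRanges(101, 600))
#' tss <- GenomicRanges::GRanges("chrS", IRanges::IRanges(301, width = 1))
#' names(tss) <- "tx1"
#' tss_spanning_widths(peaks, tss)  # width 500
#' @export
tss_spanning_widths <- function(peaks, tss, transcript_set = NULL,
                                auto_sort = TRUE) {
  o <- order(as.factor(seqnames(peaks)), start(peaks))
  if (!identical(o, seq_along(peaks))) {
    if (!auto_sort) stop2("peaks are not sorted; sort or set auto_sort")
    warning("peaks were not sorted; sorting by chromosome and start",
            call. = FALSE)
    peaks <- peaks[o]
  }
  if (!is.null(transcript_set)) tss <- tss[names(tss) %in% transcript_set]
  hits <- findOverlaps(tss, peaks, ignore.strand = TRUE)
  if (length(hits) == 0)
    return(structure(data.frame(transcript_id = character(0),
                                width = integer(0)),
                     class = c("breadth_sample", "data.frame")))
  w <- width(peaks)[S4Vectors::subjectHits(hits)]
  tx <- names(tss)[S4Vectors::queryHits(hits)]
  best <- tapply(w, tx, max)
  out <- data.frame(transcript_id = names(best),
                    width = as.integer(best),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[match(intersect(names(tss), out$transcript_id),
                   out$transcript_id), ]
  rownames(out) <- NULL
  class(out) <- c("breadth_sample", "data.frame")
  out
}

#' Empirical cumulative distribution of peak widths
#'
#' Right-continuous ECDF: `F(x)` is the fraction of widths `<= x`,
#' evaluated at each distinct support point.
#'
#' @param widths positive widths in bp.
#' @return data.frame with `width` (sorted distinct values) and
#'   `cum_fraction`; `cum_fraction[length]` is 1.
#' @examples
#' breadth_ecdf(c(1, 2, 2, 4))  # F(2) = 0.75
#' @export
breadth_ecdf <- function(widths) {
  w <- as.numeric(widths)
  if (length(w) == 0) stop2("empty width sample")
  if (any(w <= 0)) stop2("widths must be positive")
  support <- sort(unique(w))
  data.frame(width = support,
             cum_fraction = vapply(support, function(x) mean(w <= x),
                                   numeric(1)))
}

#' Compare peak-breadth distributions between two gene sets
#'
#' Two-sample two-sided KS test on the width samples (asymptotic p); D is
#' invariant under any common monotone transform of both samples.
#'
#' @param a,b `breadth_sample` data.frames (or numeric width vectors),
#'   each with at least 2 widths.
#' @return List with `D` and `p_value`.
#' @export
compare_breadth <- function(a, b) {
  wa <- if (is.data.frame(a)) a$width else a
  wb <- if (is.data.frame(b)) b$width else b
  ks_compare(wa, wb)
}

#' Histogram of peak widths
#'
#' Counts per fixed-width bin, half-open `[start, start + bin_width)`,
#' anchored at `origin` (default: the largest bin boundary at or below the
#' smallest width). Counts sum to the sample size.
#'
#' @param widths positive widths in bp.
#' @param bin_width bin width in bp (positive).
#' @param origin left edge of the first bin.
#' @return data.frame with `bin_start`, `bin_end`, `count`.
#' @examples
#' breadth_histogram(c(100, 149, 200), 50, origin = 100)  # counts 2, 0, 1
#' @export
breadth_histogram <- function(widths, bin_width,
                              origin = floor(min(widths) / bin_width) *
                                bin_width) {
  if (length(widths) == 0) stop2("empty width sample")
  if (bin_width <= 0) stop2("bin width must be positive")
  idx <- floor((widths - origin) / bin_width)
  if (any(idx < 0)) stop2("origin exceeds the smallest width")
  counts <- tabulate(idx + 1L, nbins = max(idx) + 1L)
  data.frame(bin_start = origin + (seq_along(counts) - 1L) * bin_width,
             bin_end = origin + seq_along(counts) * bin_width,
             count = counts)
}

#' Write breadth results to TSV
#'
#' @param widths a `breadth_sample` data.frame.
#' @param dir output directory (`widths.tsv`, `ecdf.tsv`).
#' @return Invisibly, the directory.
#' @export
write_breadth <- function(widths, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(widths, file.path(dir, "widths.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(breadth_ecdf(widths$width), file.path(dir, "ecdf.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
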