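#' Per-base coverage track with a library size
#'
#' A thin container for ChIP-seq style coverage: a run-length encoded
#' per-base depth vector per chromosome plus the total number of mapped
#' reads N used for per-million scaling. Tracks here use base-resolution
#' read events (one read covers one base), so N defaults to the sum of the
#' coverage.
#'
#' @param coverage a named list of numeric vectors or `Rle`s (one per
#'   chromosome), or a single vector (chromosome `chrS`).
#' @param total_reads total mapped reads N; defaults to `sum(coverage)`.
#' @return An object of class `coverage_track` with elements `coverage`
#'   (list of `Rle`) and `total_reads`.
#' @export
coverage_track <- function(coverage, total_reads = NULL) {
  if (!is.list(coverage)) coverage <- list(chrS = coverage)
  if (is.null(names(coverage))) stop2("coverage chromosomes must be named")
  coverage <- lapply(coverage, function(v) {
    v <- if (is(v, "Rle")) v else Rle(as.numeric(v))
    if (any(runValue(v) < 0)) stop2("coverage must be nonnegative")
    v
  })
  if (is.null(total_reads))
    total_reads <- sum(vapply(coverage, function(v) sum(as.numeric(v)),
                              numeric(1)))
  if (total_reads <= 0) stop2("total_reads must be positive")
  structure(list(coverage = coverage, total_reads = as.numeric(total_reads)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", length(x$coverage), "chromosome(s),",
      format(x$total_reads, big.mark = ","), "total reads\n")
  invisible(x)
}

chrom_cov <- function(track, chrom) {
  v <- track$coverage[[chrom]]
  if (is.null(v)) stop2("no coverage for chromosome '", chrom, "'")
  v
}

# mean per-base depth over 1-based closed intervals [start, end]
interval_mean_depth <- function(track, chrom, start, end) {
  v <- chrom_cov(track, chrom)
  if (any(start < 1) || any(end > length(v)) || any(start > end))
    stop2("interval out of bounds for chromosome '", chrom,
          "' (length ", length(v), ")")
  viewMeans(Views(v, start = start, end = end))
}

#' Input-normalized histone methylation level over intervals
#'
#' Implements the per-million input subtraction used throughout the ChIP
#' analyses: `level = depth_IP / (N_IP / 1e6) - depth_input / (N_input /
#' 1e6)`, where depth is the mean per-base coverage over the interval and N
#' the total mapped reads of the track. Negative values are kept; the
#' formula permits them.
#'
#' @param ip,input `coverage_track`s for the immunoprecipitation and the
#'   input control.
#' @param chrom chromosome name.
#' @param start,end 1-based closed interval bounds (vectorized).
#' @return Numeric vector of normalized levels, one per interval.
#' @examples
#' ip <- coverage_track(rep(100, 50), total_reads = 2e7)
#' inp <- coverage_track(rep(30, 50), total_reads = 1.5e7)
#' normalized_level(ip, inp, "chrS", 1, 50)  # 100/20 - 30/15 = 3
#' @export
normalized_level <- function(ip, input, chrom, start, end) {
  interval_mean_depth(ip, chrom, start, end) / (ip$total_reads / 1e6) -
    interval_mean_depth(input, chrom, start, end) / (input$total_reads / 1e6)
}

#' Write a coverage track as bedGraph plus a totals sidecar
#'
#' @param track a `coverage_track`.
#' @param path output bedGraph path; `<path>.totals.json` records N.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path) {
  grl <- lapply(names(track$coverage), function(chrom) {
    v <- track$coverage[[chrom]]
    ends <- cumsum(runLength(v))
    starts <- ends - runLength(v) + 1L
    GRanges(chrom, IRanges(starts, ends), score = runValue(v))
  })
  gr <- do.call(c, grl)
  rtracklayer::export(gr, path, format = "bedGraph")
  jsonlite::write_json(list(total_reads = track$total_reads),
                       paste0(path, ".totals.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' Bases not covered by any bedGraph record get depth 0. The library size is
#' taken from the `<path>.totals.json` sidecar when present (or from
#' `total_reads`), else it defaults to the coverage sum.
#'
#' @param path bedGraph file.
#' @param total_reads optional explicit library size.
#' @param chrom_lengths optional named vector of chromosome lengths; defaults
#'   to the last covered base per chromosome.
#' @return A `coverage_track`.
#' @export
read_bedgraph <- function(path, total_reads = NULL, chrom_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  chroms <- unique(as.character(seqnames(gr)))
  cov <- lapply(chroms, function(chrom) {
    g <- gr[as.character(seqnames(gr)) == chrom]
    g <- g[order(start(g))]
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[chrom]] else
      max(end(g))
    # records are disjoint in well-formed bedGraph; build the run-length
    # encoding directly, interleaving zero-depth gap runs
    gap_len <- start(g) - c(0L, head(end(g), -1)) - 1L
    lens <- as.vector(rbind(gap_len, width(g)))
    vals <- as.vector(rbind(0, g$score))
    tail_gap <- len - max(end(g))
    if (tail_gap > 0) {
      lens <- c(lens, tail_gap)
      vals <- c(vals, 0)
    }
    keep <- lens > 0
    Rle(vals[keep], lens[keep])
  })
  names(cov) <- chroms
  sidecar <- paste0(path, ".totals.json")
  if (is.null(total_reads) && file.exists(sidecar))
    total_reads <- jsonlite::read_json(sidecar)$total_reads
  coverage_track(cov, total_reads)
}
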