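#' Simulate IP/input chromatin coverage and peaks for planted classes
#'
#' Generates matched H3K4me3-style IP and input coverage on the synthetic
#' chromosome of a [simulate_expression()] truth table. Input coverage is
#' Poisson(background) at every base. IP coverage is Poisson(background)
#' outside peaks and Poisson(background x enrichment) inside each
#' transcript's planted peak, a `peak_width`-bp interval centered on its TSS
#' (clipped to the chromosome); with enrichment 1 the IP and input tracks are
#' exchangeable draws. ON-memory transcripts get broader and stronger peaks
#' than reprogrammed-down ones under the default [sim_config()], mirroring
#' the chromatin contrast the classifier is meant to explain.
#'
#' @param truth the `truth` data.frame from [simulate_expression()].
#' @param config the same [sim_config()].
#' @return A list with `ip` and `input` ([coverage_track()]s), `peaks`
#'   (a `GRanges` in broadPeak style: name, score, signalValue), and `tss`
#'   (a width-1 `GRanges` of TSS bases with transcript names and strands).
#' @examples
#' cfg <- sim_config(seed = 2, n_transcripts = 20,
#'                   n_samples = c(donor = 3, IVF_ectoderm = 4, NT_ectoderm = 4))
#' sim <- simulate_expression(cfg)
#' chrom <- simulate_chromatin(sim$truth, cfg)
#' chrom$ip
#' @export
simulate_chromatin <- function(truth, config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  L <- config$chrom_length
  if (any(truth$tss - 2000 < 0 | truth$tss + 2000 > L))
    stop2("TSS window exceeds chromosome bounds; enlarge chrom_length")
  set.seed(config$seed + 1L)  # distinct stream from the expression draws

  bg <- config$background_depth
  # 0-based half-open peak intervals centered on the TSS base
  half <- floor(truth$peak_width / 2)
  p_start0 <- pmax(0L, truth$tss - half)
  p_end0 <- pmin(L, truth$tss + (truth$peak_width - half))

  rate <- rep(bg, L)
  for (i in seq_len(nrow(truth))) {
    idx <- (p_start0[i] + 1L):p_end0[i]           # 1-based bases in peak
    rate[idx] <- pmax(rate[idx], bg * truth$peak_enrichment[i])
  }
  input_cov <- rpois(L, bg)
  ip_cov <- rpois(L, rate)

  peaks <- GRanges("chrS", IRanges(p_start0 + 1L, p_end0),
                   name = truth$transcript_id,
                   score = as.integer(round(10 * truth$peak_enrichment)),
                   signalValue = truth$peak_enrichment)
  names(peaks) <- truth$transcript_id
  tss <- GRanges("chrS", IRanges(truth$tss + 1L, width = 1L),
                 strand = truth$strand)
  names(tss) <- truth$transcript_id

  list(ip = coverage_track(list(chrS = Rle(as.numeric(ip_cov)))),
       input = coverage_track(list(chrS = Rle(as.numeric(input_cov)))),
       peaks = peaks,
       tss = tss)
}

#' Write simulated chromatin data to disk
#'
#' Emits `ip.bedgraph` / `input.bedgraph` (with `.totals.json` sidecars),
#' `peaks.bed` (broadPeak dialect) and `tss.bed` (BED6).
#'
#' @param chrom result of [simulate_chromatin()].
#' @param dir output directory.
#' @return Invisibly, the directory.
#' @export
write_sim_chromatin <- function(chrom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bedgraph(chrom$ip, file.path(dir, "ip.bedgraph"))
  write_bedgraph(chrom$input, file.path(dir, "input.bedgraph"))
  write_broadpeak(chrom$peaks, file.path(dir, "peaks.bed"))
  write_tss_bed(chrom$tss, file.path(dir, "tss.bed"))
  invisible(dir)
}

#' Write peaks in the BED broadPeak dialect
#'
#' Columns: chrom, start, end, name, score, strand, signalValue, pValue,
#' qValue (the last two -1 when unknown), 0-based half-open.
#'
#' @param peaks a `GRanges`, optionally with `name`, `score`, `signalValue`
#'   metadata columns.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_broadpeak <- function(peaks, path) {
  mc <- mcols(peaks)
  df <- data.frame(chrom = as.character(seqnames(peaks)),
                   start = start(peaks) - 1L,
                   end = end(peaks),
                   name = if ("name" %in% names(mc)) mc$name else
                     sprintf("peak%d", seq_along(peaks)),
                   score = if ("score" %in% names(mc)) mc$score else 0L,
                   strand = ".",
                   signalValue = if ("signalValue" %in% names(mc))
                     mc$signalValue else 0,
                   pValue = -1, qValue = -1)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED/broadPeak interval file into a GRanges
#'
#' Accepts plain BED3+ or broadPeak; coordinates are converted from 0-based
#' half-open to the 1-based closed GRanges convention.
#'
#' @param path BED or broadPeak file.
#' @return A `GRanges` with `name`, and `signalValue` when present.
#' @export
read_broadpeak <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  gr <- GRanges(df[[1]], IRanges(df[[2]] + 1L, df[[3]]))
  if (ncol(df) >= 4) {
    gr$name <- df[[4]]
    names(gr) <- df[[4]]
  }
  if (ncol(df) >= 5) gr$score <- df[[5]]
  if (ncol(df) >= 6) strand(gr) <- ifelse(df[[6]] %in% c("+", "-"),
                                          df[[6]], "*")
  if (ncol(df) >= 7) gr$signalValue <- df[[7]]
  gr
}

#' Write TSS positions as BED6
#'
#' One record per transcript: the width-1 TSS base, 0-based half-open,
#' score 0, strand as annotated.
#'
#' @param tss width-1 `GRanges` with transcript names.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_tss_bed <- function(tss, path) {
  df <- data.frame(chrom = as.character(seqnames(tss)),
                   start = start(tss) - 1L,
                   end = end(tss),
                   name = names(tss) %||% sprintf("tss%d", seq_along(tss)),
                   score = 0L,
                   strand = as.character(strand(tss)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read BED6 TSS annotation
#'
#' @param path BED6 file as written by [write_tss_bed()].
#' @return A width-1 `GRanges` named by transcript.
#' @export
read_tss_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  gr <- GRanges(df[[1]], IRanges(df[[2]] + 1L, df[[3]]),
                strand = ifelse(df[[6]] %in% c("+", "-"), df[[6]], "*"))
  names(gr) <- df[[4]]
  gr
}
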