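#' Binned input-normalized signal profiles around TSSs
#'
#' For each transcript a `window`-bp region centered on the TSS (0-based
#' coordinates: `[tss - window/2, tss + window/2)`) is cut into `bin`-bp
#' bins, and each bin gets the input-normalized per-million level of
#' [normalized_level()] — the bin summary is mean per-base depth, so values
#' are bin-size invariant. For minus-strand transcripts the bin order is
#' reversed, so bin 1 is always the most-upstream bin of the gene.
#' Transcripts whose window leaves the chromosome are skipped with a
#' warning.
#'
#' @param ip,input [coverage_track()]s.
#' @param tss width-1 `GRanges` of TSS bases (names = transcript ids,
#'   strand set), e.g. from [read_tss_bed()] or [simulate_chromatin()].
#' @param window window width in bp (default 4000; 2000 reproduces the
#'   human reanalysis setting).
#' @param bin bin width in bp (default 50); must divide `window`.
#' @return An object of class `tss_profiles`: list with `bins` (matrix,
#'   transcripts x `window/bin` bins), `integral` (row sums), `window`,
#'   `bin`.
#' @export
tss_window_profiles <- function(ip, input, tss, window = 4000, bin = 50) {
  if (window <= 0 || bin <= 0 || window %% bin != 0)
    stop2("bin must divide window and both must be positive")
  nbin <- window %/% bin
  half <- window %/% 2
  ids <- names(tss) %||% sprintf("tss%d", seq_along(tss))

  tss0 <- start(tss) - 1L                      # 0-based TSS base
  chroms <- as.character(seqnames(tss))
  lens <- vapply(chroms, function(ch) length(chrom_cov(ip, ch)), numeric(1))
  ok <- tss0 - half >= 0 & tss0 + half <= lens
  if (any(!ok)) {
    warning(sum(!ok), " transcript(s) skipped: TSS window outside ",
            "chromosome bounds", call. = FALSE)
  }
  if (!any(ok)) stop2("no TSS window fits inside the chromosome")

  keep <- which(ok)
  mat <- matrix(NA_real_, length(keep), nbin,
                dimnames = list(ids[keep], NULL))
  for (ch in unique(chroms[keep])) {
    rows <- which(chroms[keep] == ch)
    t0 <- tss0[keep][rows]
    # bin k (1-based) covers 0-based [t0 - half + (k-1)*bin, ... + bin)
    starts0 <- rep(t0 - half, each = nbin) +
      rep((seq_len(nbin) - 1L) * bin, length(rows))
    lv <- normalized_level(ip, input, ch, starts0 + 1L, starts0 + bin)
    mat[rows, ] <- matrix(lv, length(rows), nbin, byrow = TRUE)
  }
  minus <- as.character(strand(tss))[keep] == "-"
  mat[minus, ] <- mat[minus, nbin:1, drop = FALSE]

  structure(list(bins = mat, integral = rowSums(mat),
                 window = window, bin = bin),
            class = "tss_profiles")
}

#' @export
print.tss_profiles <- function(x, ...) {
  cat("tss_profiles:", nrow(x$bins), "transcripts x", ncol(x$bins),
      "bins (", x$window, "bp window,", x$bin, "bp bins )\n")
  invisible(x)
}

#' Subset TSS profiles by transcript id
#'
#' @param profiles a `tss_profiles` object.
#' @param ids transcript ids to keep (silently drops absent ones).
#' @return A `tss_profiles` restricted to `ids`.
#' @export
subset_profiles <- function(profiles, ids) {
  keep <- intersect(ids, rownames(profiles$bins))
  structure(list(bins = profiles$bins[keep, , drop = FALSE],
                 integral = profiles$integral[keep],
                 window = profiles$window, bin = profiles$bin),
            class = "tss_profiles")
}

#' Average signal metaplot of a gene set
#'
#' Per-bin arithmetic mean across the profiles of a gene set; replicate
#' tracks are profiled separately upstream and can be averaged afterwards.
#'
#' @param profiles a `tss_profiles` object (or a bins matrix).
#' @return Numeric vector, one mean level per bin, 5' to 3'.
#' @export
metaplot <- function(profiles) {
  mat <- if (inherits(profiles, "tss_profiles")) profiles$bins else
    as.matrix(profiles)
  if (nrow(mat) == 0) stop2("empty gene set")
  colMeans(mat)
}

#' Compare integral TSS signal between two gene sets
#'
#' The integral (sum over bins) level of each transcript's window is the
#' per-gene summary; the two sets of integrals are compared with a
#' two-sample two-sided KS test (asymptotic p).
#'
#' @param set_a,set_b `tss_profiles` objects (at least 2 transcripts each).
#' @return List with `D` and `p_value`.
#' @export
compare_integral_levels <- function(set_a, set_b) {
  ks_compare(set_a$integral, set_b$integral)
}

#' Write TSS profiles and a metaplot to TSV
#'
#' @param profiles a `tss_profiles` object.
#' @param dir output directory (`profiles.tsv`, `metaplot.tsv`).
#' @return Invisibly, the directory.
#' @export
write_tss_profiles <- function(profiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(transcript_id = rownames(profiles$bins),
                   profiles$bins, check.names = FALSE)
  names(df)[-1] <- sprintf("bin%03d", seq_len(ncol(profiles$bins)))
  write.table(df, file.path(dir, "profiles.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  mp <- data.frame(bin = seq_len(ncol(profiles$bins)),
                   offset_bp = (seq_len(ncol(profiles$bins)) - 1) *
                     profiles$bin - profiles$window / 2,
                   mean_level = metaplot(profiles))
  write.table(mp, file.path(dir, "metaplot.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
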