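#' Counts per million
#'
#' `CPM = count / column_total x 1e6`, per sample. Every column of the
#' result sums to 1e6 (over all transcripts, before any filtering).
#'
#' @param x a [count_matrix()] or a plain counts matrix.
#' @return Numeric matrix of CPM values, same dimnames as the counts.
#' @examples
#' m <- matrix(c(5, 15, 80), 3, 1, dimnames = list(paste0("t", 1:3), "s1"))
#' compute_cpm(m)
#' @export
compute_cpm <- function(x) {
  counts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  totals <- colSums(counts)
  bad <- totals == 0
  if (any(bad))
    stop2("sample(s) with all-zero counts: ",
          paste(colnames(counts)[bad], collapse = ", "))
  sweep(counts, 2, totals, "/") * 1e6
}

#' Reads per kilobase per million
#'
#' `RPKM = count / (length_kb x column_total_millions)`; equivalently
#' `RPKM = CPM / length_kb` for every cell.
#'
#' @param x a [count_matrix()] (lengths are taken from it), or a counts
#'   matrix with `lengths` supplied.
#' @param lengths per-transcript lengths in bp when `x` is a plain matrix.
#' @return Numeric matrix of RPKM values.
#' @examples
#' m <- matrix(c(10, 999990), 2, 1, dimnames = list(c("t1", "t2"), "s1"))
#' compute_rpkm(m, lengths = c(2000, 1000))[1, ]  # count 10, 2 kb, 1e6 reads -> 5
#' @export
compute_rpkm <- function(x, lengths = NULL) {
  if (inherits(x, "count_matrix")) {
    lengths <- x$lengths
    counts <- x$counts
  } else {
    counts <- as.matrix(x)
  }
  if (is.null(lengths)) stop2("transcript lengths are required for RPKM")
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  lengths <- as.numeric(lengths)
  if (length(lengths) != nrow(counts) || anyNA(lengths) || any(lengths <= 0))
    stop2("missing or nonpositive transcript length")
  compute_cpm(counts) / (lengths / 1000)
}

#' Expression filter: CPM > 1 in all donor or 70% of IVF or 70% of NT
#'
#' A transcript stays in the analysis if it has CPM strictly greater than
#' `cpm_cut` in every donor sample, or in at least `frac_expressed` of the
#' IVF ectoderm samples, or in at least `frac_expressed` of the NT ectoderm
#' samples. With the defaults, 8/11 IVF samples (72.7%) pass and 7/11
#' (63.6%) fail.
#'
#' @param cpm CPM matrix from [compute_cpm()].
#' @param samples sample sheet with `sample_id` and `group` columns matching
#'   the CPM columns.
#' @param cpm_cut expression cutoff (strict >), default 1.
#' @param frac_expressed required fraction of expressing samples in an
#'   ectoderm group (>=), default 0.7.
#' @return Character vector of kept transcript ids.
#' @export
expression_filter <- function(cpm, samples, cpm_cut = 1,
                              frac_expressed = 0.7) {
  if (frac_expressed <= 0 || frac_expressed > 1)
    stop2("frac_expressed must lie in (0, 1]")
  groups <- c("donor", "IVF_ectoderm", "NT_ectoderm")
  idx <- lapply(groups, function(g) which(samples$group == g))
  names(idx) <- groups
  empty <- vapply(idx, length, integer(1)) == 0
  if (any(empty))
    stop2("empty group(s): ", paste(groups[empty], collapse = ", "))
  expressed <- cpm > cpm_cut
  keep <- rowSums(!expressed[, idx$donor, drop = FALSE]) == 0 |
    rowMeans(expressed[, idx$IVF_ectoderm, drop = FALSE]) >= frac_expressed |
    rowMeans(expressed[, idx$NT_ectoderm, drop = FALSE]) >= frac_expressed
  rownames(cpm)[keep]
}
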