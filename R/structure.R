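#' Two-stage z-score scaling across batches
#'
#' Stage 1 standardizes each transcript within each batch (subtract the
#' batch mean, divide by the batch sd); stage 2 then standardizes each
#' transcript across all samples. The per-batch stage removes location and
#' scale differences between batches of experiments produced at the same
#' time; the second stage puts every transcript on one scale for clustering.
#' Sample sd (n - 1) is used throughout. Rows (or within-batch segments)
#' with zero sd are set to 0 with a warning, preserving the matrix shape.
#'
#' @param x numeric matrix, transcripts x samples (typically CPM of
#'   expression-filtered transcripts).
#' @param batches batch label per sample (length `ncol(x)`); every batch
#'   needs at least 2 samples.
#' @return A matrix of class `scaled_matrix`; after stage 2 every
#'   non-constant row has mean 0 and sd 1. Attribute `scaling_log` records
#'   the batch partition.
#' @export
double_zscore <- function(x, batches) {
  x <- as.matrix(x)
  if (anyNA(x)) stop2("input contains missing values")
  batches <- as.character(batches)
  if (length(batches) != ncol(x))
    stop2("one batch label per sample is required")
  sizes <- table(batches)
  if (any(sizes < 2))
    stop2("batch(es) with a single sample (sd undefined): ",
          paste(names(sizes)[sizes < 2], collapse = ", "))

  z <- x
  n_const <- 0
  for (b in unique(batches)) {
    cols <- which(batches == b)
    m <- rowMeans(x[, cols, drop = FALSE])
    s <- apply(x[, cols, drop = FALSE], 1, sd)
    zb <- (x[, cols, drop = FALSE] - m) / s
    zb[s == 0, ] <- 0
    n_const <- n_const + sum(s == 0)
    z[, cols] <- zb
  }
  m2 <- rowMeans(z)
  s2 <- apply(z, 1, sd)
  out <- (z - m2) / s2
  out[s2 == 0, ] <- 0
  if (n_const > 0 || any(s2 == 0))
    warning("constant transcript rows (within a batch or overall) were ",
            "set to zero", call. = FALSE)
  structure(out,
            scaling_log = list(stages = c("per-batch z-score",
                                          "global z-score"),
                               batches = split(colnames(x) %||%
                                                 seq_len(ncol(x)), batches)),
            class = c("scaled_matrix", class(out)))
}

#' Hierarchical clustering of samples (Ward criterion, Euclidean distance)
#'
#' Agglomerative clustering of the sample columns using the `ward.D`
#' convention: the Lance-Williams Ward update applied to the unsquared
#' Euclidean distance matrix. Merge order is deterministic.
#'
#' @param x a `scaled_matrix` (or any numeric matrix), transcripts x
#'   samples; samples are clustered.
#' @return An `hclust` object (merge list, heights, labels).
#' @export
hierarchical_cluster <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x) || any(!is.finite(x)))
    stop2("input contains NA or non-finite values")
  if (ncol(x) < 2) stop2("need at least two samples")
  hclust(dist(t(x), method = "euclidean"), method = "ward.D")
}

#' Serialize a dendrogram to JSON
#'
#' @param hc an `hclust` object.
#' @param path output JSON path (merge list, heights, labels).
#' @return Invisibly, `path`.
#' @export
write_dendrogram <- function(hc, path) {
  jsonlite::write_json(list(merge = unclass(as.data.frame(hc$merge)),
                            height = hc$height,
                            order = hc$order,
                            labels = hc$labels),
                       path, digits = NA)
  invisible(path)
}

#' Correlation-mode PCA of samples
#'
#' Principal components of the samples with transcripts as variables, each
#' standardized to unit variance before the eigendecomposition (the
#' correlation-matrix convention). Zero-variance transcripts are dropped
#' with a warning.
#'
#' @param x numeric matrix, transcripts x samples.
#' @return List with `scores` (samples x components), `loadings`
#'   (transcripts x components) and `variance_fraction` (sums to 1).
#' @export
pca_samples <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2)
    stop2("need at least two transcripts and two samples")
  v <- apply(x, 1, var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance transcript(s) dropped",
            call. = FALSE)
    x <- x[v > 0, , drop = FALSE]
  }
  pc <- prcomp(t(x), center = TRUE, scale. = TRUE)
  list(scores = pc$x,
       loadings = pc$rotation,
       variance_fraction = pc$sdev^2 / sum(pc$sdev^2))
}

#' Log2 fold-change matrix for heatmaps
#'
#' Per transcript and sample, `log2((value + c) / (reference_mean + c))`
#' where the reference mean is either the mean over the IVF samples or the
#' mean over all samples pooled, and `c` is a pseudocount. Optionally orders
#' rows (and columns) by Ward clustering.
#'
#' @param x numeric expression matrix (e.g. RPKM or CPM), transcripts x
#'   samples.
#' @param samples sample sheet matching the columns.
#' @param reference `"IVF"` (mean IVF expression) or `"pooled"` (mean over
#'   donor, IVF and NT together).
#' @param pseudocount pseudocount `c`, default 1.
#' @param cluster_rows,cluster_cols order rows / columns by
#'   [hierarchical_cluster()] of the fold-change matrix.
#' @return List with `matrix` (log2 FC), `row_order`, `col_order`.
#' @export
heatmap_matrix <- function(x, samples, reference = c("IVF", "pooled"),
                           pseudocount = 1, cluster_rows = TRUE,
                           cluster_cols = FALSE) {
  x <- as.matrix(x)
  reference <- match.arg(reference)
  ref_cols <- if (reference == "IVF") {
    which(samples$group == "IVF_ectoderm")
  } else {
    seq_len(ncol(x))
  }
  if (length(ref_cols) == 0) stop2("empty reference group")
  ref_mean <- rowMeans(x[, ref_cols, drop = FALSE])
  fc <- log2((x + pseudocount) / (ref_mean + pseudocount))
  row_order <- seq_len(nrow(fc))
  col_order <- seq_len(ncol(fc))
  if (cluster_rows && nrow(fc) > 1)
    row_order <- hierarchical_cluster(t(fc))$order
  if (cluster_cols && ncol(fc) > 1)
    col_order <- hierarchical_cluster(fc)$order
  list(matrix = fc, row_order = row_order, col_order = col_order)
}

#' MA table: NT/IVF fold change against donor expression
#'
#' One row per transcript: `x` is the mean over donor samples of
#' `log2(1 + RPKM)`, `y` the NT-vs-IVF log2 fold change, plus the memory
#' class for coloring when labels are given.
#'
#' @param de_nt_ivf `de_result` of the NT vs IVF contrast.
#' @param donor_rpkm RPKM matrix restricted to donor samples (columns).
#' @param labels optional `memory_labels` for the class column.
#' @return data.frame with `transcript_id`, `mean_log2_rpkm_donor`,
#'   `logFC_NT_vs_IVF`, `class`.
#' @export
ma_table <- function(de_nt_ivf, donor_rpkm, labels = NULL) {
  donor_rpkm <- as.matrix(donor_rpkm)
  if (!all(de_nt_ivf$transcript_id %in% rownames(donor_rpkm)))
    stop2("donor RPKM does not cover the DE transcript universe")
  xv <- rowMeans(log2(1 + donor_rpkm[de_nt_ivf$transcript_id, ,
                                     drop = FALSE]))
  cls <- if (is.null(labels)) NA_character_ else
    labels$primary_class[match(de_nt_ivf$transcript_id,
                               labels$transcript_id)]
  data.frame(transcript_id = de_nt_ivf$transcript_id,
             mean_log2_rpkm_donor = unname(xv),
             logFC_NT_vs_IVF = de_nt_ivf$logFC,
             class = cls,
             stringsAsFactors = FALSE, row.names = NULL)
}
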