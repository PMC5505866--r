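#' Construct a count matrix with sample metadata
#'
#' The central expression container: an integer matrix of transcripts x
#' samples together with per-transcript lengths (for RPKM) and a sample sheet
#' carrying the group (`donor`, `IVF_ectoderm`, `NT_ectoderm`), a free-text
#' treatment label and a batch label per sample. Mirrors the list-based
#' container idiom of DGEList-style packages.
#'
#' @param counts integer matrix, transcripts x samples, with rownames
#'   (transcript ids) and colnames (sample ids).
#' @param lengths per-transcript lengths in bp, named or in row order.
#' @param samples data.frame with columns `sample_id`, `group`, `treatment`,
#'   `batch`; one row per column of `counts`.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, lengths, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop2("counts needs transcript rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop2("duplicate transcript ids")
  if (anyDuplicated(colnames(counts)))
    stop2("duplicate sample ids")
  if (any(counts < 0) || any(counts != round(counts)))
    stop2("counts must be nonnegative integers")
  storage.mode(counts) <- "double"   # avoids integer overflow on column sums
  if (!is.null(names(lengths))) lengths <- lengths[rownames(counts)]
  lengths <- as.numeric(lengths)
  if (length(lengths) != nrow(counts) || anyNA(lengths) || any(lengths <= 0))
    stop2("lengths must be positive, one per transcript")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "treatment", "batch")
  if (!all(need %in% names(samples)))
    stop2("samples needs columns: ", paste(need, collapse = ", "))
  if (!identical(as.character(samples$sample_id), colnames(counts)))
    stop2("samples$sample_id must match count columns in order")
  structure(list(counts = counts,
                 lengths = stats::setNames(lengths, rownames(counts)),
                 samples = samples),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "transcripts x",
      ncol(x$counts), "samples\n")
  print(table(x$samples$group))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by transcripts and/or samples
#'
#' @param x a `count_matrix`.
#' @param i transcript index (ids, logical or integer).
#' @param j sample index.
#' @param ... unused.
#' @return A `count_matrix` restricted to the selection.
#' @export
`[.count_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  count_matrix(x$counts[i, j, drop = FALSE],
               x$lengths[i],
               x$samples[match(colnames(x$counts[, j, drop = FALSE]),
                               x$samples$sample_id), , drop = FALSE])
}

sample_index <- function(x, group) {
  idx <- which(x$samples$group == group)
  if (length(idx) == 0) stop2("no samples in group '", group, "'")
  idx
}

#' Write a count matrix to TSV files
#'
#' Emits the on-disk dialect consumed by the rest of the pipeline:
#' `counts.tsv` (transcript_id + one integer column per sample),
#' `samples.tsv` (sample_id, group, treatment, batch) and `lengths.tsv`
#' (transcript_id, length_bp).
#'
#' @param x a `count_matrix`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_count_matrix <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("counts.tsv", "samples.tsv", "lengths.tsv"))
  cts <- data.frame(transcript_id = rownames(x$counts),
                    x$counts, check.names = FALSE)
  write.table(cts, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$samples, paths[2], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(transcript_id = names(x$lengths),
                         length_bp = as.integer(x$lengths)),
              paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a count matrix from TSV files
#'
#' @param dir directory holding `counts.tsv`, `samples.tsv`, `lengths.tsv`
#'   as written by [write_count_matrix()].
#' @return A `count_matrix`.
#' @export
read_count_matrix <- function(dir) {
  cts <- read.delim(file.path(dir, "counts.tsv"), check.names = FALSE)
  samples <- read.delim(file.path(dir, "samples.tsv"),
                        colClasses = "character")
  lens <- read.delim(file.path(dir, "lengths.tsv"))
  m <- as.matrix(cts[, -1, drop = FALSE])
  rownames(m) <- cts$transcript_id
  count_matrix(m, stats::setNames(lens$length_bp, lens$transcript_id), samples)
}
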