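#' Pipeline configuration
#'
#' Collects every threshold of the analysis with its standard default
#' (FDR alpha 0.05, 3FC log2 cutoff 1.5, human thresholds 2.3 / 1.0, CPM and
#' RPKM cutoffs 1, expressed-fraction 0.7, 4000-bp TSS window with 50-bp
#' bins), plus either a [sim_config()] for synthetic mode or a directory of
#' real inputs in the package's on-disk dialect. The human and narrow-window
#' variants of the analysis are configuration presets, not code forks.
#'
#' @param sim a [sim_config()] for synthetic mode (exactly one of `sim` /
#'   `input_dir` must be given).
#' @param input_dir directory with `counts.tsv`, `samples.tsv`,
#'   `lengths.tsv`, `tss.bed`, `ip.bedgraph`, `input.bedgraph`, `peaks.bed`.
#' @param out_dir output directory for all stage artifacts.
#' @param seed integer seed for the run.
#' @param fdr_alpha,fc3_log2,cpm_cut,rpkm_cut,frac_expressed,window,bin
#'   analysis thresholds; see Details in [classify_xenopus()],
#'   [expression_filter()] and [tss_window_profiles()].
#' @param human_strong_log2,human_weak_log2 thresholds of the human
#'   fold-change-only classifier preset.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, input_dir = NULL,
                            out_dir = tempfile("ntmemory_run_"),
                            seed = 1L,
                            fdr_alpha = 0.05, fc3_log2 = 1.5,
                            cpm_cut = 1, rpkm_cut = 1,
                            frac_expressed = 0.7,
                            window = 4000, bin = 50,
                            human_strong_log2 = 2.3,
                            human_weak_log2 = 1.0) {
  if (is.null(sim) == is.null(input_dir))
    stop2("exactly one of `sim` (synthetic mode) or `input_dir` must be set")
  if (!is.null(sim) && !inherits(sim, "sim_config"))
    stop2("`sim` must be a sim_config")
  for (nm in c("fdr_alpha", "fc3_log2", "cpm_cut", "rpkm_cut",
               "frac_expressed", "window", "bin")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v <= 0)
      stop2(nm, " must be a positive scalar")
  }
  if (frac_expressed > 1) stop2("frac_expressed must lie in (0, 1]")
  if (fdr_alpha >= 1) stop2("fdr_alpha must lie in (0, 1)")
  structure(list(sim = sim, input_dir = input_dir, out_dir = out_dir,
                 seed = as.integer(seed),
                 fdr_alpha = fdr_alpha, fc3_log2 = fc3_log2,
                 cpm_cut = cpm_cut, rpkm_cut = rpkm_cut,
                 frac_expressed = frac_expressed,
                 window = window, bin = bin,
                 human_strong_log2 = human_strong_log2,
                 human_weak_log2 = human_weak_log2),
            class = "pipeline_config")
}

pipeline_log <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

#' Run the full transcriptional-memory pipeline
#'
#' Executes, in order: synthetic-data generation (in synthetic mode) or
#' input loading; CPM/RPKM normalization and the expression filter; the
#' three exact NB contrasts with BH-FDR over the filtered transcripts;
#' memory classification; TSS-signal profiles, metaplots and integral KS
#' comparison for the ON-memory vs reprogrammed-down sets; peak-breadth
#' extraction and KS comparison; double z-score scaling, Ward clustering and
#' correlation PCA. All stage tables are written under `config$out_dir` and
#' a machine-readable `report.json` summarizes class counts, KS statistics,
#' the sample clustering, record counts in and out of every filter, the
#' config hash and seed, and — in synthetic mode — the confusion matrix of
#' planted vs assigned classes.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, the report list (also written as `report.json`).
#' @export
run_full <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop2("config must be a pipeline_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  report <- list(seed = config$seed)

  if (!is.null(config$sim)) {
    pipeline_log("simulate", "generating synthetic experiment (",
                 config$sim$n_transcripts, " transcripts)")
    sim <- simulate_expression(config$sim)
    chrom <- simulate_chromatin(sim$truth, config$sim)
    write_sim_expression(sim, config$out_dir, config$sim)
    write_sim_chromatin(chrom, config$out_dir)
    counts <- sim$counts
    truth <- sim$truth
    tss <- chrom$tss
    ip <- chrom$ip
    input <- chrom$input
    peaks <- chrom$peaks
  } else {
    pipeline_log("load", "reading inputs from ", config$input_dir)
    counts <- read_count_matrix(config$input_dir)
    truth <- NULL
    tss <- read_tss_bed(file.path(config$input_dir, "tss.bed"))
    ip <- read_bedgraph(file.path(config$input_dir, "ip.bedgraph"))
    input <- read_bedgraph(file.path(config$input_dir, "input.bedgraph"))
    peaks <- read_broadpeak(file.path(config$input_dir, "peaks.bed"))
  }

  cfg_yaml <- file.path(config$out_dir, "pipeline_config.yaml")
  cfg_list <- unclass(config)
  cfg_list$sim <- if (is.null(config$sim)) NULL else unclass(config$sim)
  yaml::write_yaml(cfg_list, cfg_yaml)
  # hash only the analysis-relevant settings, not filesystem locations
  hash_list <- cfg_list[setdiff(names(cfg_list), c("out_dir", "input_dir"))]
  hash_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(hash_list, hash_file)
  report$config_hash <- unname(tools::md5sum(hash_file))
  unlink(hash_file)

  pipeline_log("normalize", ncol(counts$counts), " samples, ",
               nrow(counts$counts), " transcripts")
  cpm <- compute_cpm(counts)
  rpkm <- compute_rpkm(counts)
  kept <- expression_filter(cpm, counts$samples, cpm_cut = config$cpm_cut,
                            frac_expressed = config$frac_expressed)
  pipeline_log("filter", length(kept), " of ", nrow(counts$counts),
               " transcripts pass the expression filter")
  report$n_transcripts <- nrow(counts$counts)
  report$n_filtered <- length(kept)
  filtered <- counts[kept, ]

  de <- list()
  for (ct in c("Donor_vs_IVF", "NT_vs_IVF", "Donor_vs_NT")) {
    de[[ct]] <- exact_nb_test(filtered, ct)
    write_de_result(de[[ct]],
                    file.path(config$out_dir,
                              paste0("de_", tolower(ct), ".tsv")))
    pipeline_log("de", ct, ": ", sum(de[[ct]]$fdr < config$fdr_alpha),
                 " transcripts at FDR < ", config$fdr_alpha,
                 " (phi = ", signif(attr(de[[ct]], "dispersion"), 3), ")")
  }

  labels <- classify_xenopus(de, rpkm[kept, , drop = FALSE],
                             counts$samples,
                             fdr_alpha = config$fdr_alpha,
                             fc3_log2 = config$fc3_log2,
                             rpkm_cut = config$rpkm_cut)
  write_memory_labels(labels, config$out_dir)
  report$class_counts <- as.list(class_counts(labels))
  pipeline_log("classify",
               paste(names(report$class_counts),
                     unlist(report$class_counts),
                     sep = "=", collapse = ", "))

  on_ids <- labels$transcript_id[labels$primary_class == "ON_memory"]
  down_ids <- labels$transcript_id[labels$primary_class ==
                                     "reprogrammed_down"]
  profiles <- tss_window_profiles(ip, input, tss,
                                  window = config$window, bin = config$bin)
  write_tss_profiles(profiles, config$out_dir)
  ks_report <- list()
  if (length(intersect(on_ids, rownames(profiles$bins))) >= 2 &&
      length(intersect(down_ids, rownames(profiles$bins))) >= 2) {
    ks_report$integral_level <- compare_integral_levels(
      subset_profiles(profiles, on_ids),
      subset_profiles(profiles, down_ids))
  } else {
    pipeline_log("chip-tss", "gene sets too small for the KS comparison")
  }

  widths <- tss_spanning_widths(peaks, tss)
  write_breadth(widths, config$out_dir)
  wa <- widths$width[widths$transcript_id %in% on_ids]
  wb <- widths$width[widths$transcript_id %in% down_ids]
  if (length(wa) >= 2 && length(wb) >= 2) {
    ks_report$breadth <- compare_breadth(wa, wb)
  } else {
    pipeline_log("breadth", "gene sets too small for the KS comparison")
  }
  jsonlite::write_json(ks_report, file.path(config$out_dir,
                                            "ks_report.json"),
                       auto_unbox = TRUE, digits = NA)
  report$ks <- ks_report

  scaled <- double_zscore(cpm[kept, , drop = FALSE], counts$samples$batch)
  hc <- hierarchical_cluster(scaled)
  write_dendrogram(hc, file.path(config$out_dir, "dendrogram.json"))
  k <- length(unique(counts$samples$group))
  cl <- cutree(hc, k = k)
  report$cluster_assignment <- as.list(cl)
  pca <- pca_samples(scaled)
  write.table(data.frame(sample_id = rownames(pca$scores),
                         pca$scores[, seq_len(min(5, ncol(pca$scores))),
                                    drop = FALSE]),
              file.path(config$out_dir, "pca.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  hm <- heatmap_matrix(rpkm[kept, , drop = FALSE], counts$samples,
                       reference = "IVF", cluster_rows = nrow(rpkm) <= 5000)
  write.table(data.frame(transcript_id = rownames(hm$matrix),
                         hm$matrix, check.names = FALSE),
              file.path(config$out_dir, "heatmap.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ma <- ma_table(de$NT_vs_IVF,
                 rpkm[kept, counts$samples$group == "donor", drop = FALSE],
                 labels)
  write.table(ma, file.path(config$out_dir, "ma.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  if (!is.null(truth)) {
    conf <- table(planted = truth$planted_class[match(labels$transcript_id,
                                                      truth$transcript_id)],
                  assigned = labels$primary_class)
    report$confusion <- lapply(rownames(conf), function(r) {
      as.list(stats::setNames(as.integer(conf[r, ]), colnames(conf)))
    })
    names(report$confusion) <- rownames(conf)
  }

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  pipeline_log("done", "report written to ",
               file.path(config$out_dir, "report.json"))
  invisible(report)
}
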