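#' Configuration for the synthetic memory-experiment generator
#'
#' Bundles every tunable of the simulated NT experiment: how many transcripts,
#' the mixture of planted memory classes, the sample layout of the three
#' groups (endoderm donor cells, IVF ectoderm, NT ectoderm) across batches,
#' the negative-binomial noise model, the planted effect sizes, and the
#' chromatin geometry (one TSS per transcript on a single synthetic
#' chromosome, class-dependent H3K4me3 peak width and fold enrichment).
#'
#' The default sample layout mirrors the study design: 3 donor, 11 IVF and
#' 12 NT samples spread round-robin over 3 batches ("experiments produced at
#' the same time"). The planted memory effect is `memory_log2fc` log2 units
#' between donor and IVF; NT samples retain a fraction `nt_retention` of that
#' donor effect, which is what makes a transcript a memory gene rather than a
#' reprogrammed one.
#'
#' @param seed integer seed; every random draw of the generator flows from it.
#' @param n_transcripts number of transcripts to simulate.
#' @param class_proportions named fractions over the five planted classes
#'   `ON_memory`, `OFF_memory`, `reprogrammed_down`, `reprogrammed_up`,
#'   `unchanged`; must sum to 1.
#' @param n_samples named integer vector of samples per group
#'   (`donor`, `IVF_ectoderm`, `NT_ectoderm`); every group needs at least 1.
#' @param n_batches number of technical batches; samples are assigned
#'   round-robin within each group.
#' @param library_size_range numeric pair, uniform range of per-sample
#'   library sizes (total reads).
#' @param dispersion negative-binomial dispersion phi (variance
#'   `m + phi * m^2`); 0 degenerates to Poisson.
#' @param base_log2_expression numeric pair (mean, sd) of the baseline log2
#'   relative expression of a transcript.
#' @param memory_log2fc planted donor-vs-IVF effect in log2 units (positive).
#' @param nt_retention fraction in [0, 1] of the donor effect retained in NT
#'   ectoderm for memory classes.
#' @param batch_lognorm_sd sd of the log-normal per-batch library-scale
#'   multiplier (the minimal batch structure the double z-score removes).
#' @param transcript_length_range integer pair, uniform range of transcript
#'   lengths in bp (used for RPKM).
#' @param tss_spacing distance in bp between consecutive TSSs on the
#'   synthetic chromosome; must exceed the largest analysis window.
#' @param chrom_length length of the synthetic chromosome in bp, or `NULL` to
#'   size it automatically from `n_transcripts` and `tss_spacing`.
#' @param background_depth mean per-base coverage of the chromatin background
#'   (Poisson rate), identical for IP and input outside peaks.
#' @param peak_width_params named list, per class a numeric pair (mean bp,
#'   sd bp) of the planted H3K4me3 peak width.
#' @param peak_intensity_params named numeric vector, per class the IP fold
#'   enrichment over background inside the peak (1 = no enrichment).
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, n_transcripts = 200,
#'                   n_samples = c(donor = 3, IVF_ectoderm = 4, NT_ectoderm = 4))
#' cfg$memory_log2fc
#' @export
sim_config <- function(seed = 1L,
                       n_transcripts = 2000L,
                       class_proportions = c(ON_memory = 0.10,
                                             OFF_memory = 0.10,
                                             reprogrammed_down = 0.15,
                                             reprogrammed_up = 0.15,
                                             unchanged = 0.50),
                       n_samples = c(donor = 3L,
                                     IVF_ectoderm = 11L,
                                     NT_ectoderm = 12L),
                       n_batches = 3L,
                       library_size_range = c(8e5, 1.2e6),
                       dispersion = 0.05,
                       base_log2_expression = c(5, 2),
                       memory_log2fc = 3,
                       nt_retention = 0.8,
                       batch_lognorm_sd = 0.2,
                       transcript_length_range = c(500L, 5000L),
                       tss_spacing = 6000L,
                       chrom_length = NULL,
                       background_depth = 5,
                       peak_width_params = list(ON_memory = c(3000, 300),
                                                OFF_memory = c(800, 150),
                                                reprogrammed_down = c(800, 150),
                                                reprogrammed_up = c(800, 150),
                                                unchanged = c(1000, 200)),
                       peak_intensity_params = c(ON_memory = 6,
                                                 OFF_memory = 3,
                                                 reprogrammed_down = 3,
                                                 reprogrammed_up = 3,
                                                 unchanged = 2)) {
  classes <- memory_sim_classes()
  cfg <- list(seed = as.integer(seed),
              n_transcripts = as.integer(n_transcripts),
              class_proportions = class_proportions,
              n_samples = n_samples,
              n_batches = as.integer(n_batches),
              library_size_range = as.numeric(library_size_range),
              dispersion = as.numeric(dispersion),
              base_log2_expression = as.numeric(base_log2_expression),
              memory_log2fc = as.numeric(memory_log2fc),
              nt_retention = as.numeric(nt_retention),
              batch_lognorm_sd = as.numeric(batch_lognorm_sd),
              transcript_length_range = as.integer(transcript_length_range),
              tss_spacing = as.integer(tss_spacing),
              chrom_length = chrom_length,
              background_depth = as.numeric(background_depth),
              peak_width_params = peak_width_params,
              peak_intensity_params = peak_intensity_params)

  if (is.null(cfg$chrom_length)) {
    cfg$chrom_length <- as.integer(cfg$n_transcripts * cfg$tss_spacing +
                                     cfg$tss_spacing)
  } else {
    cfg$chrom_length <- as.integer(chrom_length)
  }

  if (is.na(cfg$seed)) stop2("seed must be an integer")
  if (cfg$n_transcripts < 1) stop2("n_transcripts must be positive")
  if (!setequal(names(cfg$class_proportions), classes))
    stop2("class_proportions must be named with exactly the classes: ",
          paste(classes, collapse = ", "))
  cfg$class_proportions <- cfg$class_proportions[classes]
  if (any(cfg$class_proportions < 0))
    stop2("class_proportions must be nonnegative")
  if (abs(sum(cfg$class_proportions) - 1) > 1e-9)
    stop2("class_proportions must sum to 1 (got ",
          format(sum(cfg$class_proportions)), ")")
  if (!setequal(names(cfg$n_samples), c("donor", "IVF_ectoderm", "NT_ectoderm")))
    stop2("n_samples must name the groups donor, IVF_ectoderm, NT_ectoderm")
  cfg$n_samples <- as.integer(cfg$n_samples[c("donor", "IVF_ectoderm",
                                              "NT_ectoderm")])
  names(cfg$n_samples) <- c("donor", "IVF_ectoderm", "NT_ectoderm")
  if (any(cfg$n_samples < 1))
    stop2("every group needs at least one sample")
  if (cfg$n_batches < 1) stop2("n_batches must be positive")
  if (length(cfg$library_size_range) != 2 || any(cfg$library_size_range <= 0) ||
      diff(cfg$library_size_range) < 0)
    stop2("library_size_range must be an increasing positive pair")
  if (cfg$dispersion < 0) stop2("dispersion must be nonnegative")
  if (cfg$memory_log2fc < 0) stop2("memory_log2fc must be nonnegative")
  if (cfg$nt_retention < 0 || cfg$nt_retention > 1)
    stop2("nt_retention must lie in [0, 1]")
  if (any(cfg$transcript_length_range <= 0) ||
      diff(cfg$transcript_length_range) < 0)
    stop2("transcript_length_range must be an increasing positive pair")
  if (cfg$background_depth <= 0) stop2("background_depth must be positive")
  if (!all(classes %in% names(cfg$peak_width_params)))
    stop2("peak_width_params must cover every class")
  if (!all(classes %in% names(cfg$peak_intensity_params)))
    stop2("peak_intensity_params must cover every class")
  if (any(unlist(cfg$peak_intensity_params) <= 0))
    stop2("peak enrichments must be positive")

  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_transcripts, "transcripts;",
      paste(names(x$n_samples), x$n_samples, sep = "=", collapse = ", "),
      "samples;", x$n_batches, "batches\n")
  cat("  dispersion phi =", x$dispersion,
      "| memory log2FC =", x$memory_log2fc,
      "| NT retention =", x$nt_retention, "\n")
  invisible(x)
}

memory_sim_classes <- function() {
  c("ON_memory", "OFF_memory", "reprogrammed_down", "reprogrammed_up",
    "unchanged")
}
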