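#' Simulate donor/IVF/NT expression with planted memory classes
#'
#' Draws a negative-binomial count matrix for the three groups of the NT
#' experiment with a known, planted memory structure. Per transcript a
#' baseline log2 relative expression is drawn, then class-specific group
#' offsets are applied (m = `memory_log2fc`, r = `nt_retention`):
#' \describe{
#'   \item{ON_memory}{donor at baseline, IVF at baseline - m, NT at
#'     baseline - m + r*m (the donor effect persists in NT).}
#'   \item{OFF_memory}{mirrored: donor at baseline - m, IVF at baseline, NT
#'     at baseline - r*m.}
#'   \item{reprogrammed_down}{donor at baseline, both ectoderms at
#'     baseline - m (correctly reset).}
#'   \item{reprogrammed_up}{donor at baseline - m, both ectoderms at
#'     baseline.}
#'   \item{unchanged}{one shared mean.}
#' }
#' Relative expressions are normalized within each group to proportions, so a
#' transcript's expected count in a sample is `library_size x batch_factor x
#' proportion`, and counts are drawn NB with mean m and variance
#' `m + phi m^2` (Poisson when `phi = 0`). Batch labels cycle round-robin
#' within each group and each batch carries a log-normal library-scale
#' multiplier. The order of random draws is fixed (classes, baselines,
#' lengths, strands, peak widths, library sizes, batch factors, counts), so a
#' given config is byte-reproducible.
#'
#' TSSs are placed non-overlapping at regular spacing along one synthetic
#' chromosome, so the chromatin generator and interval logic stay testable
#' without a real annotation.
#'
#' @param config a [sim_config()].
#' @return A list with components
#'   \item{counts}{a [count_matrix()];}
#'   \item{truth}{data.frame of planted ground truth: `transcript_id`,
#'     `planted_class`, expected CPM per group (`donor_cpm`, `ivf_cpm`,
#'     `nt_cpm`), `chrom`, `tss` (0-based), `strand`, `length_bp`,
#'     `peak_width`, `peak_enrichment`.}
#' @examples
#' sim <- simulate_expression(sim_config(seed = 1, n_transcripts = 100,
#'   n_samples = c(donor = 3, IVF_ectoderm = 4, NT_ectoderm = 4)))
#' table(sim$truth$planted_class)
#' @export
simulate_expression <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  n <- config$n_transcripts
  classes <- memory_sim_classes()
  ids <- sprintf("tx%05d", seq_len(n))

  planted <- sample(classes, n, replace = TRUE,
                    prob = config$class_proportions)
  base <- rnorm(n, config$base_log2_expression[1],
                config$base_log2_expression[2])
  lens <- as.integer(round(runif(n, config$transcript_length_range[1],
                                 config$transcript_length_range[2])))
  strands <- sample(c("+", "-"), n, replace = TRUE)
  pw_mean <- vapply(config$peak_width_params[planted], `[`, numeric(1), 1)
  pw_sd <- vapply(config$peak_width_params[planted], `[`, numeric(1), 2)
  peak_width <- pmax(100L, as.integer(round(rnorm(n, pw_mean, pw_sd))))
  peak_enr <- as.numeric(config$peak_intensity_params[planted])

  m <- config$memory_log2fc
  r <- config$nt_retention
  offs <- matrix(0, n, 3, dimnames = list(ids, c("donor", "IVF_ectoderm",
                                                 "NT_ectoderm")))
  offs[planted == "ON_memory", ] <-
    matrix(rep(c(0, -m, -m + r * m), each = sum(planted == "ON_memory")),
           ncol = 3)
  offs[planted == "OFF_memory", ] <-
    matrix(rep(c(-m, 0, -r * m), each = sum(planted == "OFF_memory")),
           ncol = 3)
  offs[planted == "reprogrammed_down", ] <-
    matrix(rep(c(0, -m, -m), each = sum(planted == "reprogrammed_down")),
           ncol = 3)
  offs[planted == "reprogrammed_up", ] <-
    matrix(rep(c(-m, 0, 0), each = sum(planted == "reprogrammed_up")),
           ncol = 3)

  rel <- 2^(base + offs)                       # relative expression per group
  prop <- sweep(rel, 2, colSums(rel), "/")     # per-group proportions
  truth_cpm <- prop * 1e6

  groups <- rep(names(config$n_samples), config$n_samples)
  n_samp <- length(groups)
  sample_ids <- unlist(lapply(names(config$n_samples), function(g) {
    sprintf("%s_%02d", sub("_ectoderm", "", g), seq_len(config$n_samples[g]))
  }))
  batches <- unlist(lapply(config$n_samples, function(k) {
    sprintf("batch%d", rep_len(seq_len(config$n_batches), k))
  }))
  lib <- runif(n_samp, config$library_size_range[1],
               config$library_size_range[2])
  batch_factor <- rlnorm(config$n_batches, 0, config$batch_lognorm_sd)
  names(batch_factor) <- sprintf("batch%d", seq_len(config$n_batches))

  mu <- prop[, groups, drop = FALSE] *
    rep(lib * batch_factor[batches], each = n)
  phi <- config$dispersion
  cts <- if (phi <= 0) {
    rpois(length(mu), mu)
  } else {
    rnbinom(length(mu), size = 1 / phi, mu = mu)
  }
  cts <- matrix(cts, n, n_samp, dimnames = list(ids, sample_ids))

  tss <- as.integer(seq_len(n) * config$tss_spacing)  # 0-based positions
  if (max(tss) + 2000 >= config$chrom_length)
    stop2("chrom_length too small for ", n, " transcripts at spacing ",
          config$tss_spacing)

  samples <- data.frame(sample_id = sample_ids, group = groups,
                        treatment = "none", batch = batches,
                        stringsAsFactors = FALSE)
  truth <- data.frame(transcript_id = ids,
                      planted_class = planted,
                      donor_cpm = truth_cpm[, "donor"],
                      ivf_cpm = truth_cpm[, "IVF_ectoderm"],
                      nt_cpm = truth_cpm[, "NT_ectoderm"],
                      chrom = "chrS",
                      tss = tss,
                      strand = strands,
                      length_bp = lens,
                      peak_width = peak_width,
                      peak_enrichment = peak_enr,
                      stringsAsFactors = FALSE, row.names = NULL)
  list(counts = count_matrix(cts, stats::setNames(lens, ids), samples),
       truth = truth)
}

#' Write simulated expression data and ground truth to disk
#'
#' @param sim result of [simulate_expression()].
#' @param dir output directory.
#' @param config optional [sim_config()] echoed as `config.yaml`.
#' @return Invisibly, the directory.
#' @export
write_sim_expression <- function(sim, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_matrix(sim$counts, dir)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", digits = NA)
  if (!is.null(config))
    yaml::write_yaml(unclass(config), file.path(dir, "config.yaml"))
  invisible(dir)
}
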