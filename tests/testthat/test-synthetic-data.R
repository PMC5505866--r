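test_that("config validation rejects inconsistent simulation settings", {
  expect_error(sim_config(class_proportions = c(ON_memory = 0.6,
                                                OFF_memory = 0.5,
                                                reprogrammed_down = 0,
                                                reprogrammed_up = 0,
                                                unchanged = 0)),
               "sum to 1")
  expect_error(sim_config(n_samples = c(donor = 0, IVF_ectoderm = 4,
                                        NT_ectoderm = 4)),
               "at least one sample")
  expect_error(sim_config(nt_retention = 1.2), "0, 1")
  expect_error(sim_config(dispersion = -0.1), "nonnegative")
})

test_that("the generator is byte-deterministic given config and seed", {
  cfg <- sim_config(seed = 9, n_transcripts = 120,
                    n_samples = c(donor = 3, IVF_ectoderm = 4,
                                  NT_ectoderm = 5))
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth, b$truth)
  ca <- simulate_chromatin(a$truth, cfg)
  cb <- simulate_chromatin(b$truth, cfg)
  expect_identical(as.numeric(ca$ip$coverage$chrS),
                   as.numeric(cb$ip$coverage$chrS))
  expect_identical(as.numeric(ca$input$coverage$chrS),
                   as.numeric(cb$input$coverage$chrS))

  d1 <- tempfile(); d2 <- tempfile()
  write_sim_expression(a, d1, cfg)
  write_sim_expression(b, d2, cfg)
  for (f in c("counts.tsv", "samples.tsv", "lengths.tsv", "truth.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("a null configuration plants no group differences", {
  s <- small_sim(seed = 21, n = 800, phi = 0, m = 0, r = 0)
  cpm <- compute_cpm(s$sim$counts)
  g <- s$sim$counts$samples$group
  ratio <- log2(rowMeans(cpm[, g == "donor"]) /
                  rowMeans(cpm[, g == "IVF_ectoderm"]))
  expect_lt(abs(mean(ratio)), 0.05)
  expect_equal(s$sim$truth$donor_cpm, s$sim$truth$ivf_cpm, tolerance = 1e-12)
  expect_equal(s$sim$truth$donor_cpm, s$sim$truth$nt_cpm, tolerance = 1e-12)
})

test_that("realized fold changes match the planted memory effect", {
  # Monte-Carlo check of the configured donor-vs-IVF effect on ON-memory
  s <- small_sim(seed = 7, n = 2000, phi = 0.05, m = 4, r = 0.8)
  cpm <- compute_cpm(s$sim$counts)
  g <- s$sim$counts$samples$group
  # restrict to planted ON transcripts expressed well enough on the low
  # (IVF) side that group means cannot be zero-inflated
  on <- s$sim$truth$planted_class == "ON_memory" & s$sim$truth$ivf_cpm >= 5
  expect_gt(sum(on), 50)
  realized <- mean(log2(rowMeans(cpm[on, g == "donor"]) /
                          rowMeans(cpm[on, g == "IVF_ectoderm"])))
  expect_lt(abs(realized - 4), 0.2)
  # NT retains r * m of the donor effect relative to IVF
  nt <- mean(log2(rowMeans(cpm[on, g == "NT_ectoderm"]) /
                    rowMeans(cpm[on, g == "IVF_ectoderm"])))
  expect_lt(abs(nt - 0.8 * 4), 0.3)
})

test_that("planted effects converge with many samples and proportions match", {
  s <- small_sim(seed = 13, n = 400, phi = 0.05, m = 2, r = 0.8,
                 groups = c(donor = 50, IVF_ectoderm = 50,
                            NT_ectoderm = 50))
  cpm <- compute_cpm(s$sim$counts)
  g <- s$sim$counts$samples$group
  on <- s$sim$truth$planted_class == "ON_memory"
  realized <- mean(log2(rowMeans(cpm[on, g == "donor"]) /
                          rowMeans(cpm[on, g == "IVF_ectoderm"])))
  expect_lt(abs(realized / 2 - 1), 0.05)

  # class proportions within ~4 sd of multinomial sampling error
  tab <- table(s$sim$truth$planted_class)
  p <- s$cfg$class_proportions
  for (cl in names(p)) {
    se <- sqrt(p[cl] * (1 - p[cl]) / 400)
    expect_lt(abs(tab[cl] / 400 - p[cl]), 4 * se + 1e-9)
  }
})

test_that("chromatin generation respects planted peak geometry", {
  cfg <- sim_config(seed = 4, n_transcripts = 150,
                    n_samples = c(donor = 3, IVF_ectoderm = 4,
                                  NT_ectoderm = 4))
  sim <- simulate_expression(cfg)
  chrom <- simulate_chromatin(sim$truth, cfg)
  on <- sim$truth$planted_class == "ON_memory"
  down <- sim$truth$planted_class == "reprogrammed_down"
  expect_gt(mean(sim$truth$peak_width[on]), mean(sim$truth$peak_width[down]))
  # planted peak intervals have the planted widths
  expect_equal(GenomicRanges::width(chrom$peaks), sim$truth$peak_width)
  # peaks are centered on their TSS
  expect_true(all(GenomicRanges::start(chrom$peaks) - 1 <= sim$truth$tss &
                    sim$truth$tss < GenomicRanges::end(chrom$peaks)))
})

test_that("unit enrichment makes IP and input exchangeable", {
  cfg <- sim_config(seed = 8, n_transcripts = 150,
                    n_samples = c(donor = 3, IVF_ectoderm = 4,
                                  NT_ectoderm = 4),
                    peak_intensity_params = c(ON_memory = 1, OFF_memory = 1,
                                              reprogrammed_down = 1,
                                              reprogrammed_up = 1,
                                              unchanged = 1))
  sim <- simulate_expression(cfg)
  chrom <- simulate_chromatin(sim$truth, cfg)
  prof <- tss_window_profiles(chrom$ip, chrom$input, chrom$tss)
  # mean normalized level over all TSS windows is ~0 (per-million units)
  expect_lt(abs(mean(prof$integral)), 0.5)
})

test_that("bedGraph round trip reproduces per-base coverage exactly", {
  set.seed(1)
  track <- coverage_track(rpois(5000, 3))
  path <- tempfile(fileext = ".bedgraph")
  write_bedgraph(track, path)
  back <- read_bedgraph(path)
  expect_identical(as.numeric(back$coverage$chrS),
                   as.numeric(track$coverage$chrS))
  expect_equal(back$total_reads, track$total_reads)
})

test_that("TSS windows that leave the chromosome are rejected", {
  cfg <- sim_config(seed = 2, n_transcripts = 50,
                    n_samples = c(donor = 3, IVF_ectoderm = 4,
                                  NT_ectoderm = 4))
  sim <- simulate_expression(cfg)
  cfg_bad <- cfg
  cfg_bad$chrom_length <- max(sim$truth$tss) - 1000L
  expect_error(simulate_chromatin(sim$truth, cfg_bad), "chrom")
})
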