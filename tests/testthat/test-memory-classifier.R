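# Helpers building classifier inputs directly, without running the DE engine.
mk_de <- function(ids, logFC, fdr) {
  data.frame(transcript_id = ids, logFC = logFC, p_value = fdr, fdr = fdr,
             mean_cpm_a = 10, mean_cpm_b = 10, stringsAsFactors = FALSE)
}

# one transcript; donor/ivf/nt may be length-2 vectors of per-sample RPKM
mk_rpkm <- function(id, donor = 5, ivf = 5, nt = 5) {
  m <- matrix(c(rep_len(donor, 2), rep_len(ivf, 2), rep_len(nt, 2)),
              nrow = 1,
              dimnames = list(id, c("d1", "d2", "i1", "i2", "n1", "n2")))
  m
}

xen_samples <- data.frame(
  sample_id = c("d1", "d2", "i1", "i2", "n1", "n2"),
  group = rep(c("donor", "IVF_ectoderm", "NT_ectoderm"), each = 2))

classify1 <- function(di, ni, dn, donor = 5, ivf = 5, nt = 5) {
  de <- list(Donor_vs_IVF = mk_de("t", di[1], di[2]),
             NT_vs_IVF = mk_de("t", ni[1], ni[2]),
             Donor_vs_NT = mk_de("t", dn[1], dn[2]))
  classify_xenopus(de, mk_rpkm("t", donor, ivf, nt), xen_samples)
}

test_that("single-transcript rule firing follows the filter strategy", {
  # (logFC, FDR) triples: Donor/IVF, NT/IVF, Donor/NT
  lab <- classify1(c(2, 0.01), c(1.6, 0.01), c(0.4, 0.5))
  expect_equal(lab$primary_class, "ON_memory")
  expect_true(lab$fc3_flag)

  # logFC NT/IVF exactly 1.5: strict boundary, no 3FC flag
  lab <- classify1(c(2, 0.01), c(1.5, 0.01), c(0.4, 0.5))
  expect_equal(lab$primary_class, "ON_memory")
  expect_false(lab$fc3_flag)

  # FDR NT/IVF exactly 0.05 is not significant -> reprogrammed_down
  lab <- classify1(c(2, 0.01), c(0.3, 0.05), c(2, 0.01))
  expect_equal(lab$primary_class, "reprogrammed_down")

  # donor RPKM at the cutoff in one sample blocks the ON class
  lab <- classify1(c(2, 0.01), c(1.6, 0.01), c(0.4, 0.5), donor = c(5, 1))
  expect_false(lab$primary_class == "ON_memory")

  # sign-discordant significant transcripts land in the resistant classes
  lab <- classify1(c(2, 0.01), c(-1, 0.01), c(2, 0.01))
  expect_equal(lab$primary_class, "resistant_other_down")
  lab <- classify1(c(-2, 0.01), c(1, 0.01), c(-2, 0.01))
  expect_equal(lab$primary_class, "resistant_other_up")

  # donor-only-expressed transcripts stay reprogrammed_down even when
  # NT/IVF is significant
  lab <- classify1(c(4, 0.001), c(1, 0.03), c(4, 0.001),
                   donor = 8, ivf = 0.2, nt = 0.2)
  expect_equal(lab$primary_class, "ON_memory")  # memory rule fires first
  lab <- classify1(c(4, 0.001), c(-1, 0.03), c(4, 0.001),
                   donor = 8, ivf = 0.2, nt = 0.2)
  expect_equal(lab$primary_class, "reprogrammed_down")
})

test_that("classes are mutually exclusive and exhaustive on simulated data", {
  s <- small_sim(seed = 31, n = 600)
  cpm <- compute_cpm(s$sim$counts)
  rpkm <- compute_rpkm(s$sim$counts)
  kept <- expression_filter(cpm, s$sim$counts$samples)
  f <- s$sim$counts[kept, ]
  de <- lapply(c(Donor_vs_IVF = "Donor_vs_IVF", NT_vs_IVF = "NT_vs_IVF",
                 Donor_vs_NT = "Donor_vs_NT"),
               function(ct) exact_nb_test(f, ct))
  lab <- classify_xenopus(de, rpkm[kept, ], s$sim$counts$samples)
  expect_equal(nrow(lab), length(kept))
  expect_true(all(!is.na(lab$primary_class)))
  valid <- c("ON_memory", "OFF_memory", "reprogrammed_down",
             "reprogrammed_up", "reprogrammed", "resistant_other_up",
             "resistant_other_down", "unclassified")
  expect_true(all(lab$primary_class %in% valid))
  # one primary class per transcript by construction of the table
  expect_equal(anyDuplicated(lab$transcript_id), 0)
  # the directional core rule sets are disjoint: ON needs both logFCs > 0
  # and OFF both < 0; resistant needs discordant signs
  expect_false(any(lab$fc3_flag &
                     !lab$primary_class %in% c("ON_memory", "OFF_memory")))

  # raising the 3FC cutoff never increases the flagged count
  lab25 <- classify_xenopus(de, rpkm[kept, ], s$sim$counts$samples,
                            fc3_log2 = 2.5)
  expect_lte(sum(lab25$fc3_flag), sum(lab$fc3_flag))

  # mismatched transcript universes error out
  de_bad <- de
  de_bad$NT_vs_IVF <- de_bad$NT_vs_IVF[-1, ]
  expect_error(classify_xenopus(de_bad, rpkm[kept, ],
                                s$sim$counts$samples), "different")
})

test_that("the human fold-change-only classifier applies printed thresholds", {
  inp <- data.frame(
    transcript_id = paste0("h", 1:8),
    logFC_donor_vs_IVF = c(3.0, 3.0, 3.0, 3.0, -3.0, -3.0, -3.0, 0.5),
    logFC_NT_vs_IVF = c(1.5, 2.5, 0.5, 1.5, -1.5, -2.5, -0.5, 0.1),
    donor_fpkm = c(4, 4, 4, 0.5, 4, 4, 4, 4))
  lab <- classify_human(inp)
  expect_equal(lab$primary_class,
               c("ON_memory", "ON_memory", "reprogrammed_down",
                 "unclassified", "OFF_memory", "OFF_memory",
                 "reprogrammed_up", "unclassified"))
  expect_equal(lab$subclass[1:2], c("fc2to5", "gt5FC"))
  expect_equal(lab$fc3_flag[1:2], c(FALSE, TRUE))
  # boundary: logFC exactly 2.3 fails the strict comparison
  b <- classify_human(data.frame(transcript_id = "b",
                                 logFC_donor_vs_IVF = 2.3,
                                 logFC_NT_vs_IVF = 1.5, donor_fpkm = 4))
  expect_equal(b$primary_class, "unclassified")
  expect_error(classify_human(data.frame(transcript_id = "x",
                                         logFC_donor_vs_IVF = Inf,
                                         logFC_NT_vs_IVF = 0,
                                         donor_fpkm = 1)), "finite")
})

test_that("replicate intersection keeps only agreeing classes", {
  ids <- paste0("t", 1:4)
  a <- ntmemory:::memory_labels(ids,
                                c("ON_memory", "ON_memory",
                                  "reprogrammed_down", "unclassified"),
                                c(TRUE, TRUE, FALSE, FALSE), "a")
  b <- ntmemory:::memory_labels(ids,
                                c("ON_memory", "reprogrammed_down",
                                  "reprogrammed_down", "unclassified"),
                                c(FALSE, FALSE, FALSE, FALSE), "b")
  m <- intersect_replicates(list(a, b))
  expect_equal(m$primary_class,
               c("ON_memory", "unclassified", "reprogrammed_down",
                 "unclassified"))
  # the 3FC flag is intersected too
  expect_false(m$fc3_flag[1])
  expect_error(intersect_replicates(list(a)), "two experiments")
  # intersection can never increase a class count
  ca <- class_counts(a); cb <- class_counts(b); cm <- class_counts(m)
  keep <- setdiff(names(ca), "unclassified")
  expect_true(all(cm[keep] <= pmin(ca[keep], cb[keep])))
})

test_that("treatment-DE exclusion removes exactly the significant set", {
  ids <- paste0("t", 1:6)
  lab <- ntmemory:::memory_labels(ids,
                                  c("ON_memory", "ON_memory", "OFF_memory",
                                    "reprogrammed_down", "unclassified",
                                    "reprogrammed_up"),
                                  c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
                                  "x")
  tde <- mk_de(ids, logFC = 0, fdr = c(0.01, 0.2, 0.05, 0.3, 0.01, 0.049))
  out <- exclude_treatment_de(lab, tde)
  # strict <: FDR 0.05 retained, 0.049 excluded
  expect_equal(out$primary_class,
               c("unclassified", "ON_memory", "OFF_memory",
                 "reprogrammed_down", "unclassified", "unclassified"))
  # every class count drops by exactly its excluded members
  excl <- tde$fdr < 0.05
  before <- class_counts(lab)
  after <- class_counts(out)
  for (cl in setdiff(names(before), c("unclassified", "ON_memory_3FC",
                                      "OFF_memory_3FC"))) {
    expect_equal(after[[cl]],
                 before[[cl]] - sum(excl & lab$primary_class == cl))
  }
})
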