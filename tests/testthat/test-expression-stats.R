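test_that("CPM follows its definition and columns sum to a million", {
  m <- matrix(c(5, 15, 80), 3, 1,
              dimnames = list(paste0("t", 1:3), "s1"))
  expect_equal(unname(compute_cpm(m)[, 1]), c(50000, 150000, 800000))
  expect_equal(compute_cpm(m)["t1", "s1"] * 0, 0)  # zero count -> CPM 0

  s <- small_sim(seed = 14, n = 100, phi = 0.1,
                 groups = c(donor = 2, IVF_ectoderm = 1, NT_ectoderm = 1))
  cpm <- compute_cpm(s$sim$counts)
  expect_equal(unname(colSums(cpm)), rep(1e6, 4), tolerance = 1e-6)

  bad <- matrix(c(1, 0, 2, 0), 2, 2,
                dimnames = list(c("a", "b"), c("ok", "empty")))
  bad[, 2] <- 0
  expect_error(compute_cpm(bad), "all-zero")
})

test_that("RPKM equals CPM over length in kilobases, cell by cell", {
  # count 10, length 2 kb, library 1e6 -> RPKM 5
  m <- matrix(c(10, 999990), 2, 1,
              dimnames = list(c("t1", "t2"), "s1"))
  expect_equal(compute_rpkm(m, lengths = c(2000, 1000))["t1", 1], 5)

  s <- small_sim(seed = 15, n = 200)
  cpm <- compute_cpm(s$sim$counts)
  rpkm <- compute_rpkm(s$sim$counts)
  expect_equal(rpkm, cpm / (s$sim$counts$lengths / 1000))
  expect_error(compute_rpkm(m, lengths = NULL), "length")
})

test_that("the expression filter applies its three clauses strictly", {
  n_ivf <- 11; n_nt <- 12
  samples <- data.frame(
    sample_id = c(paste0("d", 1:3), paste0("i", 1:n_ivf),
                  paste0("n", 1:n_nt)),
    group = rep(c("donor", "IVF_ectoderm", "NT_ectoderm"),
                c(3, n_ivf, n_nt)))
  base <- matrix(0, 4, 3 + n_ivf + n_nt,
                 dimnames = list(paste0("t", 1:4), samples$sample_id))
  cpm <- base
  cpm["t1", 1:3] <- 5                    # all donor -> kept
  cpm["t2", 3 + (1:7)] <- 5              # 7/11 IVF = 63.6% -> dropped
  cpm["t3", 3 + (1:8)] <- 5              # 8/11 IVF = 72.7% -> kept
  cpm["t4", 1:2] <- 5                    # 2/3 donor only -> dropped
  kept <- expression_filter(cpm, samples)
  expect_setequal(kept, c("t1", "t3"))
  # boundary: CPM exactly 1 does not count as expressed
  cpm["t1", 1] <- 1
  expect_false("t1" %in% expression_filter(cpm, samples))
  expect_error(expression_filter(cpm, samples[samples$group != "donor", ]),
               "empty group")
})

test_that("the exact NB test is symmetric and matches the conditional
           binomial enumeration at zero dispersion", {
  mk <- function(counts_a, counts_b) {
    m <- cbind(A = counts_a, B = counts_b)
    rownames(m) <- paste0("t", seq_len(nrow(m)))
    count_matrix(m, rep(1000, nrow(m)),
                 data.frame(sample_id = c("A", "B"),
                            group = c("g1", "g2"),
                            treatment = "none", batch = "b1"))
  }
  # identical counts, equal libraries -> logFC 0, p 1
  cm <- mk(c(10, 20, 30), c(10, 20, 30))
  de <- exact_nb_test(cm, group_a = "g1", group_b = "g2", dispersion = 0)
  expect_equal(de$logFC, rep(0, 3))
  expect_equal(de$p_value, rep(1, 3))

  # counts (10, 0), one sample per group, phi 0: p = 2 * 0.5^10
  cm2 <- mk(c(10, 90), c(0, 100))
  de2 <- exact_nb_test(cm2, group_a = "g1", group_b = "g2", dispersion = 0)
  expect_equal(de2$p_value[1], binom_split_oracle(10, 0, 1, 1),
               tolerance = 1e-12)
  expect_equal(binom_split_oracle(10, 0, 1, 1), 2 * 0.5^10,
               tolerance = 1e-12)

  # swapping groups negates logFC and keeps p
  de_sw <- exact_nb_test(cm2, group_a = "g2", group_b = "g1",
                         dispersion = 0)
  expect_equal(de_sw$p_value, de2$p_value)
  expect_equal(de_sw$logFC, -de2$logFC)

  # phi = 0 agrees with the brute-force oracle for all pooled counts <= 50
  for (na in 1:3) {
    for (ta in c(0, 3, 17, 25)) {
      for (tb in c(0, 5, 25)) {
        if (ta + tb == 0) next
        expect_equal(ntmemory:::nb_exact_pvalue(ta, tb, na, 2, 0),
                     binom_split_oracle(ta, tb, na, 2),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("the exact NB test agrees with an established exact test on a
           small fixture", {
  s <- small_sim(seed = 33, n = 120, phi = 0.1,
                 groups = c(donor = 1, IVF_ectoderm = 4, NT_ectoderm = 4))
  cm <- s$sim$counts
  keep <- cm$samples$group != "donor"
  y <- cm$counts[, keep]
  grp <- cm$samples$group[keep]
  dge <- edgeR::DGEList(counts = y, group = factor(grp))
  dge$samples$norm.factors <- 1
  et <- edgeR::exactTest(dge, dispersion = 0.1,
                         pair = c("IVF_ectoderm", "NT_ectoderm"))
  de <- exact_nb_test(cm, "NT_vs_IVF", dispersion = 0.1)
  # same model, different library equalization details: ranks and calls agree
  expect_gt(cor(de$p_value, et$table$PValue, method = "spearman"), 0.98)
  expect_gt(cor(de$logFC, et$table$logFC), 0.99)
})

test_that("BH FDR matches the step-up definition and is permutation stable", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")

  set.seed(99)
  for (i in 1:5) {
    p <- runif(37)
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), bh_fdr(p)[perm])
  }
  # monotone nondecreasing in p-rank
  p <- runif(100)
  f <- bh_fdr(p)
  expect_true(all(diff(f[order(p)]) >= -1e-12))
})

test_that("Mann-Whitney matches exact enumeration and is rank invariant", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 0.1)  # 2 of the C(6,3)=20 labelings as extreme
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  sc <- mann_whitney(c(10, 20, 30), c(40, 50, 60))
  expect_equal(sc$U, res$U)
  expect_equal(sc$p_value, res$p_value)
  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")
})

test_that("type-I error of the exact NB test is near nominal under the null", {
  s <- small_sim(seed = 17, n = 2500, phi = 0.1, m = 0, r = 0)
  de <- exact_nb_test(s$sim$counts, "NT_vs_IVF")
  expect_lt(abs(mean(de$p_value < 0.05) - 0.05), 0.02)
})
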