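# Independent brute-force oracles. These deliberately avoid the package's
# code paths: enumeration, naive loops and textbook recurrences only.

# Two-sided conditional binomial p-value for the split (ta, tb) of a pooled
# Poisson count between groups of size na, nb: enumerate all splits and sum
# the probabilities of those no more likely than the observed split.
binom_split_oracle <- function(ta, tb, na, nb) {
  total <- ta + tb
  if (total == 0) return(1)
  probs <- vapply(0:total, function(s) {
    choose(total, s) * (na / (na + nb))^s * (nb / (na + nb))^(total - s)
  }, numeric(1))
  pobs <- probs[ta + 1]
  min(1, sum(probs[probs <= pobs * (1 + 1e-12)]))
}

# Benjamini-Hochberg by the definition: p * m / rank, cumulative minimum
# from the largest rank down.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Two-sample KS D: maximum ECDF gap over the pooled support.
ks_d_oracle <- function(a, b) {
  support <- sort(unique(c(a, b)))
  max(abs(vapply(support, function(x) mean(a <= x) - mean(b <= x),
                 numeric(1))))
}

# Agglomerative clustering with the ward.D convention: Lance-Williams
# update with alpha_i = (n_i + n_k)/(n_i + n_j + n_k), beta = -n_k/(...),
# gamma = 0, applied to the distance matrix as given (unsquared Euclidean).
# Returns merge heights and the leaf sets merged at each step.
ward_d_oracle <- function(x) {
  d <- as.matrix(dist(t(x)))
  n <- ncol(d)
  active <- seq_len(n)
  members <- lapply(seq_len(n), identity)
  sizes <- rep(1, n)
  heights <- numeric(0)
  merges <- list()
  while (length(active) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        i <- active[ii]; j <- active[jj]
        if (d[i, j] < best_d) {
          best_d <- d[i, j]
          best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, best_d)
    merges <- c(merges, list(sort(c(members[[i]], members[[j]]))))
    ni <- sizes[i]; nj <- sizes[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- sizes[k]
      d_new <- ((ni + nk) * d[i, k] + (nj + nk) * d[j, k] -
                  nk * d[i, j]) / (ni + nj + nk)
      d[i, k] <- d[k, i] <- d_new
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  list(heights = heights, merges = merges)
}

# Leaf sets merged at each step of an hclust result.
hclust_merge_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  for (s in seq_len(nrow(hc$merge))) {
    grab <- function(v) if (v < 0) -v else sets[[v]]
    sets[[s]] <- sort(c(grab(hc$merge[s, 1]), grab(hc$merge[s, 2])))
  }
  sets
}

# A small simulated experiment shared by several tests.
small_sim <- function(seed = 42, n = 300, phi = 0.05, m = 3, r = 0.8,
                      groups = c(donor = 4, IVF_ectoderm = 4,
                                 NT_ectoderm = 4), ...) {
  cfg <- sim_config(seed = seed, n_transcripts = n, n_samples = groups,
                    dispersion = phi, memory_log2fc = m, nt_retention = r,
                    ...)
  list(cfg = cfg, sim = simulate_expression(cfg))
}
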