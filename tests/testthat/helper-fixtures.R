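# Fixture builders and independent oracles shared across the suite.
# Oracles deliberately avoid the code paths they check: the BH oracle scans
# explicit rejection thresholds, the UPGMA oracle agglomerates from the raw
# distance matrix, the hypergeometric oracle sums the probability mass
# function term by term, and the background-correction oracle integrates the
# convolution model numerically.

options(exonsplice.verbose = FALSE)

toy_annotation <- function(clusters = 3L, probesets = 4L, gc = 0.5) {
  cl <- sprintf("TC%02d", seq_len(clusters))
  data.frame(
    probeset_id = sprintf("%s_PS%02d", rep(cl, each = probesets),
                          rep(seq_len(probesets), clusters)),
    transcript_cluster_id = rep(cl, each = probesets),
    n_probes = 4L, level = "core", cross_hyb = FALSE,
    exon_index = rep(seq_len(probesets), clusters),
    gc_fraction = gc, stringsAsFactors = FALSE)
}

toy_design <- function(sizes = c(HLHS_RV = 6L, Control_RV = 5L, Control_LV = 5L)) {
  data.frame(
    sample_id = unlist(lapply(names(sizes), function(g)
      sprintf("%s_%02d", g, seq_len(sizes[[g]]))), use.names = FALSE),
    group = rep(names(sizes), sizes), stringsAsFactors = FALSE)
}

quick_sim_config <- function(seed, n_clusters = 30L, ...) {
  sim_config(n_clusters = n_clusters, seed = seed,
             n_background_probes = 1000L, ...)
}

# BH oracle: the adjusted value of feature i is the smallest achievable FDR
# bound m * t / #{p <= t} over all rejection thresholds t that retain i.
bh_oracle <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    ts <- sort(unique(p[p >= pi]))
    min(1, min(vapply(ts, function(t) m * t / sum(p <= t), numeric(1))))
  }, numeric(1))
}

# UPGMA oracle: explicit agglomeration; inter-cluster distance recomputed
# each step as the mean over all cross pairs of the original matrix.
upgma_oracle <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dij <- mean(d[clusters[[i]], clusters[[j]]])
        if (dij < best_d) {
          best_d <- dij
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_d)
    merges[[length(merges) + 1L]] <- sort(c(clusters[[best[1L]]], clusters[[best[2L]]]))
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# cophenetic matrix implied by the oracle's merge history
upgma_oracle_cophenetic <- function(d) {
  o <- upgma_oracle(d)
  n <- nrow(as.matrix(d))
  coph <- matrix(0, n, n)
  seen <- matrix(FALSE, n, n)
  for (s in seq_along(o$merges)) {
    idx <- o$merges[[s]]
    for (i in idx) for (j in idx) {
      if (i != j && !seen[i, j]) {
        coph[i, j] <- o$heights[[s]]
        seen[i, j] <- TRUE
      }
    }
  }
  coph
}

# Upper hypergeometric tail by explicit summation of the pmf:
# P[X >= k] = sum_{j >= k} C(K, j) C(N - K, n - j) / C(N, n).
hyper_tail_oracle <- function(k, K, N, n) {
  js <- k:min(K, n)
  js <- js[n - js <= N - K & js >= 0]
  if (!length(js)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# E[signal | observed] of the convolution model by numeric integration:
# observed x = s + b, s ~ Exp(alpha), b ~ N(mu, sigma^2).
bg_adjust_oracle <- function(x, mu, sigma, alpha) {
  vapply(x, function(xx) {
    f <- function(s) s * alpha * exp(-alpha * s) * stats::dnorm(xx - s, mu, sigma)
    g <- function(s) alpha * exp(-alpha * s) * stats::dnorm(xx - s, mu, sigma)
    # the integrand is a narrow bump near s = xx - mu; finite bounds keep
    # adaptive quadrature from missing it
    hi <- max(xx - mu, 0) + 12 * sigma
    stats::integrate(f, 0, hi, rel.tol = 1e-10, subdivisions = 2000L)$value /
      stats::integrate(g, 0, hi, rel.tol = 1e-10, subdivisions = 2000L)$value
  }, numeric(1))
}

# silhouette width of one group in a 2-D embedding, via cluster::silhouette
group_silhouette <- function(scores, labels, group) {
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(scores))
  mean(sil[labels == group, "sil_width"])
}
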