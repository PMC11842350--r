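# Risk-level statistics and cluster re-stratification.
#
# Across the three NIOSH risk levels the per-trial peaks are compared with
# Shapiro-Wilk normality checks and paired Wilcoxon signed-rank tests with
# Bonferroni correction (pairing by subject x repetition). Peak compressive
# loads, grouped with peak moments, are then re-stratified by seeded k-means
# (default k = 6) with clusters relabelled by ascending compression,
# pairwise Welch t tests between clusters, and a cluster-vs-risk-level
# cross-tabulation.

#' Shapiro-Wilk normality test
#'
#' @param values Numeric sample, 3 <= n <= 5000.
#' @return List with `W` and `p`.
#' @export
normality_test <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3 || n > 5000)
    stop("unsupported sample size for the Shapiro-Wilk test", call. = FALSE)
  if (var(values) == 0)
    stop("degenerate sample: all values identical", call. = FALSE)
  sw <- shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value)
}

signed_rank_z <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(0)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0) return(0)
  (W - mu) / sqrt(sigma2)
}

#' Pairwise Wilcoxon signed-rank tests across risk levels
#'
#' Trials are paired by subject and repetition across levels. For each pair
#' of levels the signed-rank z (normal approximation with tie correction),
#' the raw p (from [stats::wilcox.test()], exact where possible) and the
#' Bonferroni-adjusted p (`min(1, p * number of pairs)`) are reported.
#'
#' @param summaries Data frame from [summarize_trial()] rows.
#' @param metric Summary column to compare, e.g. `"peak_compression_bw"`.
#' @param pairs List of level pairs (default all three).
#' @return Data frame with `level_a`, `level_b`, `n`, `z`, `p_raw`,
#'   `p_adjusted`.
#' @export
wilcoxon_pairwise <- function(summaries, metric,
                              pairs = list(c(1, 2), c(2, 3), c(1, 3))) {
  if (!metric %in% names(summaries))
    stop(sprintf("metric '%s' not found in summaries", metric),
         call. = FALSE)
  m <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    a <- summaries[summaries$li_level == pr[1L], ]
    b <- summaries[summaries$li_level == pr[2L], ]
    key_a <- paste(a$subject_id, a$repetition)
    key_b <- paste(b$subject_id, b$repetition)
    common <- intersect(key_a, key_b)
    if (length(common) == 0 || anyDuplicated(key_a) || anyDuplicated(key_b))
      stop("pairing error: trials cannot be matched by subject x repetition",
           call. = FALSE)
    x <- a[[metric]][match(common, key_a)]
    y <- b[[metric]][match(common, key_b)]
    if (all(x == y)) {
      z <- 0; p <- 1
    } else {
      z <- signed_rank_z(x, y)
      p <- suppressWarnings(wilcox.test(x, y, paired = TRUE)$p.value)
    }
    data.frame(level_a = pr[1L], level_b = pr[2L], n = length(common),
               z = z, p_raw = p, p_adjusted = min(1, p * m))
  })
  do.call(rbind, rows)
}

#' Centroid cluster analysis of compressive loads grouped by moments
#'
#' Standardized (peak moment, peak compression) features are clustered by
#' seeded multi-start k-means; clusters are relabelled so the compression
#' centroid increases with the cluster index. The report includes pairwise
#' Welch t statistics between clusters and the risk-level-by-cluster
#' cross-tabulation.
#'
#' @param summaries Data frame of trial summaries.
#' @param k Number of clusters (default 6).
#' @param seed Seed for the k-means restarts.
#' @param nstart Number of k-means starts.
#' @return A `cluster_report`: `k`, `assignments`, `centroids` (original
#'   scale), `t_table`, `crosstab`, `sizes`.
#' @export
cluster_loads <- function(summaries, k = 6L, seed = 1L, nstart = 50L) {
  feats <- cbind(moment = summaries$peak_moment_norm,
                 compression = summaries$peak_compression_bw)
  if (nrow(feats) < k)
    stop("infeasible: fewer trials than clusters", call. = FALSE)
  km <- with_seed(seed, kmeans(scale(feats), centers = k, nstart = nstart,
                               iter.max = 100))
  centroids_orig <- apply(feats, 2, function(col)
    tapply(col, km$cluster, mean))
  ord <- order(centroids_orig[, "compression"])
  relabel <- match(seq_len(k), ord)
  assignments <- relabel[km$cluster]
  centroids <- centroids_orig[ord, , drop = FALSE]
  rownames(centroids) <- seq_len(k)
  crosstab <- table(li_level = summaries$li_level, cluster =
                      factor(assignments, levels = seq_len(k)))
  report <- structure(list(k = k, assignments = assignments,
                           centroids = centroids,
                           compression = summaries$peak_compression_bw,
                           crosstab = crosstab,
                           sizes = as.integer(table(factor(assignments,
                                                           levels = seq_len(k)))),
                           t_table = NULL),
                      class = "cluster_report")
  report$t_table <- cluster_separation_tests(report)
  report
}

#' Pairwise Welch t tests between clusters
#'
#' For every cluster pair (a < b) the Welch two-sample t statistic of the
#' compression values is computed; t is negative when the lower-labelled
#' cluster has the lower mean. Singleton clusters are excluded with a
#' warning.
#'
#' @param report A `cluster_report`.
#' @return Data frame with `cluster_a`, `cluster_b`, `t`, `p`.
#' @export
cluster_separation_tests <- function(report) {
  usable <- which(report$sizes >= 2L)
  if (length(usable) < length(report$sizes))
    warning("singleton cluster(s) excluded from separation tests")
  if (length(usable) < 2L)
    return(data.frame(cluster_a = integer(0), cluster_b = integer(0),
                      t = numeric(0), p = numeric(0)))
  pairs <- utils::combn(usable, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    xa <- report$compression[report$assignments == pr[1L]]
    xb <- report$compression[report$assignments == pr[2L]]
    if (var(xa) == 0 && var(xb) == 0 && mean(xa) == mean(xb)) {
      tt <- list(statistic = c(t = 0), p.value = 1)
    } else {
      tt <- t.test(xa, xb)
    }
    data.frame(cluster_a = pr[1L], cluster_b = pr[2L],
               t = unname(tt$statistic), p = tt$p.value)
  })
  do.call(rbind, rows)
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> k = %d, %d trials\n", x$k,
              length(x$assignments)))
  cat("  compression centroids (BW):",
      paste(sprintf("%.2f", x$centroids[, "compression"]), collapse = ", "),
      "\n  risk level x cluster:\n")
  print(x$crosstab)
  invisible(x)
}

#' Mean silhouette width over a range of k
#'
#' Companion diagnostic for the fixed default `k = 6`: average silhouette
#' widths of seeded k-means partitions over `k_range`, computed on the same
#' standardized features as [cluster_loads()].
#'
#' @param summaries Data frame of trial summaries.
#' @param k_range Candidate cluster counts.
#' @param seed,nstart Passed to the k-means runs.
#' @return Data frame with `k` and `mean_silhouette`.
#' @export
silhouette_scan <- function(summaries, k_range = 2:8, seed = 1L,
                            nstart = 25L) {
  feats <- scale(cbind(summaries$peak_moment_norm,
                       summaries$peak_compression_bw))
  dm <- as.matrix(dist(feats))
  sil_for <- function(assign) {
    ks <- sort(unique(assign))
    s <- vapply(seq_along(assign), function(i) {
      own <- assign[i]
      a <- mean(dm[i, assign == own & seq_along(assign) != i])
      if (!is.finite(a)) return(0)
      b <- min(vapply(setdiff(ks, own), function(kk)
        mean(dm[i, assign == kk]), numeric(1)))
      (b - a) / max(a, b)
    }, numeric(1))
    mean(s)
  }
  data.frame(k = k_range, mean_silhouette = vapply(k_range, function(k) {
    km <- with_seed(seed + k, kmeans(feats, k, nstart = nstart,
                                     iter.max = 100))
    sil_for(km$cluster)
  }, numeric(1)))
}

#' @importFrom stats dist
NULL
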