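# Risk statistics: trial summaries, normality, Wilcoxon, clustering.

fake_summaries <- function(n_subjects = 7, reps = 3,
                           level_means = c(6, 8, 10), sd = 0.5,
                           seed = 1) {
  set.seed(seed)
  rows <- expand.grid(subject_id = sprintf("S%02d", 1:n_subjects),
                      repetition = 1:reps, li_level = 1:3,
                      KEEP.OUT.ATTRS = FALSE)
  rows$peak_compression_bw <- level_means[rows$li_level] +
    rnorm(nrow(rows), 0, sd)
  rows$peak_moment_norm <- 0.4 * rows$peak_compression_bw +
    rnorm(nrow(rows), 0, 0.1)
  rows
}

test_that("trial summaries take peaks within the cycle only", {
  ds <- clean_dataset(seed = 3)
  tr <- ds$trials[[1]]
  p <- process_trial(tr, ds$subjects[[1]])
  loads <- estimate_trial_loads(ds$models[[1]], p)
  s <- summarize_trial(p, loads)
  expect_equal(s$peak_compression_bw, max(loads$compression_bw))
  expect_equal(s$rom_deg, p$rom * 180 / pi)
  # left/right averaging after peak extraction
  peaks <- apply(p$excitations, 2, max)
  expect_equal(s$peak_emg_longissimus,
               mean(peaks[c("longissimus_l", "longissimus_r")]))

  # a spike injected before the cycle start must not leak into the peaks
  spiked <- tr
  pre <- seq_len(floor(p$cycle$start_time * tr$fs_emg) - 60)
  spiked$emg$values[pre, "longissimus_l"] <-
    10 * max(spiked$emg$values[, "longissimus_l"])
  p2 <- process_trial(spiked, ds$subjects[[1]])
  loads2 <- estimate_trial_loads(ds$models[[1]], p2)
  s2 <- summarize_trial(p2, loads2)
  expect_equal(s2$peak_emg_longissimus, s$peak_emg_longissimus,
               tolerance = 1e-6)

  expect_error(summarize_trial(p, estimate_trial_loads(ds$models[[1]], p,
                                                       normalized = FALSE)),
               "normalized")
})

test_that("normality test is calibrated under the null and has power", {
  pvals <- vapply(1:100, function(i) {
    set.seed(2000 + i)
    normality_test(rnorm(500))$p
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.90)

  # two well-separated normals: rejected in most replicates
  rejected <- vapply(1:20, function(i) {
    set.seed(3000 + i)
    x <- c(rnorm(100, 0, 0.5), rnorm(100, 6, 0.5))
    normality_test(x)$p < 0.05
  }, logical(1))
  expect_gte(mean(rejected), 0.8)

  expect_error(normality_test(rep(1, 10)), "degenerate")
  expect_error(normality_test(c(1, 2)), "sample size")
  expect_error(normality_test(rnorm(5001)), "sample size")
})

test_that("paired Wilcoxon detects shifts and respects the Bonferroni cap", {
  df <- fake_summaries()
  # uniform-sign shift between levels: minimal attainable exact p at n = 21
  # (tiny jitter keeps the absolute differences tie-free so the exact
  # signed-rank null applies)
  set.seed(8)
  df$metric <- rnorm(nrow(df))
  jit <- function(n) runif(n, 0, 0.01)
  i2 <- df$li_level == 2; i1 <- df$li_level == 1; i3 <- df$li_level == 3
  df$metric[i2] <- df$metric[i1] + 1 + jit(sum(i2))
  df$metric[i3] <- df$metric[i1] + 2 + jit(sum(i3))
  tab <- wilcoxon_pairwise(df, "metric")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$n, rep(21, 3))
  # all 21 paired differences share one sign: exact two-sided p = 2 / 2^21
  expect_equal(tab$p_raw, rep(2 / 2^21, 3), tolerance = 1e-12)
  expect_true(all(tab$p_adjusted < 0.05))
  expect_equal(tab$p_adjusted, pmin(1, tab$p_raw * 3))
  expect_true(all(tab$z < 0))

  # identical samples: degenerate, non-significant
  df$metric <- rep(1, nrow(df))
  tab0 <- wilcoxon_pairwise(df, "metric")
  expect_equal(tab0$z, rep(0, 3))
  expect_equal(tab0$p_adjusted, rep(1, 3))

  # adjusted p never below raw p, never above 1
  df$metric <- rnorm(nrow(df))
  tab1 <- wilcoxon_pairwise(df, "metric")
  expect_true(all(tab1$p_adjusted >= tab1$p_raw))
  expect_true(all(tab1$p_adjusted <= 1))

  expect_error(wilcoxon_pairwise(df, "nope"), "not found")
  expect_error(wilcoxon_pairwise(df[df$li_level != 2, ], "metric",
                                 pairs = list(c(1, 2))), "pairing")
})

test_that("k-means re-stratification separates well-separated blobs", {
  set.seed(4)
  blob <- function(mc, mm, n = 15, s = 0.05)
    data.frame(peak_compression_bw = rnorm(n, mc, s),
               peak_moment_norm = rnorm(n, mm, s))
  df <- rbind(cbind(blob(5, 2), li_level = 1, subject_id = "a",
                    repetition = 1),
              cbind(blob(10, 4), li_level = 3, subject_id = "a",
                    repetition = 1))
  rep2 <- cluster_loads(df, k = 2, seed = 9)
  expect_equal(rep2$assignments, rep(c(1, 2), each = 15))
  # centroids ascend in compression after relabelling
  expect_true(all(diff(rep2$centroids[, "compression"]) > 0))
  # crosstab row sums equal the number of trials per risk level
  expect_equal(unname(rowSums(rep2$crosstab)), c(15, 15))
  expect_error(cluster_loads(df[1:3, ], k = 6), "infeasible")
})

test_that("cluster separation t statistics match the closed form", {
  # means 1 vs 2, equal sd 0.1, n = 10 each: |t| = 1 / (0.1 sqrt(2/10))
  x1 <- 1 + 0.1 * scale(rnorm(10, 0, 1))[, 1]
  x2 <- 2 + 0.1 * scale(rnorm(10, 0, 1))[, 1]
  report <- structure(list(k = 2, assignments = rep(1:2, each = 10),
                           compression = c(x1, x2),
                           sizes = c(10L, 10L)), class = "cluster_report")
  tab <- cluster_separation_tests(report)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$t, -1 / (0.1 * sqrt(2 / 10)), tolerance = 1e-9)
  expect_lt(tab$t, 0)   # lower-labelled cluster has the lower mean

  # identical clusters: t = 0; k = 6 gives 15 pairs
  rep6 <- structure(list(k = 6, assignments = rep(1:6, each = 4),
                         compression = rep(rnorm(4), 6),
                         sizes = rep(4L, 6)), class = "cluster_report")
  tab6 <- cluster_separation_tests(rep6)
  expect_equal(nrow(tab6), choose(6, 2))
  same <- structure(list(k = 2, assignments = rep(1:2, each = 4),
                         compression = rep(c(1, 2, 3, 4), 2),
                         sizes = c(4L, 4L)), class = "cluster_report")
  expect_equal(cluster_separation_tests(same)$t, 0, tolerance = 1e-9)

  singleton <- structure(list(k = 2, assignments = c(1, 1, 1, 2),
                              compression = c(1, 1.1, 0.9, 5),
                              sizes = c(3L, 1L)), class = "cluster_report")
  expect_warning(cluster_separation_tests(singleton), "singleton")
})

test_that("silhouette scan covers the requested k range", {
  df <- fake_summaries()
  sil <- silhouette_scan(df, k_range = 2:4, seed = 3)
  expect_equal(sil$k, 2:4)
  expect_true(all(is.finite(sil$mean_silhouette)))
  expect_true(all(sil$mean_silhouette >= -1 & sil$mean_silhouette <= 1))
})
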