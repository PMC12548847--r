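test_that("embryo-wise normalization uses pooled constants", {
  tb <- dplyr::bind_rows(
    as_trace_tbl(seq(100, 600, length.out = 11), embryo = "a"),
    as_trace_tbl(seq(100, 350, length.out = 11), embryo = "a", cell = 2L),
    as_trace_tbl(seq(0, 50, length.out = 11), embryo = "b"))
  nt <- normalize_traces(tb, "minmax_embryo", value = "intensity")
  expect_equal(nt$normalized[nt$embryo_id == "a" & nt$intensity == 350][1], 0.5)
  # each embryo maps its own extrema to [0, 1]: no cross-embryo leakage
  expect_equal(max(nt$normalized[nt$embryo_id == "a"]), 1)
  expect_equal(max(nt$normalized[nt$embryo_id == "b"]), 1)
  expect_equal(min(nt$normalized[nt$embryo_id == "b"]), 0)

  nz <- normalize_traces(tb, "zscore_embryo", value = "intensity")
  for (e in c("a", "b")) {
    v <- nz$normalized[nz$embryo_id == e]
    expect_lt(abs(mean(v)), 1e-9)
    expect_lt(abs(sd(v) - 1), 1e-9)
  }
  flat <- as_trace_tbl(rep(7, 11))
  expect_error(normalize_traces(flat, "minmax_embryo", value = "intensity"),
               class = "embryocal_normalization_error")
})

test_that("similarity is a shift-tolerant correlation in [0, 1]", {
  y <- kernel_trace(c(20, 60, 100)) + 5
  expect_equal(trace_similarity(y, y), 1, tolerance = 1e-12)
  shifted <- c(y[4:121], y[1:3])
  expect_gte(trace_similarity(y, shifted), 0.99)
  expect_error(trace_similarity(1:10, 1:9), class = "embryocal_input_error")
  # constant-trace conventions
  expect_equal(trace_similarity(rep(3, 10), rep(8, 10)), 1)
  expect_equal(trace_similarity(rep(3, 10), sin(1:10)), 0)
  # affine invariance with positive gain
  a <- kernel_trace(c(30, 90)); b <- kernel_trace(c(40, 80))
  expect_equal(trace_similarity(a, b), trace_similarity(2.5 * a + 10, 0.3 * b - 4),
               tolerance = 1e-12)
})

test_that("independent white-noise traces rarely look similar", {
  set.seed(8)
  sims <- vapply(1:1000, function(i) {
    trace_similarity(rnorm(121), rnorm(121))
  }, 1)
  expect_gte(mean(sims < 0.5), 0.95)
})

test_that("the similarity matrix matches pairwise evaluation", {
  bench <- simulate_cluster_benchmark(n_embryos = 1, cells_per_embryo = 8,
                                      seed = 6)
  nt <- normalize_traces(bench$traces, "zscore_embryo", value = "intensity")
  sm <- similarity_matrix(nt)
  vecs <- split(nt$normalized, nt$cell_id)
  for (i in 1:8) for (j in 1:8) {
    expect_equal(sm$s[i, j], trace_similarity(vecs[[i]], vecs[[j]]),
                 tolerance = 1e-10)
  }
  expect_true(isSymmetric(sm$s))
  expect_true(all(diag(sm$s) == 1))
})

test_that("density clustering handles degenerate and structured inputs", {
  d0 <- matrix(0, 30, 30)
  expect_equal(hdbscan_clusters(d0, min_cluster_size = 5), rep(1L, 30))
  expect_warning(out <- hdbscan_clusters(matrix(1, 3, 3) - diag(3),
                                         min_cluster_size = 10),
                 "outlier")
  expect_equal(out, integer(3))
  # two tight blobs + scattered noise
  set.seed(9)
  # scattered points far from both blobs join the hierarchy above the
  # blob split, so they must come out as the outlier class
  pts <- rbind(matrix(rnorm(40, 0, 0.05), 20, 2),
               matrix(rnorm(40, 5, 0.05), 20, 2),
               cbind(c(20, -15, 30, -20, 15), c(20, 8, -10, -20, 30)))
  d <- as.matrix(dist(pts))
  lab <- hdbscan_clusters(d, min_cluster_size = 8, min_samples = 5)
  expect_equal(length(unique(lab[1:20])), 1L)
  expect_equal(length(unique(lab[21:40])), 1L)
  expect_true(lab[1] != lab[21])
  expect_true(all(lab[41:45] == 0L))
  expect_identical(lab, hdbscan_clusters(d, min_cluster_size = 8, min_samples = 5))
})

test_that("global clustering recovers the archetype structure", {
  bench <- simulate_cluster_benchmark(seed = 1)
  dt <- detrend_traces(bench$traces)
  pk <- detect_transients(dt)
  fit <- cluster_traces(dt, pk, mode = "global")
  lab <- tidy(fit)
  # outlier-as-cluster: every cell carries a cluster id
  expect_false(any(is.na(lab$cluster)))
  expect_equal(length(unique(lab$cluster)), 4L)
  m <- dplyr::inner_join(lab, bench$truth$labels, by = c("embryo_id", "cell_id"))
  expect_gte(mclust::adjustedRandIndex(m$archetype, m$cluster), 0.8)
  # labels ascend with mean transient count
  ord <- lab |>
    dplyr::group_by(cluster) |>
    dplyr::summarise(m = mean(n_peaks), .groups = "drop") |>
    dplyr::arrange(cluster)
  expect_true(all(diff(ord$m) > 0))
  # quiescent cells are the outlier class, relabeled 0
  expect_true(all(lab$cluster[lab$is_outlier] == 0L))
})

test_that("per-embryo mode keeps the native outlier flag", {
  bench <- simulate_cluster_benchmark(n_embryos = 2, cells_per_embryo = 60,
                                      seed = 3)
  dt <- detrend_traces(bench$traces)
  pk <- detect_transients(dt)
  fit <- cluster_traces(dt, pk, mode = "per_embryo",
                        min_cluster_size = 8, min_samples = 5)
  lab <- tidy(fit)
  expect_true(any(lab$is_outlier))
  expect_true(all(is.na(lab$cluster[lab$is_outlier])))
  expect_true(all(!is.na(lab$cluster[!lab$is_outlier])))
})

test_that("clustering is invariant to cell order", {
  bench <- simulate_cluster_benchmark(n_embryos = 1, cells_per_embryo = 60,
                                      seed = 4)
  dt <- detrend_traces(bench$traces)
  pk <- detect_transients(dt)
  fit1 <- cluster_traces(dt, pk, mode = "global",
                         min_cluster_size = 8, min_samples = 5)
  perm <- withr::with_seed(1, sample(60))
  dt2 <- dt |>
    dplyr::mutate(cell_id = match(.data$cell_id, perm)) |>
    dplyr::arrange(.data$cell_id, .data$frame)
  pk2 <- dplyr::mutate(pk, cell_id = match(.data$cell_id, perm))
  fit2 <- cluster_traces(dt2, pk2, mode = "global",
                         min_cluster_size = 8, min_samples = 5)
  l1 <- tidy(fit1); l2 <- tidy(fit2)
  expect_equal(l2$cluster[match(match(l1$cell_id, perm), l2$cell_id)],
               l1$cluster)
})
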