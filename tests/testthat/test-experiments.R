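test_that("whole-embryo transient counting sums detected peaks", {
  # 2-min, 10-s interval timelapse: 13 frames
  quiet <- as_trace_tbl(rep(0, 13), interval = 10)
  expect_equal(count_transients(quiet)$total_transients, 0L)

  kern <- calibrate_kernel(20)
  tt <- (0:12) * 10
  one <- as_trace_tbl(eval_kernel(tt - 55, kern, 100), interval = 10)
  expect_equal(count_transients(one)$total_transients, 1L)

  multi <- dplyr::bind_rows(one, dplyr::mutate(quiet, cell_id = 2L),
                            dplyr::mutate(one, cell_id = 3L))
  expect_equal(count_transients(multi)$total_transients, 2L)
})

test_that("a mismatched detector interval falls back to the oracle", {
  m <- truth_trained_detector()  # trained on 5-s traces
  tr <- as_trace_tbl(rep(0, 13), interval = 10)
  expect_warning(out <- count_transients(tr, method = "cnn", model = m,
                                         trained_interval_s = 5),
                 "interval")
  expect_equal(out$total_transients, 0L)
})

test_that("identical groups give F = 0 and p = 1", {
  rec <- tibble::tibble(condition = rep(c("a", "b", "c"), each = 3),
                        total_transients = rep(c(1, 2, 3), 3))
  cmp <- compare_groups(rec)
  expect_equal(glance(cmp)$statistic, 0)
  expect_equal(glance(cmp)$p_value, 1)
  expect_equal(nrow(tidy(cmp)), 3L)  # all pairs covered
  expect_true(all(tidy(cmp)$p_adj >= 0 & tidy(cmp)$p_adj <= 1))
})

test_that("Tukey adjusted p-values match a studentized-range computation", {
  rec <- tibble::tibble(condition = rep(c("a", "b", "c"), c(5, 6, 4)),
                        total_transients = c(1, 2, 3, 4, 5,
                                             2, 4, 4, 5, 7, 6,
                                             6, 7, 8, 9))
  cmp <- compare_groups(rec)
  fit <- lm(total_transients ~ condition, data = rec)
  mse <- sum(residuals(fit)^2) / (15 - 3)
  mns <- tapply(rec$total_transients, rec$condition, mean)
  ns <- tapply(rec$total_transients, rec$condition, length)
  pairs <- list(c("b", "a"), c("c", "a"), c("c", "b"))
  for (k in seq_along(pairs)) {
    g <- pairs[[k]]
    q <- abs(mns[g[1]] - mns[g[2]]) /
      sqrt(mse / 2 * (1 / ns[g[1]] + 1 / ns[g[2]]))
    p_ref <- ptukey(q, nmeans = 3, df = 12, lower.tail = FALSE)
    p_pkg <- tidy(cmp)$p_adj[tidy(cmp)$pair == paste(g[1], g[2], sep = "-")]
    expect_equal(unname(p_pkg), unname(p_ref), tolerance = 1e-4)
  }
})

test_that("degenerate and malformed comparisons are rejected", {
  rec <- tibble::tibble(condition = rep(c("a", "b"), each = 3),
                        total_transients = rep(c(2, 5), each = 3))
  expect_error(compare_groups(rec), class = "embryocal_degenerate_error")
  expect_error(compare_groups(rec[1:3, ]), class = "embryocal_input_error")
  expect_error(compare_groups(rec, response = "missing"),
               class = "embryocal_input_error")
})

test_that("migration scoring applies the angular threshold convention", {
  pole <- tibble::tibble(x_um = c(0, 0), y_um = c(-50, -50))
  expect_false(score_migration(pole)$migrated)
  at45 <- tibble::tibble(x_um = c(0, 50 * sin(pi / 4)),
                         y_um = c(-50, -50 * cos(pi / 4)))
  out <- score_migration(at45)
  expect_true(out$migrated)
  expect_equal(out$angular_displacement_deg, 45, tolerance = 1e-6)
  at30 <- tibble::tibble(x_um = c(0, 50 * sin(pi / 6)),
                         y_um = c(-50, -50 * cos(pi / 6)))
  expect_true(score_migration(at30)$migrated)  # >= convention at the boundary
  expect_false(score_migration(at30, angle_threshold_deg = 31)$migrated)
  expect_error(score_migration(pole[1, ]), class = "embryocal_scoring_error")
})

test_that("rate summaries reproduce printed-percentage arithmetic", {
  outcomes <- tibble::tibble(
    embryo_id = seq_len(68),
    condition = rep(c("DMSO", "thapsigargin_10nM"), c(28, 40)),
    migrated = c(rep(TRUE, 20), rep(FALSE, 8), rep(TRUE, 4), rep(FALSE, 36)))
  s <- summarize_rates(outcomes = outcomes)
  expect_equal(s$migration$percent_migrated[s$migration$condition == "DMSO"], 71.4)
  expect_equal(s$migration$percent_migrated[s$migration$condition == "thapsigargin_10nM"], 10)
  expect_warning(summarize_rates(outcomes = outcomes[0, ]), "omitted")
})

test_that("count summaries keep the paired structure", {
  rec <- dplyr::bind_rows(
    simulate_inhibitor_experiment(12, 18, 1.3 / 18, condition = "thapsigargin_10nM",
                                  seed = 1),
    simulate_inhibitor_experiment(12, 17, 12 / 17, condition = "DMSO", seed = 2))
  s <- summarize_rates(records = rec)
  expect_equal(nrow(s$counts), 4L)
  expect_equal(nrow(s$deltas), 24L)
  expect_true(all(table(s$deltas$embryo_id, s$deltas$condition) <= 1))
  expect_equal(s$deltas$delta,
               s$deltas$total_transients - s$deltas$baseline)
})

test_that("generator effect multipliers are recovered from paired counts", {
  rec <- simulate_inhibitor_experiment(500, 18, 0.4, seed = 6)
  s <- summarize_rates(records = rec)
  m_base <- s$counts$mean_count[s$counts$timepoint == "baseline"]
  m_treat <- s$counts$mean_count[s$counts$timepoint == "treated_30min"]
  ratio <- m_treat / m_base
  se <- ratio * sqrt(1 / (18 * 500) + 1 / (0.4 * 18 * 500))
  expect_lt(abs(ratio - 0.4), 3 * se)
})
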