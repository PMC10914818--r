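# Screening analytics: threshold filter, fraction-beyond statistics,
# densities and trend tests.

mk_log <- function(affinity, qed, sa, smiles = NULL) {
  n <- length(affinity)
  data.frame(episode = seq_len(n) - 1L,
             smiles = if (is.null(smiles)) paste0("M", seq_len(n))
                      else smiles,
             affinity_kcal_mol = affinity, qed = qed, sa = sa,
             epsilon = 1, scalar_reward = -affinity / 10 + qed + sa,
             stringsAsFactors = FALSE)
}

test_that("the three-threshold filter reproduces the reported selections", {
  t <- screening_thresholds()        # 0.6 / 0.7 / -10.0, inclusive
  # the first reported candidate passes ...
  log <- mk_log(c(-10.3), c(0.70), c(0.68))
  expect_equal(nrow(filter_candidates(log, t)), 1L)
  # ... the lead's own scores fail on QED
  lead_log <- mk_log(c(-12), c(0.5), c(0.85))
  expect_equal(nrow(filter_candidates(lead_log, t)), 0L)
  # exact-boundary record passes under inclusive flags
  edge <- mk_log(c(-10.0), c(0.7), c(0.6))
  expect_equal(nrow(filter_candidates(edge, t)), 1L)
  # and fails when strict
  ts <- screening_thresholds(inclusive = FALSE)
  expect_equal(nrow(filter_candidates(edge, ts)), 0L)
})

test_that("the filter deduplicates by structure keeping the best reward", {
  log <- mk_log(c(-11, -12, -10.5), c(0.8, 0.9, 0.8), c(0.7, 0.7, 0.7),
                smiles = c("A", "A", "B"))
  out <- filter_candidates(log)
  expect_equal(nrow(out), 2L)
  expect_equal(out$affinity_kcal_mol[out$smiles == "A"], -12)
  # malformed records are skipped with a warning
  log$qed[3] <- NA
  expect_warning(out2 <- filter_candidates(log), "malformed")
  expect_equal(out2$smiles, "A")
})

test_that("filtering is idempotent, contractive and threshold-monotone", {
  set.seed(13)
  for (trial in 1:1000) {
    n <- sample(5:40, 1)
    log <- mk_log(runif(n, -14, -4), runif(n), runif(n),
                  smiles = sample(paste0("S", 1:15), n, replace = TRUE))
    t1 <- screening_thresholds(runif(1, 0, 0.9), runif(1, 0, 0.9),
                               runif(1, -12, -5))
    f1 <- filter_candidates(log, t1)
    expect_identical(filter_candidates(f1, t1), f1)
    expect_true(all(f1$smiles %in% log$smiles))
    # tightening any threshold never grows the passing set
    t2 <- screening_thresholds(min(t1$sa_min + 0.05, 1),
                               t1$qed_min, t1$affinity_max)
    expect_lte(nrow(filter_candidates(log, t2)), nrow(f1))
  }
})

test_that("fraction_beyond agrees with direct recounts", {
  expect_equal(fraction_beyond(c(-11, -9, -10.5), -10, "le"), 2 / 3)
  expect_equal(fraction_beyond(rep(0.7, 5), 0.7, "ge"), 1.0)
  expect_equal(fraction_beyond(rep(0.7, 5), 0.7, "ge", inclusive = FALSE),
               0.0)
  expect_error(fraction_beyond(numeric(0), 1), "empty")

  set.seed(8)
  vals <- runif(200, -14, -4)
  thr <- -9.5
  expect_identical(fraction_beyond(vals, thr, "le"),
                   sum(vals <= thr) / 200)
  # monotone non-increasing in the threshold for the "<=" direction
  ths <- seq(-12, -6, by = 0.5)
  fr <- vapply(ths, function(t) fraction_beyond(vals, t, "le"), 0)
  expect_true(all(diff(fr) >= 0))
  fr_rev <- vapply(rev(ths), function(t) fraction_beyond(vals, t, "le"), 0)
  expect_true(all(diff(fr_rev) <= 0))
})

test_that("reward densities recover known distributions and normalize", {
  set.seed(4)
  d <- reward_density(rnorm(10000))
  expect_lt(abs(d$modes[1]), 0.1)
  area <- sum(diff(d$x) * (head(d$y, -1) + tail(d$y, -1)) / 2)
  expect_equal(area, 1, tolerance = 1e-6)
  expect_true(all(d$y >= 0))

  u <- reward_density(runif(10000))
  inner <- u$x > 0.15 & u$x < 0.85
  se <- stats::sd(u$y[inner])
  expect_lt(max(abs(u$y[inner] - 1)), 3 * max(se, 0.05))

  deg <- reward_density(rep(1.5, 50))
  expect_equal(deg$point_mass, 1.5)
  expect_error(reward_density(1:5), "at least 10")
})

test_that("trend statistics detect improvement and stay null-calibrated", {
  log <- mk_log(seq(-5, -12, length.out = 50), runif(50), runif(50))
  tr <- trend_statistic(log, "affinity_kcal_mol")
  expect_equal(tr$rho, -1)
  expect_lt(tr$p_value, 1e-6)

  set.seed(6)
  null_log <- mk_log(sample(runif(1000, -12, -5)), runif(1000),
                     runif(1000))
  tr0 <- trend_statistic(null_log, "affinity_kcal_mol")
  expect_lt(abs(tr0$rho), 0.1)
  expect_gt(tr0$p_value, 0.01)

  const <- mk_log(rep(-8, 20), runif(20), runif(20))
  expect_true(trend_statistic(const, "affinity_kcal_mol")$constant)
})
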