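make_panel <- function(n_a = 6, n_b = 6, scale = "CAHAI", seed = 1,
                       shift = 0) {
  set.seed(seed)
  tibble::tibble(
    subject = sprintf("s%02d", 1:(n_a + n_b)),
    group = c(rep("RGS", n_a), rep("control", n_b)),
    scale = scale,
    t0 = rnorm(n_a + n_b, 50, 10),
    t3 = NA_real_) |>
    dplyr::mutate(t3 = t0 + rnorm(n_a + n_b) +
                    ifelse(group == "RGS", shift, 0))
}

test_that("polarity normalization reverses only the inverted scales", {
  panel <- tibble::tibble(
    subject = c("a", "a", "b", "b"),
    group = "RGS",
    scale = c("Hamilton", "CAHAI", "Hamilton", "CAHAI"),
    t0 = c(10, 40, 12, 50), t3 = c(12, 41.53, 11, 50))
  norm <- normalize_polarity(panel)
  # Hamilton change +2 becomes -2; CAHAI is untouched
  expect_equal(norm$t3[1] - norm$t0[1], -2)
  expect_equal(norm$t3[2] - norm$t0[2], 1.53)
  # idempotence
  expect_equal(as.data.frame(normalize_polarity(norm)), as.data.frame(norm))
  expect_error(normalize_polarity(dplyr::mutate(panel, scale = "bogus")),
               "unknown scale")
})

test_that("signed-rank p-values match exhaustive sign enumeration", {
  all_pos <- c(0.4, 1.1, 2.3, 3.2, 4.8, 5.5)
  res <- wilcoxon_signed_rank(all_pos)
  expect_equal(res$p_value, 2 / 64)
  expect_equal(res$statistic, 21)

  anti <- wilcoxon_signed_rank(c(1, -1, 2, -2))
  expect_equal(anti$p_value, 1)

  set.seed(51)
  for (i in 1:8) {
    n <- sample(4:8, 1)
    d <- round(rnorm(n, 0.3, 1), 3)
    while (any(d == 0) || any(duplicated(abs(d)))) d <- round(rnorm(n, 0.3, 1), 3)
    expect_equal(wilcoxon_signed_rank(d)$p_value, oracle_signed_rank_p(d),
                 tolerance = 1e-12)
  }

  expect_warning(res0 <- wilcoxon_signed_rank(rep(0, 4)), "zero")
  expect_equal(res0$p_value, 1)
})

test_that("the large-sample signed-rank approximation tracks the exact law", {
  set.seed(52)
  d <- rnorm(30, 0.5)
  approx_p <- wilcoxon_signed_rank(d)$p_value
  exact_p <- suppressWarnings(wilcox.test(d, exact = TRUE)$p.value)
  expect_equal(wilcoxon_signed_rank(d)$method, "normal approximation")
  expect_lt(abs(approx_p - exact_p), 0.01)
})

test_that("Mann-Whitney p-values match exhaustive enumeration", {
  sep <- mann_whitney_u(c(4, 5, 6), c(1, 2, 3))
  expect_equal(sep$statistic, 9)
  expect_equal(sep$p_value, 0.1)

  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 3 * 3 / 2)
  expect_equal(same$p_value, 1)

  set.seed(53)
  for (i in 1:8) {
    a <- round(rnorm(5), 3); b <- round(rnorm(5, 0.5), 3)
    while (any(duplicated(c(a, b)))) b <- round(rnorm(5, 0.5), 3)
    expect_equal(mann_whitney_u(a, b)$p_value, oracle_mann_whitney_p(a, b),
                 tolerance = 1e-12)
  }

  # invariance to a common shift
  a <- c(1.2, 3.4, 2.2, 5.1); b <- c(0.3, 2.8, 4.4)
  expect_equal(mann_whitney_u(a + 100, b + 100)$p_value,
               mann_whitney_u(a, b)$p_value)
  expect_error(mann_whitney_u(numeric(0), b), "non-empty")
})

test_that("the Friedman statistic matches hand-computed ranks", {
  concord <- matrix(rep(c(1, 5, 9), 10), nrow = 10, byrow = TRUE) +
    matrix(runif(30, 0, 0.4), 10)
  res <- friedman_rank_test(concord)
  expect_equal(res$statistic, 20)
  expect_lt(res$p_value, 1e-4)

  flat <- matrix(7, 5, 3)
  res0 <- friedman_rank_test(flat)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  set.seed(54)
  fix <- matrix(rnorm(12), 4, 3)
  expect_equal(friedman_rank_test(fix)$statistic, oracle_friedman_stat(fix),
               tolerance = 1e-12)

  with_na <- fix; with_na[2, 3] <- NA
  rownames(with_na) <- paste0("s", 1:4)
  expect_error(friedman_rank_test(with_na), "s2")
  expect_error(friedman_rank_test(fix[, 1, drop = FALSE]), "at least 2")
})

test_that("Spearman correlations match the permutation law", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_correlation(x, x * 2 + 1)$estimate, 1)
  expect_equal(spearman_correlation(x, rev(x))$estimate, -1)

  set.seed(55)
  for (i in 1:5) {
    x <- rnorm(6); y <- rnorm(6)
    res <- spearman_correlation(x, y)
    expect_equal(res$p_value, oracle_spearman_p(x, y), tolerance = 1e-9)
  }
  expect_error(spearman_correlation(rep(1, 5), rnorm(5)), "constant")
  expect_error(spearman_correlation(1:2, 1:2), "at least 3")
})

test_that("pooled Cohen's d has the textbook form and sign convention", {
  expect_equal(cohens_d(1, 1, 10, 1, 1, 10), 0)
  # antisymmetry under group swap
  expect_equal(cohens_d(2, 1.5, 12, 1, 2.5, 14),
               -cohens_d(1, 2.5, 14, 2, 1.5, 12))
  # closed form at unequal n
  d <- cohens_d(1.53, 2.4, 17, -0.67, 6.01, 18)
  sp <- sqrt((16 * 2.4^2 + 17 * 6.01^2) / 33)
  expect_equal(d, (1.53 + 0.67) / sp, tolerance = 1e-12)
  # full-precision values from the trial's printed group moments
  expect_equal(d, 0.4755709, tolerance = 1e-6)
  expect_equal(cohens_d(0.29, 0.59, 17, 0, 0, 18), 0.7058996,
               tolerance = 1e-6)
  expect_equal(cohens_d(0.35, 1.62, 17, 1.22, 3.84, 18), -0.2921396,
               tolerance = 1e-6)
  expect_error(cohens_d(1, 0, 10, 2, 0, 10), "zero")
  expect_error(cohens_d(1, 1, 1, 2, 1, 10), "n >= 2")
})

test_that("report cells equal the individual test outputs", {
  panel <- make_panel(n_a = 8, n_b = 9, seed = 56, shift = 0.8)
  rep <- build_outcomes_report(panel)
  row <- rep[rep$timepoint == "t3", ]
  imp <- panel$t3 - panel$t0
  ia <- imp[panel$group == "RGS"]; ib <- imp[panel$group == "control"]
  expect_equal(row$mean_treated, mean(ia))
  expect_equal(row$p_between, mann_whitney_u(ia, ib)$p_value)
  expect_equal(row$p_within_treated, wilcoxon_signed_rank(ia)$p_value)
  expect_equal(row$cohen_d,
               cohens_d(mean(ia), sd(ia), 8, mean(ib), sd(ib), 9))

  gl <- glance(rep)
  expect_equal(gl$n_scales, 1)
  expect_equal(gl$alpha, 0.05)
})

test_that("reversed scales report recovery-oriented improvements", {
  set.seed(57)
  n <- 20
  panel <- tibble::tibble(
    subject = sprintf("s%02d", 1:(2 * n)),
    group = rep(c("RGS", "control"), each = n),
    scale = "Hamilton",
    t0 = rnorm(2 * n, 10, 2))
  # treated mood scores drop (improve) by 3 points on the native scale
  panel$t3 <- panel$t0 + ifelse(panel$group == "RGS", -3, 0) + rnorm(2 * n, 0, 0.5)
  rep <- build_outcomes_report(panel)
  expect_gt(rep$mean_treated, 0)
  expect_gt(rep$cohen_d, 0)
})

test_that("Bonferroni correction only ever raises between-group p-values", {
  panel <- dplyr::bind_rows(make_panel(seed = 58, scale = "CAHAI"),
                            make_panel(seed = 59, scale = "UE-FM"),
                            make_panel(seed = 60, scale = "grip"))
  plain <- build_outcomes_report(panel)
  bonf <- build_outcomes_report(panel, correction = "bonferroni")
  expect_true(all(bonf$p_between_adjusted >= bonf$p_between))
  expect_equal(bonf$p_between, plain$p_between)
})

test_that("baseline balance uses rank-sum and chi-square tests", {
  panel <- make_panel(n_a = 10, n_b = 10, seed = 61)
  demo <- tibble::tibble(subject = panel$subject, group = panel$group,
                         sex = rep(c("f", "m"), 10))
  bal <- baseline_balance(panel, demo)
  expect_equal(nrow(bal), 2)
  cont <- bal[bal$type == "continuous", ]
  expect_equal(cont$p_value,
               mann_whitney_u(panel$t0[panel$group == "RGS"],
                              panel$t0[panel$group == "control"])$p_value)
})
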