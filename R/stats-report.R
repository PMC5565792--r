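# Nonparametric statistical layer of the two-arm trial: scale polarity
# handling, paired and unpaired rank tests, Friedman time effects,
# Spearman correlations, pooled-SD effect sizes and the outcome report.

trial_scales <- function() {
  c("UE-FM", "CAHAI", "Barthel", "MRCp", "MRCd", "ASp", "ASd",
    "grip", "Hamilton", "VAS-S", "MMSE")
}

reversed_scales <- function() c("Hamilton", "VAS-S", "ASp", "ASd")

#' Orient all clinical scales so that positive change means recovery
#'
#' Scores on the depression, pain and spasticity scales (Hamilton, VAS-S,
#' ASp, ASd) decrease with recovery; this negates them so that a positive
#' change expresses recovery on every scale. A marker attribute makes the
#' operation idempotent — normalizing twice equals normalizing once.
#'
#' @param panel A long outcome panel: columns `subject`, `group`, `scale`
#'   and score columns (`t0`, `t3`, `t12`, any subset).
#' @return The panel with reversed-polarity scales negated and attribute
#'   `polarity_normalized = TRUE`.
#' @export
normalize_polarity <- function(panel) {
  if (isTRUE(attr(panel, "polarity_normalized"))) return(panel)
  if (!"scale" %in% names(panel)) abort("`panel` needs a `scale` column.")
  unknown <- setdiff(unique(panel$scale), trial_scales())
  if (length(unknown) > 0) {
    abort(sprintf("unknown scale(s): %s", paste(unknown, collapse = ", ")))
  }
  score_cols <- intersect(c("t0", "t3", "t12"), names(panel))
  flip <- panel$scale %in% reversed_scales()
  for (col in score_cols) {
    panel[[col]] <- ifelse(flip, -panel[[col]], panel[[col]])
  }
  attr(panel, "polarity_normalized") <- TRUE
  panel
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Exact-distribution p-value (sign enumeration) whenever the number of
#' nonzero, untied differences is at most `exact_n`; otherwise the normal
#' approximation with tie and continuity correction. Zero differences are
#' dropped (Wilcoxon's convention).
#'
#' @param differences Numeric vector of paired differences.
#' @param exact_n Largest n for which the exact distribution is used
#'   (default 25).
#' @return A one-row tibble: `statistic` (V, sum of positive ranks),
#'   `p_value` (two-sided), `n` (nonzero differences), `method`.
#' @export
wilcoxon_signed_rank <- function(differences, exact_n = 25) {
  differences <- differences[!is.na(differences)]
  if (length(differences) == 0) abort("no differences supplied.")
  nz <- differences[differences != 0]
  if (length(nz) == 0) {
    warn("all differences are zero; p = 1.")
    return(tibble(statistic = 0, p_value = 1, n = 0L, method = "degenerate"))
  }
  ties <- any(duplicated(abs(nz)))
  exact <- length(nz) <= exact_n && !ties
  ht <- suppressWarnings(
    wilcox.test(differences, mu = 0, exact = exact, correct = TRUE)
  )
  tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
         n = length(nz),
         method = if (exact) "exact" else "normal approximation")
}

#' Mann-Whitney U test between two groups
#'
#' Exact p-value by enumeration when the samples are untied and small
#' enough; otherwise the normal approximation with midrank tie correction
#' and continuity correction.
#'
#' @param a,b Numeric vectors for the two groups (group `a` first; with
#'   trial data the convention is treated group first).
#' @param exact_n Largest `length(a) + length(b)` for which the exact
#'   distribution is guaranteed (exact enumeration is also used for larger
#'   untied samples, where it remains cheap).
#' @return A one-row tibble: `statistic` (U for group `a`), `p_value`
#'   (two-sided), `n_a`, `n_b`, `method`.
#' @examples
#' mann_whitney_u(c(4, 5, 6), c(1, 2, 3))
#' @export
mann_whitney_u <- function(a, b, exact_n = 12) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) abort("both groups must be non-empty.")
  ties <- any(duplicated(c(a, b)))
  exact <- !ties && (length(a) + length(b) <= max(exact_n, 50))
  ht <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE)
  )
  tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
         n_a = length(a), n_b = length(b),
         method = if (exact) "exact" else "normal approximation")
}

#' Friedman rank test for repeated measures
#'
#' Rank-based test for a time (condition) effect across repeated
#' measurements of the same subjects, with midrank tie correction and the
#' asymptotic chi-square p-value.
#'
#' @param scores A numeric matrix or data frame, subjects in rows and
#'   conditions (e.g. sessions or evaluation weeks) in columns. Rows with
#'   missing values are an error, which reports the offending subjects.
#' @return A one-row tibble: `statistic` (chi-square), `df`, `p_value`,
#'   `n` (subjects), `k` (conditions).
#' @examples
#' friedman_rank_test(matrix(c(1, 2, 3, 1, 2, 3, 1, 3, 2), 3, byrow = TRUE))
#' @export
friedman_rank_test <- function(scores) {
  m <- as.matrix(scores)
  if (ncol(m) < 2 || nrow(m) < 2) {
    abort("need at least 2 subjects and 2 conditions.")
  }
  bad <- which(!complete.cases(m))
  if (length(bad) > 0) {
    abort(sprintf("incomplete rows for subject(s): %s",
                  paste(rownames(m)[bad] %||% bad, collapse = ", ")))
  }
  ht <- friedman.test(m)
  stat <- unname(ht$statistic)
  p <- ht$p.value
  if (is.nan(stat)) {
    # every subject ties all conditions: no evidence of a time effect
    stat <- 0
    p <- 1
  }
  tibble(statistic = stat, df = unname(ht$parameter), p_value = p,
         n = nrow(m), k = ncol(m))
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks, with the exact permutation p-value for
#' small untied samples (n <= `exact_n`) and the t-approximation
#' otherwise.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @param exact_n Largest n for which the exact permutation distribution
#'   is used (default 8).
#' @return A one-row tibble: `estimate` (r_s), `p_value` (two-sided), `n`.
#' @export
spearman_correlation <- function(x, y, exact_n = 8) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("need at least 3 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("constant input: Spearman correlation undefined.")
  }
  ties <- any(duplicated(x)) || any(duplicated(y))
  exact <- length(x) <= exact_n && !ties
  ht <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = exact)
  )
  tibble(estimate = unname(ht$estimate), p_value = ht$p.value,
         n = length(x))
}

#' Pooled-SD Cohen's d between two groups
#'
#' `d = (mean_a - mean_b) / s_pooled` with the degrees-of-freedom-weighted
#' pooled standard deviation
#' `s_pooled = sqrt(((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2))`.
#' Sign convention: group `a` is the treated group, so positive d favours
#' treatment.
#'
#' @param mean_a,sd_a,n_a Moments of group a (treated).
#' @param mean_b,sd_b,n_b Moments of group b (control).
#' @param hedges Apply Hedges' small-sample bias correction (default
#'   `FALSE`).
#' @return Cohen's d (a single number).
#' @examples
#' cohens_d(1.53, 2.4, 17, -0.67, 6.01, 18)
#' @export
cohens_d <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b, hedges = FALSE) {
  if (n_a < 2 || n_b < 2) abort("both groups need n >= 2.")
  if (any(c(sd_a, sd_b) < 0)) abort("standard deviations must be >= 0.")
  if (sd_a == 0 && sd_b == 0) {
    abort("both standard deviations are zero: d undefined.")
  }
  sp <- sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2))
  d <- (mean_a - mean_b) / sp
  if (hedges) d <- d * (1 - 3 / (4 * (n_a + n_b) - 9))
  d
}

#' Full between- and within-group outcomes report
#'
#' For every clinical scale and follow-up timepoint: polarity-normalized
#' improvements (later minus baseline), within-group Wilcoxon signed-rank
#' p-values, the between-group Mann-Whitney p-value and pooled Cohen's d
#' (treated group first). No multiple-comparison correction is applied by
#' default; Bonferroni is available.
#'
#' @param panel A long outcome panel (`subject`, `group`, `scale`, `t0`,
#'   `t3` and optionally `t12`). `group` must have exactly two levels; the
#'   treated level is `treated` (default `"RGS"`).
#' @param alpha Two-sided significance level (default 0.05).
#' @param correction `"none"` (default) or `"bonferroni"` (applied to the
#'   between-group p-values within each timepoint).
#' @param treated Name of the treated group level.
#' @return A tibble of class `outcomes_report`, one row per scale by
#'   timepoint, with group means (SD), within- and between-group p-values
#'   and Cohen's d; `alpha` and `correction` stored as attributes.
#' @export
build_outcomes_report <- function(panel, alpha = 0.05,
                                  correction = c("none", "bonferroni"),
                                  treated = "RGS") {
  correction <- match.arg(correction)
  need <- c("subject", "group", "scale", "t0", "t3")
  miss <- setdiff(need, names(panel))
  if (length(miss) > 0) {
    abort(sprintf("panel is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  groups <- unique(panel$group)
  if (length(groups) != 2 || !treated %in% groups) {
    abort("`panel$group` must have exactly 2 levels including `treated`.")
  }
  control <- setdiff(groups, treated)
  panel <- normalize_polarity(panel)
  timepoints <- intersect(c("t3", "t12"), names(panel))

  rows <- list()
  for (tp in timepoints) {
    for (sc in unique(panel$scale)) {
      sub <- panel[panel$scale == sc, ]
      imp <- sub[[tp]] - sub$t0
      ia <- imp[sub$group == treated]
      ib <- imp[sub$group == control]
      ia <- ia[!is.na(ia)]; ib <- ib[!is.na(ib)]
      if (length(ia) < 2 || length(ib) < 2) {
        inform(sprintf("scale %s (%s): a group is missing; cells left NA.",
                       sc, tp))
        rows[[length(rows) + 1L]] <- tibble(
          scale = sc, timepoint = tp, mean_treated = NA_real_,
          sd_treated = NA_real_, n_treated = length(ia),
          p_within_treated = NA_real_, mean_control = NA_real_,
          sd_control = NA_real_, n_control = length(ib),
          p_within_control = NA_real_, p_between = NA_real_,
          cohen_d = NA_real_)
        next
      }
      d <- if (sd(ia) == 0 && sd(ib) == 0) {
        if (mean(ia) == mean(ib)) 0 else NA_real_
      } else {
        cohens_d(mean(ia), sd(ia), length(ia), mean(ib), sd(ib), length(ib))
      }
      rows[[length(rows) + 1L]] <- tibble(
        scale = sc, timepoint = tp,
        mean_treated = mean(ia), sd_treated = sd(ia), n_treated = length(ia),
        p_within_treated = wilcoxon_signed_rank(ia)$p_value,
        mean_control = mean(ib), sd_control = sd(ib), n_control = length(ib),
        p_within_control = wilcoxon_signed_rank(ib)$p_value,
        p_between = mann_whitney_u(ia, ib)$p_value,
        cohen_d = d)
    }
  }
  report <- bind_rows(rows)
  if (correction == "bonferroni") {
    report <- report |>
      group_by(.data$timepoint) |>
      mutate(p_between_adjusted = p.adjust(.data$p_between, "bonferroni")) |>
      ungroup()
  }
  report <- report |>
    mutate(significant = !is.na(.data$p_between) &
             (if (correction == "bonferroni") .data$p_between_adjusted
              else .data$p_between) <= alpha)
  structure(report, class = c("outcomes_report", class(report)),
            alpha = alpha, correction = correction, treated = treated)
}

#' @export
print.outcomes_report <- function(x, digits = 2, ...) {
  cat(sprintf("Outcomes report (treated = %s, alpha = %g, correction = %s)\n",
              attr(x, "treated"), attr(x, "alpha"), attr(x, "correction")))
  for (tp in unique(x$timepoint)) {
    cat(sprintf("\n== %s ==\n",
                if (tp == "t3") "End (week 3)" else "Follow-up (week 12)"))
    sub <- x[x$timepoint == tp, ]
    cat(sprintf("%-9s %18s %6s %18s %6s %9s %7s\n", "scale",
                "treated mean (SD)", "P", "control mean (SD)", "P",
                "between P", "d"))
    for (i in seq_len(nrow(sub))) {
      cat(sprintf("%-9s %11.2f (%5.2f) %6.2f %11.2f (%5.2f) %6.2f %9.2f %7.2f\n",
                  sub$scale[i], sub$mean_treated[i], sub$sd_treated[i],
                  sub$p_within_treated[i], sub$mean_control[i],
                  sub$sd_control[i], sub$p_within_control[i],
                  sub$p_between[i], sub$cohen_d[i]))
    }
  }
  invisible(x)
}

#' @rdname build_outcomes_report
#' @param x An `outcomes_report`.
#' @param ... Unused.
#' @export
glance.outcomes_report <- function(x, ...) {
  tibble(n_scales = length(unique(x$scale)),
         n_timepoints = length(unique(x$timepoint)),
         n_significant = sum(x$significant, na.rm = TRUE),
         alpha = attr(x, "alpha"),
         correction = attr(x, "correction"))
}

#' @rdname build_outcomes_report
#' @param object An `outcomes_report`.
#' @export
autoplot.outcomes_report <- function(object, ...) {
  d <- as_tibble(object) |>
    mutate(label = ifelse(.data$timepoint == "t3", "week 3", "week 12"))
  ggplot2::ggplot(d, ggplot2::aes(.data$cohen_d, .data$scale,
                                  colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_point(size = 3) +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(x = "Cohen's d (treated - control)", y = NULL,
                  colour = "between-group\nsignificant") +
    ggplot2::theme_minimal()
}

#' Baseline balance table
#'
#' Compares the two arms at baseline: Mann-Whitney rank-sum tests on
#' continuous baseline scores (per scale) and chi-square tests on optional
#' categorical demographics.
#'
#' @param panel A long outcome panel with a `t0` column.
#' @param demographics Optional tibble (`subject`, `group`, one column per
#'   categorical variable).
#' @param treated Name of the treated group level.
#' @return A tibble: `variable`, `type`, summary per group, `p_value`.
#' @export
baseline_balance <- function(panel, demographics = NULL, treated = "RGS") {
  groups <- unique(panel$group)
  control <- setdiff(groups, treated)
  rows <- panel |>
    group_by(.data$scale) |>
    summarise(
      type = "continuous",
      summary_treated = sprintf("%.2f (%.2f)",
                                mean(.data$t0[.data$group == treated]),
                                sd(.data$t0[.data$group == treated])),
      summary_control = sprintf("%.2f (%.2f)",
                                mean(.data$t0[.data$group == control]),
                                sd(.data$t0[.data$group == control])),
      p_value = mann_whitney_u(.data$t0[.data$group == treated],
                               .data$t0[.data$group == control])$p_value,
      .groups = "drop") |>
    dplyr::rename(variable = "scale")
  if (!is.null(demographics)) {
    vars <- setdiff(names(demographics), c("subject", "group"))
    cat_rows <- purrr::map_dfr(vars, function(v) {
      tab <- table(demographics$group, demographics[[v]])
      ht <- suppressWarnings(chisq.test(tab))
      tibble(variable = v, type = "categorical",
             summary_treated = paste(tab[treated, ], collapse = "/"),
             summary_control = paste(tab[control, ], collapse = "/"),
             p_value = ht$p.value)
    })
    rows <- bind_rows(rows, cat_rows)
  }
  rows
}

#' Monte-Carlo power of the between-group comparison
#'
#' Estimates the rejection rate of the two-sided Mann-Whitney comparison
#' of normally distributed improvements at a given true standardized
#' effect, group sizes and alpha — a simulation utility for planning and
#' for calibrating the reporting pipeline (the rejection rate at effect 0
#' is the empirical type-I error).
#'
#' @param effect True standardized mean difference (treated minus
#'   control).
#' @param n_a,n_b Group sizes.
#' @param replicates Number of simulated trials.
#' @param alpha Two-sided significance level.
#' @return The rejection proportion.
#' @export
mc_power_mann_whitney <- function(effect, n_a = 17, n_b = 18,
                                  replicates = 1000, alpha = 0.05) {
  rej <- vapply(seq_len(replicates), function(i) {
    a <- rnorm(n_a, effect, 1)
    b <- rnorm(n_b, 0, 1)
    mann_whitney_u(a, b)$p_value <= alpha
  }, logical(1))
  mean(rej)
}
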