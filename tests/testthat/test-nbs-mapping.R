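make_sites <- function(ml, ap, amp, intensity = 50, subject = "s1",
                       muscle = "APB", hemisphere = "pathological",
                       session = "pre") {
  tibble::tibble(subject = subject, muscle = muscle, hemisphere = hemisphere,
                 session = session, ml_mm = ml, ap_mm = ap,
                 intensity_pct_mso = intensity, mep_uv = amp)
}

test_that("the threshold rule picks the smallest qualifying intensity", {
  resp <- tibble::tibble(
    intensity_pct_mso = rep(c(35, 40), each = 10),
    mep_uv = c(ifelse(1:10 <= 4, 80, 20), ifelse(1:10 <= 6, 80, 20)))
  expect_equal(estimate_rmt(resp), 40)

  silent <- tibble::tibble(intensity_pct_mso = rep(c(40, 50), each = 5),
                           mep_uv = runif(10, 0, 49))
  expect_true(is.na(estimate_rmt(silent)))
  expect_error(estimate_rmt(resp[0, ]), "empty")

  # exactly half responding does not qualify (strictly more than 50%)
  half <- tibble::tibble(intensity_pct_mso = 40,
                         mep_uv = c(rep(80, 5), rep(10, 5)))
  expect_true(is.na(estimate_rmt(half)))
})

test_that("adding low-intensity responses never raises the threshold estimate", {
  base <- tibble::tibble(intensity_pct_mso = rep(44, 10),
                         mep_uv = c(rep(90, 7), rep(10, 3)))
  est0 <- estimate_rmt(base)
  more <- dplyr::bind_rows(base,
                           tibble::tibble(intensity_pct_mso = rep(40, 10),
                                          mep_uv = rep(90, 10)))
  expect_lte(estimate_rmt(more), est0)
})

test_that("threshold recovery is within one 2%-MSO level", {
  set.seed(41)
  est <- replicate(200, estimate_rmt(simulate_recruitment_series(45)))
  expect_lt(abs(mean(est) - 45), 2)
})

test_that("stimulation efficacy is the interpolated P80 over max intensity", {
  one <- make_sites(0, 0, 330, intensity = 60)
  expect_equal(stimulation_efficacy(one), 5.5)

  five <- make_sites(1:5, 0, c(100, 200, 300, 400, 500), intensity = 50)
  expect_equal(stimulation_efficacy(five), 420 / 50)

  # degree-1 homogeneity in amplitudes
  k <- 3.7
  scaled <- dplyr::mutate(five, mep_uv = mep_uv * k)
  expect_equal(stimulation_efficacy(scaled), k * stimulation_efficacy(five))

  zero <- make_sites(1:3, 0, 0)
  expect_equal(stimulation_efficacy(zero), 0)
  expect_error(stimulation_efficacy(zero[0, ]), "empty")

  esc <- make_sites(1:4, 0, c(60, 70, 80, 90), intensity = c(50, 50, 60, 60))
  expect_equal(stimulation_efficacy(esc, "device_max"),
               unname(quantile(c(60, 70, 80, 90), 0.8)) / 100)
})

test_that("the centroid is the amplitude-weighted responsive mean", {
  single <- make_sites(10, -20, 300)
  expect_equal(map_centroid(single), c(ml = 10, ap = -20))

  square <- make_sites(c(0, 0, 10, 10), c(0, 10, 0, 10), rep(200, 4))
  expect_equal(map_centroid(square), c(ml = 5, ap = 5))

  fix <- make_sites(c(0, 5, 10, 0, 5, 10), c(0, 0, 0, 5, 5, 5),
                    c(120, 400, 60, 80, 300, 55))
  w <- c(120, 400, 60, 80, 300, 55)
  expect_equal(map_centroid(fix),
               c(ml = sum(w * fix$ml_mm) / sum(w),
                 ap = sum(w * fix$ap_mm) / sum(w)),
               tolerance = 1e-9)

  # sub-threshold sites do not contribute
  with_silent <- dplyr::bind_rows(fix, make_sites(100, 100, 10))
  expect_equal(map_centroid(with_silent), map_centroid(fix))

  # uniform amplitude scaling leaves the centroid unchanged
  expect_equal(map_centroid(dplyr::mutate(fix, mep_uv = mep_uv * 2.5)),
               map_centroid(fix))

  # centroid lies inside the responsive convex hull
  set.seed(42)
  for (i in 1:10) {
    r <- make_sites(runif(12, -20, 20), runif(12, -20, 20),
                    runif(12, 60, 500))
    cent <- map_centroid(r)
    expect_gte(cent["ml"], min(r$ml_mm)); expect_lte(cent["ml"], max(r$ml_mm))
    expect_gte(cent["ap"], min(r$ap_mm)); expect_lte(cent["ap"], max(r$ap_mm))
  }

  expect_error(map_centroid(make_sites(0, 0, 20)), "unmappable")
})

test_that("centroid displacement is the signed post-minus-pre shift", {
  same <- centroid_displacement(c(ml = 2, ap = 3), c(ml = 2, ap = 3))
  expect_equal(unlist(same), c(d_ml_mm = 0, d_ap_mm = 0, displacement_mm = 0))

  pyth <- centroid_displacement(c(ml = 0, ap = 0), c(ml = 3, ap = 4))
  expect_equal(pyth$displacement_mm, 5)

  # translation invariance and magnitude symmetry
  a <- c(ml = -4, ap = 7); b <- c(ml = 1, ap = 2); shift <- c(ml = 10, ap = -3)
  expect_equal(centroid_displacement(a + shift, b + shift)$displacement_mm,
               centroid_displacement(a, b)$displacement_mm)
  expect_equal(centroid_displacement(b, a)$displacement_mm,
               centroid_displacement(a, b)$displacement_mm)

  pre <- make_sites(0, 0, 300, muscle = "APB")
  post <- make_sites(3, 4, 300, muscle = "ECR", session = "post")
  expect_error(centroid_displacement(pre, post), "muscle")
})

test_that("map area is the responsive convex hull area", {
  expect_equal(map_area(make_sites(c(0, 10), c(0, 0), c(300, 300))), 0)
  square <- make_sites(c(0, 0, 10, 10), c(0, 10, 0, 10), rep(200, 4))
  expect_equal(map_area(square), 100)

  set.seed(43)
  r <- make_sites(runif(20, -25, 25), runif(20, -25, 25), runif(20, 60, 600))
  expect_equal(map_area(r), oracle_hull_area(r$ml_mm, r$ap_mm),
               tolerance = 1e-9)

  # collinear responsive sites enclose nothing
  line <- make_sites(c(0, 5, 10), c(0, 5, 10), rep(200, 3))
  expect_equal(map_area(line), 0)
})

test_that("map comparison pairs sessions and recovers treatment effects", {
  set.seed(44)
  tr_null <- map_truth(centroid = c(0, 0))
  rows <- list()
  for (s in sprintf("n%02d", 1:10)) {
    rows[[length(rows) + 1]] <- acquire_motor_map(tr_null, session = "pre",
                                                  subject = s)
    rows[[length(rows) + 1]] <- acquire_motor_map(tr_null, session = "post",
                                                  subject = s)
  }
  ch <- compare_maps(dplyr::bind_rows(rows))
  expect_equal(nrow(ch), 10)
  expect_lt(abs(mean(ch$se_change)), 2)

  # a subject missing its post session is excluded with a warning
  lone <- acquire_motor_map(tr_null, session = "pre", subject = "n99")
  expect_warning(ch2 <- compare_maps(dplyr::bind_rows(rows, list(lone))),
                 "n99")
  expect_equal(nrow(ch2), 10)
})

test_that("an excitability gain is detected by the within-subject Wilcoxon", {
  set.seed(45)
  tr_gain <- map_truth(centroid = c(0, 0), excitability = 1.5)
  detected <- replicate(30, {
    ch <- compare_maps(dplyr::bind_rows(lapply(sprintf("g%02d", 1:14),
      function(s) dplyr::bind_rows(
        acquire_motor_map(tr_gain, session = "pre", subject = s),
        acquire_motor_map(tr_gain, session = "post", subject = s)))))
    wilcoxon_signed_rank(ch$se_change)$p_value <= 0.05 &&
      mean(ch$se_change) > 0
  })
  expect_gte(mean(detected), 0.8)
})

test_that("clinical gains built from SE changes correlate strongly", {
  set.seed(46)
  tr <- map_truth(centroid = c(0, 0), excitability = 1.4)
  ch <- compare_maps(dplyr::bind_rows(lapply(sprintf("c%02d", 1:14),
    function(s) dplyr::bind_rows(
      acquire_motor_map(tr, session = "pre", subject = s),
      acquire_motor_map(tr, session = "post", subject = s)))))
  clinical <- 2 + 1.5 * ch$se_change + rnorm(nrow(ch), 0, 0.2 * sd(ch$se_change))
  rs <- spearman_correlation(ch$se_change, clinical)
  expect_gt(rs$estimate, 0.8)
})
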