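make_incidence <- function(asr_f, asr_m, lo = NULL, hi = NULL,
                           cancer = "c1") {
  n <- length(asr_f)
  if (is.null(lo)) { lo <- seq(0, by = 10, length.out = n); hi <- lo + 10 }
  data.frame(cancer = cancer, sex = rep(c("F", "M"), each = n),
             age_lo = rep(lo, 2), age_hi = rep(hi, 2),
             asr = c(asr_f, asr_m))
}

test_that("ratio curve is F/M per bracket with undefined zero brackets", {
  tab <- make_incidence(asr_f = c(2, 4, 0, 8), asr_m = c(2, 2, 2, 0))
  cur <- compute_ratio_curve(tab, "c1")
  expect_equal(cur$ratio[1:2], c(1, 2))
  expect_equal(cur$log2_ratio[1:2], c(0, 1))
  expect_true(all(is.na(cur$ratio[3:4])))     # zero in either sex
  expect_equal(nrow(cur), 4)                  # grid never shrinks
  expect_error(compute_ratio_curve(tab, "nope"), "not found")
  all_zero <- make_incidence(rep(0, 4), rep(1, 4))
  expect_error(compute_ratio_curve(all_zero, "c1"), "degenerate")
})

test_that("PV index matches its formula on forced curves", {
  n <- 9
  lo <- seq(0, 80, by = 10)
  flat <- make_incidence(rep(5, n), rep(5, n), lo, lo + 10)
  pv <- premenopausal_variation_index(compute_ratio_curve(flat, "c1"))
  expect_identical(pv$pv, 0)
  expect_equal(pv$bias_class, "unbiased")
  pv_log <- premenopausal_variation_index(compute_ratio_curve(flat, "c1"),
                                          scale = "log2_ratio")
  expect_identical(pv_log$pv, 0)

  # ratio 1.5 throughout premenopause ([15,55) midpoints), 1 elsewhere
  mid <- lo + 5
  f <- ifelse(mid >= 15 & mid < 55, 7.5, 5)
  bump <- make_incidence(f, rep(5, n), lo, lo + 10)
  pv2 <- premenopausal_variation_index(compute_ratio_curve(bump, "c1"))
  expect_equal(pv2$pv, 0.5)
  expect_equal(pv2$bias_class, "female_biased")
})

test_that("PV equals a brute-force recomputation on randomized grids", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(6:18, 1)
    widths <- sample(3:12, n, replace = TRUE)
    lo <- cumsum(c(0, widths[-n]))
    hi <- lo + widths
    mid <- (lo + hi) / 2
    if (!all(c(any(mid < 15), any(mid >= 15 & mid < 55), any(mid >= 55)))) {
      next
    }
    f <- runif(n, 0.5, 4); m <- runif(n, 0.5, 4)
    tab <- make_incidence(f, m, lo, hi)
    cur <- compute_ratio_curve(tab, "c1")
    pv <- premenopausal_variation_index(cur)
    expect_equal(pv$pv, brute_pv(mid, f / m), tolerance = 1e-12)
    pv_log <- premenopausal_variation_index(cur, scale = "log2_ratio")
    expect_equal(pv_log$pv, brute_pv(mid, f / m, log2scale = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("PV errors name an empty period", {
  lo <- c(0, 20, 60); hi <- c(10, 30, 70)     # premenopause covered
  tab <- make_incidence(c(1, 0, 1), c(1, 1, 1), lo, hi)
  expect_error(
    premenopausal_variation_index(compute_ratio_curve(tab, "c1")),
    "premenopause")
})

test_that("classification rule is strict at the 0.2 boundaries", {
  expect_equal(classify_pv(0.25), "female_biased")
  expect_equal(classify_pv(-0.25), "male_biased")
  expect_equal(classify_pv(0.2), "unbiased")
  expect_equal(classify_pv(-0.2), "unbiased")
  expect_equal(classify_pv(0), "unbiased")
  expect_error(classify_pv(NaN), "finite")
})

test_that("swapping the sexes negates log2-scale PV and flips the class", {
  set.seed(7)
  n <- 10
  lo <- seq(0, 90, by = 10); hi <- lo + 10
  f <- runif(n, 0.5, 6); m <- runif(n, 0.5, 6)
  pv_fm <- premenopausal_variation_index(
    compute_ratio_curve(make_incidence(f, m, lo, hi), "c1"),
    scale = "log2_ratio")
  pv_mf <- premenopausal_variation_index(
    compute_ratio_curve(make_incidence(m, f, lo, hi), "c1"),
    scale = "log2_ratio")
  expect_equal(pv_fm$pv, -pv_mf$pv, tolerance = 1e-12)
  flip <- c(female_biased = "male_biased", male_biased = "female_biased",
            unbiased = "unbiased")
  expect_equal(unname(flip[pv_fm$bias_class]), pv_mf$bias_class)
})

test_that("polynomial trend interpolates exact polynomials", {
  lo <- seq(0, 80, by = 5); hi <- lo + 5
  mid <- (lo + hi) / 2
  beta <- c(0.3, -0.02, 1e-3, -2e-5, 1e-7)
  y <- drop(outer(mid, 0:4, `^`) %*% beta)
  tab <- make_incidence(2^y, rep(1, length(mid)), lo, hi)
  fit <- fit_polynomial_trend(compute_ratio_curve(tab, "c1"))
  expect_equal(fit$coefficients, beta, tolerance = 1e-6)
  expect_lt(fit$residual_sse, 1e-12)

  const <- make_incidence(rep(4, length(mid)), rep(1, length(mid)), lo, hi)
  cfit <- fit_polynomial_trend(compute_ratio_curve(const, "c1"))
  expect_equal(cfit$coefficients, c(2, 0, 0, 0, 0), tolerance = 1e-8)
})

test_that("polynomial trend matches the normal-equations oracle", {
  set.seed(11)
  lo <- seq(0, 85, by = 5); hi <- lo + 5
  mid <- (lo + hi) / 2
  for (rep in 1:10) {
    f <- runif(length(mid), 0.5, 5)
    tab <- make_incidence(f, rep(1, length(mid)), lo, hi)
    cur <- compute_ratio_curve(tab, "c1")
    fit <- fit_polynomial_trend(cur, degree = 4)
    # scale ages to keep the oracle's normal equations well conditioned
    oracle <- brute_polyfit(mid / 100, log2(f), 4)
    rescaled <- fit$coefficients * 100^(0:4)
    expect_equal(rescaled, oracle, tolerance = 1e-6)
    expect_equal(predict(fit, mid),
                 drop(outer(mid / 100, 0:4, `^`) %*% oracle),
                 tolerance = 1e-6)
  }
})

test_that("underdetermined polynomial fits are refused", {
  lo <- c(0, 20, 40, 60); hi <- lo + 10
  tab <- make_incidence(runif(4, 1, 2), rep(1, 4), lo, hi)
  expect_error(fit_polynomial_trend(compute_ratio_curve(tab, "c1")),
               "underdetermined")
})

test_that("concordance flags planted bumps, flat curves, and adversaries", {
  cfg <- sim_config(seed = 5, n_cancers = 1, bias_amplitude = 1.8,
                    asr_noise_sd = 0.02)
  cur <- compute_ratio_curve(gen_incidence_table(cfg), "cancer_01")
  pv <- premenopausal_variation_index(cur)
  fit <- fit_polynomial_trend(cur)
  expect_true(concordance_check(pv, fit))

  # flat: PV within the unbiased band is concordant by definition
  lo <- seq(0, 80, by = 10); hi <- lo + 10
  flat <- make_incidence(rep(3, 9), rep(3, 9), lo, hi)
  fcur <- compute_ratio_curve(flat, "c1")
  expect_true(concordance_check(premenopausal_variation_index(fcur),
                                fit_polynomial_trend(fcur)))

  # adversarial: one extreme premenopausal bracket makes the raw-ratio
  # mean (and so PV) positive while the log2-scale curve the polynomial
  # fits is dominated by the negative brackets, so the fitted
  # premenopausal mean sits below the flanks
  adv <- make_incidence(2^c(0.5, -4, -4, -4, 3, 0.5, 0.5, 0.5, 0.5),
                        rep(1, 9), lo, hi)
  acur <- compute_ratio_curve(adv, "c1")
  apv <- premenopausal_variation_index(acur, scale = "raw_ratio")
  afit <- fit_polynomial_trend(acur)
  expect_gt(apv$pv, 0.2)
  expect_false(concordance_check(apv, afit))
})

test_that("concordance refuses mismatched cancers", {
  cfg <- sim_config(seed = 5, n_cancers = 2, asr_noise_sd = 0.02)
  it <- gen_incidence_table(cfg)
  c1 <- compute_ratio_curve(it, "cancer_01")
  c2 <- compute_ratio_curve(it, "cancer_02")
  expect_error(concordance_check(premenopausal_variation_index(c1),
                                 fit_polynomial_trend(c2)),
               "different cancers")
})

test_that("female-bias enrichment test has the exact binomial tail", {
  none <- rep("unbiased", 10)
  expect_equal(bias_enrichment_test(none)$p_value, 1)
  all_f <- rep("female_biased", 6)
  expect_equal(bias_enrichment_test(all_f)$p_value, (1 / 3)^6,
               tolerance = 1e-12)
  classes <- c(rep("female_biased", 13), rep("unbiased", 7),
               rep("male_biased", 4))
  res <- bias_enrichment_test(classes)
  expect_equal(res$count_female_biased, 13)
  expect_equal(res$n, 24)
  expect_equal(res$p_value, brute_binom_tail(13, 24, 1 / 3),
               tolerance = 1e-12)
  expect_error(bias_enrichment_test(classes, p0 = 1), "p0")
})

test_that("pv_table classifies a simulated multi-cancer table", {
  amp <- rep(c(0.7, 1, 1.5), each = 4)
  cfg <- sim_config(seed = 21, n_cancers = 12, bias_amplitude = amp,
                    asr_noise_sd = 0.05)
  res <- pv_table(gen_incidence_table(cfg))
  expect_equal(nrow(res), 12)
  truth <- rep(c("male_biased", "unbiased", "female_biased"), each = 4)
  expect_gte(mean(res$bias_class == truth), 0.9)
  expect_true(all(res$concordant[abs(res$pv) > 0.2] %in% c(TRUE, FALSE)))
})
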