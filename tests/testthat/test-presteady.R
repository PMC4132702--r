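test_that("fit_sto recovers noise-free parameters and beats the grid oracle", {
  t <- seq(0, 10, 0.5)
  curve <- generate_sto_curve(A0 = 1, k_obs = 0.5, times = t)
  fit <- fit_sto(curve)
  expect_true(fit$converged)
  expect_equal(coef_of_test(fit, "A0"), 1, tolerance = 1e-6)
  expect_equal(coef_of_test(fit, "k_obs"), 0.5, tolerance = 1e-6)
  # optimizer RSS must not exceed the exhaustive grid search's
  oracle <- grid_search_burst(t, curve$product, with_kss = FALSE)
  expect_lte(fit$rss, oracle$rss + 1e-12)

  zero <- fit_sto(generate_sto_curve(0, 1, t))
  expect_true(zero$degenerate)
  expect_equal(coef_of_test(zero, "A0"), 0)
  expect_true(is.na(coef_of_test(zero, "k_obs")))

  expect_error(fit_sto(generate_sto_curve(1, 1, c(0, 1, 2))), ">= 4")
  expect_warning(fit_sto(generate_mto_curve(1, 1, 0.1, t)), "MTO")
})

test_that("fit_burst recovers noise-free parameters, k_pd = k_ss/A0", {
  t <- seq(0, 10, 0.25)
  curve <- generate_mto_curve(A0 = 2, k_obs = 1, k_ss = 0.5, times = t)
  fit <- fit_burst(curve)
  expect_equal(coef_of_test(fit, "A0"), 2, tolerance = 1e-6)
  expect_equal(coef_of_test(fit, "k_obs"), 1, tolerance = 1e-6)
  expect_equal(coef_of_test(fit, "k_ss"), 0.5, tolerance = 1e-6)
  expect_equal(coef_of_test(fit, "k_pd"), 0.25, tolerance = 1e-6)
  # k_pd is exactly the ratio of the fitted terms
  expect_identical(coef_of_test(fit, "k_pd"),
                   coef_of_test(fit, "k_ss") / coef_of_test(fit, "A0"))
  oracle <- grid_search_burst(t, curve$product, with_kss = TRUE)
  expect_lte(fit$rss, oracle$rss + 1e-12)

  # k_ss = 0: k_pd = 0 and agreement with fit_sto
  flat <- generate_mto_curve(2, 1, 0, t)
  fb <- fit_burst(flat)
  expect_equal(coef_of_test(fb, "k_pd"), 0, tolerance = 1e-9)
  fs <- suppressWarnings(fit_sto(flat))
  expect_equal(coef_of_test(fb, "A0"), coef_of_test(fs, "A0"), tolerance = 1e-6)
  expect_equal(coef_of_test(fb, "k_obs"), coef_of_test(fs, "k_obs"),
               tolerance = 1e-6)

  expect_true(fit_burst(generate_mto_curve(0, 1, 0, t))$degenerate)
})

test_that("noise-free recovery holds over random parameter draws", {
  set.seed(101)
  t <- seq(0, 10, 0.2)
  for (i in 1:25) {
    A0 <- 10^runif(1, -0.5, 1)
    k <- 10^runif(1, -0.3, 0.7)
    kss <- A0 * 10^runif(1, -1.7, -0.4)  # k_pd well below k_obs
    fit <- fit_burst(generate_mto_curve(A0, k, kss, t))
    expect_equal(coef_of_test(fit, "A0"), A0, tolerance = 1e-6)
    expect_equal(coef_of_test(fit, "k_obs"), k, tolerance = 1e-6)
    expect_equal(coef_of_test(fit, "k_pd"), kss / A0, tolerance = 1e-6)
  }
  for (i in 1:25) {
    A0 <- 10^runif(1, -1, 1)
    k <- 10^runif(1, -0.5, 1)
    fit <- fit_sto(generate_sto_curve(A0, k, t))
    expect_equal(coef_of_test(fit, "A0"), A0, tolerance = 1e-6)
    expect_equal(coef_of_test(fit, "k_obs"), k, tolerance = 1e-6)
  }
})

test_that("burst fixtures reproduce published turnover numbers", {
  fit246 <- fit_burst(fixture_mto_curve("eA", "246"))
  expect_equal(coef_of_test(fit246, "k_pd"), 0.24, tolerance = 1e-6)
  fit247 <- fit_burst(fixture_mto_curve("eA", "247"))
  expect_equal(coef_of_test(fit247, "k_pd"), 0.11, tolerance = 1e-6)
  # burst amplitude equals active enzyme: 22% of 7 nM
  expect_equal(coef_of_test(fit246, "A0"), 0.22 * 7, tolerance = 1e-6)

  # equal k_chem across codons: STO fits indistinguishable across the five
  fx <- mpg_fixtures()
  k_hats <- vapply(unique(fx$mechanism$codon), function(cod) {
    row <- fixture_mech("eA", cod)
    coef_of_test(fit_sto(generate_sto_curve(1, row$k_chem, seq(0, 10, 0.25))),
                 "k_obs")
  }, numeric(1))
  expect_lt(diff(range(k_hats)), 1e-8)
})

test_that("every non-hotspot k_pd exceeds every hotspot k_pd in round-trip", {
  fx <- mpg_fixtures()
  for (les in c("eA", "Hx")) {
    mech <- dplyr::filter(fx$mechanism, lesion == les)
    kpd_hat <- vapply(mech$codon, function(cod) {
      coef_of_test(fit_burst(fixture_mto_curve(les, cod)), "k_pd")
    }, numeric(1))
    expect_gt(min(kpd_hat[!mech$hotspot]), max(kpd_hat[mech$hotspot]))
  }
})

test_that("active-site titration recovers the generating active fraction", {
  t <- seq(0, 10, 0.25)
  concs <- c(3.5, 7, 10, 20)
  full <- active_site_titration(
    generate_titration_series(concs, 1.0, 1.2, 0.24, t), concs)
  expect_equal(full$active_fraction, 1.0, tolerance = 1e-6)

  for (af in c(0.22, 0.83)) {
    ttn <- active_site_titration(
      generate_titration_series(concs, af, 1.2, 0.24, t), concs)
    expect_equal(ttn$active_fraction, af, tolerance = 1e-6)
    expect_gt(ttn$r.squared, 0.999)
    # amplitudes ascend with enzyme concentration
    expect_true(all(diff(ttn$table$A0_hat) > 0))
  }
  expect_error(active_site_titration(
    generate_titration_series(7, 0.5, 1.2, 0.24, t), 7), ">= 2")
})

test_that("fold_change and the group t-test match hand arithmetic", {
  expect_equal(fold_change(0.24, 0.02)$ratio, 12)
  expect_equal(fold_change(0.24, 0.24)$ratio, 1)
  expect_equal(fold_change(0.26, 0.01)$ratio, 26)
  expect_error(fold_change(0.24, 0), "> 0")

  # textbook pooled-variance example
  cmp <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  oracle <- hand_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cmp$statistic, oracle$t, tolerance = 1e-10)
  expect_equal(cmp$statistic, -3.674, tolerance = 1e-3)
  expect_equal(cmp$p.value, 0.02131, tolerance = 1e-3)
  expect_equal(cmp$df, 4)

  same <- compare_groups(c(2, 2), c(2, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  # fixture half-life groupings against the hand formula; the HUVEC
  # grouping separates significantly at the codon level
  hep <- compare_groups(c(3.0, 16.5), c(18.5, 19.5, 20.5),
                        labels = c("non-hotspot", "hotspot"))
  hep_oracle <- hand_t_test(c(3.0, 16.5), c(18.5, 19.5, 20.5))
  expect_equal(hep$statistic, hep_oracle$t, tolerance = 1e-12)
  expect_equal(hep$p.value, hep_oracle$p, tolerance = 1e-12)
  expect_lt(hep$difference, 0)
  huv <- compare_groups(c(4.0, 5.0), c(9.1, 12.2, 15.3),
                        labels = c("non-hotspot", "hotspot"))
  expect_lt(huv$p.value, 0.05)
  expect_error(compare_groups(1, c(2, 3)), ">= 2")
})
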