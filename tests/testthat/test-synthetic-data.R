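test_that("noise-off generators evaluate their formulas exactly", {
  t <- seq(0, 10, 0.5)
  sto <- generate_sto_curve(A0 = 1, k_obs = 0.5, times = t)
  expect_equal(sto$product, 1 - exp(-0.5 * t))
  # half amplitude at t = ln(2)/k
  half <- generate_sto_curve(1, 0.5, times = c(0, log(2) / 0.5, 5))
  expect_equal(half$product[2], 0.5)

  expect_true(all(generate_sto_curve(A0 = 0, k_obs = 2, times = t)$product == 0))

  mto <- generate_mto_curve(A0 = 2, k_obs = 1, k_ss = 0.5, times = t)
  expect_equal(mto$product[t == 10], 2 * (1 - exp(-10)) + 5)
  # degenerate burst: k_ss = 0 collapses to the STO curve
  expect_equal(generate_mto_curve(A0 = 1, k_obs = 0.5, k_ss = 0, times = t)$product,
               sto$product)

  rep0 <- generate_repair_timecourse(3, times = c(0, 3, 6))
  expect_equal(rep0$percent_repair[rep0$time == 3], 50)
  expect_true(all(generate_repair_timecourse(Inf, times = c(0, 5, 48))$percent_repair == 0))
  expect_error(generate_repair_timecourse(-1, times = c(0, 5)), "positive")
  expect_error(generate_sto_curve(A0 = -1, k_obs = 0.5, times = t), "non-negative")
})

test_that("identical parameters and seed give bit-identical noisy output", {
  ns <- noise_spec(cv = 0.05, floor_sd = 0.1, seed = 42)
  t <- seq(0, 10, 0.5)
  a <- generate_mto_curve(2, 1, 0.5, t, noise = ns)
  b <- generate_mto_curve(2, 1, 0.5, t, noise = ns)
  expect_identical(a$product, b$product)
  c2 <- generate_mto_curve(2, 1, 0.5, t, noise = noise_spec(0.05, 0.1, 43))
  expect_false(identical(a$product, c2$product))
  # noise without a seed is refused
  expect_error(noise_spec(cv = 0.05), "seed")
  # the global RNG stream is left untouched
  set.seed(7); before <- rnorm(1)
  set.seed(7); invisible(generate_mto_curve(2, 1, 0.5, t, noise = ns))
  expect_identical(rnorm(1), before)
})

test_that("titration series has amplitudes proportional to enzyme", {
  t <- seq(0, 10, 0.25)
  series <- generate_titration_series(c(3.5, 7), 0.5, k_obs = 1.2,
                                      k_pd = 0.24, times = t)
  # burst amplitude term alone at large t: product - k_ss*t -> A0
  amp <- vapply(series, function(cv) {
    kss <- 0.24 * 0.5 * enzyme_total_of(cv)
    (cv$product[nrow(cv)] - kss * cv$time[nrow(cv)]) / (1 - exp(-1.2 * 10))
  }, numeric(1))
  expect_equal(unname(amp), c(1.75, 3.5), tolerance = 1e-9)
  one <- generate_titration_series(7, 1, 1.2, 0.24, t)[[1]]
  expect_equal(one$product[nrow(one)] - 0.24 * 7 * 10, 7, tolerance = 1e-4)
  expect_error(generate_titration_series(numeric(0), 0.5, 1, 0.1, t), "non-empty")
})

test_that("Ct generator is the algebraic inverse of percent_repair_from_ct", {
  tab <- generate_ct_table(true_repair_fraction = 1, ct_full_repair = 20)
  expect_equal(tab$ct_sample, 20)
  tab2 <- generate_ct_table(0.5, ct_full_repair = 20, efficiency = 2)
  expect_equal(tab2$ct_sample, 21)
  fr <- c(1, 0.9, 0.5, 0.271, 0.01, 1e-6)
  for (eff in c(2, 1.9, 1.5)) {
    back <- percent_repair_from_ct(generate_ct_table(fr, 20, eff))
    expect_equal(back$percent_repair, 100 * fr, tolerance = 1e-12)
  }
  expect_error(generate_ct_table(0), "\\(0, 1\\]")
  expect_error(generate_ct_table(0.5, efficiency = 2.5), "efficiency")
})

test_that("sensorgram generator covers its degenerate limits", {
  s0 <- generate_sensorgram_set(1e-3, 1e-3, 100, concs = 0)
  expect_true(all(s0$response == 0))
  sflat <- generate_sensorgram_set(1e-3, 0, 100, concs = 10)
  dis <- sflat$response[sflat$phase == "dissociation"]
  expect_equal(dis, rep(dis[1], length(dis)))
  # association end point continuous into dissociation
  s <- generate_sensorgram_set(1e-3, 1e-3, 100, concs = 10, dt = 1)
  last_assoc <- s$response[s$phase == "association"][sum(s$phase == "association")]
  first_dis <- s$response[s$phase == "dissociation"][1]
  expect_equal(first_dis, last_assoc * exp(-1e-3), tolerance = 1e-12)
})

test_that("mechanism ODE matches its analytic limits and conserves substrate", {
  fx_row <- list(label = "x", K_D = 10, k_on = 100, k_chem = 1, k_pd = 0.24,
                 active_fraction = 1)
  t <- seq(0, 10, 0.1)
  # no catalysis -> no product
  zero <- simulate_mechanism_ode(modifyList(fx_row, list(k_chem = 0)),
                                 500, 1, t)
  expect_true(all(zero$product < 1e-9))

  # enzyme-excess limit: trace matches the STO closed form within 1% of
  # the amplitude at every point
  sto <- simulate_mechanism_ode(fx_row, 500, 1, t)
  cf <- 1 * (1 - exp(-1 * t))
  expect_lt(max(abs(sto$product - cf)), 0.01 * 1)
  # pointwise relative 1% under deeper saturation (K_D = 0.1 nM)
  deep <- simulate_mechanism_ode(modifyList(fx_row, list(K_D = 0.1)), 500, 1, t)
  sel <- t >= 0.25
  expect_lt(max(abs(deep$product[sel] - cf[sel]) / cf[sel]), 0.01)

  # substrate-excess limit: late-phase slope within 5% of k_pd * A0
  burst_par <- list(label = "b", K_D = 1, k_on = 10, k_chem = 5, k_pd = 0.24,
                    active_fraction = 0.22)
  mto <- simulate_mechanism_ode(burst_par, 7, 75, t)
  sel <- mto$time >= 5
  slope <- coef(lm(mto$product[sel] ~ mto$time[sel]))[[2]]
  expect_equal(slope, 0.24 * 0.22 * 7, tolerance = 0.05)

  # mass balance [S]+[ES]+[EP]+[P] = substrate_total at every step
  expect_lt(max(abs(attr(mto, "mass_balance"))), 1e-9)
  expect_lt(max(abs(attr(sto, "mass_balance"))), 1e-9)

  expect_error(simulate_mechanism_ode(fx_row, 7, 75, c(1, 2)), "ascend from 0")
  expect_error(simulate_mechanism_ode(list(K_D = 1), 7, 75, t), "lacks field")
})

test_that("fixture catalog carries the published ground truth", {
  fx <- mpg_fixtures()
  expect_equal(fixture_mech("eA", "246")$k_pd, 0.24)
  expect_equal(fixture_mech("eA", "247")$k_pd, 0.11)
  expect_equal(fixture_mech("Hx", "246")$k_pd, 0.25)
  expect_equal(fixture_mech("Hx", "247")$k_pd, 0.26)
  expect_equal(fx$titration$active_fraction, c(0.22, 0.83))
  hep <- dplyr::filter(fx$repair, cell_context == "HepG2", lesion == "eA")
  expect_equal(hep$t_half[hep$codon == "246"], 3.0)
  expect_equal(hep$t_half[hep$codon == "247"], 16.5)
  # hotspot values sit inside their published ranges
  ea_hot <- dplyr::filter(fx$mechanism, lesion == "eA", hotspot)
  expect_true(all(ea_hot$k_pd >= 0.02 & ea_hot$k_pd <= 0.04))
  hx_hot <- dplyr::filter(fx$mechanism, lesion == "Hx", hotspot)
  expect_true(all(hx_hot$k_pd >= 0.01 & hx_hot$k_pd <= 0.08))
  expect_true(all(c("printed", "range-interpolated") %in% fx$mechanism$provenance))
  # JSON serialization round-trips the catalog values
  path <- withr::local_tempfile(fileext = ".json")
  write_fixtures_json(path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(js$mechanism$k_pd, fx$mechanism$k_pd)
  expect_equal(js$titration_enzyme_concs, c(3.5, 7, 10, 20))
})
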