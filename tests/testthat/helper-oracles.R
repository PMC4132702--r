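# Independent oracles kept deliberately dumb: exhaustive grid searches and
# hand formulas, never the package's own optimizer path.

# Coarse log-grid search over (A0, k_obs[, k_ss]) minimizing RSS of the
# burst/STO model, refined once around the best cell.
grid_search_burst <- function(t, y, with_kss = TRUE, n_grid = 20) {
  rss_of <- function(A0, k, kss) sum((y - (A0 * (1 - exp(-k * t)) + kss * t))^2)
  A0s <- exp(seq(log(max(max(y), 1e-6) / 20), log(max(max(y), 1e-6) * 2),
                 length.out = n_grid))
  ks <- exp(seq(log(0.01), log(20), length.out = n_grid))
  ksss <- if (with_kss) {
    tail_slope <- (y[length(y)] - y[length(y) - 2]) /
      (t[length(t)] - t[length(t) - 2])
    c(0, exp(seq(log(max(tail_slope, 1e-6) / 10),
                 log(max(tail_slope, 1e-6) * 10), length.out = n_grid)))
  } else 0
  best <- list(rss = Inf)
  for (A0 in A0s) for (k in ks) for (kss in ksss) {
    r <- rss_of(A0, k, kss)
    if (r < best$rss) best <- list(A0 = A0, k = k, kss = kss, rss = r)
  }
  # one refinement pass: finer grid around the best cell
  refine <- function(v, f = 1.6, n = 15) exp(seq(log(v / f), log(v * f),
                                                 length.out = n))
  for (A0 in refine(best$A0)) for (k in refine(best$k)) {
    for (kss in (if (with_kss && best$kss > 0) refine(best$kss) else best$kss)) {
      r <- rss_of(A0, k, kss)
      if (r < best$rss) best <- list(A0 = A0, k = k, kss = kss, rss = r)
    }
  }
  best
}

# Pooled-variance two-sample t-test from the textbook formula.
hand_t_test <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}

fixture_mech <- function(lesion_, codon_) {
  dplyr::filter(mpg_fixtures()$mechanism, lesion == lesion_, codon == codon_)
}

# Noise-free burst curve for a fixture row on the standard assay grid.
fixture_mto_curve <- function(lesion, codon, times = seq(0, 10, 0.25)) {
  fx <- mpg_fixtures()
  row <- fixture_mech(lesion, codon)
  A0 <- row$active_fraction * fx$burst_enzyme_total
  generate_mto_curve(A0 = A0, k_obs = row$k_obs, k_ss = row$k_pd * A0,
                     times = times, label = row$label,
                     enzyme_total = fx$burst_enzyme_total,
                     substrate_total = fx$burst_substrate_total)
}

coef_of_test <- function(fit, term) {
  tidy(fit)$estimate[tidy(fit)$term == term]
}
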