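#' Fit the single-turnover equation to a progress curve
#'
#' Bounded nonlinear least squares of `[P] = A0 (1 - exp(-k_obs t))`.
#' Initialization: `A0 <- max(product)`, `k_obs <- ln(2) / t_halfmax` where
#' `t_halfmax` is the earliest time at which the signal reaches half its
#' maximum. In the single-turnover regime `k_obs` approximates `k_chem`.
#'
#' @param curve A [progress_curve()] (or any data frame with `time` and
#'   `product` columns), >= 4 points. A warning is issued for MTO-regime
#'   input.
#' @return An object of class `sto_fit`: estimates, standard errors from
#'   the local linearization, RSS, convergence and degeneracy flags. Use
#'   [generics::tidy()] / [generics::glance()] to extract tibbles.
#' @export
#' @examples
#' curve <- generate_sto_curve(A0 = 1, k_obs = 0.5, times = seq(0, 10, 0.5))
#' fit_sto(curve)
fit_sto <- function(curve) {
  check_curve(curve, min_points = 4)
  if (!is.null(curve$regime) && any(curve$regime == "MTO")) {
    rlang::warn("fitting the STO equation to an MTO-regime curve")
  }
  t <- curve$time
  y <- curve$product

  if (all(y <= 0)) {
    return(new_kinfit("sto_fit",
      estimate = tibble::tibble(
        term = c("A0", "k_obs"), estimate = c(0, NA_real_),
        std.error = NA_real_),
      rss = 0, n = length(y), converged = TRUE, degenerate = TRUE,
      curve = curve))
  }

  A0_init <- max(y)
  k_init <- ln2_over_halfmax(t, y, A0_init)
  fit <- try(minpack.lm::nlsLM(
    y ~ A0 * (1 - exp(-k_obs * t)),
    start = list(A0 = A0_init, k_obs = k_init),
    lower = c(0, 0),
    control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                         maxiter = 500)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(new_kinfit("sto_fit",
      estimate = tibble::tibble(
        term = c("A0", "k_obs"), estimate = c(A0_init, k_init),
        std.error = NA_real_),
      rss = NA_real_, n = length(y), converged = FALSE, degenerate = FALSE,
      curve = curve))
  }
  new_kinfit("sto_fit",
    estimate = coef_table(fit),
    rss = sum(stats::resid(fit)^2), n = length(y),
    converged = fit$convInfo$isConv %||% TRUE, degenerate = FALSE,
    curve = curve, fit = fit)
}

#' Fit the burst (multiple-turnover) equation to a progress curve
#'
#' Bounded nonlinear least squares of
#' `[P] = A0 (1 - exp(-k_obs t)) + k_ss t`. The burst amplitude `A0`
#' estimates the active enzyme concentration (bounded above by the curve's
#' `enzyme_total` when known) and the product-dissociation rate is derived
#' as `k_pd = k_ss / A0` (min^-1). Initialization: straight line through the
#' final third of the points gives `k_ss` (slope) and `A0` (intercept);
#' `k_obs` from the half-rise time of the early residual.
#'
#' @param curve A [progress_curve()] with >= 6 points spanning both phases.
#' @return An object of class `burst_fit` with terms `A0`, `k_obs`, `k_ss`
#'   and derived `k_pd`; see [fit_sto()] for the result contract.
#' @export
#' @examples
#' curve <- generate_mto_curve(A0 = 2, k_obs = 1, k_ss = 0.5,
#'                             times = seq(0, 10, 0.25))
#' fit_burst(curve)
fit_burst <- function(curve) {
  check_curve(curve, min_points = 6)
  t <- curve$time
  y <- curve$product
  n <- length(y)

  if (all(y <= 0)) {
    return(new_kinfit("burst_fit",
      estimate = tibble::tibble(
        term = c("A0", "k_obs", "k_ss", "k_pd"),
        estimate = c(0, NA_real_, 0, NA_real_), std.error = NA_real_),
      rss = 0, n = n, converged = TRUE, degenerate = TRUE, curve = curve))
  }

  # linear tail -> k_ss and A0 starting values
  tail_idx <- seq.int(max(1L, n - floor(n / 3) + 1L), n)
  tail_fit <- stats::lm(y[tail_idx] ~ t[tail_idx])
  kss_init <- max(unname(stats::coef(tail_fit)[2]), 0)
  A0_init <- max(unname(stats::coef(tail_fit)[1]), max(y) / 10)
  resid_early <- pmax(y - kss_init * t, 0)
  k_init <- ln2_over_halfmax(t, resid_early, max(A0_init, max(resid_early)))

  upper_A0 <- enzyme_total_of(curve)
  if (is.na(upper_A0)) upper_A0 <- Inf
  A0_init <- min(A0_init, upper_A0)

  fit <- try(minpack.lm::nlsLM(
    y ~ A0 * (1 - exp(-k_obs * t)) + k_ss * t,
    start = list(A0 = A0_init, k_obs = k_init, k_ss = kss_init),
    lower = c(0, 0, 0), upper = c(upper_A0, Inf, Inf),
    control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                         maxiter = 500)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(new_kinfit("burst_fit",
      estimate = tibble::tibble(
        term = c("A0", "k_obs", "k_ss", "k_pd"),
        estimate = c(A0_init, k_init, kss_init, NA_real_),
        std.error = NA_real_),
      rss = NA_real_, n = n, converged = FALSE, degenerate = FALSE,
      curve = curve))
  }

  est <- coef_table(fit)
  A0_hat <- est$estimate[est$term == "A0"]
  kss_hat <- est$estimate[est$term == "k_ss"]
  degenerate <- A0_hat <= max(y) * 1e-6
  kpd_hat <- if (degenerate) NA_real_ else kss_hat / A0_hat
  # delta-method SE for the ratio, ignoring the (A0, k_ss) covariance
  se_A0 <- est$std.error[est$term == "A0"]
  se_kss <- est$std.error[est$term == "k_ss"]
  se_kpd <- if (degenerate || anyNA(c(se_A0, se_kss))) NA_real_ else
    abs(kpd_hat) * sqrt((se_kss / max(kss_hat, 1e-300))^2 + (se_A0 / A0_hat)^2)
  est <- dplyr::bind_rows(est, tibble::tibble(
    term = "k_pd", estimate = kpd_hat, std.error = se_kpd))

  new_kinfit("burst_fit",
    estimate = est, rss = sum(stats::resid(fit)^2), n = n,
    converged = fit$convInfo$isConv %||% TRUE, degenerate = degenerate,
    curve = curve, fit = fit)
}

#' Active-site titration
#'
#' Fits the burst equation to each curve of an enzyme-concentration series
#' and regresses the burst amplitudes on total enzyme through the origin;
#' the slope is the active fraction of the preparation.
#'
#' @param series List of [progress_curve()]s, one per concentration.
#' @param enzyme_concs Total enzyme, nM, parallel to `series`; taken from
#'   each curve's `enzyme_total` attribute when omitted.
#' @return An object of class `titration_fit`: `active_fraction`, its
#'   standard error, regression R^2, the per-curve burst fits, and a
#'   per-concentration amplitude table.
#' @export
active_site_titration <- function(series, enzyme_concs = NULL) {
  if (is.null(enzyme_concs)) {
    enzyme_concs <- purrr::map_dbl(series, enzyme_total_of)
  }
  if (length(series) < 2 || length(enzyme_concs) != length(series)) {
    rlang::abort("need >= 2 curves with matching `enzyme_concs`")
  }
  if (anyNA(enzyme_concs)) rlang::abort("enzyme concentrations unknown for some curves")

  fits <- purrr::map(series, fit_burst)
  usable <- purrr::map_lgl(fits, ~ .x$converged && !.x$degenerate)
  if (any(!usable)) {
    rlang::warn(sprintf("%d degenerate/non-converged curve(s) excluded from titration",
                        sum(!usable)))
  }
  if (sum(usable) < 2) rlang::abort("fewer than 2 usable burst fits; cannot titrate")

  tab <- tibble::tibble(
    enzyme_total = enzyme_concs[usable],
    A0_hat = purrr::map_dbl(fits[usable], ~ coef_of(.x, "A0"))
  )
  reg <- stats::lm(A0_hat ~ 0 + enzyme_total, data = tab)
  slope <- unname(stats::coef(reg)[1])
  reg_sm <- quiet_lm_summary(reg)
  structure(list(
    active_fraction = slope,
    se = unname(reg_sm$coefficients[1, "Std. Error"]),
    r.squared = reg_sm$r.squared,
    table = tab,
    fits = fits,
    excluded = which(!usable)
  ), class = "titration_fit")
}

#' Fold change between two rate constants
#'
#' @param numerator,denominator Rates, min^-1; `denominator` must be > 0.
#' @return A one-row tibble with `ratio` (numerator/denominator) and its
#'   labeled inverse, so either ordering can be read off.
#' @export
#' @examples
#' fold_change(0.24, 0.02)
fold_change <- function(numerator, denominator) {
  if (denominator <= 0) rlang::abort("`denominator` must be > 0")
  tibble::tibble(
    numerator = numerator, denominator = denominator,
    ratio = numerator / denominator,
    inverse_ratio = denominator / numerator
  )
}

#' Unpaired two-tailed Student's t-test between two groups
#'
#' Equal-variance (pooled) two-sample t-test, the comparison used for
#' hotspot versus non-hotspot parameter groups. Sign convention: the t
#' statistic is computed as group A minus group B (pass non-hotspot values
#' as `values_a`).
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param labels Character vector of two group labels.
#' @return A one-row tibble: group means, difference (a - b), `statistic`,
#'   `df`, `p.value`.
#' @export
#' @examples
#' compare_groups(c(3.0, 16.5), c(18.5, 19.5, 20.5),
#'                labels = c("non-hotspot", "hotspot"))
compare_groups <- function(values_a, values_b,
                           labels = c("a", "b")) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    rlang::abort("each group needs >= 2 values")
  }
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0 &&
      mean(values_a) == mean(values_b)) {
    return(tibble::tibble(
      group_a = labels[1], group_b = labels[2],
      mean_a = mean(values_a), mean_b = mean(values_b),
      difference = 0, statistic = 0,
      df = length(values_a) + length(values_b) - 2, p.value = 1))
  }
  tt <- stats::t.test(values_a, values_b, var.equal = TRUE,
                      alternative = "two.sided")
  tibble::tibble(
    group_a = labels[1], group_b = labels[2],
    mean_a = mean(values_a), mean_b = mean(values_b),
    difference = mean(values_a) - mean(values_b),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p.value = tt$p.value
  )
}

# ---- internals ----------------------------------------------------------

check_curve <- function(curve, min_points) {
  if (!is.data.frame(curve) || !all(c("time", "product") %in% names(curve))) {
    rlang::abort("`curve` must be a data frame with `time` and `product` columns")
  }
  if (nrow(curve) < min_points) {
    rlang::abort(sprintf("need >= %d time points, got %d", min_points, nrow(curve)))
  }
  invisible(TRUE)
}

# ln2 / (earliest time reaching half of A0); ties broken by earliest index
ln2_over_halfmax <- function(t, y, A0) {
  idx <- which(y >= A0 / 2)
  idx <- idx[t[idx] > 0]
  if (length(idx) == 0) return(log(2) / max(t[t > 0]))
  log(2) / t[min(idx)]
}

coef_table <- function(fit) {
  sm <- summary(fit)$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    std.error = unname(sm[, "Std. Error"])
  )
}

coef_of <- function(kinfit, term) {
  kinfit$estimate$estimate[kinfit$estimate$term == term]
}

new_kinfit <- function(class, estimate, rss, n, converged, degenerate,
                       curve = NULL, fit = NULL) {
  structure(list(
    estimate = estimate, rss = rss, n = n,
    converged = isTRUE(converged), degenerate = isTRUE(degenerate),
    curve = curve, fit = fit
  ), class = c(class, "kinfit"))
}

#' @export
print.kinfit <- function(x, ...) {
  cat("<", class(x)[1], "> ", x$n, " points; RSS = ",
      format(x$rss, digits = 4), "\n", sep = "")
  if (x$degenerate) cat("  [degenerate fit]\n")
  if (!x$converged) cat("  [did not converge]\n")
  print(x$estimate)
  invisible(x)
}

#' @export
print.titration_fit <- function(x, ...) {
  cat("<titration_fit> active fraction = ",
      format(100 * x$active_fraction, digits = 4), "% (SE ",
      format(100 * x$se, digits = 2), " pp), R^2 = ",
      format(x$r.squared, digits = 4), "\n", sep = "")
  print(x$table)
  invisible(x)
}
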