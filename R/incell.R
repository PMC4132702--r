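#' Percent repair from a qPCR Ct table
#'
#' Under the amplification-blocking model an unrepaired lesion is converted
#' to a nicked, non-amplifiable template, so the repaired fraction is
#' `efficiency^(ct_full_repair - ct_sample)`, clamped to `[0, 1]`. Samples
#' whose Ct undershoots the fully-repaired reference by more than
#' `tol_cycles` are clamped to 100% with a warning.
#'
#' @param table A [generate_ct_table()] tibble (columns `ct_sample`,
#'   `ct_full_repair`, `efficiency`, optionally `sample_id`).
#' @param tol_cycles Ct undershoot tolerated silently (cycles).
#' @return The input with a `percent_repair` column appended.
#' @export
#' @examples
#' percent_repair_from_ct(generate_ct_table(c(1, 0.5, 0.25)))
percent_repair_from_ct <- function(table, tol_cycles = 0.2) {
  stopifnot(is.data.frame(table),
            all(c("ct_sample", "ct_full_repair", "efficiency") %in% names(table)))
  check_efficiency(table$efficiency)
  if (any(!is.finite(table$ct_sample)) || any(table$ct_sample <= 0)) {
    rlang::abort("`ct_sample` must be finite and positive")
  }
  dct <- table$ct_full_repair - table$ct_sample
  if (any(dct > tol_cycles)) {
    rlang::warn(sprintf(
      "%d sample(s) amplified earlier than the fully-repaired reference; clamped to 100%%",
      sum(dct > tol_cycles)))
  }
  frac <- pmin(table$efficiency^dct, 1)
  dplyr::mutate(table, percent_repair = 100 * frac)
}

#' Estimate a repair half-life from an in-cell time course
#'
#' Default method fits `percent = plateau (1 - exp(-k t))` by bounded
#' nonlinear least squares (`plateau` in (0, 100]) and reports
#' `t_half = ln(2) / k`. The `linear_interpolation` alternative takes the
#' first crossing of 50% between adjacent observations, linear in time.
#' A curve that never reaches 50% is censored: `t_half` is reported as a
#' lower bound at the last observed time.
#'
#' @param tc A [generate_repair_timecourse()] tibble, or any data frame
#'   with `time` (h) and `percent_repair` columns.
#' @param method `"exponential_fit"` (default) or `"linear_interpolation"`.
#' @return An object of class `half_life_fit`: `t_half` (h), `se`,
#'   `censored`, `method`, plus codon/lesion/context metadata when present.
#' @export
#' @examples
#' tc <- generate_repair_timecourse(3, times = c(0, 5, 16, 24, 48))
#' estimate_half_life(tc)
estimate_half_life <- function(tc, method = c("exponential_fit",
                                              "linear_interpolation")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(tc),
            all(c("time", "percent_repair") %in% names(tc)))
  t <- tc$time
  y <- tc$percent_repair
  min_pts <- if (method == "exponential_fit") 3 else 2
  if (length(t) < min_pts) {
    rlang::abort(sprintf("`%s` needs >= %d time points", method, min_pts))
  }

  meta <- list(codon = first_or_na(tc[["codon"]]),
               lesion = first_or_na(tc[["lesion"]]),
               cell_context = first_or_na(tc[["cell_context"]]),
               hotspot = first_or_na(tc[["hotspot"]]))

  if (max(y) < 50) {
    return(new_half_life(NA_real_, NA_real_, censored = TRUE,
                         bound = max(t), method = method, meta = meta))
  }

  if (method == "linear_interpolation") {
    i <- which(y >= 50)[1]
    th <- if (i == 1) t[1] else
      t[i - 1] + (t[i] - t[i - 1]) * (50 - y[i - 1]) / (y[i] - y[i - 1])
    return(new_half_life(th, NA_real_, censored = FALSE, bound = NA_real_,
                         method = method, meta = meta))
  }

  k_init <- log(2) / max(t[which(y >= max(y) / 2)[1]], min(t[t > 0]))
  fit <- try(minpack.lm::nlsLM(
    y ~ plateau * (1 - exp(-k * t)),
    start = list(plateau = min(max(y) * 1.05, 100), k = k_init),
    lower = c(1e-6, 1e-9), upper = c(100, Inf),
    control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                         maxiter = 500)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) {
    rlang::warn("exponential half-life fit failed; falling back to interpolation")
    return(estimate_half_life(tc, "linear_interpolation"))
  }
  k_hat <- unname(stats::coef(fit)["k"])
  se_k <- unname(summary(fit)$coefficients["k", "Std. Error"])
  new_half_life(log(2) / k_hat, log(2) * se_k / k_hat^2, censored = FALSE,
                bound = NA_real_, method = method, meta = meta,
                plateau = unname(stats::coef(fit)["plateau"]))
}

new_half_life <- function(t_half, se, censored, bound, method, meta,
                          plateau = NA_real_) {
  structure(c(list(
    t_half = t_half, se = se, censored = censored, bound = bound,
    method = method, plateau = plateau), meta),
    class = "half_life_fit")
}

first_or_na <- function(x) if (is.null(x)) NA else x[1]

#' @export
print.half_life_fit <- function(x, ...) {
  if (x$censored) {
    cat("<half_life_fit> censored: t1/2 > ", x$bound, " h (", x$method, ")\n",
        sep = "")
  } else {
    cat("<half_life_fit> t1/2 = ", format(x$t_half, digits = 4), " h (",
        x$method, ")\n", sep = "")
  }
  invisible(x)
}

#' Assay linearity from mixing standards
#'
#' Ordinary least squares of observed on expected percent repair across
#' mixing standards; reports slope, intercept and R^2.
#'
#' @param standards A [generate_mixing_standards()] tibble (columns
#'   `expected_percent`, `observed_percent`), >= 3 distinct expected values.
#' @return A one-row tibble: `slope`, `intercept`, `r.squared`, `n`.
#' @export
mixing_linearity <- function(standards) {
  stopifnot(is.data.frame(standards),
            all(c("expected_percent", "observed_percent") %in% names(standards)))
  if (nrow(standards) < 3 ||
      length(unique(standards$expected_percent)) < 3) {
    rlang::abort("linearity needs >= 3 standards with distinct expected values")
  }
  fit <- stats::lm(observed_percent ~ expected_percent, data = standards)
  tibble::tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r.squared = quiet_lm_summary(fit)$r.squared,
    n = nrow(standards)
  )
}

#' Excision slope of an extract activity time course
#'
#' OLS slope (free intercept) of percent product formation over time, the
#' summary used for nuclear-extract excision assays.
#'
#' @param times Minutes, >= 2 points.
#' @param percent_product Percent product per time point.
#' @param label Optional label.
#' @return A one-row tibble: `label`, `slope` (% product min^-1), `se`,
#'   `r.squared`.
#' @export
#' @examples
#' excision_slope(c(10, 20), c(20, 40))
excision_slope <- function(times, percent_product, label = NA_character_) {
  if (length(times) < 2 || length(times) != length(percent_product)) {
    rlang::abort("need >= 2 paired points")
  }
  fit <- stats::lm(percent_product ~ times)
  sm <- quiet_lm_summary(fit)
  tibble::tibble(
    label = label,
    slope = unname(stats::coef(fit)[2]),
    se = unname(sm$coefficients[2, "Std. Error"]),
    r.squared = if (length(times) > 2) sm$r.squared else 1
  )
}

#' Hotspot classification of a p53 codon
#'
#' Membership in the configured codon catalog: by default codons 249, 179
#' and 255 are adenine-mutation hotspots and 246, 247 are non-hotspots.
#'
#' @param codon Codon label, e.g. `"249"`.
#' @param hotspots,non_hotspots Character vectors overriding the catalog.
#' @return `TRUE` for a hotspot, `FALSE` for a non-hotspot.
#' @export
#' @examples
#' classify_codon("249")
classify_codon <- function(codon,
                           hotspots = c("249", "179", "255"),
                           non_hotspots = c("246", "247")) {
  codon <- as.character(codon)
  if (!codon %in% c(hotspots, non_hotspots)) {
    rlang::abort(sprintf(
      "unknown codon '%s'; catalog: hotspots {%s}, non-hotspots {%s}",
      codon, paste(hotspots, collapse = ", "),
      paste(non_hotspots, collapse = ", ")))
  }
  codon %in% hotspots
}

#' Group medians of repair half-lives
#'
#' Medians of `t_half` per group (standard mean-of-middle-two rule for even
#' n). Censored results are excluded with a warning; an empty group after
#' exclusion is an error.
#'
#' @param results A tibble with columns `t_half`, `hotspot` (logical) and
#'   optionally `censored`; [half_life_fit] objects can be row-bound via
#'   [generics::tidy()].
#' @return A tibble with one row per group: `hotspot`, `median_t_half`, `n`.
#' @export
median_by_group <- function(results) {
  stopifnot(is.data.frame(results),
            all(c("t_half", "hotspot") %in% names(results)))
  if (!"censored" %in% names(results)) results$censored <- FALSE
  results$censored[is.na(results$censored)] <- FALSE
  if (any(results$censored)) {
    rlang::warn(sprintf("%d censored result(s) excluded from medians",
                        sum(results$censored)))
    results <- dplyr::filter(results, !.data$censored)
  }
  out <- results |>
    dplyr::group_by(.data$hotspot) |>
    dplyr::summarise(median_t_half = stats::median(.data$t_half),
                     n = dplyr::n(), .groups = "drop")
  if (!all(c(TRUE, FALSE) %in% out$hotspot) && length(unique(out$hotspot)) < 2) {
    rlang::warn("only one group present")
  }
  if (any(out$n == 0)) rlang::abort("empty group after censoring exclusions")
  out
}
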