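#' Tidy a kinetic fit
#'
#' @param x An `sto_fit` or `burst_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @exportS3Method generics::tidy
tidy.kinfit <- function(x, ...) x$estimate

#' @rdname tidy.kinfit
#' @exportS3Method generics::glance
glance.kinfit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n = x$n, converged = x$converged,
                 degenerate = x$degenerate)
}

#' Tidy an active-site titration
#'
#' @param x A `titration_fit`.
#' @param ... Unused.
#' @return One row per concentration: `enzyme_total`, `A0_hat`.
#' @exportS3Method generics::tidy
tidy.titration_fit <- function(x, ...) x$table

#' @rdname tidy.titration_fit
#' @exportS3Method generics::glance
glance.titration_fit <- function(x, ...) {
  tibble::tibble(active_fraction = x$active_fraction, se = x$se,
                 r.squared = x$r.squared, n_curves = nrow(x$table))
}

#' Tidy a repair half-life fit
#'
#' @param x A `half_life_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the estimate, its SE, the censoring flag
#'   and bound, the method, and any codon/lesion/context metadata.
#' @exportS3Method generics::tidy
tidy.half_life_fit <- function(x, ...) {
  tibble::tibble(
    codon = x$codon, lesion = x$lesion, cell_context = x$cell_context,
    hotspot = x$hotspot, t_half = x$t_half, se = x$se,
    censored = x$censored, bound = x$bound, method = x$method
  )
}

#' Tidy a Langmuir binding fit
#'
#' @param x A `langmuir_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`ka`, `kd`, `KD`, `Rmax`).
#' @exportS3Method generics::tidy
tidy.langmuir_fit <- function(x, ...) {
  tibble::tibble(
    term = c("ka", "kd", "KD", "Rmax"),
    estimate = c(x$ka, x$kd, x$KD, x$Rmax),
    std.error = c(x$se[["ka"]], x$se[["kd"]], NA_real_, x$se[["Rmax"]])
  )
}

#' @rdname tidy.langmuir_fit
#' @exportS3Method generics::glance
glance.langmuir_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n = x$n, converged = x$converged,
                 confounded = x$confounded)
}

#' Plot an active-site titration
#'
#' Burst amplitude against total enzyme with the through-origin regression
#' whose slope is the active fraction.
#'
#' @param object A `titration_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.titration_fit <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$enzyme_total, y = .data$A0_hat)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$active_fraction, intercept = 0,
                         linetype = "dashed") +
    ggplot2::labs(
      x = "[enzyme] total (nM)", y = "burst amplitude A0 (nM)",
      title = sprintf("Active fraction %.1f%%", 100 * object$active_fraction))
}
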