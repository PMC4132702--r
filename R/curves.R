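#' Construct a progress-curve tibble
#'
#' A progress curve records product formation ([P], nM) over time (minutes)
#' for one glycosylase excision reaction, either single turnover (STO,
#' enzyme >> substrate) or multiple turnover / burst (MTO, substrate >>
#' enzyme). The enzyme and substrate totals travel as attributes so that
#' fitters can bound the burst amplitude.
#'
#' @param times Time points, minutes, non-negative and strictly increasing.
#' @param product Product concentrations, nM, same length as `times`.
#' @param label Free-text label (e.g. `"246eA"`).
#' @param replicate Integer replicate index.
#' @param regime `"STO"` or `"MTO"`.
#' @param enzyme_total,substrate_total Totals in nM (NA if unknown).
#'
#' @return A tibble of class `progress_curve` with columns
#'   `label`, `replicate`, `regime`, `time`, `product`.
#' @export
progress_curve <- function(times, product, label = "curve", replicate = 1L,
                           regime = c("STO", "MTO"),
                           enzyme_total = NA_real_, substrate_total = NA_real_) {
  regime <- match.arg(regime)
  stopifnot(length(times) == length(product))
  if (any(!is.finite(times)) || any(times < 0)) {
    rlang::abort("`times` must be finite and non-negative")
  }
  if (any(diff(times) <= 0)) rlang::abort("`times` must be strictly increasing")
  if (any(product < -1e-9)) rlang::abort("`product` must be non-negative")
  out <- tibble::tibble(
    label = label, replicate = as.integer(replicate), regime = regime,
    time = as.numeric(times), product = pmax(as.numeric(product), 0)
  )
  attr(out, "enzyme_total") <- enzyme_total
  attr(out, "substrate_total") <- substrate_total
  class(out) <- c("progress_curve", class(out))
  out
}

enzyme_total_of <- function(curve) {
  et <- attr(curve, "enzyme_total")
  if (is.null(et)) NA_real_ else et
}

#' Plot a progress curve
#'
#' @param object A `progress_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.progress_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$product)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(
      x = "time (min)", y = "[product] (nM)",
      title = unique(object$label),
      subtitle = paste0(unique(object$regime), " regime")
    )
}
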