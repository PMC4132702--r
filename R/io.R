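#' Write progress curves as long-format CSV
#'
#' Columns `label`, `replicate`, `regime`, `time`, `value`; measurement
#' units go to a JSON sidecar (`<path>.units.json`).
#'
#' @param curves A [progress_curve()] or list of them.
#' @param path Output CSV path.
#' @param units Named list of units written to the sidecar.
#' @return `path`, invisibly.
#' @export
write_curves_csv <- function(curves, path,
                             units = list(time = "min", value = "nM")) {
  if (is.data.frame(curves)) curves <- list(curves)
  long <- purrr::map_dfr(curves, function(cv) {
    tibble::tibble(label = cv$label, replicate = cv$replicate,
                   regime = cv$regime, time = cv$time, value = cv$product,
                   enzyme_total = enzyme_total_of(cv))
  })
  utils::write.csv(long, path, row.names = FALSE)
  jsonlite::write_json(units, paste0(path, ".units.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read long-format progress curves from CSV
#'
#' Inverse of [write_curves_csv()]: splits on `label` + `replicate` and
#' rebuilds one [progress_curve()] per trace.
#'
#' @param path CSV path with columns `label`, `replicate`, `regime`,
#'   `time`, `value` and optionally `enzyme_total`.
#' @return A named list of [progress_curve()] objects.
#' @export
read_curves_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "replicate", "regime", "time", "value")
  if (!all(need %in% names(df))) {
    rlang::abort(paste0("curve CSV must have columns: ",
                        paste(need, collapse = ", ")))
  }
  df <- dplyr::arrange(df, .data$label, .data$replicate, .data$time)
  groups <- split(df, interaction(df$label, df$replicate, drop = TRUE))
  out <- purrr::map(groups, function(g) {
    progress_curve(g$time, g$value, label = g$label[1],
                   replicate = g$replicate[1], regime = g$regime[1],
                   enzyme_total = if ("enzyme_total" %in% names(g))
                     g$enzyme_total[1] else NA_real_)
  })
  stats::setNames(out, purrr::map_chr(out, ~ paste0(.x$label[1], ".", .x$replicate[1])))
}
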