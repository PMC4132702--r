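#' Read and validate a pipeline run configuration
#'
#' YAML configuration with a closed schema: unknown keys are rejected
#' before any computation. Defaults give a noise-free simulated run over
#' the packaged fixture catalog.
#'
#' @param config Path to a YAML file, or a named list.
#' @return A validated config list of class `run_config`.
#' @export
#' @examples
#' read_run_config(list(mode = "simulate", seed = 1))
read_run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  allowed <- c("mode", "seed", "outdir", "noise", "thalf_method",
               "lesions", "cell_contexts", "input_curves", "format")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    rlang::abort(paste0("unknown config key(s): ",
                        paste(unknown, collapse = ", "),
                        "; allowed: ", paste(allowed, collapse = ", ")))
  }
  cfg <- list(
    mode = config$mode %||% "simulate",
    seed = as.integer(config$seed %||% 1L),
    outdir = config$outdir,
    noise = config$noise %||% list(cv = 0, floor_sd = 0),
    thalf_method = config$thalf_method %||% "exponential_fit",
    lesions = config$lesions %||% c("eA", "Hx"),
    cell_contexts = config$cell_contexts %||% c("HepG2", "HUVEC"),
    input_curves = config$input_curves,
    format = config$format %||% "csv"
  )
  if (!cfg$mode %in% c("simulate", "analyze")) {
    rlang::abort("`mode` must be 'simulate' or 'analyze'")
  }
  if (!cfg$thalf_method %in% c("exponential_fit", "linear_interpolation")) {
    rlang::abort("`thalf_method` must be 'exponential_fit' or 'linear_interpolation'")
  }
  noise_keys <- setdiff(names(cfg$noise), c("cv", "floor_sd"))
  if (length(noise_keys)) {
    rlang::abort(paste0("unknown noise key(s): ", paste(noise_keys, collapse = ", ")))
  }
  if (cfg$mode == "analyze" && is.null(cfg$input_curves)) {
    rlang::abort("`input_curves` (CSV path) is required in analyze mode")
  }
  structure(cfg, class = "run_config")
}

#' Run the full simulate-fit-compare pipeline
#'
#' In `simulate` mode: generates burst curves, titration series, in-cell
#' repair time courses and mixing standards from the packaged fixture
#' catalog (with the configured noise and seed), fits every stage, and
#' assembles report tables shaped like the published per-codon summaries.
#' In `analyze` mode: reads user progress curves from CSV and fits the
#' burst equation per trace.
#'
#' @param config A path, list, or [read_run_config()] result.
#' @return An object of class `run_report`: tibbles `enzymology` (per
#'   codon x lesion burst-fit parameters and recovered `k_pd`),
#'   `titration`, `incell` (per codon half-lives), `group_comparisons`,
#'   `fold_changes`, `mixing`, and a `provenance` list. When
#'   `config$outdir` is set, tables are written there as CSV plus a JSON
#'   summary.
#' @export
#' @examples
#' report <- run_pipeline(list(mode = "simulate", seed = 1))
#' report$enzymology
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  fx <- mpg_fixtures()
  noisy <- (cfg$noise$cv %||% 0) > 0 || (cfg$noise$floor_sd %||% 0) > 0
  mknoise <- function(offset) {
    if (!noisy) noise_off() else
      noise_spec(cfg$noise$cv %||% 0, cfg$noise$floor_sd %||% 0,
                 cfg$seed + offset)
  }

  if (cfg$mode == "analyze") {
    curves <- read_curves_csv(cfg$input_curves)
    enz <- purrr::imap_dfr(curves, function(cv, nm) {
      f <- fit_burst(cv)
      tibble::tibble(label = nm, A0 = coef_of(f, "A0"),
                     k_obs = coef_of(f, "k_obs"), k_ss = coef_of(f, "k_ss"),
                     k_pd = coef_of(f, "k_pd"), rss = f$rss,
                     converged = f$converged, degenerate = f$degenerate)
    })
    report <- structure(list(
      enzymology = enz, titration = NULL, incell = NULL,
      group_comparisons = NULL, fold_changes = NULL, mixing = NULL,
      provenance = provenance_of(cfg)), class = "run_report")
    return(write_report(report, cfg))
  }

  times_min <- seq(0, 10, 0.25)

  # --- enzymology: one burst curve per codon x lesion -----------------
  mech <- dplyr::filter(fx$mechanism, .data$lesion %in% cfg$lesions)
  enz <- purrr::pmap_dfr(mech, function(...) {
    row <- list(...)
    A0 <- row$active_fraction * fx$burst_enzyme_total
    curve <- generate_mto_curve(
      A0 = A0, k_obs = row$k_obs, k_ss = row$k_pd * A0, times = times_min,
      noise = mknoise(match(row$label, mech$label)), label = row$label,
      enzyme_total = fx$burst_enzyme_total,
      substrate_total = fx$burst_substrate_total)
    f <- fit_burst(curve)
    tibble::tibble(
      label = row$label, lesion = row$lesion, codon = row$codon,
      hotspot = row$hotspot, true_k_pd = row$k_pd,
      A0 = coef_of(f, "A0"), k_obs = coef_of(f, "k_obs"),
      k_ss = coef_of(f, "k_ss"), k_pd = coef_of(f, "k_pd"),
      rss = f$rss, converged = f$converged)
  })

  # --- active-site titration per preparation --------------------------
  concs <- attr(fx$titration, "enzyme_concs")
  titr <- purrr::pmap_dfr(
    dplyr::filter(fx$titration, .data$preparation %in% cfg$lesions),
    function(preparation, active_fraction, provenance) {
      kpd <- enz$true_k_pd[enz$lesion == preparation & enz$codon == "246"][1]
      series <- generate_titration_series(
        concs, active_fraction, k_obs = 1.2, k_pd = kpd, times = times_min,
        noise = mknoise(100 + match(preparation, fx$titration$preparation)),
        substrate_total = fx$burst_substrate_total)
      ttn <- active_site_titration(series, concs)
      tibble::tibble(preparation = preparation,
                     true_active_fraction = active_fraction,
                     active_fraction = ttn$active_fraction,
                     se = ttn$se, r.squared = ttn$r.squared)
    })

  # --- in-cell repair half-lives --------------------------------------
  times_h <- c(0, 5, 16, 24, 48)
  rep_fx <- dplyr::filter(
    fx$repair,
    (.data$cell_context %in% cfg$cell_contexts & .data$lesion == "eA") |
      (.data$lesion == "AP" & "HepG2" %in% cfg$cell_contexts))
  incell <- purrr::pmap_dfr(rep_fx, function(...) {
    row <- list(...)
    tc <- generate_repair_timecourse(
      row$t_half, times_h,
      noise = mknoise(200 + match(paste(row$cell_context, row$lesion, row$codon),
                                  paste(rep_fx$cell_context, rep_fx$lesion,
                                        rep_fx$codon))),
      codon = row$codon, lesion = row$lesion,
      cell_context = row$cell_context, hotspot = row$hotspot)
    generics::tidy(estimate_half_life(tc, cfg$thalf_method)) |>
      dplyr::mutate(true_t_half = row$t_half)
  })

  # --- group comparisons and fold ranges ------------------------------
  cmp_one <- function(df, label) {
    ok <- !df$hotspot
    dplyr::mutate(compare_groups(df$value[ok], df$value[!ok],
                                 labels = c("non-hotspot", "hotspot")),
                  comparison = label, .before = 1)
  }
  comparisons <- dplyr::bind_rows(
    purrr::map(cfg$lesions, function(les) {
      d <- dplyr::filter(enz, .data$lesion == les)
      cmp_one(dplyr::transmute(d, hotspot = .data$hotspot, value = .data$k_pd),
              paste0("k_pd_", les))
    }),
    purrr::map(unique(rep_fx$cell_context[rep_fx$lesion == "eA"]), function(ctx) {
      d <- dplyr::filter(incell, .data$cell_context == ctx, .data$lesion == "eA",
                         !.data$censored)
      cmp_one(dplyr::transmute(d, hotspot = .data$hotspot, value = .data$t_half),
              paste0("t_half_", ctx))
    })
  )
  folds <- purrr::map_dfr(cfg$lesions, function(les) {
    d <- dplyr::filter(enz, .data$lesion == les)
    dplyr::mutate(fold_change(max(d$k_pd[!d$hotspot]), min(d$k_pd[d$hotspot])),
                  comparison = paste0("k_pd_", les, "_max_over_min"), .before = 1)
  })

  ap <- dplyr::filter(incell, .data$lesion == "AP")
  ap_medians <- if (nrow(ap)) median_by_group(ap) else NULL

  # --- mixing linearity per codon -------------------------------------
  mixing <- purrr::map_dfr(unique(fx$mechanism$codon), function(cod) {
    std <- generate_mixing_standards(
      fx$mixing_fractions,
      noise = if (!noisy) noise_off() else
        mknoise(300 + match(cod, unique(fx$mechanism$codon))))
    dplyr::mutate(mixing_linearity(std), codon = cod, .before = 1)
  })

  report <- structure(list(
    enzymology = enz, titration = titr, incell = incell,
    ap_medians = ap_medians, group_comparisons = comparisons,
    fold_changes = folds, mixing = mixing,
    provenance = provenance_of(cfg)), class = "run_report")
  write_report(report, cfg)
}

provenance_of <- function(cfg) {
  plain <- unclass(cfg)
  plain$outdir <- NULL
  list(seed = cfg$seed,
       config_hash = rlang::hash(plain),
       package_version = as.character(utils::packageVersion("mpgrepair")))
}

write_report <- function(report, cfg) {
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(report)) {
      if (is.data.frame(report[[nm]])) {
        utils::write.csv(report[[nm]],
                         file.path(cfg$outdir, paste0(nm, ".csv")),
                         row.names = FALSE)
      }
    }
    jsonlite::write_json(
      c(report$provenance, list(tables = names(Filter(is.data.frame, report)))),
      file.path(cfg$outdir, "run_summary.json"),
      auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed", x$provenance$seed, "\n")
  for (nm in names(x)) {
    if (is.data.frame(x[[nm]])) cat("  $", nm, ": ", nrow(x[[nm]]), " rows\n", sep = "")
  }
  invisible(x)
}

#' Flatten a run report into named quantities
#'
#' @param report A [run_pipeline()] result.
#' @return A named numeric vector (e.g. `kpd_eA_246`,
#'   `active_fraction_pct_eA`, `thalf_HepG2_246`,
#'   `ap_median_nonhotspot`, `fold_eA_max_over_min`, `mixing_r2_min`).
#' @export
report_values <- function(report) {
  stopifnot(inherits(report, "run_report"))
  out <- c()
  if (!is.null(report$enzymology) && "codon" %in% names(report$enzymology)) {
    e <- report$enzymology
    out <- c(out, stats::setNames(e$k_pd, paste0("kpd_", e$lesion, "_", e$codon)))
  }
  if (!is.null(report$titration)) {
    t <- report$titration
    out <- c(out, stats::setNames(100 * t$active_fraction,
                                  paste0("active_fraction_pct_", t$preparation)))
  }
  if (!is.null(report$incell)) {
    i <- dplyr::filter(report$incell, .data$lesion == "eA", !.data$censored)
    out <- c(out, stats::setNames(i$t_half,
                                  paste0("thalf_", i$cell_context, "_", i$codon)))
  }
  if (!is.null(report$ap_medians)) {
    m <- report$ap_medians
    out <- c(out, stats::setNames(
      m$median_t_half,
      paste0("ap_median_", ifelse(m$hotspot, "hotspot", "nonhotspot"))))
  }
  if (!is.null(report$fold_changes)) {
    f <- report$fold_changes
    out <- c(out, stats::setNames(f$ratio, paste0(
      "fold_", sub("^k_pd_", "", sub("_max_over_min$", "", f$comparison)),
      "_max_over_min")))
  }
  if (!is.null(report$mixing)) {
    out <- c(out, mixing_r2_min = min(report$mixing$r.squared))
  }
  out
}

#' Validate a run report against expectations
#'
#' Checks each expected quantity against the report at its tolerance and
#' returns a machine-readable verdict table.
#'
#' @param report A [run_pipeline()] result.
#' @param expectations A tibble with columns `quantity` (a
#'   [report_values()] name), `expected`, and either `tol_rel` (relative)
#'   or `tol_abs` (absolute); defaults via [fixture_expectations()].
#' @return A tibble with one row per expectation: `quantity`, `expected`,
#'   `value`, `pass`, `reason`.
#' @export
#' @examples
#' report <- run_pipeline(list(mode = "simulate", seed = 1))
#' validate_report(report)
validate_report <- function(report, expectations = fixture_expectations()) {
  stopifnot(inherits(report, "run_report"), is.data.frame(expectations))
  vals <- report_values(report)
  purrr::pmap_dfr(expectations, function(quantity, expected, tol_rel = NA,
                                         tol_abs = NA, ...) {
    if (!quantity %in% names(vals)) {
      return(tibble::tibble(quantity = quantity, expected = expected,
                            value = NA_real_, pass = FALSE,
                            reason = "missing from report"))
    }
    v <- unname(vals[[quantity]])
    ok <- if (!is.na(tol_abs)) abs(v - expected) <= tol_abs else
      abs(v - expected) <= (tol_rel %|NA|% 1e-4) * abs(expected)
    tibble::tibble(quantity = quantity, expected = expected, value = v,
                   pass = ok, reason = if (ok) "ok" else "outside tolerance")
  })
}

`%|NA|%` <- function(x, y) if (is.na(x)) y else x

#' Default expectations for a noise-free fixture run
#'
#' The packaged ground-truth values every parameter-recovery run should
#' reproduce (relative tolerance 1e-4 unless stated).
#'
#' @return A tibble usable as `expectations` in [validate_report()].
#' @export
fixture_expectations <- function() {
  fx <- mpg_fixtures()
  mech <- fx$mechanism
  rep_ea <- dplyr::filter(fx$repair, .data$lesion == "eA",
                          .data$cell_context %in% c("HepG2", "HUVEC"))
  dplyr::bind_rows(
    tibble::tibble(quantity = paste0("kpd_", mech$lesion, "_", mech$codon),
                   expected = mech$k_pd, tol_rel = 1e-4),
    tibble::tibble(quantity = paste0("active_fraction_pct_", fx$titration$preparation),
                   expected = 100 * fx$titration$active_fraction,
                   tol_abs = 0.5),
    tibble::tibble(quantity = paste0("thalf_", rep_ea$cell_context, "_", rep_ea$codon),
                   expected = rep_ea$t_half, tol_rel = 1e-3),
    tibble::tibble(quantity = c("ap_median_nonhotspot", "ap_median_hotspot"),
                   expected = c(1.5, 1.3), tol_rel = 1e-3),
    tibble::tibble(quantity = c("fold_eA_max_over_min", "fold_Hx_max_over_min"),
                   expected = c(12, 26), tol_rel = 1e-3)
  )
}
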