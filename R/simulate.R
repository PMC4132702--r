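#' Single-turnover progress curve from the closed form
#'
#' Evaluates the single-turnover (STO) equation
#' `[P] = A0 (1 - exp(-k_obs t))` and adds seeded noise. In the STO regime
#' (enzyme in large excess over substrate) `k_obs` approximates `k_chem`,
#' the glycosidic-bond cleavage rate.
#'
#' @param A0 Exponential amplitude, nM (>= 0).
#' @param k_obs Observed rate constant, min^-1 (>= 0).
#' @param times Time points, minutes.
#' @param noise A [noise_spec()].
#' @param label,replicate Curve metadata.
#' @param enzyme_total,substrate_total Optional totals (nM) stored as
#'   attributes; `substrate_total` also caps the noisy signal.
#' @return A [progress_curve()] with `regime = "STO"`.
#' @export
#' @examples
#' generate_sto_curve(A0 = 1, k_obs = 0.5, times = seq(0, 10, 0.5))
generate_sto_curve <- function(A0, k_obs, times, noise = noise_off(),
                               label = "STO", replicate = 1L,
                               enzyme_total = NA_real_,
                               substrate_total = NA_real_) {
  check_nonneg(A0 = A0, k_obs = k_obs)
  y <- A0 * (1 - exp(-k_obs * times))
  y <- apply_noise(y, noise, lower = 0,
                   upper = if (is.na(substrate_total)) Inf else substrate_total)
  progress_curve(times, y, label = label, replicate = replicate, regime = "STO",
                 enzyme_total = enzyme_total, substrate_total = substrate_total)
}

#' Multiple-turnover (burst) progress curve from the closed form
#'
#' Evaluates the burst equation `[P] = A0 (1 - exp(-k_obs t)) + k_ss t`:
#' an exponential burst whose amplitude `A0` estimates the active enzyme
#' concentration, followed by a linear steady-state phase of slope `k_ss`.
#' The product-dissociation (turnover) rate is `k_pd = k_ss / A0`.
#'
#' @inheritParams generate_sto_curve
#' @param k_ss Steady-state slope, nM min^-1 (>= 0).
#' @return A [progress_curve()] with `regime = "MTO"`.
#' @export
generate_mto_curve <- function(A0, k_obs, k_ss, times, noise = noise_off(),
                               label = "MTO", replicate = 1L,
                               enzyme_total = NA_real_,
                               substrate_total = NA_real_) {
  check_nonneg(A0 = A0, k_obs = k_obs, k_ss = k_ss)
  y <- A0 * (1 - exp(-k_obs * times)) + k_ss * times
  y <- apply_noise(y, noise, lower = 0,
                   upper = if (is.na(substrate_total)) Inf else substrate_total)
  progress_curve(times, y, label = label, replicate = replicate, regime = "MTO",
                 enzyme_total = enzyme_total, substrate_total = substrate_total)
}

#' Active-site titration series
#'
#' Generates one burst curve per enzyme concentration `E`, with burst
#' amplitude `A0 = active_fraction * E` and steady-state slope
#' `k_ss = k_pd * A0` — the design used to titrate the active fraction of an
#' enzyme preparation from the concentration dependence of the burst
#' amplitude.
#'
#' @param enzyme_concs Total enzyme concentrations, nM (positive).
#' @param active_fraction Fraction of enzyme competent for burst chemistry,
#'   in `[0, 1]`.
#' @param k_obs Burst rate constant, min^-1.
#' @param k_pd Product-dissociation rate, min^-1.
#' @param times Time points, minutes.
#' @param noise A [noise_spec()]; each curve gets an offset seed.
#' @param substrate_total Substrate, nM (default 75).
#' @return A list of [progress_curve()] objects, one per concentration.
#' @export
generate_titration_series <- function(enzyme_concs, active_fraction, k_obs,
                                      k_pd, times, noise = noise_off(),
                                      substrate_total = 75) {
  if (length(enzyme_concs) == 0 || any(enzyme_concs <= 0)) {
    rlang::abort("`enzyme_concs` must be non-empty and positive")
  }
  stopifnot(active_fraction >= 0, active_fraction <= 1)
  check_nonneg(k_obs = k_obs, k_pd = k_pd)
  purrr::imap(as.list(enzyme_concs), function(E, i) {
    A0 <- active_fraction * E
    noise_i <- if (is_noise_off(noise)) noise else
      noise_spec(noise$cv, noise$floor_sd, noise$seed + i)
    generate_mto_curve(
      A0 = A0, k_obs = k_obs, k_ss = k_pd * A0, times = times, noise = noise_i,
      label = paste0("E", E, "nM"), enzyme_total = E,
      substrate_total = substrate_total
    )
  })
}

#' In-cell repair time course
#'
#' Percent repair versus time follows a single-exponential approach to a
#' plateau, `percent(t) = plateau (1 - exp(-ln(2) t / t_half))`, so that
#' `t_half` is the time at which half the plateau is reached. `t_half = Inf`
#' encodes no detectable repair (the Mpg-null condition) and yields an
#' all-zero trace.
#'
#' @param t_half Repair half-life, hours (> 0, or `Inf` for no repair).
#' @param times Time points, hours, including 0.
#' @param plateau Plateau percent repair (default 100).
#' @param noise A [noise_spec()].
#' @param codon,lesion,cell_context,hotspot Metadata columns.
#' @return A tibble of class `repair_timecourse` with columns `codon`,
#'   `lesion`, `cell_context`, `hotspot`, `time`, `percent_repair`.
#' @export
#' @examples
#' generate_repair_timecourse(3, times = c(0, 5, 16, 24, 48))
generate_repair_timecourse <- function(t_half, times, plateau = 100,
                                       noise = noise_off(), codon = "246",
                                       lesion = "eA", cell_context = "HepG2",
                                       hotspot = FALSE) {
  if (!is.infinite(t_half) && t_half <= 0) {
    rlang::abort("`t_half` must be positive (or Inf for no repair)")
  }
  stopifnot(plateau > 0, plateau <= 100)
  if (!0 %in% times) rlang::abort("`times` must include 0 h")
  y <- if (is.infinite(t_half)) rep(0, length(times)) else
    plateau * (1 - exp(-log(2) * times / t_half))
  y <- apply_noise(y, noise, lower = 0, upper = 100)
  out <- tibble::tibble(
    codon = codon, lesion = lesion, cell_context = cell_context,
    hotspot = hotspot, time = as.numeric(times), percent_repair = y
  )
  class(out) <- c("repair_timecourse", class(out))
  out
}

#' qPCR Ct table for a known repair fraction
#'
#' Inverse of [percent_repair_from_ct()]: under the amplification-blocking
#' model (an unrepaired lesion is converted to a nick, which blocks
#' amplification) a repaired fraction `f` of template shifts the cycle
#' threshold by `-log(f)/log(efficiency)` relative to a fully amplifiable
#' reference.
#'
#' @param true_repair_fraction Repaired fractions in `(0, 1]` (0 is
#'   undefined — no amplifiable template; represent as censored upstream).
#' @param ct_full_repair Reference Ct (fully repaired template), cycles.
#' @param efficiency Amplification base per cycle, in `(1, 2]`.
#' @param noise A [noise_spec()] applied additively to Ct (use `floor_sd`
#'   in cycles; `cv` is proportional to Ct).
#' @return A tibble of class `ct_table` with columns `sample_id`,
#'   `ct_sample`, `ct_full_repair`, `efficiency`.
#' @export
generate_ct_table <- function(true_repair_fraction, ct_full_repair = 20,
                              efficiency = 2, noise = noise_off()) {
  if (any(true_repair_fraction <= 0) || any(true_repair_fraction > 1)) {
    rlang::abort("`true_repair_fraction` must lie in (0, 1]; 0 has no defined Ct")
  }
  check_efficiency(efficiency)
  stopifnot(ct_full_repair > 0, is.finite(ct_full_repair))
  ct <- ct_full_repair - log(true_repair_fraction) / log(efficiency)
  ct <- apply_noise(ct, noise, lower = 0)
  out <- tibble::tibble(
    sample_id = paste0("s", seq_along(ct)),
    ct_sample = ct, ct_full_repair = ct_full_repair, efficiency = efficiency
  )
  class(out) <- c("ct_table", class(out))
  out
}

#' Mixing standards for assay-linearity validation
#'
#' Emulates defined blends of damaged and undamaged plasmid spanning
#' 0–100% repaired-equivalent, assayed for percent repair: observed =
#' expected plus seeded noise, clamped to `[0, 100]`.
#'
#' @param fractions Expected percents, default `c(0,10,30,50,70,90,100)`.
#' @param noise A [noise_spec()].
#' @return A tibble with columns `expected_percent`, `observed_percent`.
#' @export
generate_mixing_standards <- function(fractions = c(0, 10, 30, 50, 70, 90, 100),
                                      noise = noise_off()) {
  if (any(fractions < 0) || any(fractions > 100)) {
    rlang::abort("`fractions` must lie within [0, 100]")
  }
  tibble::tibble(
    expected_percent = as.numeric(fractions),
    observed_percent = apply_noise(as.numeric(fractions), noise,
                                   lower = 0, upper = 100)
  )
}

#' Concentration-series SPR sensorgrams under the 1:1 Langmuir model
#'
#' For analyte concentration `C`, the association phase follows
#' `R(t) = Req (1 - exp(-(ka C + kd) t))` with
#' `Req = Rmax ka C / (ka C + kd)`, and the dissociation phase decays from
#' the association end point as `R(t) = R_end exp(-kd (t - t_assoc))`.
#'
#' @param ka Association rate, nM^-1 s^-1 (>= 0).
#' @param kd Dissociation rate, s^-1 (>= 0).
#' @param Rmax Saturating response, RU.
#' @param concs Analyte concentrations, nM (>= 0).
#' @param t_assoc,t_dissoc Phase durations, seconds.
#' @param dt Sampling interval, seconds.
#' @param noise A [noise_spec()]; each concentration gets an offset seed.
#' @return A tibble of class `sensorgram_set` with columns `analyte_conc`,
#'   `phase` (`"association"`/`"dissociation"`), `time` (s, from injection
#'   start), `response` (RU); attribute `t_assoc` marks the phase boundary.
#' @export
generate_sensorgram_set <- function(ka, kd, Rmax, concs, t_assoc = 120,
                                    t_dissoc = 120, dt = 1,
                                    noise = noise_off()) {
  check_nonneg(ka = ka, kd = kd, Rmax = Rmax)
  if (any(concs < 0)) rlang::abort("`concs` must be non-negative")
  out <- purrr::imap_dfr(as.list(concs), function(C, i) {
    ta <- seq(0, t_assoc, by = dt)
    td <- seq(dt, t_dissoc, by = dt) + t_assoc
    denom <- ka * C + kd
    Req <- if (denom == 0) 0 else Rmax * ka * C / denom
    Ra <- Req * (1 - exp(-denom * ta))
    Rend <- Req * (1 - exp(-denom * t_assoc))
    Rd <- Rend * exp(-kd * (td - t_assoc))
    noise_i <- if (is_noise_off(noise)) noise else
      noise_spec(noise$cv, noise$floor_sd, noise$seed + i)
    tibble::tibble(
      analyte_conc = C,
      phase = c(rep("association", length(ta)), rep("dissociation", length(td))),
      time = c(ta, td),
      response = apply_noise(c(Ra, Rd), noise_i, lower = -Inf)
    )
  })
  attr(out, "t_assoc") <- t_assoc
  class(out) <- c("sensorgram_set", class(out))
  out
}

check_nonneg <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0) {
      rlang::abort(sprintf("`%s` must be a single finite non-negative number", nm))
    }
  }
  invisible(TRUE)
}

check_efficiency <- function(efficiency) {
  if (any(efficiency <= 1) || any(efficiency > 2)) {
    rlang::abort("`efficiency` must lie in (1, 2]")
  }
  invisible(TRUE)
}
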