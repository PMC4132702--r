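#' Global 1:1 Langmuir fit to a sensorgram concentration series
#'
#' Nonlinear least squares across all analyte concentrations with shared
#' `ka`, `kd`, `Rmax`: association
#' `R(t) = Req (1 - exp(-(ka C + kd) t))`, `Req = Rmax ka C / (ka C + kd)`;
#' dissociation decays from the association end point at `kd`. The
#' equilibrium dissociation constant is reported as `KD = kd / ka`.
#'
#' @param set A [generate_sensorgram_set()] tibble (columns `analyte_conc`,
#'   `phase`, `time`, `response`; attribute `t_assoc`). At least two
#'   nonzero concentrations are required for an unconfounded fit; with one,
#'   the result is flagged `confounded` but still reported.
#' @param t_assoc Association end time (s); taken from the attribute when
#'   omitted.
#' @return An object of class `langmuir_fit`: `ka` (nM^-1 s^-1), `kd`
#'   (s^-1), `KD` (nM), `Rmax` (RU), standard errors, RSS, convergence and
#'   confounding flags.
#' @export
#' @examples
#' set <- generate_sensorgram_set(ka = 1e-3, kd = 1e-3, Rmax = 100,
#'                                concs = c(5, 10, 20, 40))
#' fit_langmuir(set)
fit_langmuir <- function(set, t_assoc = NULL) {
  stopifnot(is.data.frame(set),
            all(c("analyte_conc", "phase", "time", "response") %in% names(set)))
  t_assoc <- t_assoc %||% attr(set, "t_assoc")
  if (is.null(t_assoc)) rlang::abort("association end time (`t_assoc`) unknown")
  set <- dplyr::filter(set, .data$analyte_conc > 0)
  concs <- unique(set$analyte_conc)
  if (length(concs) < 1) rlang::abort("need at least one nonzero concentration")
  confounded <- length(concs) < 2
  if (confounded) {
    rlang::warn("single analyte concentration: ka and Rmax are confounded")
  }

  model <- function(par, data) {
    ka <- par[1]; kd <- par[2]; Rmax <- par[3]
    denom <- ka * data$analyte_conc + kd
    Req <- ifelse(denom > 0, Rmax * ka * data$analyte_conc / denom, 0)
    Rend <- Req * (1 - exp(-denom * t_assoc))
    ifelse(data$phase == "association",
           Req * (1 - exp(-denom * data$time)),
           Rend * exp(-kd * (data$time - t_assoc)))
  }
  # starting values: kd from the tail decay, Rmax from the largest response
  Rmax0 <- max(set$response) * 1.2
  kd0 <- 1e-3
  ka0 <- kd0 / max(stats::median(concs), 1e-6)
  res_fn <- function(par) set$response - model(par, set)
  fit <- minpack.lm::nls.lm(
    par = c(ka = ka0, kd = kd0, Rmax = Rmax0), fn = res_fn,
    lower = c(0, 0, 0),
    control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                         maxiter = 1000))
  par <- fit$par
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA_real_, 3))
  structure(list(
    ka = unname(par["ka"]), kd = unname(par["kd"]),
    KD = unname(par["kd"] / par["ka"]), Rmax = unname(par["Rmax"]),
    se = stats::setNames(se, c("ka", "kd", "Rmax")),
    rss = sum(fit$fvec^2), n = nrow(set),
    converged = fit$info %in% 1:4, confounded = confounded,
    t_assoc = t_assoc
  ), class = "langmuir_fit")
}

#' @export
print.langmuir_fit <- function(x, ...) {
  cat("<langmuir_fit> ka = ", format(x$ka, digits = 4),
      " nM^-1 s^-1, kd = ", format(x$kd, digits = 4),
      " s^-1, KD = ", format(x$KD, digits = 4), " nM\n", sep = "")
  if (x$confounded) cat("  [ka/Rmax confounded: single concentration]\n")
  if (!x$converged) cat("  [did not converge]\n")
  invisible(x)
}

#' Observed-rate linearity diagnostic for the 1:1 model
#'
#' Fits each association phase to a mono-exponential to obtain the
#' per-concentration observed rate `kobs`, then regresses `kobs` on
#' concentration: under the 1:1 Langmuir model the slope is `ka` and the
#' intercept is `kd`. Serves as an independent check on the global fit.
#'
#' @inheritParams fit_langmuir
#' @return A one-row tibble: `ka` (slope), `kd` (intercept), `r.squared`,
#'   and the per-concentration `kobs` table as a list column.
#' @export
kobs_linearity <- function(set, t_assoc = NULL) {
  stopifnot(is.data.frame(set))
  t_assoc <- t_assoc %||% attr(set, "t_assoc")
  assoc <- dplyr::filter(set, .data$phase == "association",
                         .data$analyte_conc > 0)
  concs <- sort(unique(assoc$analyte_conc))
  if (length(concs) < 3) {
    rlang::abort("kobs linearity needs >= 3 nonzero concentrations")
  }
  kobs_tab <- purrr::map_dfr(concs, function(C) {
    d <- dplyr::filter(assoc, .data$analyte_conc == C)
    fit <- minpack.lm::nlsLM(
      response ~ Req * (1 - exp(-kobs * time)), data = d,
      start = list(Req = max(d$response), kobs = 0.01),
      lower = c(0, 0),
      control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                           maxiter = 500))
    tibble::tibble(analyte_conc = C, kobs = unname(stats::coef(fit)["kobs"]))
  })
  reg <- stats::lm(kobs ~ analyte_conc, data = kobs_tab)
  tibble::tibble(
    ka = unname(stats::coef(reg)[2]),
    kd = max(unname(stats::coef(reg)[1]), 0),
    r.squared = quiet_lm_summary(reg)$r.squared,
    kobs = list(kobs_tab)
  )
}

#' Plot a sensorgram set
#'
#' @param object A `sensorgram_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sensorgram_set <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time, y = .data$response,
                               colour = factor(.data$analyte_conc))) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "t_assoc"),
                        linetype = "dashed", alpha = 0.5) +
    ggplot2::labs(x = "time (s)", y = "response (RU)",
                  colour = "analyte (nM)")
}
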