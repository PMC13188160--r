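#' Fit the dermal decontamination model for a scenario
#'
#' One-call front door to the package: builds the eigenfunction expansion,
#' the closed-form steady-state partition, the per-pathway time constants,
#' the regime classification, and the decontamination-window report for a
#' scenario given either in dimensional form ([agent_scenario()]) or directly
#' as the dimensionless triplet `(Da, pi_surf, beta)`.
#'
#' @param scenario An [agent_scenario()] or [decon_scenario()].
#' @param n_terms Number of eigenfunction terms; default 400.
#' @return Object of class `"decon_model"` with components `scenario`,
#'   `timescale` (minutes conversion when a dimensional scenario was given,
#'   otherwise `NULL`), `eigen`, `steady`, `time_constants`, `regime`, and
#'   `window`.
#' @seealso [predict.decon_model()], [plot.decon_model()]
#' @examples
#' vx <- decon_model(agent_scenario("VX + RSDL", D_sc = 4.3e-10, h = 13.4,
#'                                  k_bulk = 2.1e-4))
#' vx
#' coef(vx)
#' @export
decon_model <- function(scenario, n_terms = 400) {
  timescale <- NULL
  if (inherits(scenario, "agent_scenario")) {
    gr <- dimensionless_groups(scenario)
    scn <- gr$scenario
    timescale <- gr$timescale
    label <- scenario$name
  } else {
    scn <- as_decon_scenario(scenario)
    label <- NULL
  }
  es <- build_eigensystem(scn, n_terms)
  structure(
    list(scenario = scn, label = label, timescale = timescale, eigen = es,
         steady = steady_fractions(scn),
         time_constants = effective_time_constants(es),
         regime = classify_regime(scn$Da),
         window = decontamination_window(scn, timescale, n_terms)),
    class = "decon_model")
}

#' @export
print.decon_model <- function(x, ...) {
  cat("Dermal decontamination model",
      if (!is.null(x$label)) paste0("- ", x$label), "\n")
  print(x$scenario)
  if (!is.null(x$timescale)) print(x$timescale)
  print(x$regime)
  cat(sprintf("Steady partition: M_abs = %.4f, M_surf = %.4f, M_reac = %.4f\n",
              x$steady$M_abs_inf, x$steady$M_surf_inf, x$steady$M_reac_inf))
  invisible(x)
}

#' @export
summary.decon_model <- function(object, ...) {
  structure(object, class = c("summary.decon_model", class(object)))
}

#' @export
print.summary.decon_model <- function(x, ...) {
  print.decon_model(x)
  cat("\n")
  print(x$time_constants)
  cat("\n")
  print(x$window)
  invisible(x)
}

#' @export
coef.decon_model <- function(object, ...) {
  c(Da = object$scenario$Da, pi_surf = object$scenario$pi_surf,
    beta = object$scenario$beta)
}

#' Evaluate transient mass fractions of a fitted model
#'
#' @param object A [decon_model()].
#' @param tau Dimensionless times (default grid of [transient_curves()]).
#' @param ... Unused.
#' @return A `"mass_curves"` data frame.
#' @export
predict.decon_model <- function(object, tau = NULL, ...) {
  transient_curves(object$eigen, tau)
}

#' Plot the transient mass-fraction curves of a fitted model
#'
#' @param x A [decon_model()].
#' @param ... Passed to [plot.mass_curves()].
#' @return `x`, invisibly.
#' @export
plot.decon_model <- function(x, ...) {
  plot(predict(x), ...)
  invisible(x)
}
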