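#' Parameter sweeps of time constants and steady fractions
#'
#' Convenience sweeps over the Damkohler number at several surface-loss
#' numbers, the parameterization used for the package's standard figures:
#' `pi_surf` in `{0.4, 0.8, 1.2, 1.6, 2.0}` and `Da` spanning `[0, 10]`.
#' `sweep_time_constants()` returns the first-moment effective time constant
#' of each pathway; `sweep_steady_fractions()` the asymptotic partition.
#'
#' @param da Numeric vector of Damkohler numbers. Defaults to 60 points on
#'   `[0.05, 10]` for time constants (all three pathways defined) and 60
#'   points on `[0, 10]` for steady fractions.
#' @param pi_surf Numeric vector of surface-loss numbers.
#' @param beta Deposit depth fraction.
#' @param n_terms Series length.
#' @return A long data frame: `Da`, `pi_surf`, then `tau_eff_abs`,
#'   `tau_eff_surf`, `tau_eff_reac` or `M_abs_inf`, `M_surf_inf`,
#'   `M_reac_inf`.
#' @examples
#' sw <- sweep_steady_fractions(da = c(0, 5, 10), pi_surf = c(0.4, 2))
#' @export
sweep_time_constants <- function(da = seq(0.05, 10, length.out = 60),
                                 pi_surf = c(0.4, 0.8, 1.2, 1.6, 2.0),
                                 beta = 0.1, n_terms = 400) {
  g <- expand.grid(Da = da, pi_surf = pi_surf, KEEP.OUT.ATTRS = FALSE)
  tc <- mapply(function(d, p) {
    v <- effective_time_constants(
      build_eigensystem(decon_scenario(d, p, beta), n_terms))
    c(v$tau_eff$abs, v$tau_eff$surf, v$tau_eff$reac)
  }, g$Da, g$pi_surf)
  g$tau_eff_abs <- tc[1, ]
  g$tau_eff_surf <- tc[2, ]
  g$tau_eff_reac <- tc[3, ]
  g
}

#' @rdname sweep_time_constants
#' @export
sweep_steady_fractions <- function(da = seq(0, 10, length.out = 60),
                                   pi_surf = c(0.4, 0.8, 1.2, 1.6, 2.0),
                                   beta = 0.1) {
  g <- expand.grid(Da = da, pi_surf = pi_surf, KEEP.OUT.ATTRS = FALSE)
  sf <- mapply(function(d, p) {
    v <- steady_fractions(decon_scenario(d, p, beta))
    c(v$M_abs_inf, v$M_surf_inf, v$M_reac_inf)
  }, g$Da, g$pi_surf)
  g$M_abs_inf <- sf[1, ]
  g$M_surf_inf <- sf[2, ]
  g$M_reac_inf <- sf[3, ]
  g
}
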