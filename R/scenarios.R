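#' Describe a dimensional agent/decontaminant exposure scenario
#'
#' Collects the dimensional physical properties of an agent-decontaminant
#' combination in the units customarily reported for stratum corneum
#' permeation work. These are the inputs from which the dimensionless groups
#' `Da` and `pi_surf` are computed by [dimensionless_groups()].
#'
#' @param name Text label for the scenario (e.g. `"VX + RSDL"`).
#' @param D_sc Diffusivity of the agent in the stratum corneum, cm^2/s.
#' @param h Stratum corneum thickness, micrometres.
#' @param k_bulk First-order bulk neutralization rate constant, 1/s.
#'   Zero means no reactive decontaminant in the tissue.
#' @param k_surf Interfacial-reaction mass-transfer velocity, cm/s.
#' @param k_evap Evaporation mass-transfer velocity, cm/s.
#' @param P_vap Vapor pressure, mmHg. Metadata only: no correlation from
#'   vapor pressure to an evaporation coefficient is implemented, so this
#'   value never enters a computation. Supply `k_evap` instead.
#' @param beta Fraction of the stratum corneum depth initially occupied by
#'   the deposit, in (0, 1]. Defaults to 0.1.
#'
#' @return An object of class `"agent_scenario"`.
#' @seealso [dimensionless_groups()], [read_scenario_json()]
#' @examples
#' vx <- agent_scenario("VX + RSDL", D_sc = 4.3e-10, h = 13.4,
#'                      k_bulk = 2.1e-4)
#' dimensionless_groups(vx)
#' @export
agent_scenario <- function(name = "scenario", D_sc, h, k_bulk = 0,
                           k_surf = 0, k_evap = 0, P_vap = NA_real_,
                           beta = 0.1) {
  check_num(D_sc, "D_sc", positive = TRUE)
  check_num(h, "h", positive = TRUE)
  check_num(k_bulk, "k_bulk")
  check_num(k_surf, "k_surf")
  check_num(k_evap, "k_evap")
  check_beta(beta)
  structure(
    list(name = as.character(name)[1], D_sc = D_sc, h = h, k_bulk = k_bulk,
         k_surf = k_surf, k_evap = k_evap, P_vap = P_vap, beta = beta),
    class = "agent_scenario")
}

#' @export
print.agent_scenario <- function(x, ...) {
  cat("Agent exposure scenario:", x$name, "\n")
  cat(sprintf("  D_sc   = %g cm^2/s (stratum corneum diffusivity)\n", x$D_sc))
  cat(sprintf("  h      = %g um (stratum corneum thickness)\n", x$h))
  cat(sprintf("  k_bulk = %g 1/s, k_surf = %g cm/s, k_evap = %g cm/s\n",
              x$k_bulk, x$k_surf, x$k_evap))
  if (!is.na(x$P_vap))
    cat(sprintf("  P_vap  = %g mmHg (metadata only)\n", x$P_vap))
  cat(sprintf("  beta   = %g (deposit depth fraction)\n", x$beta))
  invisible(x)
}

#' Construct a dimensionless scenario directly
#'
#' Builds the `(Da, pi_surf, beta)` triplet that drives every solution in the
#' package, when the dimensionless groups are known directly (as in parameter
#' sweeps) rather than derived from dimensional properties.
#'
#' @param Da Bulk Damkohler number `k_bulk * h^2 / D_sc`, >= 0. Ratio of the
#'   diffusion time scale to the bulk-reaction time scale.
#' @param pi_surf Surface-loss number, >= 0: combined evaporation and
#'   interfacial-reaction clearance relative to bulk diffusion. Acts as the
#'   Robin (radiation) coefficient at the exposed surface.
#' @param beta Initial deposit depth fraction in (0, 1]; default 0.1.
#' @param kappa_evap,Da_surf Optional split of `pi_surf` into its evaporation
#'   and surface-reaction parts. When both are given they must sum to
#'   `pi_surf`; the split is used by [baseline_pair()] to build the
#'   no-decontamination baseline.
#'
#' @return An object of class `"decon_scenario"`.
#' @examples
#' decon_scenario(Da = 10, pi_surf = 11.2)    # Tabun-volatility decon case
#' decon_scenario(Da = 0.88, pi_surf = 0.17)  # VX with RSDL
#' @export
decon_scenario <- function(Da, pi_surf, beta = 0.1,
                           kappa_evap = NULL, Da_surf = NULL) {
  check_num(Da, "Da")
  check_num(pi_surf, "pi_surf")
  check_beta(beta)
  if (!is.null(kappa_evap) || !is.null(Da_surf)) {
    if (is.null(kappa_evap) || is.null(Da_surf))
      stop("supply both `kappa_evap` and `Da_surf`, or neither", call. = FALSE)
    check_num(kappa_evap, "kappa_evap")
    check_num(Da_surf, "Da_surf")
    if (abs(kappa_evap + Da_surf - pi_surf) > 1e-9 * max(1, pi_surf))
      stop("kappa_evap + Da_surf must equal pi_surf", call. = FALSE)
  }
  structure(list(Da = Da, pi_surf = pi_surf, beta = beta,
                 kappa_evap = kappa_evap, Da_surf = Da_surf),
            class = "decon_scenario")
}

#' @export
print.decon_scenario <- function(x, ...) {
  cat(sprintf("Dimensionless scenario: Da = %g, pi_surf = %g, beta = %g\n",
              x$Da, x$pi_surf, x$beta))
  if (!is.null(x$kappa_evap) && x$pi_surf > 0)
    cat(sprintf("  pi_surf split: kappa_evap = %g + Da_surf = %g\n",
                x$kappa_evap, x$Da_surf))
  invisible(x)
}

#' Compute the dimensionless groups and diffusion time scale
#'
#' Reduces a dimensional [agent_scenario()] to the two dimensionless groups
#' governing the model: the bulk Damkohler number `Da = k_bulk h^2 / D_sc`
#' and the surface-loss number `pi_surf = kappa_evap + Da_surf` with
#' `kappa_evap = k_evap h / D_sc` and `Da_surf = k_surf h / D_sc`. The
#' characteristic diffusion time `t_diff = h^2 / D_sc` converts dimensionless
#' time tau to minutes.
#'
#' @param agent An [agent_scenario()].
#' @return A list with components `scenario` (a [decon_scenario()]) and
#'   `timescale` (class `"decon_timescale"`, with `t_diff` and `to_minutes`
#'   in minutes).
#' @examples
#' gr <- dimensionless_groups(
#'   agent_scenario("VX + RSDL", D_sc = 4.3e-10, h = 13.4, k_bulk = 2.1e-4))
#' gr$scenario$Da         # ~0.88: low-Da, diffusion-dominated
#' gr$timescale$t_diff    # ~69.6 min to breakthrough
#' @export
dimensionless_groups <- function(agent) {
  stopifnot(inherits(agent, "agent_scenario"))
  h_cm <- agent$h * 1e-4                    # um -> cm
  Da <- agent$k_bulk * h_cm^2 / agent$D_sc
  kappa_evap <- agent$k_evap * h_cm / agent$D_sc
  Da_surf <- agent$k_surf * h_cm / agent$D_sc
  scn <- decon_scenario(Da = Da, pi_surf = kappa_evap + Da_surf,
                        beta = agent$beta,
                        kappa_evap = kappa_evap, Da_surf = Da_surf)
  t_diff <- h_cm^2 / agent$D_sc / 60        # s -> min
  ts <- structure(list(t_diff = t_diff, to_minutes = t_diff),
                  class = "decon_timescale")
  list(scenario = scn, timescale = ts)
}

#' @export
print.decon_timescale <- function(x, ...) {
  cat(sprintf("Characteristic diffusion time h^2/D_sc = %.4g min\n", x$t_diff))
  invisible(x)
}

#' Read a scenario from a JSON file
#'
#' Scenario files are JSON objects with keys `name`, `D_sc_cm2_s`, `h_um`,
#' `k_bulk_per_s`, `k_surf_cm_s`, `k_evap_cm_s`, `P_vap_mmHg` (optional) and
#' `beta` (optional, default 0.1).
#'
#' @param path Path to the JSON file.
#' @return An [agent_scenario()].
#' @export
read_scenario_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("D_sc_cm2_s", "h_um")
  missing <- setdiff(required, names(j))
  if (length(missing))
    stop("scenario file is missing required key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  agent_scenario(
    name   = if (!is.null(j$name)) j$name else basename(path),
    D_sc   = as.numeric(j$D_sc_cm2_s),
    h      = as.numeric(j$h_um),
    k_bulk = if (!is.null(j$k_bulk_per_s)) as.numeric(j$k_bulk_per_s) else 0,
    k_surf = if (!is.null(j$k_surf_cm_s)) as.numeric(j$k_surf_cm_s) else 0,
    k_evap = if (!is.null(j$k_evap_cm_s)) as.numeric(j$k_evap_cm_s) else 0,
    P_vap  = if (!is.null(j$P_vap_mmHg)) as.numeric(j$P_vap_mmHg) else NA_real_,
    beta   = if (!is.null(j$beta)) as.numeric(j$beta) else 0.1)
}

#' Preset dimensionless scenarios
#'
#' Named presets used throughout the documentation and tests:
#' \describe{
#'   \item{`"VX"`}{`Da = 0.88`, `pi_surf = 0.17`: VX decontaminated with
#'     RSDL, surface loss by evaporation only. Diffusion-dominated.}
#'   \item{`"strong-decon"`}{`Da = 10`, `pi_surf = 11.2`: strongly reactive
#'     decontaminant on a highly volatile agent (surface-loss number from
#'     Tabun evaporation). Bulk reaction-dominated.}
#'   \item{`"Tabun-evaporation"`}{`pi_surf = 11.2` with `Da` settable via
#'     `Da`; volatile-agent surface clearance.}
#'   \item{`"pure-diffusion"`}{`Da = 0`, `pi_surf = 0`: absorption is the
#'     only removal pathway.}
#' }
#' All presets use `beta = 0.1`.
#'
#' @param name Preset name (case-insensitive).
#' @param Da Damkohler number for the `"Tabun-evaporation"` preset
#'   (default 0).
#' @return A [decon_scenario()].
#' @examples
#' decon_fixture("strong-decon")
#' @export
decon_fixture <- function(name, Da = 0) {
  switch(tolower(name),
    "vx" = decon_scenario(0.88, 0.17),
    "strong-decon" = decon_scenario(10, 11.2),
    "tabun-evaporation" = decon_scenario(Da, 11.2,
                                         kappa_evap = 11.2, Da_surf = 0),
    "pure-diffusion" = decon_scenario(0, 0),
    stop("unknown fixture: ", name,
         " (available: VX, strong-decon, Tabun-evaporation, pure-diffusion)",
         call. = FALSE))
}

# -- validation helpers -------------------------------------------------------

check_num <- function(x, field, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", field), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0 (got %g)", field, x), call. = FALSE)
  if (!positive && x < 0)
    stop(sprintf("`%s` must be >= 0 (got %g)", field, x), call. = FALSE)
  invisible(x)
}

check_beta <- function(beta) {
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) ||
      beta <= 0 || beta > 1)
    stop(sprintf("`beta` must lie in (0, 1] (got %s)",
                 format(beta)), call. = FALSE)
  invisible(beta)
}

as_decon_scenario <- function(x) {
  if (inherits(x, "decon_scenario")) return(x)
  if (inherits(x, "agent_scenario")) return(dimensionless_groups(x)$scenario)
  stop("expected a `decon_scenario` or `agent_scenario` object", call. = FALSE)
}
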