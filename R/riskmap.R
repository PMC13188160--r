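#' Steady-state absorption risk map over the Da-pi_surf plane
#'
#' Evaluates the closed-form steady-state absorbed fraction
#' ([steady_fractions()]) on a rectangular grid of the two dimensionless
#' groups and labels each cell as `"high-risk"` (absorbed fraction above
#' `high`, i.e. the majority of the agent reaches the systemic circulation),
#' `"safer"` (below `low`), or `"intermediate"`. Default axis ranges cover
#' the parameter sweep representative of chemical-warfare-agent literature:
#' `Da` in `[0, 10]`, `pi_surf` in `[0.4, 2]`.
#'
#' @param da_range,pi_range Length-2 numeric ranges for the axes.
#' @param resolution Number of grid points per axis (>= 2); default 101.
#' @param beta Deposit depth fraction; default 0.1.
#' @param low,high Zone thresholds on the absorbed fraction: safer below
#'   `low` (default 0.20), high-risk above `high` (default 0.50).
#' @return Object of class `"risk_map"`: list with `da_axis`, `pi_axis`,
#'   matrix `m_abs_inf` (rows = Da, columns = pi_surf), character matrix
#'   `zone`, and the parameters.
#' @examples
#' rm <- build_risk_map(resolution = 21)
#' table(rm$zone)
#' @export
build_risk_map <- function(da_range = c(0, 10), pi_range = c(0.4, 2),
                           resolution = 101, beta = 0.1,
                           low = 0.20, high = 0.50) {
  stopifnot(length(da_range) == 2, length(pi_range) == 2)
  if (diff(da_range) <= 0 || diff(pi_range) <= 0)
    stop("axis ranges must be non-degenerate (max > min)", call. = FALSE)
  if (resolution < 2) stop("`resolution` must be >= 2", call. = FALSE)
  check_beta(beta)
  da_axis <- seq(da_range[1], da_range[2], length.out = resolution)
  pi_axis <- seq(pi_range[1], pi_range[2], length.out = resolution)
  m <- outer(da_axis, pi_axis, Vectorize(function(d, p)
    steady_fractions(decon_scenario(d, p, beta))$M_abs_inf))
  zone <- matrix("intermediate", nrow(m), ncol(m))
  zone[m < low] <- "safer"
  zone[m > high] <- "high-risk"
  structure(list(da_axis = da_axis, pi_axis = pi_axis, m_abs_inf = m,
                 zone = zone, beta = beta, low = low, high = high),
            class = "risk_map")
}

#' @export
print.risk_map <- function(x, ...) {
  cat(sprintf(
    "Absorption risk map: %d x %d grid, Da in [%g, %g], pi_surf in [%g, %g], beta = %g\n",
    length(x$da_axis), length(x$pi_axis), min(x$da_axis), max(x$da_axis),
    min(x$pi_axis), max(x$pi_axis), x$beta))
  cat(sprintf("  M_abs(Inf) range [%.4f, %.4f]; zones: %s\n",
              min(x$m_abs_inf), max(x$m_abs_inf),
              paste(sprintf("%s %d", names(table(x$zone)), table(x$zone)),
                    collapse = ", ")))
  invisible(x)
}

#' Plot a risk map as a filled heat map with the safer-zone contour
#'
#' @param x A `"risk_map"` object.
#' @param ... Further arguments passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.risk_map <- function(x, ...) {
  pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  graphics::image(x$da_axis, x$pi_axis, x$m_abs_inf, col = pal,
                  xlab = "Da", ylab = expression(pi[surf]), ...)
  graphics::contour(x$da_axis, x$pi_axis, x$m_abs_inf,
                    levels = c(x$low, x$high), lwd = 2, add = TRUE,
                    labcex = 0.9)
  graphics::title(main = sprintf(
    "Steady-state absorbed fraction (beta = %g)", x$beta))
  invisible(x)
}

#' Export a risk map as long-format CSV
#'
#' Columns `da, pi_surf, m_abs_inf, zone`, one row per grid cell, full double
#' precision.
#'
#' @param map A `"risk_map"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_risk_map_csv <- function(map, path) {
  stopifnot(inherits(map, "risk_map"))
  df <- expand.grid(da = map$da_axis, pi_surf = map$pi_axis,
                    KEEP.OUT.ATTRS = FALSE)
  df$m_abs_inf <- as.vector(map$m_abs_inf)
  df$zone <- as.vector(map$zone)
  write_csv_full(df, path)
}
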